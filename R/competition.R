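#' Parameters of the two-strain resource-competition model
#'
#' Builds a validated parameter set for within-colony competition between a
#' cooperator strain (C) and a defector strain (D) sharing a finite nutrient
#' pool. The pool size accessible to a colony, `N0`, is a sigmoidal function
#' of the initial cooperator proportion (see [nutrient_access()]): cooperators
#' expand the colony and thereby the nutrients it can reach, from `N_min`
#' (pure defectors, no expansion) up to `N_max` (pure cooperators).
#'
#' Under `kinetics = "zeroth_order"` both strains grow exponentially at
#' per-capita rates `Y_C * q` and `Y_D * q` while nutrients remain, and stop
#' instantly when cumulative consumption reaches `N0`. Under
#' `kinetics = "monod"` every rate carries the saturation factor
#' `N / (K_n + N)`.
#'
#' @param q Nutrient uptake rate per cell (nutrient cell^-1 h^-1).
#' @param K_n Monod half-saturation constant (nutrient units); only used when
#'   `kinetics = "monod"`.
#' @param Y_C,Y_D Growth yields of cooperators and defectors
#'   (cells nutrient^-1). Costly cooperation corresponds to `Y_C < Y_D`.
#' @param N_min,N_max Nutrients accessible to a pure-defector and a
#'   pure-cooperator colony respectively (nutrient units), `0 < N_min <= N_max`.
#' @param g_sat Steepness of the sigmoidal nutrient-access curve
#'   (dimensionless); `g_sat = 0` selects the exact linear limit.
#' @param p_half Midpoint of the sigmoid on the proportion axis, in `[0, 1]`.
#' @param duration Competition length in hours.
#' @param kinetics `"zeroth_order"` (default) or `"monod"`.
#'
#' @return An object of class `competition_params`.
#' @seealso [nutrient_access()], [run_competition()], [response_curves()]
#' @export
#' @examples
#' pars <- competition_params(Y_C = 0.8, Y_D = 1, N_min = 1e6, N_max = 4e6)
#' run_competition(0.5, 1e6, pars)
competition_params <- function(q = 1, K_n = 0, Y_C, Y_D, N_min, N_max,
                               g_sat = 12, p_half = 0.25, duration = 24,
                               kinetics = c("zeroth_order", "monod")) {
  kinetics <- match.arg(kinetics)
  p <- list(q = q, K_n = K_n, Y_C = Y_C, Y_D = Y_D, N_min = N_min,
            N_max = N_max, g_sat = g_sat, p_half = p_half,
            duration = duration, kinetics = kinetics)
  if (!all(vapply(p[names(p) != "kinetics"], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all competition parameters must be finite scalars", call. = FALSE)
  stopifnot(q > 0, K_n >= 0, Y_C > 0, Y_D > 0,
            N_min > 0, N_min <= N_max, duration > 0,
            g_sat >= 0, p_half >= 0, p_half <= 1)
  structure(p, class = "competition_params")
}

#' Parameters of the growth-driven cooperation variant
#'
#' In the growth-driven model the nutrient pool is fixed at `N_0_fixed` and
#' cooperation instead raises the per-cell uptake rate: `q(p_i)` interpolates
#' linearly between `q_D` (pure defectors) and `q_C` (pure cooperators).
#' Because the pool does not grow with cooperator proportion, the group
#' benefit is transient — it vanishes once every colony exhausts its
#' nutrients.
#'
#' @param q_D,q_C Uptake rates of pure-defector and pure-cooperator
#'   populations (nutrient cell^-1 h^-1), `q_C >= q_D > 0`. Defaults 0.5 and 1.
#' @param N_0_fixed Fixed nutrient pool (nutrient units).
#' @inheritParams competition_params
#' @return An object of class `growth_driven_params`.
#' @seealso [run_growth_driven()]
#' @export
growth_driven_params <- function(q_D = 0.5, q_C = 1, N_0_fixed, K_n = 0,
                                 Y_C, Y_D, duration = 24,
                                 kinetics = c("zeroth_order", "monod")) {
  kinetics <- match.arg(kinetics)
  p <- list(q_D = q_D, q_C = q_C, N_0_fixed = N_0_fixed, K_n = K_n,
            Y_C = Y_C, Y_D = Y_D, duration = duration, kinetics = kinetics)
  if (!all(vapply(p[names(p) != "kinetics"], function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))))
    stop("all growth-driven parameters must be finite scalars", call. = FALSE)
  stopifnot(q_D > 0, q_C >= q_D, N_0_fixed > 0, K_n >= 0,
            Y_C > 0, Y_D > 0, duration > 0)
  structure(p, class = "growth_driven_params")
}

#' @export
print.competition_params <- function(x, ...) {
  cat("Two-strain competition parameters (", x$kinetics, " kinetics)\n",
      sep = "")
  cat(sprintf("  yields Y_C = %g, Y_D = %g (ratio %.3f)\n",
              x$Y_C, x$Y_D, x$Y_C / x$Y_D))
  cat(sprintf("  nutrient access N0: %g (p=0) to %g (p=1), g_sat = %g, p_half = %g\n",
              x$N_min, x$N_max, x$g_sat, x$p_half))
  cat(sprintf("  q = %g, K_n = %g, duration = %g h\n", x$q, x$K_n, x$duration))
  invisible(x)
}

#' @export
print.growth_driven_params <- function(x, ...) {
  cat("Growth-driven cooperation parameters (", x$kinetics, " kinetics)\n",
      sep = "")
  cat(sprintf("  uptake q(p): %g (p=0) to %g (p=1); fixed pool N0 = %g\n",
              x$q_D, x$q_C, x$N_0_fixed))
  cat(sprintf("  yields Y_C = %g, Y_D = %g; duration = %g h\n",
              x$Y_C, x$Y_D, x$duration))
  invisible(x)
}

#' Nutrients accessible to a colony as a function of cooperator proportion
#'
#' Diminishing-returns group benefit: the pool is
#' `N0(p) = N_min + (N_max - N_min) * S(p)` where `S` is a logistic in `p`
#' with steepness `g_sat` and midpoint `p_half`, affinely rescaled so that
#' `S(0) = 0` and `S(1) = 1` exactly. `g_sat = 0` gives the linear limit
#' `S(p) = p` (a benefit without diminishing returns).
#'
#' @param p_init Initial cooperator proportion(s) in `[0, 1]`; vectorized.
#' @param params A [competition_params()] object.
#' @return Nutrient amount(s) in `[N_min, N_max]`, non-decreasing in `p_init`.
#' @export
#' @examples
#' pars <- competition_params(Y_C = 0.8, Y_D = 1, N_min = 1e6, N_max = 4e6)
#' nutrient_access(c(0, 0.5, 1), pars)
nutrient_access <- function(p_init, params) {
  stopifnot(inherits(params, "competition_params"))
  if (any(!is.finite(p_init)) || any(p_init < 0) || any(p_init > 1))
    stop("p_init must lie in [0, 1]", call. = FALSE)
  S <- .saturation(p_init, params$g_sat, params$p_half)
  params$N_min + (params$N_max - params$N_min) * S
}

# rescaled logistic; exact linear limit at g_sat = 0
.saturation <- function(p, g_sat, p_half) {
  if (g_sat == 0) return(p)
  L <- stats::plogis(g_sat * (p - p_half))
  L0 <- stats::plogis(g_sat * (0 - p_half))
  L1 <- stats::plogis(g_sat * (1 - p_half))
  (L - L0) / (L1 - L0)
}

# Vectorized exact solution of the zeroth-order competition:
# C'(t) = aC*C, D'(t) = aD*D while consumed(t) < N0, growth frozen after.
# consumed(t) = (C0/Y_C)(e^{aC t}-1) + (D0/Y_D)(e^{aD t}-1).
# Exhaustion time solved by safeguarded Newton started from the fastest
# single-strain closed form (an upper bound on consumption, hence a point
# where G >= N0; G is convex so Newton descends monotonically to the root).
.zeroth_order_outcome <- function(C0, D0, N0, Y_C, Y_D, q, duration) {
  n <- max(length(C0), length(D0), length(N0), length(q))
  C0 <- rep_len(C0, n); D0 <- rep_len(D0, n); N0 <- rep_len(N0, n)
  q <- rep_len(q, n)
  aC <- Y_C * q; aD <- Y_D * q
  G <- function(t, j) {
    (C0[j] / Y_C) * (exp(pmin(aC[j] * t, 700)) - 1) +
      (D0[j] / Y_D) * (exp(pmin(aD[j] * t, 700)) - 1)
  }
  Gp <- function(t, j) {
    q[j] * (C0[j] * exp(pmin(aC[j] * t, 700)) +
              D0[j] * exp(pmin(aD[j] * t, 700)))
  }
  all_j <- seq_len(n)
  # single-strain exhaustion times; min over present strains bounds t* above
  tC <- ifelse(C0 > 0, log1p(Y_C * N0 / pmax(C0, .Machine$double.xmin)) / aC, Inf)
  tD <- ifelse(D0 > 0, log1p(Y_D * N0 / pmax(D0, .Machine$double.xmin)) / aD, Inf)
  t0 <- pmin(tC, tD)

  exhausted <- G(duration, all_j) >= N0 & N0 > 0
  tstar <- rep(duration, n)
  tstar[N0 <= 0] <- 0
  idx <- which(exhausted)
  if (length(idx)) {
    t <- pmin(t0[idx], duration)
    for (iter in 1:100) {
      g <- G(t, idx) - N0[idx]
      step <- g / Gp(t, idx)
      t <- pmax(t - step, 0)
      if (all(abs(g) <= 1e-13 * N0[idx])) break
    }
    tstar[idx] <- t
  }
  Cf <- C0 * exp(aC * tstar)
  Df <- D0 * exp(aD * tstar)
  consumed <- pmin(G(tstar, all_j), N0)
  list(C_final = Cf, D_final = Df, N_final = pmax(N0 - consumed, 0),
       t_end = tstar, exhausted = exhausted | N0 <= 0)
}

.outcome_frame <- function(p_init, C0, D0, Cf, Df, N0, Nf, t_end) {
  tot0 <- C0 + D0
  totf <- Cf + Df
  pf <- ifelse(totf > 0, Cf / totf, p_init)
  data.frame(p_init = p_init, p_final = pf, delta_p_i = pf - p_init,
             w_i = totf / tot0, C_final = Cf, D_final = Df,
             N_0 = N0, N_consumed = N0 - Nf, t_end = t_end)
}

#' Simulate one within-colony competition
#'
#' Runs the two-strain competition at a given initial cooperator proportion.
#' The nutrient pool is `N0 = nutrient_access(p_init, params)`; both strains
#' consume at per-cell rate `q` and convert nutrients at their own yields.
#' With zeroth-order kinetics the default solver is the exact semianalytic
#' solution; `solver = "ode"` integrates the ODE system with event-detected
#' nutrient exhaustion instead (the two agree to better than 1e-6 and the
#' ODE route is kept as an independent cross-check). Monod kinetics always
#' use the ODE.
#'
#' @param p_init Initial cooperator proportion in `[0, 1]`.
#' @param total_inoculum Total founding cells (cooperators plus defectors).
#' @param params A [competition_params()] object.
#' @param solver `"auto"` (semianalytic for zeroth order, ODE for Monod),
#'   `"semianalytic"`, or `"ode"`.
#' @return A one-row data frame of class `competition_outcome` with columns
#'   `p_init`, `p_final`, `delta_p_i`, `w_i` (final over initial total cells),
#'   `C_final`, `D_final`, `N_0`, `N_consumed`, `t_end`.
#' @export
#' @examples
#' pars <- competition_params(Y_C = 0.8, Y_D = 1, N_min = 1e6, N_max = 4e6)
#' run_competition(0.17, 1e6, pars)
run_competition <- function(p_init, total_inoculum, params,
                            solver = c("auto", "semianalytic", "ode")) {
  solver <- match.arg(solver)
  stopifnot(inherits(params, "competition_params"), total_inoculum > 0)
  if (!is.finite(p_init) || p_init < 0 || p_init > 1)
    stop("p_init must lie in [0, 1]", call. = FALSE)
  if (params$kinetics == "monod" || solver == "ode")
    return(.run_competition_ode(p_init, total_inoculum, params))
  run_competition_semianalytic(p_init, total_inoculum, params)
}

#' Exact semianalytic solution of the zeroth-order competition
#'
#' Solves the nutrient-exhaustion time `t*` from
#' `(C0/Y_C)(e^{Y_C q t*} - 1) + (D0/Y_D)(e^{Y_D q t*} - 1) = N0`
#' by safeguarded Newton iteration (the consumption curve is convex and
#' increasing, so the iteration started from the fastest single-strain bound
#' converges monotonically), then evaluates the exponential-growth solution.
#' If nutrients are not exhausted within `duration` the outcome at
#' `t = duration` is returned with `N_consumed < N_0`.
#'
#' @inheritParams run_competition
#' @return As [run_competition()].
#' @export
run_competition_semianalytic <- function(p_init, total_inoculum, params) {
  stopifnot(inherits(params, "competition_params"),
            params$kinetics == "zeroth_order", total_inoculum > 0)
  if (!is.finite(p_init) || p_init < 0 || p_init > 1)
    stop("p_init must lie in [0, 1]", call. = FALSE)
  C0 <- p_init * total_inoculum
  D0 <- (1 - p_init) * total_inoculum
  N0 <- nutrient_access(p_init, params)
  z <- .zeroth_order_outcome(C0, D0, N0, params$Y_C, params$Y_D, params$q,
                             params$duration)
  out <- .outcome_frame(p_init, C0, D0, z$C_final, z$D_final, N0, z$N_final,
                        z$t_end)
  class(out) <- c("competition_outcome", "data.frame")
  out
}

# deSolve route: lsodar with a terminal root at N = 0 (zeroth order) or a
# plain integration to `duration` (Monod; N only reaches 0 asymptotically).
.run_competition_ode <- function(p_init, total_inoculum, params,
                                 q_override = NULL, N0_override = NULL) {
  C0 <- p_init * total_inoculum
  D0 <- (1 - p_init) * total_inoculum
  q <- if (is.null(q_override)) params$q else q_override
  N0 <- if (is.null(N0_override)) nutrient_access(p_init, params) else N0_override
  monod <- params$kinetics == "monod"
  K_n <- params$K_n
  Y_C <- params$Y_C; Y_D <- params$Y_D
  deriv <- function(t, y, parms) {
    f <- if (monod) max(y[3], 0) / (K_n + max(y[3], 0)) else as.numeric(y[3] > 0)
    list(c(Y_C * q * f * y[1], Y_D * q * f * y[2], -q * f * (y[1] + y[2])))
  }
  y0 <- c(C = C0, D = D0, N = N0)
  atol <- 1e-10 * max(N0, total_inoculum, 1)
  if (monod) {
    sol <- deSolve::ode(y0, times = c(0, params$duration), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-10, atol = atol)
  } else {
    sol <- deSolve::ode(y0, times = c(0, params$duration), func = deriv,
                        parms = NULL, method = "lsodar",
                        rootfun = function(t, y, parms) y[3],
                        rtol = 1e-10, atol = atol)
  }
  if (any(!is.finite(sol[nrow(sol), ])))
    stop("ODE integration failed; last state: ",
         paste(utils::capture.output(sol[nrow(sol), ]), collapse = " "),
         call. = FALSE)
  last <- sol[nrow(sol), ]
  out <- .outcome_frame(p_init, C0, D0, max(last[["C"]], 0),
                        max(last[["D"]], 0), N0, max(last[["N"]], 0),
                        last[["time"]])
  class(out) <- c("competition_outcome", "data.frame")
  out
}

#' Simulate growth-driven cooperation
#'
#' Same dynamics as [run_competition()] but cooperation raises the uptake
#' rate rather than the nutrient pool: `q(p) = q_D + (q_C - q_D) * p` and the
#' pool is fixed at `N_0_fixed`. Once every colony exhausts its nutrients the
#' final colony size is set by the pool and the yields alone, so the group
#' benefit of faster growth is transient.
#'
#' @inheritParams run_competition
#' @param params A [growth_driven_params()] object.
#' @return As [run_competition()].
#' @export
run_growth_driven <- function(p_init, total_inoculum, params,
                              solver = c("auto", "semianalytic", "ode")) {
  solver <- match.arg(solver)
  stopifnot(inherits(params, "growth_driven_params"), total_inoculum > 0)
  if (!is.finite(p_init) || p_init < 0 || p_init > 1)
    stop("p_init must lie in [0, 1]", call. = FALSE)
  q_p <- params$q_D + (params$q_C - params$q_D) * p_init
  if (params$kinetics == "monod" || solver == "ode") {
    cp <- competition_params(q = q_p, K_n = params$K_n, Y_C = params$Y_C,
                             Y_D = params$Y_D, N_min = params$N_0_fixed,
                             N_max = params$N_0_fixed,
                             duration = params$duration,
                             kinetics = params$kinetics)
    return(.run_competition_ode(p_init, total_inoculum, cp,
                                q_override = q_p,
                                N0_override = params$N_0_fixed))
  }
  C0 <- p_init * total_inoculum
  D0 <- (1 - p_init) * total_inoculum
  z <- .zeroth_order_outcome(C0, D0, params$N_0_fixed, params$Y_C,
                             params$Y_D, q_p, params$duration)
  out <- .outcome_frame(p_init, C0, D0, z$C_final, z$D_final,
                        params$N_0_fixed, z$N_final, z$t_end)
  class(out) <- c("competition_outcome", "data.frame")
  out
}

#' Within-colony selection and fitness response curves
#'
#' Evaluates the competition model over a grid of initial cooperator
#' proportions, returning the within-colony proportion change
#' `delta_p_i(p_i)` (individual-level selection) and the colony fitness
#' `w_i(p_i)` (group-level selection). This table is the interpolation
#' surface consumed by the multilevel-selection engine.
#'
#' @param params A [competition_params()] or [growth_driven_params()] object.
#' @param grid Proportions in `[0, 1]`; must be non-empty.
#' @param total_inoculum Founding cells per colony (equal across colonies).
#' @param solver Passed to the per-colony simulators.
#' @return A data frame ordered by `p_init` with the columns of
#'   [run_competition()].
#' @export
#' @examples
#' pars <- competition_params(Y_C = 0.8, Y_D = 1, N_min = 1e6, N_max = 4e6)
#' head(response_curves(pars, seq(0, 1, by = 0.25)))
response_curves <- function(params, grid, total_inoculum = 1e6,
                            solver = c("auto", "semianalytic", "ode")) {
  solver <- match.arg(solver)
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (any(!is.finite(grid)) || any(grid < 0) || any(grid > 1))
    stop("grid values must lie in [0, 1]", call. = FALSE)
  grid <- sort(grid)
  runner <- if (inherits(params, "growth_driven_params"))
    run_growth_driven else run_competition
  if (solver == "auto" && params$kinetics == "zeroth_order") {
    # vectorized exact path
    C0 <- grid * total_inoculum
    D0 <- (1 - grid) * total_inoculum
    if (inherits(params, "growth_driven_params")) {
      N0 <- rep_len(params$N_0_fixed, length(grid))
      q <- params$q_D + (params$q_C - params$q_D) * grid
    } else {
      N0 <- nutrient_access(grid, params)
      q <- params$q
    }
    z <- .zeroth_order_outcome(C0, D0, N0, params$Y_C, params$Y_D, q,
                               params$duration)
    out <- .outcome_frame(grid, C0, D0, z$C_final, z$D_final, N0, z$N_final,
                          z$t_end)
    rownames(out) <- NULL
    return(out)
  }
  out <- do.call(rbind, lapply(grid, function(p)
    runner(p, total_inoculum, params, solver = solver)))
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Reference parameter sets for the three cooperation regimes
#'
#' Canonical synthetic parameter sets used throughout the package's examples
#' and tests, one per qualitative regime of swarming cooperation:
#' \describe{
#'   \item{`costly`}{Constitutively induced cooperation: cooperators pay a
#'     yield cost (`Y_C/Y_D = 0.8`) and the group benefit saturates strongly
#'     past `p ~ 0.5` (steep sigmoid, midpoint 0.25) — strong diminishing
#'     returns.}
#'   \item{`wildtype`}{Metabolically prudent cooperation: a marginal yield
#'     advantage (`Y_C/Y_D = 1.05`) and a near-linear nutrient-access curve
#'     (no diminishing returns).}
#'   \item{`neutral`}{As `wildtype` but with exactly equal yields; the
#'     individual level is neutral and only the group benefit acts.}
#'   \item{`growth_driven`}{Fixed nutrient pool with uptake rate rising from
#'     `q_D = 0.5` to `q_C = 1` and a cooperator yield cost; benefits are
#'     transient.}
#' }
#'
#' @param regime One of `"costly"`, `"wildtype"`, `"neutral"`,
#'   `"growth_driven"`.
#' @param duration Competition length in hours (default 24).
#' @return A [competition_params()] or [growth_driven_params()] object.
#' @export
#' @examples
#' example_params("costly")
example_params <- function(regime = c("costly", "wildtype", "neutral",
                                      "growth_driven"),
                           duration = 24) {
  regime <- match.arg(regime)
  switch(regime,
    costly = competition_params(q = 1, Y_C = 0.8, Y_D = 1, N_min = 1e6,
                                N_max = 4e6, g_sat = 12, p_half = 0.25,
                                duration = duration),
    wildtype = competition_params(q = 1, Y_C = 1.05, Y_D = 1, N_min = 1e6,
                                  N_max = 4e6, g_sat = 0, p_half = 0.5,
                                  duration = duration),
    neutral = competition_params(q = 1, Y_C = 1, Y_D = 1, N_min = 1e6,
                                 N_max = 4e6, g_sat = 0, p_half = 0.5,
                                 duration = duration),
    growth_driven = growth_driven_params(q_D = 0.5, q_C = 1, N_0_fixed = 8e6,
                                         Y_C = 0.8, Y_D = 1,
                                         duration = duration))
}
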