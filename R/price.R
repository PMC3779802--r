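#' Price-equation partition of selection on cooperator frequency
#'
#' Partitions the change in the global cooperator proportion across a set of
#' subpopulations (colonies) into its two selection components:
#' \deqn{\Delta p = \underbrace{\mathrm{Cov}(w_i, p_i)/E(w_i)}_{\text{group}}
#'       + \underbrace{E(w_i \Delta p_i)/E(w_i)}_{\text{individual}}}
#' where `p_i` is a colony's initial cooperator proportion, `Delta p_i` its
#' within-colony change and `w_i` its fitness (final over initial size).
#' All expectations are weighted by the supplied group weights (relative
#' inocula or probability masses). The pooled final proportion is also
#' computed directly as `sum(weight * w * p_final) / sum(weight * w)` and the
#' partition identity is verified against it.
#'
#' @param groups Data frame with columns `p_init`, `p_final`, `w` (alias
#'   `w_i` accepted) and optionally `weight` (default equal weights).
#' @return An object of class `price_decomposition`: list with
#'   `delta_p_global`, `group_term`, `individual_term`, `mean_fitness`,
#'   `p_initial`, `p_final`.
#' @export
#' @examples
#' g <- data.frame(p_init = c(0.2, 0.8), p_final = c(0.1, 0.7), w = c(1, 3))
#' price_decompose(g)  # group +0.15, individual -0.10, net +0.05
price_decompose <- function(groups) {
  stopifnot(is.data.frame(groups), nrow(groups) >= 1)
  if (!"w" %in% names(groups) && "w_i" %in% names(groups))
    groups$w <- groups$w_i
  need <- c("p_init", "p_final", "w")
  if (!all(need %in% names(groups)))
    stop("groups must have columns p_init, p_final, w", call. = FALSE)
  wt <- if ("weight" %in% names(groups)) groups$weight
        else rep(1, nrow(groups))
  if (any(wt < 0) || sum(wt) <= 0)
    stop("weights must be non-negative and not all zero", call. = FALSE)
  if (any(groups$p_init < 0 | groups$p_init > 1 |
          groups$p_final < 0 | groups$p_final > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  wt <- wt / sum(wt)
  p <- groups$p_init; pf <- groups$p_final; w <- groups$w
  Ew <- sum(wt * w)
  if (Ew <= 0)
    stop("degenerate pool: mean fitness is zero", call. = FALSE)
  p_bar <- sum(wt * p)
  group_term <- (sum(wt * w * p) - Ew * p_bar) / Ew
  individual_term <- sum(wt * w * (pf - p)) / Ew
  p_pooled <- sum(wt * w * pf) / Ew
  delta_p <- p_pooled - p_bar
  if (abs((group_term + individual_term) - delta_p) > 1e-9)
    stop("internal error: Price partition identity violated", call. = FALSE)
  structure(list(delta_p_global = delta_p, group_term = group_term,
                 individual_term = individual_term, mean_fitness = Ew,
                 p_initial = p_bar, p_final = p_pooled),
            class = "price_decomposition")
}

#' @export
print.price_decomposition <- function(x, ...) {
  cat(sprintf(
    "Price decomposition: delta_p = %+.6g (group %+.6g, individual %+.6g)\n",
    x$delta_p_global, x$group_term, x$individual_term))
  cat(sprintf("  p: %.6g -> %.6g; mean fitness E(w) = %.6g\n",
              x$p_initial, x$p_final, x$mean_fitness))
  invisible(x)
}

#' Precompute the within-colony response surface
#'
#' Evaluates [response_curves()] on a fine proportion grid and wraps the
#' `delta_p_i(p)` and `w_i(p)` curves in interpolators (natural spline for
#' the proportion change; monotonicity-preserving Hermite spline for
#' fitness). The multilevel-selection routines evaluate this surface for
#' every subpopulation instead of re-integrating the competition model.
#'
#' @inheritParams response_curves
#' @param n_grid Number of grid points on `[0, 1]` (default 401).
#' @return An object of class `response_surface` with elements `delta_p(p)`,
#'   `w(p)` (functions), `curves` (the underlying table) and
#'   `all_exhausted` (`TRUE` when every grid colony consumed its whole pool,
#'   `N_final < 1e-6 * N_0`).
#' @export
response_surface <- function(params, total_inoculum = 1e6, n_grid = 401) {
  grid <- seq(0, 1, length.out = n_grid)
  curves <- response_curves(params, grid, total_inoculum)
  delta_fun <- stats::splinefun(curves$p_init, curves$delta_p_i,
                                method = "natural")
  w_fun <- stats::splinefun(curves$p_init, curves$w_i, method = "monoH.FC")
  structure(list(
    delta_p = function(p) delta_fun(p),
    w = function(p) w_fun(p),
    curves = curves,
    params = params,
    total_inoculum = total_inoculum,
    all_exhausted = all(curves$N_0 - curves$N_consumed < 1e-6 * curves$N_0)
  ), class = "response_surface")
}

#' Global selection response under structured seeding
#'
#' For a global cooperator proportion `p_global` and structure strength
#' `sigma`, sets `mu` so the mixing distribution has exact mean `p_global`,
#' forms an ensemble of subpopulations with equal inocula (deterministic
#' probability-weighted quadrature nodes on the X scale by default, or a
#' seeded Monte-Carlo sample), runs the competition model in each, and
#' returns the Price decomposition of the global change.
#'
#' @param p_global Global cooperator proportion, strictly inside `(0, 1)`.
#' @param sigma Structure parameter of the mixing distribution, `>= 0`.
#' @param params Competition parameters ([competition_params()] or
#'   [growth_driven_params()]); ignored when `surface` is supplied.
#' @param n_groups Number of subpopulations (quadrature nodes or draws).
#' @param mode `"quadrature"` (deterministic, default) or `"sampled"`.
#' @param total_inoculum Founding cells per colony.
#' @param seed Seed for `"sampled"` mode.
#' @param surface Optional precomputed [response_surface()].
#' @return A [price_decompose()] result with attributes `mu`, `sigma`,
#'   `mode`.
#' @export
#' @examples
#' dec <- global_response(0.5, 2, example_params("costly"))
#' dec$delta_p_global
global_response <- function(p_global, sigma, params = NULL, n_groups = 201,
                            mode = c("quadrature", "sampled"),
                            total_inoculum = 1e6, seed = NULL,
                            surface = NULL) {
  mode <- match.arg(mode)
  stopifnot(p_global > 0, p_global < 1, sigma >= 0, n_groups >= 1)
  if (is.null(surface)) {
    if (is.null(params)) stop("supply params or surface", call. = FALSE)
    surface <- response_surface(params, total_inoculum)
  }
  if (sigma == 0) {
    p_i <- p_global
    wt <- 1
    mu <- .x_of_p(p_global)
  } else {
    mu <- mu_for_mean(p_global, sigma)
    if (mode == "quadrature") {
      z <- stats::qnorm((seq_len(n_groups) - 0.5) / n_groups)
      p_i <- .p_of_x(mu + sigma * z)
      wt <- rep(1 / n_groups, n_groups)
    } else {
      p_i <- rmixprop(n_groups, mixture_dist(mu, sigma), seed = seed)
      wt <- rep(1 / n_groups, n_groups)
    }
  }
  dp <- surface$delta_p(p_i)
  pf <- pmin(pmax(p_i + dp, 0), 1)
  w <- pmax(surface$w(p_i), 0)
  out <- price_decompose(data.frame(p_init = p_i, p_final = pf, w = w,
                                    weight = wt))
  attr(out, "mu") <- mu
  attr(out, "sigma") <- sigma
  attr(out, "mode") <- mode
  out
}

#' Scan global selection over structure strength and global proportion
#'
#' Fills the `Delta p(p, sigma)` table using deterministic quadrature-mode
#' [global_response()], locates interior equilibria (zero crossings of
#' `Delta p(p)` at each `sigma`; a `+` to `-` crossing is a stable
#' coexistence point), and finds the fixation threshold `sigma*`: the
#' smallest `sigma` at which `Delta p > 0` for every `p` on the grid,
#' refined by bisection to `refine_tol` (grid resolution is part of the
#' reported result).
#'
#' @inheritParams global_response
#' @param p_grid Global proportions to evaluate (default 99 interior points).
#' @param sigma_grid Structure strengths to evaluate (default 0 to 6 by 0.1).
#' @param refine_tol Bisection tolerance for `sigma*` (default 1e-2).
#' @return An object of class `mls_scan`: list with `grid` (data frame
#'   `p, sigma, delta_p, group_term, individual_term`), `sigma_star`
#'   (`NA` when fixation is not reached on the grid), and `equilibria`
#'   (data frame `sigma, p_eq, stable`).
#' @export
mls_scan <- function(params, p_grid = seq(0.01, 0.99, length.out = 99),
                     sigma_grid = seq(0, 6, by = 0.1), n_groups = 201,
                     total_inoculum = 1e6, surface = NULL,
                     refine_tol = 1e-2) {
  stopifnot(length(p_grid) >= 1, length(sigma_grid) >= 1,
            all(p_grid > 0 & p_grid < 1), all(sigma_grid >= 0))
  if (is.null(surface)) surface <- response_surface(params, total_inoculum)
  p_grid <- sort(p_grid); sigma_grid <- sort(sigma_grid)

  delta_row <- function(sigma) {
    lapply(p_grid, function(p)
      global_response(p, sigma, n_groups = n_groups, surface = surface))
  }
  rows <- lapply(sigma_grid, function(s) {
    decs <- delta_row(s)
    data.frame(p = p_grid, sigma = s,
               delta_p = vapply(decs, `[[`, numeric(1), "delta_p_global"),
               group_term = vapply(decs, `[[`, numeric(1), "group_term"),
               individual_term = vapply(decs, `[[`, numeric(1),
                                        "individual_term"))
  })
  grid <- do.call(rbind, rows)

  min_dp <- vapply(rows, function(r) min(r$delta_p), numeric(1))
  sigma_star <- NA_real_
  fix_idx <- which(min_dp > 0)
  if (length(fix_idx)) {
    i <- fix_idx[1]
    if (i == 1) {
      sigma_star <- sigma_grid[1]
    } else {
      lo <- sigma_grid[i - 1]; hi <- sigma_grid[i]
      f <- function(s) min(vapply(
        p_grid, function(p) global_response(p, s, n_groups = n_groups,
                                            surface = surface)$delta_p_global,
        numeric(1)))
      while (hi - lo > refine_tol) {
        mid <- (lo + hi) / 2
        if (f(mid) > 0) hi <- mid else lo <- mid
      }
      sigma_star <- hi  # upper end of bracket: delta_p > 0 holds there
    }
  }

  eq <- do.call(rbind, lapply(rows, function(r) {
    dp <- r$delta_p
    s <- sign(dp)
    cross <- which(s[-length(s)] * s[-1] < 0)
    if (!length(cross)) return(NULL)
    data.frame(
      sigma = r$sigma[1],
      p_eq = vapply(cross, function(j) {
        # linear interpolation of the zero crossing
        p_grid[j] - dp[j] * (p_grid[j + 1] - p_grid[j]) / (dp[j + 1] - dp[j])
      }, numeric(1)),
      stable = vapply(cross, function(j) dp[j] > 0 && dp[j + 1] < 0,
                      logical(1)))
  }))
  if (is.null(eq))
    eq <- data.frame(sigma = numeric(0), p_eq = numeric(0),
                     stable = logical(0))

  structure(list(grid = grid, sigma_star = sigma_star, equilibria = eq,
                 p_grid = p_grid, sigma_grid = sigma_grid,
                 surface = surface),
            class = "mls_scan")
}

#' @export
print.mls_scan <- function(x, ...) {
  cat(sprintf("Multilevel-selection scan: %d p-values x %d sigma-values\n",
              length(x$p_grid), length(x$sigma_grid)))
  if (is.finite(x$sigma_star))
    cat(sprintf("  fixation threshold sigma* = %.2f\n", x$sigma_star))
  else
    cat("  no fixation threshold on the evaluated sigma grid\n")
  ns <- sum(x$equilibria$stable)
  cat(sprintf("  %d interior equilibria (%d stable)\n",
              nrow(x$equilibria), ns))
  invisible(x)
}

#' Direct multilevel-selection calculation by re-sampling competition data
#'
#' Model-free counterpart of [global_response()]: for each pair of initial
#' proportions `(p_low, p_high)`, replicates at the two levels are combined
#' with equal total weight per level into a two-point global population
#' (initial `p = (p_low + p_high)/2`), the pooled `Delta p` is computed via
#' [price_decompose()], and the relatedness of the two-point mixing
#' distribution is `Var/(E(1-E))` with `Var = ((p_high - p_low)/2)^2`.
#' The `(0, 1)` pair gives the asymptotic `r = 1` point.
#'
#' @param dataset A [competition_dataset()] (or data frame with columns
#'   `p_init`, `p_final`, `w_i`).
#' @param pairs List of length-2 numeric vectors `(p_low, p_high)`, or a
#'   two-column matrix/data frame.
#' @param tol Matching tolerance on the recorded proportion levels.
#' @return Data frame with one row per pair: `p_low`, `p_high`, `r`,
#'   `delta_p`, `group_term`, `individual_term`, `n_low`, `n_high`.
#' @export
direct_resample <- function(dataset, pairs, tol = 1e-6) {
  stopifnot(is.data.frame(dataset))
  if (!"w" %in% names(dataset) && "w_i" %in% names(dataset))
    dataset$w <- dataset$w_i
  if (is.matrix(pairs) || is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.numeric(pairs[i, ]))
  out <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    lo <- min(pr); hi <- max(pr)
    rows_lo <- dataset[abs(dataset$p_init - lo) <= tol, , drop = FALSE]
    rows_hi <- dataset[abs(dataset$p_init - hi) <= tol, , drop = FALSE]
    for (lev in list(c(lo, nrow(rows_lo)), c(hi, nrow(rows_hi))))
      if (lev[2] == 0)
        stop(sprintf("dataset has no replicates at p_init = %g", lev[1]),
             call. = FALSE)
    g <- rbind(
      data.frame(p_init = lo, p_final = rows_lo$p_final, w = rows_lo$w,
                 weight = 0.5 / nrow(rows_lo)),
      data.frame(p_init = hi, p_final = rows_hi$p_final, w = rows_hi$w,
                 weight = 0.5 / nrow(rows_hi)))
    dec <- price_decompose(g)
    m <- (lo + hi) / 2
    v <- ((hi - lo) / 2)^2
    data.frame(p_low = lo, p_high = hi, r = v / (m * (1 - m)),
               delta_p = dec$delta_p_global, group_term = dec$group_term,
               individual_term = dec$individual_term,
               n_low = nrow(rows_lo), n_high = nrow(rows_hi))
  })
  do.call(rbind, out)
}

#' Compare global selection across competition durations
#'
#' Re-runs the `Delta p(sigma)` curve at each duration. For
#' expansion-driven cooperation (pool grows with `p_i`) the curve is
#' unchanged once every colony has exhausted its pool — the benefit is
#' time-independent. For growth-driven cooperation the benefit exists only
#' while colonies are still growing; with exhaustion everywhere the
#' cooperator loses at every `sigma`.
#'
#' @param params [competition_params()] or [growth_driven_params()].
#' @param sigma_grid Structure strengths to evaluate.
#' @param durations Competition lengths in hours (default `c(24, 48)`).
#' @param p_global Global cooperator proportion (default 0.5).
#' @inheritParams global_response
#' @return Data frame `duration, sigma, delta_p, group_term,
#'   individual_term, all_exhausted`.
#' @export
compare_durations <- function(params, sigma_grid = seq(0, 6, by = 0.5),
                              durations = c(24, 48), p_global = 0.5,
                              n_groups = 201, total_inoculum = 1e6) {
  out <- lapply(durations, function(d) {
    pd <- params
    pd$duration <- d
    surf <- response_surface(pd, total_inoculum)
    decs <- lapply(sigma_grid, function(s)
      global_response(p_global, s, n_groups = n_groups, surface = surf))
    data.frame(duration = d, sigma = sigma_grid,
               delta_p = vapply(decs, `[[`, numeric(1), "delta_p_global"),
               group_term = vapply(decs, `[[`, numeric(1), "group_term"),
               individual_term = vapply(decs, `[[`, numeric(1),
                                        "individual_term"),
               all_exhausted = surf$all_exhausted)
  })
  do.call(rbind, out)
}
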