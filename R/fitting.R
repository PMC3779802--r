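#' Assemble a replicated competition dataset
#'
#' Validates per-colony count records and derives the analysis columns:
#' final proportion `p_final`, within-colony change `delta_p_i` and colony
#' fitness `w_i` (final over initial total cells).
#'
#' @param x Data frame with columns `p_init`, `replicate`, `C_0`, `D_0`,
#'   `C_final`, `D_final` and optionally `condition` (default
#'   `"default"`). Counts must be non-negative with `C_0 + D_0 > 0`, and
#'   `p_init` must agree with `C_0/(C_0+D_0)` to recording precision.
#' @param tol Tolerance for the `p_init` consistency check (default 0.005).
#' @return The validated data frame with derived columns, classed
#'   `competition_dataset`.
#' @export
competition_dataset <- function(x, tol = 0.005) {
  stopifnot(is.data.frame(x))
  need <- c("p_init", "replicate", "C_0", "D_0", "C_final", "D_final")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"condition" %in% names(x)) x$condition <- "default"
  with(x, stopifnot(all(C_0 >= 0), all(D_0 >= 0), all(C_final >= 0),
                    all(D_final >= 0), all(C_0 + D_0 > 0)))
  if (any(abs(x$p_init - x$C_0 / (x$C_0 + x$D_0)) > tol))
    stop("p_init inconsistent with C_0/(C_0+D_0)", call. = FALSE)
  totf <- x$C_final + x$D_final
  x$p_final <- ifelse(totf > 0, x$C_final / totf, x$p_init)
  x$delta_p_i <- x$p_final - x$p_init
  x$w_i <- totf / (x$C_0 + x$D_0)
  class(x) <- c("competition_dataset", "data.frame")
  x
}

#' Read a competition dataset from CSV
#'
#' @param path CSV file with the [competition_dataset()] schema.
#' @return A `competition_dataset`.
#' @export
read_competition_csv <- function(path) {
  competition_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

.fittable <- c("Y_C", "Y_D", "N_min", "N_max", "g_sat", "p_half")

.default_bounds <- function(total_inoculum) {
  list(Y_C = c(0.05, 20), Y_D = c(0.05, 20),
       N_min = c(1e-3, 100) * total_inoculum,
       N_max = c(1e-3, 100) * total_inoculum,
       g_sat = c(0.05, 100), p_half = c(0, 1))
}

# lean predictor for the optimizer's inner loop: no data-frame assembly,
# no constructor validation (bounds are enforced by the optimizer box and
# the N_max >= N_min guard in the loss)
.predict_dp_w <- function(vals, p_levels, n0) {
  C0 <- p_levels * n0
  D0 <- (1 - p_levels) * n0
  S <- .saturation(p_levels, vals$g_sat, vals$p_half)
  N0 <- vals$N_min + (vals$N_max - vals$N_min) * S
  z <- .zeroth_order_outcome(C0, D0, N0, vals$Y_C, vals$Y_D, vals$q,
                             vals$duration)
  totf <- z$C_final + z$D_final
  pf <- ifelse(totf > 0, z$C_final / totf, p_levels)
  list(dp = pf - p_levels, w = totf / n0)
}

# transform to/from the optimizer scale (log for positive parameters)
.to_theta <- function(vals, free) {
  vapply(free, function(nm)
    if (nm == "p_half") vals[[nm]] else log(vals[[nm]]), numeric(1))
}
.from_theta <- function(theta, free) {
  out <- as.list(theta)
  names(out) <- free
  for (nm in free) if (nm != "p_half") out[[nm]] <- exp(out[[nm]])
  out
}

#' Fit the competition model to replicated data
#'
#' Estimates competition parameters by minimizing a joint weighted
#' least-squares objective over the replicate means of `delta_p_i` and `w_i`
#' at each observed proportion level. The two residual blocks are scaled by
#' the standard deviation of the observations in the block, and each level
#' is weighted by its replicate count. Optimization runs from Latin-
#' hypercube starts within the parameter bounds (plus a data-driven
#' heuristic start), with local refinement of the best candidates.
#'
#' The uptake rate `q` is fixed at 1 by convention: with zeroth-order
#' exhaustion data only the products `Y * q` are identified. Note a second
#' gauge freedom of such data — rescaling both yields by `c` and both
#' nutrient pools by `1/c` leaves every final count unchanged — so the
#' individual yields are identified only up to this scaling while the yield
#' ratio `Y_C/Y_D` is always identified. Fix one yield via `fixed` to pin
#' the gauge when absolute parameter values matter.
#'
#' @param dataset A [competition_dataset()].
#' @param free Character vector of parameters to estimate, a subset of
#'   `Y_C, Y_D, N_min, N_max, g_sat, p_half`.
#' @param fixed Named list of fixed values; defaults
#'   `q = 1, K_n = 0, duration = 24, kinetics = "zeroth_order"` plus any
#'   non-free model parameter.
#' @param bounds Named list of `c(lower, upper)` per free parameter;
#'   sensible defaults relative to the inoculum are used when `NULL`.
#' @param n_starts Number of Latin-hypercube starting points (default 20).
#' @param n_local Number of best starts refined by local optimization
#'   (default 6).
#' @param seed Seed for the start design (makes the fit deterministic).
#' @return An object of class `fit_result`: list with `params`
#'   (a [competition_params()]), `yield_ratio`, `loss`, `estimates`,
#'   `free`, `fixed`, `observed` (per-level summary), `total_inoculum`,
#'   `convergence`.
#' @export
fit_competition <- function(dataset, free = .fittable,
                            fixed = list(), bounds = NULL,
                            n_starts = 20, n_local = 6, seed = 1) {
  stopifnot(inherits(dataset, "competition_dataset") ||
              is.data.frame(dataset))
  free <- match.arg(free, .fittable, several.ok = TRUE)
  base_fixed <- list(q = 1, K_n = 0, duration = 24,
                     kinetics = "zeroth_order")
  fixed <- utils::modifyList(base_fixed, fixed)
  not_free <- setdiff(.fittable, free)
  miss <- setdiff(not_free, names(fixed))
  if (length(miss))
    stop("parameters neither free nor fixed: ",
         paste(miss, collapse = ", "), call. = FALSE)

  obs <- .level_summary(dataset)
  # each level contributes two observables: delta_p_i and w_i
  if (2L * nrow(obs) < length(free))
    stop(sprintf(
      "under-identified: %d proportion levels (%d observables) for %d free parameters",
      nrow(obs), 2L * nrow(obs), length(free)), call. = FALSE)
  n0 <- mean(dataset$C_0 + dataset$D_0)
  if (is.null(bounds)) bounds <- .default_bounds(n0)
  if (!all(free %in% names(bounds)))
    stop("bounds must cover every free parameter", call. = FALSE)

  s_dp <- stats::sd(dataset$delta_p_i)
  s_w <- stats::sd(dataset$w_i)
  if (!is.finite(s_dp) || s_dp <= 0) s_dp <- 1
  if (!is.finite(s_w) || s_w <= 0) s_w <- 1
  wts <- obs$n / sum(obs$n)

  loss_fun <- function(theta) {
    vals <- utils::modifyList(fixed, .from_theta(theta, free))
    if (!all(is.finite(unlist(vals[.fittable]))) ||
        vals$N_max < vals$N_min) return(1e10)
    pred <- .predict_dp_w(vals, obs$p_init, n0)
    sum(wts * (((pred$dp - obs$delta_p) / s_dp)^2 +
                 ((pred$w - obs$w) / s_w)^2))
  }

  lower <- .to_theta(lapply(bounds, `[`, 1), free)
  upper <- .to_theta(lapply(bounds, `[`, 2), free)

  # start candidates: LHS design plus a data-driven heuristic
  set.seed(seed)
  design <- lhs::randomLHS(n_starts, length(free))
  starts <- lapply(seq_len(n_starts), function(i)
    lower + design[i, ] * (upper - lower))
  heur <- list(Y_C = 1, Y_D = 1,
               N_min = max(min(obs$w) - 1, 0.05) * n0,
               N_max = max(max(obs$w) - 1, 0.1) * n0,
               g_sat = 10, p_half = 0.3)
  th <- .to_theta(heur, free)
  starts <- c(starts, list(pmin(pmax(th, lower), upper)))

  pre <- vapply(starts, loss_fun, numeric(1))
  ord <- order(pre)[seq_len(min(n_local, length(starts)))]
  fits <- lapply(starts[ord], function(th)
    stats::nlminb(th, loss_fun, lower = lower, upper = upper,
                  control = list(abs.tol = 1e-12, rel.tol = 1e-10,
                                 iter.max = 500, eval.max = 2000)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (!is.finite(best$objective) || best$objective >= 1e10)
    stop("fit failed to converge from every start; losses: ",
         paste(signif(vapply(fits, `[[`, numeric(1), "objective"), 4),
               collapse = ", "), call. = FALSE)

  est <- .from_theta(best$par, free)
  params <- do.call(competition_params, utils::modifyList(fixed, est))
  structure(list(params = params,
                 yield_ratio = params$Y_C / params$Y_D,
                 loss = best$objective,
                 estimates = est, free = free, fixed = fixed,
                 bounds = bounds, observed = obs, total_inoculum = n0,
                 convergence = best$convergence, seed = seed,
                 theta = best$par, lower = lower, upper = upper),
            class = "fit_result")
}

.level_summary <- function(dataset) {
  lev <- sort(unique(dataset$p_init))
  do.call(rbind, lapply(lev, function(p) {
    d <- dataset[dataset$p_init == p, ]
    data.frame(p_init = p, delta_p = mean(d$delta_p_i), w = mean(d$w_i),
               n = nrow(d))
  }))
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Competition-model fit\n")
  cat(sprintf("  loss = %.4g over %d proportion levels; yield ratio Y_C/Y_D = %.3f\n",
              x$loss, nrow(x$observed), x$yield_ratio))
  est <- unlist(x$estimates)
  cat("  estimates:", paste(sprintf("%s = %.4g", names(est), est),
                            collapse = ", "), "\n")
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap (%d resamples) min-max intervals:\n",
                x$bootstrap$B))
    iv <- x$bootstrap$intervals
    for (nm in rownames(iv))
      cat(sprintf("    %s: [%.4g, %.4g]\n", nm, iv[nm, 1], iv[nm, 2]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for a competition-model fit
#'
#' Case-resampling bootstrap: within each proportion level the replicates
#' are resampled with replacement, the model is refitted (local optimization
#' started from the point estimate), and per-parameter intervals are
#' reported as the min-max over resamples, including the point estimate.
#' A resample that loses a proportion level entirely cannot occur under
#' within-level resampling; a resample whose refit fails is redrawn.
#'
#' @param dataset A [competition_dataset()].
#' @param fit A [fit_competition()] result for `dataset`; fitted afresh when
#'   `NULL` (extra arguments are passed on to [fit_competition()]).
#' @param B Number of bootstrap resamples (default 200). `B = 0` returns
#'   degenerate intervals equal to the point estimate.
#' @param seed Seed controlling the resampling.
#' @param ... Passed to [fit_competition()] when `fit` is `NULL`.
#' @return The `fit_result` with an added `bootstrap` element: list with
#'   `B`, `intervals` (matrix with columns `min`, `max`, rows = free
#'   parameters plus `yield_ratio`) and `estimates` (per-resample matrix).
#' @export
bootstrap_fit <- function(dataset, fit = NULL, B = 200, seed = 1, ...) {
  stopifnot(B >= 0)
  if (is.null(fit)) fit <- fit_competition(dataset, ...)
  free <- fit$free
  draw <- function() {
    idx <- unlist(lapply(unique(dataset$p_init), function(p) {
      rows <- which(dataset$p_init == p)
      sample(rows, length(rows), replace = TRUE)
    }))
    dataset[idx, , drop = FALSE]
  }
  set.seed(seed)
  est <- matrix(NA_real_, nrow = B, ncol = length(free) + 1,
                dimnames = list(NULL, c(free, "yield_ratio")))
  b <- 1
  tries <- 0
  while (b <= B) {
    tries <- tries + 1
    if (tries > 10 * max(B, 1))
      stop("bootstrap refits failing persistently", call. = FALSE)
    d <- draw()
    refit <- try(.refit_from(fit, d), silent = TRUE)
    if (inherits(refit, "try-error")) next
    est[b, ] <- c(unlist(refit$estimates)[free],
                  refit$estimates_ratio)
    b <- b + 1
  }
  point <- c(unlist(fit$estimates)[free], fit$yield_ratio)
  names(point) <- c(free, "yield_ratio")
  all_est <- rbind(point, est)
  intervals <- cbind(min = apply(all_est, 2, min),
                     max = apply(all_est, 2, max))
  fit$bootstrap <- list(B = B, intervals = intervals, estimates = est,
                        seed = seed)
  fit
}

# local refit starting at the point estimate (theta scale)
.refit_from <- function(fit, dataset) {
  obs <- .level_summary(dataset)
  n0 <- fit$total_inoculum
  free <- fit$free; fixed <- fit$fixed
  s_dp <- stats::sd(dataset$delta_p_i)
  s_w <- stats::sd(dataset$w_i)
  if (!is.finite(s_dp) || s_dp <= 0) s_dp <- 1
  if (!is.finite(s_w) || s_w <= 0) s_w <- 1
  wts <- obs$n / sum(obs$n)
  loss_fun <- function(theta) {
    vals <- utils::modifyList(fixed, .from_theta(theta, free))
    if (!all(is.finite(unlist(vals[.fittable]))) ||
        vals$N_max < vals$N_min) return(1e10)
    pred <- .predict_dp_w(vals, obs$p_init, n0)
    sum(wts * (((pred$dp - obs$delta_p) / s_dp)^2 +
                 ((pred$w - obs$w) / s_w)^2))
  }
  sol <- stats::nlminb(fit$theta, loss_fun, lower = fit$lower,
                       upper = fit$upper,
                       control = list(abs.tol = 1e-12, rel.tol = 1e-10,
                                      iter.max = 300, eval.max = 1200))
  est <- .from_theta(sol$par, free)
  vals <- utils::modifyList(fixed, est)
  list(estimates = est, estimates_ratio = vals$Y_C / vals$Y_D,
       loss = sol$objective)
}

#' Predicted response curves from a fitted model
#'
#' Evaluates the fitted competition model over a proportion grid; this is
#' the interpolation surface the multilevel-selection engine consumes.
#'
#' @param fit A [fit_competition()] result.
#' @param grid Proportions in `[0, 1]` (default 101 points).
#' @return As [response_curves()].
#' @export
predict_curves <- function(fit, grid = seq(0, 1, length.out = 101)) {
  stopifnot(inherits(fit, "fit_result"))
  response_curves(fit$params, grid, fit$total_inoculum)
}
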