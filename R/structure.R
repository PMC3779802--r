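#' Logit-normal model of group composition
#'
#' Population structure is described by the distribution of the cooperator
#' mixing proportion `p_i` across colonies: the cooperator-to-defector ratio
#' is log-normal, i.e. `X = log10(C/D) ~ Normal(mu, sigma)` and
#' `p_i = (1 + 10^-X)^-1`. A single parameter `sigma` moves the density from
#' unimodal (well-mixed seeding, low relatedness) to bimodal (strong
#' segregation, high relatedness).
#'
#' @param mu Mean of `X = log10(C/D)`.
#' @param sigma Standard deviation of `X`, `>= 0`.
#' @return An object of class `mixture_dist`.
#' @seealso [dmixprop()], [rmixprop()], [structure_moments()], [relatedness()]
#' @export
#' @examples
#' d <- mixture_dist(0, 4.2)
#' relatedness(d)
mixture_dist <- function(mu, sigma) {
  stopifnot(is.numeric(mu), is.numeric(sigma), length(mu) == 1L,
            length(sigma) == 1L, is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(mu = mu, sigma = sigma), class = "mixture_dist")
}

#' @export
print.mixture_dist <- function(x, ...) {
  cat(sprintf("Logit-normal mixing distribution: log10(C/D) ~ N(%g, %g)\n",
              x$mu, x$sigma))
  invisible(x)
}

# p as a function of X and its inverse
.p_of_x <- function(x) 1 / (1 + 10^(-x))
.x_of_p <- function(p) log10(p / (1 - p))

#' Density of the cooperator mixing proportion
#'
#' Change-of-variables density of `p_i = (1 + 10^-X)^-1`: the normal density
#' of `X` at `log10(p/(1-p))` times the Jacobian `1 / (ln10 * p * (1-p))`.
#' The density is supported on the open interval `(0, 1)`; at the endpoints
#' the value 0 is returned by convention.
#'
#' @param p Proportion(s); vectorized.
#' @param dist A [mixture_dist()] with `sigma > 0`.
#' @return Density values.
#' @export
dmixprop <- function(p, dist) {
  stopifnot(inherits(dist, "mixture_dist"))
  if (dist$sigma <= 0)
    stop("density requires sigma > 0", call. = FALSE)
  out <- numeric(length(p))
  ok <- is.finite(p) & p > 0 & p < 1
  out[ok] <- stats::dnorm(.x_of_p(p[ok]), dist$mu, dist$sigma) /
    (log(10) * p[ok] * (1 - p[ok]))
  out[!is.finite(p)] <- NA_real_
  out
}

#' Draw mixing proportions
#'
#' Samples `X ~ Normal(mu, sigma)` and returns `p_i = (1 + 10^-X)^-1`.
#'
#' @param n Number of draws.
#' @param dist A [mixture_dist()].
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of proportions in `(0, 1)` (degenerate at
#'   `sigma = 0`).
#' @export
rmixprop <- function(n, dist, seed = NULL) {
  stopifnot(inherits(dist, "mixture_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  .p_of_x(stats::rnorm(n, dist$mu, dist$sigma))
}

#' Moments of the mixing distribution and whole-group relatedness
#'
#' Computes `E(p_i)`, `Var(p_i)` and the whole-group relatedness
#' `r = Var(p_i) / (E(p_i) * (1 - E(p_i)))`.
#'
#' `method = "quadrature"` (the default used everywhere relatedness is
#' reported) integrates adaptively on the X (normal) scale, which avoids the
#' endpoint singularity of the Jacobian on the p scale. `"monte_carlo"` uses
#' `n_mc` seeded draws. `"delta"` is the first-order Taylor (Delta-method)
#' approximation `E ~ (1+10^-mu)^-1`, `Var ~ g'(mu)^2 sigma^2`; it is exposed
#' as a labeled diagnostic only, because for large `sigma` it exceeds the
#' logical bound `E(1-E)` (and then its implied relatedness exceeds 1).
#'
#' @param dist A [mixture_dist()].
#' @param method `"quadrature"`, `"monte_carlo"` or `"delta"`.
#' @param n_mc Number of Monte-Carlo draws for `"monte_carlo"`.
#' @param seed Optional seed for `"monte_carlo"`.
#' @return An object of class `structure_moments`: list with `mean_p`,
#'   `var_p`, `relatedness`, `method`.
#' @export
#' @examples
#' structure_moments(mixture_dist(0, 1))
structure_moments <- function(dist,
                              method = c("quadrature", "monte_carlo", "delta"),
                              n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(dist, "mixture_dist"))
  method <- match.arg(method)
  mu <- dist$mu; sigma <- dist$sigma
  if (method == "delta") {
    m <- .p_of_x(mu)
    gprime <- log(10) * m * (1 - m)      # d/dx (1+10^-x)^-1
    v <- gprime^2 * sigma^2
  } else if (sigma == 0) {
    m <- .p_of_x(mu); v <- 0
  } else if (method == "quadrature") {
    f1 <- function(x) .p_of_x(x) * stats::dnorm(x, mu, sigma)
    m <- stats::integrate(f1, -Inf, Inf, rel.tol = 1e-11,
                          abs.tol = 1e-13)$value
    f2 <- function(x) (.p_of_x(x) - m)^2 * stats::dnorm(x, mu, sigma)
    v <- stats::integrate(f2, -Inf, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-13)$value
  } else {
    p <- rmixprop(n_mc, dist, seed = seed)
    m <- mean(p)
    v <- mean((p - m)^2)
  }
  r <- if (m > 0 && m < 1) v / (m * (1 - m)) else NA_real_
  structure(list(mean_p = m, var_p = v, relatedness = r, method = method),
            class = "structure_moments")
}

#' @export
print.structure_moments <- function(x, ...) {
  cat(sprintf("E(p_i) = %.6g, Var(p_i) = %.6g, r = %.4f  [%s]\n",
              x$mean_p, x$var_p, x$relatedness, x$method))
  invisible(x)
}

#' Whole-group relatedness of a mixing distribution
#'
#' `r = Var(p_i) / (E(p_i) * (1 - E(p_i)))` with exact (quadrature) moments:
#' the between-group variance in cooperator proportion relative to its
#' maximum under full segregation. `r = 0` for unstructured populations
#' (`sigma = 0`), `r -> 1` under complete segregation.
#'
#' @param dist A [mixture_dist()].
#' @return Relatedness in `[0, 1]`.
#' @export
#' @examples
#' relatedness(mixture_dist(0, 4.2))  # ~0.84
relatedness <- function(dist) {
  m <- structure_moments(dist, method = "quadrature")
  if (!is.finite(m$relatedness))
    stop("relatedness undefined: mean proportion is degenerate (0 or 1)",
         call. = FALSE)
  m$relatedness
}

#' Locate mu giving a target mean proportion
#'
#' Root-finds `mu` such that the exact (quadrature) mean of the mixing
#' distribution equals `target_mean`; used to hold the global cooperator
#' proportion fixed while scanning `sigma`. At `sigma = 0` the closed form
#' `mu = -log10(1/target - 1)` is returned.
#'
#' @param target_mean Desired `E(p_i)`, strictly inside `(0, 1)`.
#' @param sigma Structure parameter, `>= 0`.
#' @return The value of `mu` (mean proportion reproduced to 1e-8).
#' @export
mu_for_mean <- function(target_mean, sigma) {
  stopifnot(target_mean > 0, target_mean < 1, sigma >= 0)
  if (sigma == 0) return(-log10(1 / target_mean - 1))
  f <- function(mu) structure_moments(mixture_dist(mu, sigma))$mean_p -
    target_mean
  hw <- max(4, 2 * sigma) + abs(log10(target_mean / (1 - target_mean)))
  stats::uniroot(f, c(-hw, hw), tol = 1e-10, extendInt = "upX")$root
}

#' Relatedness under Poisson bottleneck seeding
#'
#' If each colony is founded by `n ~ Poisson(lambda)` cells (colonies with no
#' founders are excluded) and each founder is independently a cooperator with
#' probability `p`, the across-colony variance of the founding proportion is
#' `p(1-p) * E(1/n | n >= 1)`, so the whole-group relatedness is
#' `r = E(1/n | n >= 1)` regardless of `p`. The series is summed to a
#' relative tail below 1e-12.
#'
#' @param lambda Mean founder cells per colony, `> 0`.
#' @return Relatedness in `(0, 1)`; `r -> 1` as `lambda -> 0` (almost every
#'   seeded colony is founded by a single cell).
#' @export
#' @examples
#' poisson_seeding_relatedness(0.65)  # ~0.84
poisson_seeding_relatedness <- function(lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda > 0)
  n_max <- max(30, ceiling(lambda + 15 * sqrt(lambda) + 20))
  repeat {
    n <- seq_len(n_max)
    terms <- (1 / n) * stats::dpois(n, lambda)
    if (terms[n_max] < 1e-12 * sum(terms)) break
    n_max <- n_max * 2
  }
  sum(terms) / (1 - stats::dpois(0, lambda))
}

#' Invert the Poisson-seeding relatedness
#'
#' Finds the mean founder number per colony such that the zero-truncated
#' Poisson seeding model produces a given whole-group relatedness.
#' `r(lambda)` is strictly decreasing, so a monotone bisection applies.
#'
#' @param target_r Relatedness strictly inside `(0, 1)`.
#' @return `lambda` such that [poisson_seeding_relatedness()] equals
#'   `target_r` to 1e-10.
#' @export
#' @examples
#' lambda_for_relatedness(0.84)
lambda_for_relatedness <- function(target_r) {
  if (!is.numeric(target_r) || target_r <= 0 || target_r >= 1)
    stop("target_r must lie strictly inside (0, 1)", call. = FALSE)
  f <- function(lam) poisson_seeding_relatedness(lam) - target_r
  lo <- 1e-8
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
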