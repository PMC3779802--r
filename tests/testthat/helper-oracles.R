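# Independent oracles used across tests.

# Brute-force fixed-step Euler integration of the zeroth-order competition;
# independent of the package's solvers.
euler_competition <- function(p_init, total_inoculum, params, dt = 1e-4) {
  C <- p_init * total_inoculum
  D <- (1 - p_init) * total_inoculum
  N <- nutrient_access(p_init, params)
  t <- 0
  while (t < params$duration && N > 0) {
    cons <- params$q * (C + D) * dt
    if (cons >= N) {
      frac <- N / cons
      C <- C + params$Y_C * params$q * C * dt * frac
      D <- D + params$Y_D * params$q * D * dt * frac
      N <- 0
      break
    }
    C <- C + params$Y_C * params$q * C * dt
    D <- D + params$Y_D * params$q * D * dt
    N <- N - cons
    t <- t + dt
  }
  tot0 <- total_inoculum
  totf <- C + D
  list(p_final = C / totf, delta_p_i = C / totf - p_init, w_i = totf / tot0)
}

# Monte-Carlo oracle for Poisson bottleneck relatedness: simulate colonies,
# drop empty ones, estimate Var(p_i)/(E(p_i)(1-E(p_i))).
mc_seeding_relatedness <- function(lambda, p_global, n_colonies, seed) {
  set.seed(seed)
  n <- stats::rpois(n_colonies, lambda)
  n <- n[n >= 1]
  p_i <- stats::rbinom(length(n), n, p_global) / n
  m <- mean(p_i)
  v <- mean((p_i - m)^2)
  list(r = v / (m * (1 - m)), n_used = length(n), p_i = p_i, mean = m)
}

# random but valid competition parameter set (costly or beneficial)
random_params <- function() {
  Nmin <- runif(1, 0.5e6, 2e6)
  competition_params(
    q = runif(1, 0.5, 2),
    Y_C = runif(1, 0.5, 1.5),
    Y_D = runif(1, 0.5, 1.5),
    N_min = Nmin,
    N_max = Nmin * runif(1, 1, 5),
    g_sat = runif(1, 0.5, 20),
    p_half = runif(1, 0.1, 0.9),
    duration = 24)
}
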