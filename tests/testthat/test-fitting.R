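truth_costly <- example_params("costly")

test_that("dataset constructor validates and derives analysis columns", {
  d <- generate_competitions(synth_config(truth_costly, replicates = 2,
                                          noise_cv = 0, seed = 1))
  expect_s3_class(d, "competition_dataset")
  expect_true(all(c("p_final", "delta_p_i", "w_i") %in% names(d)))
  raw <- as.data.frame(d)[, c("p_init", "replicate", "C_0", "D_0",
                              "C_final", "D_final")]
  bad <- raw
  bad$p_init[1] <- 0.9  # inconsistent with counts
  expect_error(competition_dataset(bad), "inconsistent")
  expect_error(competition_dataset(raw[, -3]), "missing columns")
  # CSV round trip
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(d), f, row.names = FALSE)
  expect_equal(read_competition_csv(f)$w_i, d$w_i)
})

test_that("zero-noise data recover the generating parameters within 1%", {
  d0 <- generate_competitions(synth_config(truth_costly, noise_cv = 0,
                                           seed = 1))
  # fix one yield to pin the yield/nutrient scaling gauge
  fit <- fit_competition(d0, free = c("Y_C", "N_min", "N_max", "g_sat",
                                      "p_half"),
                         fixed = list(Y_D = 1), seed = 1)
  est <- unlist(fit$estimates)
  tr <- unlist(truth_costly[names(est)])
  expect_equal(est, tr, tolerance = 0.01)
  expect_lt(fit$loss, 1e-8)
  expect_equal(fit$yield_ratio, 0.8, tolerance = 0.01)
})

test_that("equal-yield truth yields a ratio of one", {
  neutral <- competition_params(Y_C = 1, Y_D = 1, N_min = 1e6, N_max = 4e6,
                                g_sat = 12, p_half = 0.25)
  d <- generate_competitions(synth_config(neutral, noise_cv = 0.05,
                                          seed = 2))
  fit <- fit_competition(d, seed = 2)
  expect_equal(fit$yield_ratio, 1, tolerance = 0.05)
})

test_that("fits are deterministic given dataset and seed", {
  d <- generate_competitions(synth_config(truth_costly, replicates = 3,
                                          noise_cv = 0.15, seed = 5))
  f1 <- fit_competition(d, seed = 3)
  f2 <- fit_competition(d, seed = 3)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$loss, f2$loss)
})

test_that("the loss is locally minimal at the truth for clean data", {
  d0 <- generate_competitions(synth_config(truth_costly, noise_cv = 0,
                                           seed = 1))
  obs <- d0
  free <- c("Y_C", "Y_D", "N_min", "N_max", "g_sat", "p_half")
  loss_at <- function(vals) {
    pars <- do.call(competition_params, vals)
    pred <- response_curves(pars, sort(unique(obs$p_init)), 1e6)
    om <- aggregate(cbind(delta_p_i, w_i) ~ p_init, data = obs, mean)
    sum((pred$delta_p_i - om$delta_p_i)^2 / sd(obs$delta_p_i)^2 +
          (pred$w_i - om$w_i)^2 / sd(obs$w_i)^2)
  }
  base <- truth_costly[c("q", "K_n", free, "duration", "kinetics")]
  l0 <- loss_at(base)
  for (nm in free) for (f in c(0.8, 1.2)) {
    pert <- base
    pert[[nm]] <- pert[[nm]] * f
    if (pert$N_max < pert$N_min || pert$p_half > 1) next
    expect_gt(loss_at(pert), l0)
  }
})

test_that("under-identified configurations are rejected", {
  d <- generate_competitions(synth_config(truth_costly,
                                          levels = c(0.2, 0.8),
                                          replicates = 3, noise_cv = 0,
                                          seed = 1))
  expect_error(fit_competition(d), "under-identified")
  expect_error(fit_competition(d, free = c("Y_C", "N_max"),
                               fixed = list(Y_D = 1, N_min = 1e6,
                                            g_sat = 12, p_half = 0.25),
                               bounds = list(Y_C = c(0.1, 10))),
               "bounds")
  expect_error(fit_competition(d, free = c("Y_C", "N_max")),
               "neither free nor fixed")
})

test_that("bootstrap intervals behave across noise and replication", {
  d0 <- generate_competitions(synth_config(truth_costly, noise_cv = 0,
                                           seed = 1))
  fit0 <- fit_competition(d0, free = c("Y_C", "N_min", "N_max"),
                          fixed = list(Y_D = 1, g_sat = 12, p_half = 0.25),
                          seed = 1)
  # B = 0: degenerate intervals equal to the point estimate
  b0 <- bootstrap_fit(d0, fit = fit0, B = 0)
  expect_equal(b0$bootstrap$intervals[, "min"],
               b0$bootstrap$intervals[, "max"])
  # zero noise: resampling identical replicates cannot widen the intervals
  bz <- bootstrap_fit(d0, fit = fit0, B = 10, seed = 2)
  iv <- bz$bootstrap$intervals
  rel_width <- (iv[, "max"] - iv[, "min"]) / pmax(abs(iv[, "max"]), 1e-12)
  expect_lt(max(rel_width), 1e-4)
  point <- c(unlist(fit0$estimates), yield_ratio = fit0$yield_ratio)
  expect_true(all(iv[, "min"] <= point + 1e-12 &
                    iv[, "max"] >= point - 1e-12))
  # more replicates tighten the yield-ratio interval; the contrast must be
  # large because with very few replicates the case bootstrap understates
  # the spread (small-n bias), masking the standard-error gain
  widths <- vapply(c(3, 48), function(R) {
    d <- generate_competitions(synth_config(truth_costly, replicates = R,
                                            noise_cv = 0.15, seed = 11))
    f <- fit_competition(d, free = c("Y_C", "N_min", "N_max"),
                         fixed = list(Y_D = 1, g_sat = 12, p_half = 0.25),
                         seed = 11)
    b <- bootstrap_fit(d, fit = f, B = 40, seed = 11)
    iv <- b$bootstrap$intervals["yield_ratio", ]
    iv[["max"]] - iv[["min"]]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("predicted curves pin the endpoints and cover the data", {
  d <- generate_competitions(synth_config(truth_costly, replicates = 6,
                                          noise_cv = 0.1, seed = 4))
  fit <- fit_competition(d, seed = 4)
  pc <- predict_curves(fit, seq(0, 1, length.out = 21))
  expect_equal(pc$delta_p_i[c(1, 21)], c(0, 0))
  for (p in unique(d$p_init)) {
    reps <- d[d$p_init == p, ]
    pred <- predict_curves(fit, p)
    expect_gte(pred$w_i, min(reps$w_i) * 0.95)
    expect_lte(pred$w_i, max(reps$w_i) * 1.05)
  }
})
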