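#' Configuration for a synthetic competition experiment
#'
#' Describes a simulated plate-competition design: proportion levels at
#' which strains are mixed, replicates per level, the (equal) inoculum, and
#' multiplicative count noise. The default design mirrors a typical
#' plate-competition layout: five mixing levels spanning the proportion
#' range, six replicate colonies per level, one million founding cells, and
#' log-normal noise with a 15% coefficient of variation on final CFU counts
#' (standard for serial-dilution assays).
#'
#' @param truth A [competition_params()] or [growth_driven_params()] object —
#'   the generating ("true") parameter set.
#' @param levels Mixing proportions, within `[0, 1]`.
#' @param replicates Replicate colonies per level, `>= 1`.
#' @param inoculum Founding cells per colony (default `1e6`).
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise applied to each final count (default 0.15; 0 disables noise).
#' @param seed Integer seed making the generated dataset reproducible.
#' @param condition Label stored in the dataset (default `"synthetic"`).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(truth,
                         levels = c(0.01, 0.17, 0.5, 0.83, 0.99),
                         replicates = 6, inoculum = 1e6, noise_cv = 0.15,
                         seed = 1, condition = "synthetic") {
  stopifnot(inherits(truth, "competition_params") ||
              inherits(truth, "growth_driven_params"),
            all(levels >= 0 & levels <= 1), replicates >= 1,
            inoculum > 0, noise_cv >= 0)
  structure(list(truth = truth, levels = sort(unique(levels)),
                 replicates = as.integer(replicates), inoculum = inoculum,
                 noise_cv = noise_cv, seed = as.integer(seed),
                 condition = condition),
            class = "synth_config")
}

#' Generate a synthetic competition dataset
#'
#' Runs the deterministic competition model at each mixing level, then
#' applies independent log-normal multiplicative noise (mean 1, coefficient
#' of variation `noise_cv`) to each replicate's final counts and rounds to
#' whole cells. The initial split of the inoculum is exact, so a strain
#' absent at inoculation stays absent. Fixed seeds give byte-identical
#' datasets.
#'
#' @param config A [synth_config()].
#' @return A [competition_dataset()].
#' @export
#' @examples
#' cfg <- synth_config(example_params("costly"), replicates = 3, seed = 42)
#' head(generate_competitions(cfg))
generate_competitions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  det <- response_curves(config$truth, config$levels, config$inoculum)
  set.seed(config$seed)
  sdlog <- sqrt(log(1 + config$noise_cv^2))
  rows <- lapply(seq_len(nrow(det)), function(i) {
    p <- det$p_init[i]
    C0 <- p * config$inoculum
    D0 <- (1 - p) * config$inoculum
    R <- config$replicates
    noise <- function(n) if (sdlog == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    Cf <- det$C_final[i] * noise(R)
    Df <- det$D_final[i] * noise(R)
    if (config$noise_cv > 0) {
      Cf <- round(Cf); Df <- round(Df)
    }
    data.frame(condition = config$condition, p_init = p,
               replicate = seq_len(R), C_0 = C0, D_0 = D0,
               C_final = Cf, D_final = Df)
  })
  competition_dataset(do.call(rbind, rows))
}

#' Generate a group ensemble from the mixing distribution
#'
#' Draws subpopulation proportions from the logit-normal mixing model with
#' `mu` chosen so the exact mean equals `p_global`, and attaches equal
#' inocula (the model's stated assumption: every colony starts from the
#' same population density).
#'
#' @param p_global Global cooperator proportion, strictly inside `(0, 1)`.
#' @param sigma Structure strength, `>= 0` (`0` gives identical groups).
#' @param n_groups Number of subpopulations.
#' @param inoculum Founding cells per subpopulation.
#' @param seed Optional integer seed.
#' @return A data frame of class `group_ensemble` with columns `p_init`,
#'   `inoculum`; the `provenance` attribute is `"sampled"`.
#' @export
generate_ensemble <- function(p_global, sigma, n_groups, inoculum = 1e6,
                              seed = NULL) {
  stopifnot(p_global > 0, p_global < 1, sigma >= 0, n_groups >= 1)
  p <- if (sigma == 0) rep(p_global, n_groups)
  else rmixprop(n_groups, mixture_dist(mu_for_mean(p_global, sigma), sigma),
                seed = seed)
  structure(data.frame(p_init = p, inoculum = inoculum),
            class = c("group_ensemble", "data.frame"),
            provenance = "sampled")
}
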