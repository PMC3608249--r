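# Parameter-recovery studies: repeated cohort simulation and re-estimation
# of the generative quantities, used to validate the estimators at the
# study's scale.

#' Simulate-and-refit recovery study over replicate cohorts
#'
#' For each seed, simulates a cohort from the configuration, fits the
#' polygenic model to one methylation unit (rank-normalized, standard
#' sex/age covariates) and runs the kinship-adjusted association test of
#' one trait on one methylation predictor (both rank-normalized).  Model
#' fitting uses the generator's true unit fractions, so the recovered
#' means estimate the generative heritability and standardized effect
#' directly; the measurement layer is deliberately not applied.
#'
#' @param seeds integer vector of cohort seeds (one replicate each).
#' @param unit methylation unit whose heritability is refitted.
#' @param trait trait for the association test.
#' @param predictor methylation column used as the association predictor
#'   (default the regional average).
#' @param config_fn function(seed) returning a \code{cohort_config}.
#' @return data.frame with one row per seed: \code{seed}, \code{n},
#'   \code{h2_hat}, \code{beta_hat}.
#' @export
recovery_study <- function(seeds, unit = "9", trait = "TC",
                           predictor = "AVG",
                           config_fn = default_cohort_config) {
  rows <- lapply(seeds, function(s) {
    co <- simulate_cohort(config_fn(s), measurement = FALSE)
    eig <- kinship_eigen(co$phi)
    X <- make_covariate_design(co$covariates$age, co$covariates$sex)
    h2_hat <- fit_polygenic(rank_normalize(co$meth_true[, unit]), X,
                            eig = eig)$h2
    at <- association_test(rank_normalize(co$phenotypes[[trait]]), X,
                           eig = eig,
                           x_focal = rank_normalize(co$meth_true[, predictor]))
    data.frame(seed = s, n = nrow(co$ped), h2_hat = h2_hat,
               beta_hat = at$beta)
  })
  do.call(rbind, rows)
}
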