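test_that("a minimal family config produces a 4-person nuclear family", {
  cfg <- default_cohort_config(seed = 70L)
  cfg$n_families <- 1L
  cfg$sibship_mean <- 2    # sibship is exactly 2 + Poisson(0)
  cfg$p_extend <- 0
  set.seed(cfg$seed)
  gp <- gen_pedigrees(cfg)
  expect_equal(nrow(gp$ped), 4L)
  expect_length(founders(gp$ped), 2L)
  expect_error({
    bad <- cfg; bad$sibship_mean <- 1
    gen_pedigrees(bad)
  }, "family-shape")
})

test_that("default family shapes hit the target cohort size across seeds", {
  sizes <- vapply(1:50, function(s) {
    set.seed(s)
    nrow(gen_pedigrees(default_cohort_config(seed = s))$ped)
  }, numeric(1))
  expect_lt(abs(mean(sizes) - 517) / 517, 0.10)
  expect_equal(length(unique(sizes)) > 1, TRUE)
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- small_cohort_config(seed = 71L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$ped, co2$ped)
  expect_identical(co1$meth_true, co2$meth_true)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_identical(co1$records, co2$records)
  co3 <- simulate_cohort(small_cohort_config(seed = 72L))
  expect_false(identical(co1$meth_true, co3$meth_true))
})

test_that("simulated traits reproduce the kinship covariance structure", {
  # 6-person family: parents, two sibs, one sib's spouse and child
  ped <- as_pedigree(data.frame(
    fam = "F", id = c("f", "m", "s1", "s2", "sp", "k"),
    father = c(NA, NA, "f", "f", NA, "s1"),
    mother = c(NA, NA, "m", "m", NA, "sp"),
    sex = c("male", "female", "male", "female", "female", "male")))
  phi <- kinship_matrix(ped)
  eig <- kinship_eigen(phi)
  h2 <- 0.6; s2 <- 2.5
  set.seed(73)
  draws <- t(replicate(2000, simulate_trait_with_h2(eig, h2, fixed = 0,
                                                    total_var = s2)))
  emp <- cov(draws)
  theo <- 2 * phi * h2 * s2 + diag((1 - h2) * s2, 6)
  # elementwise within 3 Monte-Carlo SEs (normal theory: var of a sample
  # covariance ~ (v_ii v_jj + v_ij^2)/n)
  mcse <- sqrt((diag(theo) %o% diag(theo) + theo^2) / 2000)
  expect_true(all(abs(emp - theo) <= 3.5 * mcse))
  # h2 = 1: parent-offspring correlation near 2*phi = 0.5
  set.seed(74)
  d1 <- t(replicate(500, simulate_trait_with_h2(eig, 1)))
  expect_lt(abs(cor(d1[, "f"], d1[, "k"]) - 0.25), 0.15)
  expect_lt(abs(cor(d1[, "f"], d1[, "s1"]) - 0.5), 0.15)
  # h2 = 0: iid, sib correlation near zero
  set.seed(75)
  d0 <- t(replicate(500, simulate_trait_with_h2(eig, 0)))
  expect_lt(abs(cor(d0[, "s1"], d0[, "s2"])), 0.15)
})

test_that("the methylation panel respects means, clamping and age slopes", {
  cfg <- default_cohort_config(seed = 76L)
  co <- simulate_cohort(cfg, measurement = FALSE)
  m <- co$meth_true
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(colnames(m), c(cfg$units$unit, "AVG"))
  expect_true(all(co$clamp_fraction <= 0.05))
  # realized unit means near their specification
  expect_true(all(abs(colMeans(m[, cfg$units$unit]) - cfg$units$mean) <
                    4 * cfg$units$sd / sqrt(nrow(m)) + 0.01))
  # unit 9 age slope has the configured sign in-sample
  sl <- coef(lm(m[, "9"] ~ co$covariates$age))[2]
  expect_gt(sl, 0)
})

test_that("phenotypes land on the configured sex-specific raw scales", {
  cfg <- default_cohort_config(seed = 77L)
  co <- simulate_cohort(cfg, measurement = FALSE)
  fem <- co$covariates$sex == "female"
  tc <- co$phenotypes$TC
  spec <- cfg$traits[cfg$traits$trait == "TC", ]
  expect_lt(abs(mean(tc[fem]) - spec$mean_f), 4 * spec$sd_f / sqrt(sum(fem)))
  expect_lt(abs(mean(tc[!fem]) - spec$mean_m),
            4 * spec$sd_m / sqrt(sum(!fem)))
  expect_lt(abs(sd(tc[fem]) / spec$sd_f - 1), 0.15)
  # variance misconfiguration is rejected
  bad <- cfg
  bad$traits$assoc_beta[1] <- 1.2
  set.seed(1)
  eig <- kinship_eigen(co$phi)
  expect_error(simulate_phenotypes(bad, eig, co$meth_true,
                                   co$covariates$sex), "assoc_beta")
})

test_that("a lossless measurement layer reproduces the truth after QC", {
  cfg <- small_cohort_config(seed = 78L)
  cfg$noise_sd <- 0
  cfg$cell_exclusion_rate <- 0
  cfg$subject_failure_rate <- 0
  co <- simulate_cohort(cfg)
  bm <- build_methylation_matrix(co$records, panel = cfg$units$unit,
                                 avg_label = cfg$avg_label)
  expect_true(all(bm$qc$retained))
  expect_equal(as.matrix(bm$matrix), co$meth_true[rownames(bm$matrix), ],
               tolerance = 1e-12)
})

test_that("injected QC failures appear at their configured rates", {
  cfg <- default_cohort_config(seed = 79L)
  co <- simulate_cohort(cfg)
  bm <- build_methylation_matrix(co$records, panel = cfg$units$unit,
                                 avg_label = cfg$avg_label)
  n <- nrow(co$ped)
  # subject failures: binomial(n, 0.025)
  rej <- sum(!bm$qc$retained)
  ci <- qbinom(c(0.005, 0.995), n, cfg$subject_failure_rate)
  expect_true(rej >= ci[1] && rej <= ci[2])
  # cell exclusions among retained subjects: binomial around 0.048
  kept <- bm$cells[bm$cells$subject %in% rownames(bm$matrix), ]
  excl <- sum(kept$excluded)
  ci2 <- qbinom(c(0.005, 0.995), nrow(kept), cfg$cell_exclusion_rate)
  expect_true(excl >= ci2[1] && excl <= ci2[2])
})

test_that("cohorts round-trip through the directory writer", {
  cfg <- small_cohort_config(seed = 80L)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$ped), as.data.frame(co$ped))
  expect_equal(back$phenotypes$TC,
               unname(co$phenotypes$TC), tolerance = 1e-6)
  expect_equal(nrow(back$records), nrow(co$records))
  expect_equal(back$config$seed, cfg$seed)
  expect_equal(back$config$units$h2, cfg$units$h2)
  # truth file records every generative parameter including the seed
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_true(all(c("seed", "n_families", "units", "traits", "noise_sd",
                    "cell_exclusion_rate", "subject_failure_rate") %in%
                    names(truth)))
  # a different seed yields different data with identical schemas
  dir2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(small_cohort_config(seed = 81L)), dir2)
  b2 <- read_cohort(dir2)
  expect_identical(names(b2$phenotypes), names(back$phenotypes))
  expect_false(identical(b2$records$fraction, back$records$fraction))
})
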