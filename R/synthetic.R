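# Synthetic extended-family cohort generator.  Emulates the statistical
# structure the family-based methylation analysis assumes: 40 extended
# nuclear families totalling ~517 members, per-unit methylation fractions
# with published-scale heritabilities and age/sex effects, phenotypes with
# standardized methylation effects, triplicate measurement noise, and the
# QC failure modes (high-variance cells, low-calling-rate subjects).

#' Default per-unit methylation panel specification
#'
#' The 17-unit promoter/first-exon panel.  Heritability, age slope (per
#' year, fraction scale) and sex effect (female minus male, fraction scale)
#' follow the published per-unit estimates; unit means follow the region's
#' qualitative profile (low promoter methylation rising steeply in the
#' first exon).  Raw SDs are derived from the age-effect variance fraction,
#' sd_u = |beta_age| * age_sd / sqrt(ve_age), capped at min(mean, 1-mean)/3
#' so that boundary clamping stays negligible.
#'
#' @param age_sd assumed SD of age in years used in the SD derivation.
#' @return data.frame with columns \code{unit}, \code{mean}, \code{sd},
#'   \code{h2}, \code{beta_age}, \code{beta_sex}.
#' @export
default_unit_panel <- function(age_sd = 15.5) {
  u <- data.frame(
    unit = c("1", "2", "3", "4", "5", "6/7", "8", "9", "10/11/12", "13",
             "14", "15", "16", "17/18", "19", "20", "21/22"),
    mean = c(0.02, 0.015, 0.02, 0.03, 0.025, 0.03, 0.06, 0.10, 0.12, 0.45,
             0.55, 0.60, 0.65, 0.75, 0.80, 0.85, 0.90),
    h2 = c(0.21, 0.05, 0.09, 0.18, 0.15, 0.17, 0.17, 0.48, 0.19, 0.46,
           0.48, 0.15, 0.32, 0.03, 0.26, 0.41, 0.14),
    beta_age = c(1.7e-4, 1.6e-4, 1.5e-4, 4.0e-5, 1.1e-4, 1.2e-4, -2.0e-5,
                 2.9e-4, 2.8e-4, 2.2e-4, 2.8e-4, -2.8e-4, 2.3e-4, 1.3e-4,
                 -3.3e-4, 1.0e-5, -7.0e-5),
    ve_age = c(2.99e-3, 1.03e-2, 1.41e-2, 1.27e-3, 1.41e-2, 1.52e-2,
               3.09e-4, 2.09e-2, 2.05e-2, 8.40e-3, 7.52e-3, 4.15e-3,
               1.04e-2, 9.21e-4, 5.46e-3, 2.61e-5, 5.56e-4),
    beta_sex = c(1.9e-3, -7.3e-4, 4.6e-3, 2.7e-3, 5.4e-4, 2.5e-4, 6.2e-3,
                 -7.6e-4, 6.0e-3, 3.9e-3, 1.3e-2, 4.5e-3, 6.3e-3, 7.6e-3,
                 1.3e-2, 8.1e-3, -5.5e-3),
    stringsAsFactors = FALSE)
  implied <- abs(u$beta_age) * age_sd / sqrt(u$ve_age)
  cap <- pmin(u$mean, 1 - u$mean) / 3
  u$sd <- pmax(0.005, pmin(implied, cap))
  u$ve_age <- NULL
  u
}

#' Default per-trait phenotype specification
#'
#' A representative subset of the cohort's metabolic-syndrome traits with
#' sex-specific raw means/SDs and heritabilities on the published scale,
#' and the four published standardized methylation-association effects
#' (total cholesterol on the regional average; non-HDL particle size on
#' unit 17/18; diastolic blood pressure on unit 13; insulin sensitivity on
#' unit 21/22).  \code{assoc_unit} of \code{"AVG"} means the regional
#' average.
#'
#' @return data.frame with columns \code{trait}, \code{mean_m},
#'   \code{sd_m}, \code{mean_f}, \code{sd_f}, \code{h2}, \code{assoc_unit},
#'   \code{assoc_beta}.
#' @export
default_trait_panel <- function() {
  data.frame(
    trait = c("TC", "LDLc", "HDLc", "TG", "BMI", "WHR", "dBP", "sBP",
              "SI", "BMED", "Adiponectin"),
    mean_m = c(193.08, 131.44, 38.24, 135.40, 31.45, 0.93, 78.97, 128.69,
               3.32, 27.67, 6.66),
    sd_m = c(45.75, 40.55, 12.05, 208.06, 8.40, 0.08, 12.18, 15.34,
             2.94, 1.09, 3.06),
    mean_f = c(189.06, 126.95, 43.65, 106.45, 33.95, 0.83, 75.68, 124.90,
               2.86, 28.07, 9.47),
    sd_f = c(40.03, 36.61, 18.63, 64.89, 10.19, 0.09, 10.74, 19.07,
             2.79, 1.28, 4.77),
    h2 = c(0.29, 0.33, 0.69, 0.52, 0.43, 0.23, 0.22, 0.22, 0.20, 0.42,
           0.60),
    assoc_unit = c("AVG", NA, NA, NA, NA, NA, "13", NA, "21/22", "17/18",
                   NA),
    assoc_beta = c(0.17, NA, NA, NA, NA, NA, -0.16, NA, -0.16, -0.15, NA),
    stringsAsFactors = FALSE)
}

#' Default simulation configuration
#'
#' Family shapes target ~517 individuals across 40 extended nuclear
#' families (founding couple, sibship, married-in spouses, third-generation
#' children); generation-structured ages give a cohort mean near 43.6 years
#' with SD near 15.5; the female fraction among non-couple members is
#' 0.589; the measurement layer runs triplicates with 0.02 noise SD and
#' injects high-variance cells (rate 0.048) and failing subjects
#' (rate 0.025) matching the QC narrative.
#'
#' @param seed integer seed stored in the config.
#' @return a list of class \code{cohort_config}.
#' @export
default_cohort_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_families = 40L,
    sibship_mean = 4.3, p_extend = 0.5, kids_mean = 2.1,
    age_parents = 71, age_sibs = 49, age_kids = 27, age_gen_sd = 5,
    age_spouse_sd = 3, age_min = 5,
    female_fraction = 0.589,
    units = default_unit_panel(),
    traits = default_trait_panel(),
    noise_sd = 0.02, replicates = 3L,
    cell_exclusion_rate = 0.048, subject_failure_rate = 0.025,
    avg_label = "AVG"), class = "cohort_config")
}

#' Generate an extended-family pedigree with covariates
#'
#' Each family is a founding couple plus a sibship; each sib is extended
#' (spouse plus children) with probability \code{p_extend}.  Sibship sizes
#' are 2 + Poisson(sibship_mean - 2), children counts 1 +
#' Poisson(kids_mean - 1).  Ages are generation-structured Gaussians; sexes
#' of non-couple members are female with the configured fraction.  Uses the
#' current RNG stream.
#'
#' @param config a \code{cohort_config}.
#' @return list with \code{ped} (a \code{pedigree}) and \code{covariates}
#'   (data.frame id, age, sex aligned with the pedigree).
#' @export
gen_pedigrees <- function(config) {
  if (config$n_families < 1L) stop("n_families must be >= 1")
  if (config$sibship_mean < 2 || config$kids_mean < 1) {
    stop("impossible family-shape parameters")
  }
  rows <- list(); ages <- numeric(0)
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("F%02d", f)
    cnt <- 0L
    nid <- function() {
      cnt <<- cnt + 1L
      sprintf("%s_%03d", fam, cnt)
    }
    add <- function(id, father, mother, sex, age) {
      rows[[length(rows) + 1L]] <<- data.frame(
        fam = fam, id = id, father = father, mother = mother, sex = sex,
        stringsAsFactors = FALSE)
      ages[length(ages) + 1L] <<- age
    }
    base_age <- stats::rnorm(1, config$age_parents, config$age_gen_sd)
    fa <- nid(); add(fa, NA, NA, "male", base_age + stats::rnorm(1, 0, config$age_spouse_sd))
    mo <- nid(); add(mo, NA, NA, "female", base_age + stats::rnorm(1, 0, config$age_spouse_sd))
    nsib <- 2L + stats::rpois(1, max(0, config$sibship_mean - 2))
    for (s in seq_len(nsib)) {
      sib <- nid()
      sib_sex <- if (stats::runif(1) < config$female_fraction) "female" else "male"
      sib_age <- stats::rnorm(1, config$age_sibs, config$age_gen_sd)
      add(sib, fa, mo, sib_sex, sib_age)
      if (stats::runif(1) < config$p_extend) {
        sp <- nid()
        add(sp, NA, NA, if (sib_sex == "male") "female" else "male",
            sib_age + stats::rnorm(1, 0, config$age_spouse_sd))
        nkid <- 1L + stats::rpois(1, max(0, config$kids_mean - 1))
        for (k in seq_len(nkid)) {
          kid <- nid()
          add(kid, if (sib_sex == "male") sib else sp,
              if (sib_sex == "male") sp else sib,
              if (stats::runif(1) < config$female_fraction) "female" else "male",
              stats::rnorm(1, config$age_kids, config$age_gen_sd))
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  ped <- as_pedigree(df)
  cov <- data.frame(id = ped$id, age = pmax(config$age_min, ages),
                    sex = ped$sex, stringsAsFactors = FALSE)
  list(ped = ped, covariates = cov)
}

#' Simulate a trait with a given heritability on a pedigree
#'
#' Draws the additive genetic part g ~ MVN(0, 2*Phi*h2*total_var) through
#' the eigen-factorization of 2*Phi and an independent residual
#' e ~ N(0, (1-h2)*total_var), returning fixed + g + e.  Uses the current
#' RNG stream.
#'
#' @param eig [kinship_eigen()] of the pedigree.
#' @param h2 heritability in [0,1].
#' @param fixed fixed-effect contribution per subject (scalar or vector).
#' @param total_var total (genetic + residual) variance.
#' @return numeric vector aligned with \code{eig$ids}.
#' @export
simulate_trait_with_h2 <- function(eig, h2, fixed = 0, total_var = 1) {
  stopifnot(inherits(eig, "kinship_eigen"), h2 >= 0, h2 <= 1, total_var >= 0)
  n <- length(eig$values)
  g <- if (h2 > 0) {
    drop(eig$vectors %*% (sqrt(eig$values * h2 * total_var) * stats::rnorm(n)))
  } else rep(0, n)
  e <- stats::rnorm(n, 0, sqrt((1 - h2) * total_var))
  stats::setNames(fixed + g + e, eig$ids)
}

#' Simulate true methylation fractions for the unit panel
#'
#' Latent unit value = mean + beta_age * (age - mean(age)) + beta_sex *
#' 1(female) + g + e, with g + e variance sd^2 split by the unit's h2,
#' clamped to [0,1].  Warns when any unit clamps more than 5% of subjects.
#'
#' @param config a \code{cohort_config}.
#' @param eig kinship eigen-decomposition.
#' @param age,sex covariates aligned with \code{eig$ids}.
#' @return list with \code{fractions} (subject x unit matrix, regional
#'   average appended as the configured \code{avg_label} column) and
#'   \code{clamp_fraction} (per unit).
#' @export
simulate_methylation_panel <- function(config, eig, age, sex) {
  units <- config$units
  n <- length(eig$values)
  out <- matrix(NA_real_, n, nrow(units),
                dimnames = list(eig$ids, units$unit))
  clampf <- stats::setNames(numeric(nrow(units)), units$unit)
  fem <- as.numeric(sex == "female")
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    fixed <- u$mean + u$beta_age * (age - mean(age)) + u$beta_sex * fem
    lat <- simulate_trait_with_h2(eig, u$h2, fixed = fixed,
                                  total_var = u$sd^2)
    cl <- pmin(1, pmax(0, lat))
    clampf[i] <- mean(cl != lat)
    out[, i] <- cl
  }
  if (any(clampf > 0.05)) {
    warning("clamping fraction above 5% for unit(s): ",
            paste(names(clampf)[clampf > 0.05], collapse = ", "))
  }
  avg <- rowMeans(out)
  out <- cbind(out, avg)
  colnames(out)[ncol(out)] <- config$avg_label
  list(fractions = out, clamp_fraction = clampf)
}

#' Simulate raw phenotypes with planted methylation effects
#'
#' On the standardized scale each trait is beta * z(methylation predictor)
#' plus a polygenic part with the trait's residual heritability and an
#' independent residual, the three scaled to unit total variance; the
#' z-value is then mapped to the raw scale by the sex-specific mean/SD.
#'
#' @param config a \code{cohort_config}.
#' @param eig kinship eigen-decomposition.
#' @param meth true methylation matrix from
#'   [simulate_methylation_panel()] (with the regional-average column).
#' @param sex sex vector aligned with subjects.
#' @return data.frame of raw trait values (rownames subject ids) with the
#'   generative betas attached as attribute \code{"truth"}.
#' @export
simulate_phenotypes <- function(config, eig, meth, sex) {
  traits <- config$traits
  n <- length(eig$values)
  out <- matrix(NA_real_, n, nrow(traits),
                dimnames = list(eig$ids, traits$trait))
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    b <- if (is.na(tr$assoc_beta)) 0 else tr$assoc_beta
    if (b^2 >= 1) stop("trait '", tr$trait, "': assoc_beta^2 must be < 1")
    lin <- 0
    if (b != 0) {
      x <- meth[, tr$assoc_unit]
      lin <- b * (x - mean(x)) / stats::sd(x)
    }
    z <- lin + simulate_trait_with_h2(eig, tr$h2, fixed = 0,
                                      total_var = 1 - b^2)
    fem <- sex == "female"
    raw <- ifelse(fem, tr$mean_f + tr$sd_f * z, tr$mean_m + tr$sd_m * z)
    out[, i] <- raw
  }
  df <- as.data.frame(out)
  attr(df, "truth") <- traits[, c("trait", "assoc_unit", "assoc_beta", "h2")]
  df
}

#' Apply the measurement layer to true unit fractions
#'
#' Produces replicate-level records: triplicate draws with Gaussian noise
#' (clamped), plus the two injected QC failure modes -- failing subjects,
#' for whom two panel units return no measurement at all (NA replicates,
#' driving the measurement calling rate to 16/18 with the regional
#' average, below the 95% rule), and high-variance cells among the rest,
#' whose replicates are spread so the replicate SD exceeds the 0.1
#' exclusion rule.
#'
#' @param config a \code{cohort_config}.
#' @param fractions subject x unit matrix of true fractions (no regional
#'   average column).
#' @return data.frame of \code{ReplicateRecord}s: subject, unit, replicate,
#'   fraction (NA for failed measurements).
#' @export
apply_measurement_layer <- function(config, fractions) {
  subjects <- rownames(fractions)
  units <- colnames(fractions)
  ns <- length(subjects); nu <- length(units)
  R <- as.integer(config$replicates)
  fail <- stats::runif(ns) < config$subject_failure_rate
  bad <- matrix(stats::runif(ns * nu) < config$cell_exclusion_rate, ns, nu)
  miss <- matrix(FALSE, ns, nu)
  for (s in which(fail)) miss[s, sample.int(nu, 2L)] <- TRUE
  # long layout: subject-major, then unit, replicate fastest
  truthv <- rep(as.vector(t(fractions)), each = R)
  badv <- rep(as.vector(t(bad)), each = R)
  missv <- rep(as.vector(t(miss)), each = R)
  spread <- rep(rep_len(c(-0.2, 0, 0.2), R), ns * nu)
  noise <- stats::rnorm(length(truthv), 0, config$noise_sd)
  vals <- pmin(1, pmax(0, ifelse(badv, truthv + spread, truthv + noise)))
  vals[missv] <- NA_real_
  data.frame(subject = rep(subjects, each = nu * R),
             unit = rep(rep(units, each = R), times = ns),
             replicate = rep(seq_len(R), times = ns * nu),
             fraction = vals, stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Runs the full generative chain under a single seed: pedigree and
#' covariates, kinship, true methylation, raw phenotypes, and replicate-
#' level measurements.  Regeneration from the same config is bit-identical.
#'
#' @param config a \code{cohort_config} (see [default_cohort_config()]).
#' @param measurement apply the measurement layer (TRUE by default; the
#'   true fractions are always retained in the result).
#' @return object of class \code{synthetic_cohort}: \code{config},
#'   \code{ped}, \code{covariates}, \code{phi}, \code{meth_true},
#'   \code{clamp_fraction}, \code{phenotypes}, \code{records}.
#' @export
simulate_cohort <- function(config = default_cohort_config(),
                            measurement = TRUE) {
  set.seed(config$seed)
  gp <- gen_pedigrees(config)
  phi <- kinship_matrix(gp$ped)
  eig <- kinship_eigen(phi)
  mp <- simulate_methylation_panel(config, eig, gp$covariates$age,
                                   gp$covariates$sex)
  phen <- simulate_phenotypes(config, eig, mp$fractions, gp$covariates$sex)
  units_only <- mp$fractions[, setdiff(colnames(mp$fractions),
                                       config$avg_label), drop = FALSE]
  recs <- if (measurement) apply_measurement_layer(config, units_only)
          else NULL
  structure(list(config = config, ped = gp$ped,
                 covariates = gp$covariates, phi = phi,
                 meth_true = mp$fractions,
                 clamp_fraction = mp$clamp_fraction,
                 phenotypes = phen, records = recs),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory
#'
#' Emits a PED-like pedigree file, a phenotype CSV (id, age, sex, traits),
#' a long-format replicate methylation CSV, and a YAML file holding every
#' generative parameter including the seed.  The files round-trip through
#' [read_cohort()] / the pipeline readers.
#'
#' @param cohort a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    pedigree = file.path(dir, "pedigree.ped"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    methylation = file.path(dir, "methylation_replicates.csv"),
    truth = file.path(dir, "truth.yaml"))
  ped <- cohort$ped
  out <- data.frame(fam = ped$fam, id = ped$id,
                    father = ifelse(is.na(ped$father), "0", ped$father),
                    mother = ifelse(is.na(ped$mother), "0", ped$mother),
                    sex = ifelse(ped$sex == "male", 1L, 2L))
  utils::write.table(out, paths$pedigree, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  phen <- cbind(cohort$covariates, cohort$phenotypes)
  utils::write.csv(phen, paths$phenotypes, row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$records)) {
    utils::write.csv(cohort$records, paths$methylation, row.names = FALSE,
                     quote = FALSE)
  }
  cfg <- cohort$config
  cfg$units <- as.list(cfg$units)
  cfg$traits <- as.list(cfg$traits)
  yaml::write_yaml(cfg, paths$truth)
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return list with \code{ped}, \code{phenotypes} (data.frame),
#'   \code{records} (replicate long table or NULL), \code{config}.
#' @export
read_cohort <- function(dir) {
  ped <- read_pedigree(file.path(dir, "pedigree.ped"))
  phen <- utils::read.csv(file.path(dir, "phenotypes.csv"),
                          check.names = FALSE,
                          colClasses = c(id = "character"))
  mpath <- file.path(dir, "methylation_replicates.csv")
  recs <- if (file.exists(mpath)) {
    utils::read.csv(mpath, check.names = FALSE,
                    colClasses = c(subject = "character",
                                   unit = "character"))
  } else NULL
  cfg <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  cfg$units <- as.data.frame(cfg$units, stringsAsFactors = FALSE)
  cfg$traits <- as.data.frame(cfg$traits, stringsAsFactors = FALSE)
  class(cfg) <- "cohort_config"
  list(ped = ped, phenotypes = phen, records = recs, config = cfg)
}
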