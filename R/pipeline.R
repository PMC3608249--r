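# Orchestration of the family-based methylation analysis: heritability and
# covariate scans per unit, trait-by-unit association scans with
# significance flags, and kinship-adjusted expression association with an
# FDR detection filter.

#' Heritability and age/sex covariate scan over the methylation panel
#'
#' For each panel column (units plus the regional average) the unit values
#' are rank-normalized, the polygenic model is fitted with the standard
#' sex/age covariate design, heritability is tested against the
#' boundary-mixture null, and the age and sex fixed effects are each
#' tested by a 1-df LRT, with coefficients reported back on the fraction
#' scale.
#'
#' @param meth subject x column methylation data.frame/matrix (rownames
#'   subject ids), e.g. \code{build_methylation_matrix()$matrix}.
#' @param covariates data.frame with \code{id}, \code{age}, \code{sex}.
#' @param phi kinship matrix covering the subjects.
#' @param rint_offset rank-normalization convention (see
#'   [rank_normalize()]).
#' @return data.frame, one row per column: unit, n, h2, h2_se, p_h2,
#'   beta_age, se_age, p_age, ve_age, beta_sex, se_sex, p_sex, ve_sex.
#' @export
run_heritability_scan <- function(meth, covariates, phi,
                                  rint_offset = "midrank") {
  meth <- as.matrix(meth)
  ids <- rownames(meth)
  if (length(unique(covariates$id)) < nrow(covariates)) {
    stop("duplicate ids in covariates")
  }
  rows <- lapply(colnames(meth), function(un) {
    y_raw <- meth[, un]
    ok <- !is.na(y_raw)
    out <- data.frame(unit = un, n = sum(ok), h2 = NA_real_,
                      h2_se = NA_real_, p_h2 = NA_real_,
                      beta_age = NA_real_, se_age = NA_real_,
                      p_age = NA_real_, ve_age = NA_real_,
                      beta_sex = NA_real_, se_sex = NA_real_,
                      p_sex = NA_real_, ve_sex = NA_real_,
                      stringsAsFactors = FALSE)
    if (sum(ok) < 10L || stats::sd(y_raw[ok]) == 0) return(out)
    sid <- ids[ok]
    cv <- covariates[match(sid, covariates$id), ]
    X <- make_covariate_design(cv$age, cv$sex)
    y <- rank_normalize(y_raw[ok], offset = rint_offset)
    sc <- covariate_scan(y, X, phi = phi[sid, sid],
                         meth_raw_sd = stats::sd(y_raw[ok]))
    out[, c("h2", "h2_se", "p_h2", "beta_age", "se_age", "p_age",
            "ve_age", "beta_sex", "se_sex", "p_sex", "ve_sex")] <-
      sc[, c("h2", "h2_se", "p_h2", "beta_age", "se_age", "p_age",
             "ve_age", "beta_sex", "se_sex", "p_sex", "ve_sex")]
    out
  })
  do.call(rbind, rows)
}

#' Trait-by-unit kinship-adjusted association scan
#'
#' Rank-normalizes each trait and each methylation column, tests every
#' trait-unit pair with the polygenic association LRT, back-transforms the
#' effect to raw trait units per 1% methylation, and flags pairs at the
#' significant and suggestive per-test thresholds (Bonferroni over the
#' panel width by default).
#'
#' @param meth subject x column methylation data (units + regional
#'   average).
#' @param traits subject-level data.frame of raw trait values (rownames or
#'   \code{id} column aligned via \code{covariates$id}).
#' @param covariates data.frame with \code{id}, \code{age}, \code{sex}.
#' @param phi kinship matrix.
#' @param trait_names traits to scan (default: all columns of
#'   \code{traits} except id/age/sex).
#' @param alpha_significant,alpha_suggestive family-wise levels.
#' @param method threshold method, \code{"bonferroni"} or \code{"sidak"}.
#' @param m_tests test count used for the thresholds (defaults to the
#'   panel width, i.e. units + regional average).
#' @param rint_offset rank-normalization convention.
#' @return data.frame with one row per trait x column: trait, unit, n,
#'   beta, se, variance_explained, raw_change, p_value, significant,
#'   suggestive.
#' @export
run_association_scan <- function(meth, traits, covariates, phi,
                                 trait_names = NULL,
                                 alpha_significant = 0.05,
                                 alpha_suggestive = 0.10,
                                 method = "bonferroni", m_tests = NULL,
                                 rint_offset = "midrank") {
  meth <- as.matrix(meth)
  ids <- rownames(meth)
  if (is.null(trait_names)) {
    trait_names <- setdiff(colnames(traits), c("id", "age", "sex"))
  }
  absent <- setdiff(trait_names, colnames(traits))
  if (length(absent)) {
    stop("trait column(s) absent: ", paste(absent, collapse = ", "))
  }
  if (is.null(m_tests)) m_tests <- ncol(meth)
  thr_sig <- per_test_threshold(alpha_significant, m_tests, method)
  thr_sug <- per_test_threshold(alpha_suggestive, m_tests, method)
  tid <- if ("id" %in% colnames(traits)) as.character(traits$id)
         else rownames(traits)
  rows <- list()
  for (tr in trait_names) {
    for (un in colnames(meth)) {
      y_raw <- traits[match(ids, tid), tr]
      x_raw <- meth[, un]
      ok <- !is.na(y_raw) & !is.na(x_raw)
      row <- data.frame(trait = tr, unit = un, n = sum(ok),
                        beta = NA_real_, se = NA_real_,
                        variance_explained = NA_real_,
                        raw_change = NA_real_, p_value = NA_real_,
                        significant = NA, suggestive = NA,
                        stringsAsFactors = FALSE)
      if (sum(ok) >= 10L && stats::sd(x_raw[ok]) > 0 &&
          stats::sd(y_raw[ok]) > 0) {
        sid <- ids[ok]
        cv <- covariates[match(sid, covariates$id), ]
        X <- make_covariate_design(cv$age, cv$sex)
        y <- rank_normalize(y_raw[ok], offset = rint_offset)
        x <- rank_normalize(x_raw[ok], offset = rint_offset)
        at <- association_test(y, X, phi = phi[sid, sid], x_focal = x,
                               trait_raw_sd = stats::sd(y_raw[ok]),
                               meth_raw_sd = stats::sd(x_raw[ok]))
        row$beta <- at$beta; row$se <- at$se
        row$variance_explained <- at$variance_explained
        row$raw_change <- at$raw_change
        row$p_value <- at$p_value
        row$significant <- at$p_value < thr_sig
        row$suggestive <- at$p_value < thr_sug
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Kinship-adjusted expression-trait association with detection filtering
#'
#' Normalizes probe intensities ([normalize_expression()]), retains probes
#' detectable at the given FDR (BH over per-probe detection p-values), and
#' tests each retained probe against each trait in the polygenic model.
#'
#' @param intensities probes x samples matrix of raw intensities (column
#'   names are subject ids).
#' @param detection_p per-probe detection p-values (named by probe).
#' @param traits,covariates,phi as in [run_association_scan()].
#' @param trait_names traits to test.
#' @param q detection FDR level.
#' @param rint_offset rank-normalization convention.
#' @return data.frame: probe, trait, n, beta, se, p_value; zero rows (with
#'   a message) when no probe survives detection.
#' @export
run_expression_association <- function(intensities, detection_p, traits,
                                       covariates, phi, trait_names = NULL,
                                       q = 0.05, rint_offset = "midrank") {
  expr <- normalize_expression(intensities)
  det <- bh_fdr(detection_p, q = q)
  keep <- rownames(expr)[det$selected]
  if (length(keep) == 0L) {
    message("no probes detectable at FDR ", q)
    return(data.frame(probe = character(0), trait = character(0),
                      n = integer(0), beta = numeric(0), se = numeric(0),
                      p_value = numeric(0)))
  }
  if (is.null(trait_names)) {
    trait_names <- setdiff(colnames(traits), c("id", "age", "sex"))
  }
  tid <- if ("id" %in% colnames(traits)) as.character(traits$id)
         else rownames(traits)
  sids <- colnames(expr)
  rows <- list()
  for (pr in keep) {
    for (tr in trait_names) {
      y_raw <- traits[match(sids, tid), tr]
      x_raw <- expr[pr, ]
      ok <- !is.na(y_raw) & !is.na(x_raw)
      sid <- sids[ok]
      cv <- covariates[match(sid, covariates$id), ]
      X <- make_covariate_design(cv$age, cv$sex)
      y <- rank_normalize(y_raw[ok], offset = rint_offset)
      x <- as.numeric(scale(x_raw[ok]))
      at <- association_test(y, X, phi = phi[sid, sid], x_focal = x)
      rows[[length(rows) + 1L]] <-
        data.frame(probe = pr, trait = tr, n = at$n, beta = at$beta,
                   se = at$se, p_value = at$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Manhattan-style plot of an association scan
#'
#' Plots -log10(p) per panel column for each trait, with the significant
#' and suggestive per-test thresholds as horizontal lines.
#'
#' @param scan result of [run_association_scan()].
#' @param thresholds numeric vector of per-test p thresholds to draw.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the plotted data.
#' @export
plot_association <- function(scan, thresholds = NULL, ...) {
  units <- unique(scan$unit)
  xs <- match(scan$unit, units)
  ys <- -log10(scan$p_value)
  tr <- factor(scan$trait)
  graphics::plot(xs, ys, pch = as.integer(tr) %% 25, xaxt = "n",
                 xlab = "CpG unit", ylab = expression(-log[10](p)), ...)
  graphics::axis(1, at = seq_along(units), labels = units, las = 2,
                 cex.axis = 0.7)
  if (!is.null(thresholds)) {
    graphics::abline(h = -log10(thresholds), lty = 2,
                     col = c("blue", "grey40"))
  }
  graphics::legend("topright", legend = levels(tr),
                   pch = seq_along(levels(tr)) %% 25, cex = 0.7)
  invisible(data.frame(x = xs, y = ys, trait = scan$trait))
}
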