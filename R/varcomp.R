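# Maximum-likelihood polygenic variance-component models on pedigree
# covariance: trait covariance Omega = 2*Phi*sigma2_a + I*sigma2_e with
# linear fixed effects.  The additive relationship matrix 2*Phi is
# eigen-rotated once; beta and the total variance are profiled out
# analytically and the heritability ratio is optimized on [0,1).

#' Rank-based inverse normal transformation
#'
#' Maps values to standard-normal quantiles of their (average, for ties)
#' ranks.  The default offset convention is z = qnorm((r - 0.5)/n);
#' alternatives are Blom ((r - 3/8)/(n + 1/4)) and van der Waerden
#' (r/(n + 1)).  Missing values are propagated.
#'
#' @param x numeric vector (>= 3 non-missing, not all equal).
#' @param offset rank-to-probability convention.
#' @return transformed vector, same length and order as \code{x}.
#' @export
rank_normalize <- function(x, offset = c("midrank", "blom", "waerden")) {
  offset <- match.arg(offset)
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 3L) stop("need at least 3 non-missing values")
  if (length(unique(v)) < 2L) stop("all values identical: no ordering information")
  r <- rank(v, ties.method = "average")
  n <- length(v)
  p <- switch(offset,
              midrank = (r - 0.5) / n,
              blom = (r - 3 / 8) / (n + 1 / 4),
              waerden = r / (n + 1))
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm(p)
  out
}

#' Standard covariate design for the polygenic models
#'
#' Builds the fixed-effect design with intercept, sex, age, age squared,
#' sex-by-age and sex-by-age-squared.  Age is centered at its sample mean
#' before squaring, so the linear age coefficient is the slope at the mean
#' age.  Constant columns (e.g. single-sex data) are dropped.
#'
#' @param age numeric ages in years.
#' @param sex \code{"male"}/\code{"female"} (female coded 1).
#' @return numeric design matrix with named columns.
#' @export
make_covariate_design <- function(age, sex) {
  if (length(age) != length(sex)) stop("age and sex lengths differ")
  fem <- as.numeric(sex == "female")
  a <- age - mean(age)
  X <- cbind(intercept = 1, sex = fem, age = a, age2 = a^2,
             sex_age = fem * a, sex_age2 = fem * a^2)
  keep <- apply(X, 2, function(col) stats::sd(col) > 0) | colnames(X) == "intercept"
  X <- X[, keep, drop = FALSE]
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  X
}

# Profile log-likelihood machinery: given the rotation of y and X by the
# eigenvectors of K = 2*Phi, evaluate the ML profile log-likelihood at a
# heritability ratio h, with beta and total variance profiled out.
.profile_ll <- function(h, ys, Xs, lambda, want = "ll") {
  n <- length(ys)
  v <- h * lambda + (1 - h)
  if (any(v <= 0)) return(if (want == "ll") -Inf else NULL)
  w <- 1 / v
  sw <- sqrt(w)
  fit <- stats::lm.fit(Xs * sw, ys * sw)
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + sum(log(v)) + n)
  if (want == "ll") return(ll)
  beta <- fit$coefficients
  XtVX <- crossprod(Xs * sw)
  beta_cov <- tryCatch(solve(XtVX) * sigma2,
                       error = function(e) stop("singular design matrix"))
  list(ll = ll, beta = beta, beta_se = sqrt(diag(beta_cov)),
       sigma2_total = sigma2)
}

#' Fit the polygenic variance-component model by maximum likelihood
#'
#' Maximizes the multivariate-normal log-likelihood with mean X beta and
#' covariance 2*Phi*sigma2_a + I*sigma2_e.  The kinship kernel is rotated
#' once by its eigenvectors; beta and the total variance are profiled
#' analytically and h2 = sigma2_a/(sigma2_a + sigma2_e) is found by bounded
#' one-dimensional search on [0, 1) to tolerance 1e-8.  The h2 standard
#' error comes from the numerical second derivative of the profile
#' log-likelihood (NA at the h2 = 0 boundary).
#'
#' @param y numeric response (typically rank-normalized).
#' @param X fixed-effect design matrix (see [make_covariate_design()]).
#' @param phi kinship matrix; ignored when \code{eig} is given.
#' @param eig optional precomputed [kinship_eigen()] of the same pedigree,
#'   for repeated fits.
#' @param h2_fixed when non-NULL, h2 is held at this value instead of being
#'   estimated (use 0 for the no-polygenic null model).
#' @param tol search tolerance for h2.
#' @return object of class \code{polygenic_fit}: \code{sigma2_a},
#'   \code{sigma2_e}, \code{h2}, \code{h2_se}, \code{beta}, \code{beta_se},
#'   \code{loglik}, \code{n}, \code{df_fixed}.
#' @export
fit_polygenic <- function(y, X, phi = NULL, eig = NULL, h2_fixed = NULL,
                          tol = 1e-8) {
  if (is.null(eig)) {
    if (is.null(phi)) stop("supply phi or eig")
    eig <- kinship_eigen(phi)
  }
  X <- as.matrix(X)
  n <- length(y)
  if (n != length(eig$values) || nrow(X) != n) {
    stop("y, X and the kinship kernel have mismatched dimensions")
  }
  if (any(is.na(y)) || any(is.na(X))) stop("missing values in y or X")
  if (n < ncol(X) + 2L) stop("too few observations for the design")
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  U <- eig$vectors
  lambda <- eig$values
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  if (is.null(h2_fixed)) {
    upper <- 1 - 1e-6
    opt <- stats::optimize(.profile_ll, interval = c(0, upper),
                           maximum = TRUE, tol = tol,
                           ys = ys, Xs = Xs, lambda = lambda)
    cand <- c(opt$maximum, 0, upper)
    lls <- vapply(cand, .profile_ll, numeric(1), ys = ys, Xs = Xs,
                  lambda = lambda)
    h2 <- cand[which.max(lls)]
    if (h2 < 1e-7) h2 <- 0
  } else {
    stopifnot(h2_fixed >= 0, h2_fixed < 1)
    h2 <- h2_fixed
  }
  full <- .profile_ll(h2, ys, Xs, lambda, want = "all")
  h2_se <- NA_real_
  if (is.null(h2_fixed)) {
    step <- 1e-3
    lo <- max(0, h2 - step); hi <- min(1 - 1e-6, h2 + step)
    if (h2 > step && h2 < 1 - 1e-6 - step) {
      d2 <- (.profile_ll(hi, ys, Xs, lambda) - 2 * full$ll +
               .profile_ll(lo, ys, Xs, lambda)) / step^2
      if (is.finite(d2) && d2 < 0) h2_se <- sqrt(-1 / d2)
    }
  }
  structure(list(
    sigma2_a = h2 * full$sigma2_total,
    sigma2_e = (1 - h2) * full$sigma2_total,
    h2 = h2, h2_se = h2_se,
    beta = stats::setNames(full$beta, colnames(X)),
    beta_se = stats::setNames(full$beta_se, colnames(X)),
    loglik = full$ll, n = n, df_fixed = ncol(X),
    h2_fixed = !is.null(h2_fixed)), class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("Polygenic variance-component fit (ML)\n")
  cat(sprintf("  n = %d, fixed effects = %d\n", x$n, x$df_fixed))
  cat(sprintf("  h2 = %.4f%s, sigma2_a = %.4g, sigma2_e = %.4g\n",
              x$h2, if (is.na(x$h2_se)) "" else sprintf(" (SE %.4f)", x$h2_se),
              x$sigma2_a, x$sigma2_e))
  cat(sprintf("  loglik = %.4f\n", x$loglik))
  invisible(x)
}

#' Likelihood-ratio test for heritability with the boundary-mixture null
#'
#' sigma2_a is tested on its lower boundary, so the LRT statistic is
#' distributed under the null as a 0.5:0.5 mixture of a point mass at zero
#' and chi-square with 1 df: p = 1 when T = 0, else 0.5 * P(chisq_1 >= T).
#'
#' @param fit_full fit with h2 free.
#' @param fit_h0 same design fit with \code{h2_fixed = 0}.
#' @param tolerance allowed negative slack in the LRT before erroring.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
heritability_test <- function(fit_full, fit_h0, tolerance = 1e-6) {
  if (fit_full$n != fit_h0$n || fit_full$df_fixed != fit_h0$df_fixed) {
    stop("fits have mismatched designs")
  }
  T <- 2 * (fit_full$loglik - fit_h0$loglik)
  if (T < -tolerance) stop("full-model loglik below null: not nested fits?")
  T <- max(0, T)
  p <- if (T == 0) 1 else 0.5 * stats::pchisq(T, df = 1, lower.tail = FALSE)
  list(statistic = T, p_value = p)
}

#' Kinship-adjusted association test for a focal predictor
#'
#' Fits the polygenic model with and without the focal column appended to
#' the covariate design and reports the 1-df likelihood-ratio p-value, the
#' focal coefficient and its Wald SE from the full fit, the fraction of
#' trait variance explained (beta^2 Var(x)/Var(y) on the analysis scale),
#' and optionally the raw-scale change per 1 percentage-point of
#' methylation (via [back_transform_effect()] when the raw SDs are given).
#'
#' @param y response (rank-normalized trait).
#' @param X covariate design.
#' @param phi,eig kinship kernel (one of the two).
#' @param x_focal focal predictor values, typically rank-normalized
#'   methylation; must be non-constant.
#' @param trait_raw_sd,meth_raw_sd optional raw-scale SDs for the
#'   back-transformed effect.
#' @return one-row data.frame: \code{beta}, \code{se}, \code{lrt},
#'   \code{p_value}, \code{variance_explained}, \code{raw_change},
#'   \code{h2}, \code{n}.
#' @export
association_test <- function(y, X, phi = NULL, eig = NULL, x_focal,
                             trait_raw_sd = NULL, meth_raw_sd = NULL) {
  if (stats::sd(x_focal) == 0) stop("x_focal is constant")
  if (length(x_focal) != length(y)) stop("x_focal and y lengths differ")
  if (is.null(eig)) eig <- kinship_eigen(phi)
  X <- as.matrix(X)
  Xf <- cbind(X, focal = x_focal)
  fit_full <- fit_polygenic(y, Xf, eig = eig)
  fit_null <- fit_polygenic(y, X, eig = eig)
  T <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  p <- stats::pchisq(T, df = 1, lower.tail = FALSE)
  b <- unname(fit_full$beta["focal"])
  ve <- b^2 * stats::var(x_focal) / stats::var(y)
  raw <- if (!is.null(trait_raw_sd) && !is.null(meth_raw_sd)) {
    back_transform_effect(b, trait_raw_sd, meth_raw_sd)
  } else NA_real_
  data.frame(beta = b, se = unname(fit_full$beta_se["focal"]),
             lrt = T, p_value = p, variance_explained = ve,
             raw_change = raw, h2 = fit_full$h2, n = fit_full$n)
}

#' Age and sex effects on a methylation unit
#'
#' Treats a (rank-normalized) methylation unit as the trait and tests each
#' covariate by a 1-df LRT dropping its column from the full design, with
#' the coefficient and Wald SE taken from the full fit.  When
#' \code{meth_raw_sd} is given, the age and sex coefficients are also
#' reported back on the fraction scale (per year, and female-vs-male).
#'
#' @param y rank-normalized unit values.
#' @param X full covariate design containing \code{age} and \code{sex}
#'   columns.
#' @param phi,eig kinship kernel.
#' @param meth_raw_sd raw-scale SD of the unit (for fraction-scale betas).
#' @return one-row data.frame with h2, its SE and boundary-mixture p, and
#'   per-covariate beta (z and fraction scale), SE, p and variance
#'   explained.
#' @export
covariate_scan <- function(y, X, phi = NULL, eig = NULL,
                           meth_raw_sd = NULL) {
  if (is.null(eig)) eig <- kinship_eigen(phi)
  X <- as.matrix(X)
  for (cl in c("age", "sex")) {
    if (!cl %in% colnames(X)) stop("design lacks a '", cl, "' column")
  }
  fit_full <- fit_polygenic(y, X, eig = eig)
  fit_noh2 <- fit_polygenic(y, X, eig = eig, h2_fixed = 0)
  h2t <- heritability_test(fit_full, fit_noh2)
  one <- function(cl) {
    fit0 <- fit_polygenic(y, X[, colnames(X) != cl, drop = FALSE], eig = eig)
    T <- max(0, 2 * (fit_full$loglik - fit0$loglik))
    b <- unname(fit_full$beta[cl])
    xv <- X[, cl]
    list(beta = b, se = unname(fit_full$beta_se[cl]),
         p = stats::pchisq(T, df = 1, lower.tail = FALSE),
         ve = b^2 * stats::var(xv) / stats::var(y))
  }
  ag <- one("age"); sx <- one("sex")
  sc <- if (is.null(meth_raw_sd)) NA_real_ else meth_raw_sd / stats::sd(y)
  data.frame(h2 = fit_full$h2, h2_se = fit_full$h2_se, p_h2 = h2t$p_value,
             beta_age = ag$beta * sc, se_age = ag$se * sc, p_age = ag$p,
             ve_age = ag$ve,
             beta_sex = sx$beta * sc, se_sex = sx$se * sc, p_sex = sx$p,
             ve_sex = sx$ve,
             beta_age_z = ag$beta, beta_sex_z = sx$beta, n = fit_full$n)
}

#' Back-transform a standardized effect to raw trait units per 1% methylation
#'
#' Approximates the raw-scale change as
#' beta_z * trait_raw_sd * (0.01 / meth_raw_sd): the z-scale effect rescaled
#' by the two raw standard deviations, evaluated for a 1 percentage-point
#' methylation increment.
#'
#' @param beta_z standardized (z-scale) coefficient.
#' @param trait_raw_sd raw SD of the trait.
#' @param meth_raw_sd raw SD of the methylation fraction.
#' @return change in raw trait units per 1% methylation.
#' @export
back_transform_effect <- function(beta_z, trait_raw_sd, meth_raw_sd) {
  if (trait_raw_sd <= 0 || meth_raw_sd <= 0) stop("SDs must be positive")
  beta_z * trait_raw_sd * (0.01 / meth_raw_sd)
}

#' Normalize expression intensities for kinship-adjusted association
#'
#' Log2-transforms probe intensities and quantile-normalizes across samples
#' (so all samples share one sorted value multiset), the standard
#' preprocessing for bead-array expression before model fitting.
#'
#' @param intensities numeric matrix, probes in rows, samples in columns;
#'   strictly positive.
#' @return normalized matrix of the same dimension.
#' @export
normalize_expression <- function(intensities) {
  m <- as.matrix(intensities)
  bad <- which(m <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-positive intensity at probe ",
         rownames(m)[bad[1, 1]] %||% bad[1, 1], ", sample ",
         colnames(m)[bad[1, 2]] %||% bad[1, 2])
  }
  limma::normalizeQuantiles(log2(m))
}
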