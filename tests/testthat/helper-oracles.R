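# Independent oracles used by the tests: gene-dropping Monte-Carlo kinship,
# explicit-inverse GLS/ML for the polygenic model, and small fixture
# pedigrees built in code.

# Monte-Carlo kinship by gene dropping: founders carry unique allele
# labels; each child inherits one allele from each parent uniformly.  The
# kinship estimate for a pair is the allele-sharing probability averaged
# over the four allele pairings.  Returns the estimate matrix and the
# per-pair Monte-Carlo standard errors.
gene_drop_kinship <- function(ped, n_drops = 1e5) {
  n <- nrow(ped)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  # topological order: founders first (parents precede children)
  ord <- integer(0); placed <- logical(n)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (is.na(fi) | placed[ifelse(is.na(fi), 1L, fi)]) &
                     (is.na(mi) | placed[ifelse(is.na(mi), 1L, mi)]))
    ord <- c(ord, ready); placed[ready] <- TRUE
  }
  A1 <- matrix(0L, n_drops, n); A2 <- matrix(0L, n_drops, n)
  for (i in ord) {
    if (is.na(fi[i])) {
      A1[, i] <- 2L * i - 1L; A2[, i] <- 2L * i
    } else {
      pick <- stats::runif(n_drops) < 0.5
      A1[, i] <- ifelse(pick, A1[, fi[i]], A2[, fi[i]])
      pick <- stats::runif(n_drops) < 0.5
      A2[, i] <- ifelse(pick, A1[, mi[i]], A2[, mi[i]])
    }
  }
  est <- se <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    share <- 0.25 * ((A1[, i] == A1[, j]) + (A1[, i] == A2[, j]) +
                       (A2[, i] == A1[, j]) + (A2[, i] == A2[, j]))
    est[i, j] <- est[j, i] <- mean(share)
    se[i, j] <- se[j, i] <- stats::sd(share) / sqrt(n_drops)
  }
  list(phi = est, se = se)
}

# Explicit-inverse ML oracle for the polygenic model: grid search over h2
# with the covariance built and inverted directly.
gls_oracle <- function(y, X, K, h2_grid = seq(0, 0.999, length.out = 600)) {
  n <- length(y)
  X <- as.matrix(X)
  one <- function(h2) {
    V <- h2 * K + (1 - h2) * diag(n)
    Vi <- solve(V)
    b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    s2 <- drop(t(r) %*% Vi %*% r) / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(s2) +
                    as.numeric(determinant(V)$modulus) + n)
    list(ll = ll, beta = drop(b), s2 = s2)
  }
  lls <- vapply(h2_grid, function(h) one(h)$ll, numeric(1))
  best <- which.max(lls)
  c(one(h2_grid[best]), list(h2 = h2_grid[best], ll_grid = lls))
}

# Two-family fixture: family A spans three generations (a6/a7 are
# grandchildren of a1/a2 and full sibs), family B is a nuclear sibship.
ped_two_families <- function() {
  as_pedigree(data.frame(
    fam = rep(c("A", "B"), c(7, 5)),
    id = c("a1", "a2", "a3", "a4", "a5", "a6", "a7",
           "b1", "b2", "b3", "b4", "b5"),
    father = c(NA, NA, "a1", "a1", NA, "a3", "a3", NA, NA, "b1", "b1", "b1"),
    mother = c(NA, NA, "a2", "a2", NA, "a5", "a5", NA, NA, "b2", "b2", "b2"),
    sex = c("male", "female", "male", "female", "female", "male", "female",
            "male", "female", "male", "female", "male"),
    stringsAsFactors = FALSE))
}

# First-cousin fixture: c7 and c8 are children of the sibs c3 and c4.
ped_cousins <- function() {
  as_pedigree(data.frame(
    fam = "F",
    id = paste0("c", 1:8),
    father = c(NA, NA, "c1", "c1", NA, NA, "c3", "c4"),
    mother = c(NA, NA, "c2", "c2", NA, NA, "c5", "c6"),
    sex = c("male", "female", "male", "male", "female", "female",
            "male", "female"),
    stringsAsFactors = FALSE))
}

# Random A/C/G/T string.
random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Small simulated cohort shared by pipeline tests (kept modest for speed).
small_cohort_config <- function(seed = 11L) {
  cfg <- default_cohort_config(seed = seed)
  cfg$n_families <- 12L
  cfg
}
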