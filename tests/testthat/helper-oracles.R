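# Independent oracles and small fixture builders shared across tests.

# Brute-force eigensystem of the covariance matrix via singular value
# decomposition of the centred data -- an independent route to the same
# eigenproblem that shape_pca() solves with eigen().
svd_pca_oracle <- function(x) {
  x <- as.matrix(x)
  ctr <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  vals <- sv$d^2 / (nrow(x) - 1)
  list(eigenvalues = vals, eigenvectors = sv$v)
}

# Brute-force best-ratio search: explicit two-sample statistics per pair,
# no covariance-matrix shortcut.
brute_force_best_ratio <- function(L, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  chars <- colnames(L)
  best <- NULL
  for (i in seq_along(chars)) {
    for (j in seq_along(chars)) {
      if (j <= i) next
      r <- L[, i] - L[, j]
      r1 <- r[groups == lv[1L]]
      r2 <- r[groups == lv[2L]]
      sp <- sqrt(((length(r1) - 1) * var(r1) + (length(r2) - 1) * var(r2)) /
                   (length(r1) + length(r2) - 2))
      delta <- abs(mean(r1) - mean(r2)) / sp
      if (is.null(best) || delta > best$delta)
        best <- list(pair = c(chars[i], chars[j]), delta = delta)
    }
  }
  best
}

# Closed-form one-way two-group F from summary statistics.
f_from_summaries <- function(n1, m1, s1, n2, m2, s2) {
  gm <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ssb <- n1 * (m1 - gm)^2 + n2 * (m2 - gm)^2
  ssw <- (n1 - 1) * s1^2 + (n2 - 1) * s2^2
  (ssb / 1) / (ssw / (n1 + n2 - 2))
}

# A numeric vector rescaled to an exact sample mean and SD.
with_exact_moments <- function(x, mean, sd) {
  z <- (x - base::mean(x)) / stats::sd(x)
  z * sd + mean
}

# Tiny complete measurement matrix fixture on a subset of characters.
toy_matrix <- function(n = 6, chars = c("hwi.l", "teg.l", "fm2.l", "fm3.l"),
                       seed = 42) {
  vals <- tetrixmra:::with_seed(seed, {
    matrix(exp(rnorm(n * length(chars), mean = 1, sd = 0.2)),
           n, length(chars), dimnames = list(NULL, chars))
  })
  measurement_matrix(vals, morph = rep(c("bipunctata", "kraussi"),
                                       length.out = n))
}
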