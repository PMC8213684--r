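test_that("isosize is the geometric mean and is scale-equivariant", {
  vals <- matrix(c(1, 2, 4, 8,
                   1, 1, 1, 1), 2, 4, byrow = TRUE,
                 dimnames = list(NULL, c("hwi.l", "teg.l", "fm2.l", "fm3.l")))
  m <- measurement_matrix(vals)
  iso <- compute_isosize(m)
  expect_equal(unname(iso), c(2 * sqrt(2), 1), tolerance = 1e-12)

  m3 <- measurement_matrix(vals * c(3, 1))  # scale first specimen by 3
  iso3 <- compute_isosize(m3)
  expect_equal(unname(iso3), c(3 * 2 * sqrt(2), 1), tolerance = 1e-12)

  vals[1, 1] <- NA
  expect_error(compute_isosize(measurement_matrix(vals)), "impute")
})

test_that("log-shape rows sum to zero and are isometry-invariant", {
  m <- gen_morphometrics(morpho_sim_config(
    n_per_morph = c(bipunctata = 10, kraussi = 10), seed = 2))
  shp <- shape_transform(m)
  expect_lt(max(abs(rowSums(shp))), 1e-10)

  # an isometric specimen has all-zero shape; scalar multiples coincide
  vals <- rbind(rep(2.5, 4), c(1, 2, 3, 4), 10 * c(1, 2, 3, 4))
  colnames(vals) <- c("hwi.l", "teg.l", "fm2.l", "fm3.l")
  s <- shape_transform(measurement_matrix(vals))
  expect_equal(unname(s[1, ]), rep(0, 4), tolerance = 1e-12)
  expect_equal(s[2, ], s[3, ], tolerance = 1e-12)
})

test_that("shape PCA matches an independent SVD solver on small problems", {
  for (seed in 1:3) {
    m <- toy_matrix(n = 20, chars = c("hwi.l", "teg.l", "fm2.l", "fm3.l",
                                      "prn.l"), seed = seed)
    shp <- shape_transform(m)
    fit <- shape_pca(shp)
    oracle <- svd_pca_oracle(shp)
    expect_equal(fit$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
    for (k in seq_len(ncol(shp) - 1L)) {  # skip the null-space component
      expect_equal(abs(sum(fit$eigenvectors[, k] * oracle$eigenvectors[, k])),
                   1, tolerance = 1e-8)
    }
  }
})

test_that("eigenvectors are orthonormal, sign-fixed, with a zero-eigenvalue
           equal-weights component", {
  m <- gen_morphometrics(morpho_sim_config(
    n_per_morph = c(bipunctata = 40, kraussi = 40), seed = 6))
  fit <- shape_pca(shape_transform(m))
  p <- ncol(fit$eigenvectors)
  expect_equal(crossprod(fit$eigenvectors), diag(p), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (k in seq_len(p))
    expect_gt(fit$eigenvectors[which.max(abs(fit$eigenvectors[, k])), k], 0)
  expect_lt(fit$eigenvalues[p], 1e-12)
  expect_equal(unname(abs(fit$eigenvectors[, p])), rep(1 / sqrt(p), p),
               tolerance = 1e-6)
  expect_equal(sum(fit$variance_explained), 100, tolerance = 1e-10)
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
})

test_that("two characters force the (1,-1)/sqrt(2) shape contrast", {
  vals <- matrix(exp(rnorm(20, 1, 0.2)), 10, 2,
                 dimnames = list(NULL, c("hwi.l", "teg.l")))
  fit <- shape_pca(shape_transform(measurement_matrix(vals)))
  expect_equal(unname(sort(abs(fit$eigenvectors[, 1]))),
               rep(1 / sqrt(2), 2), tolerance = 1e-10)
})

test_that("duplicating every specimen leaves eigenvectors and variance
           shares unchanged", {
  m <- toy_matrix(n = 12, seed = 31)
  shp <- shape_transform(m)
  f1 <- shape_pca(shp)
  f2 <- shape_pca(rbind(shp, shp))
  expect_equal(f1$eigenvectors, f2$eigenvectors, tolerance = 1e-9)
  expect_equal(f1$variance_explained, f2$variance_explained,
               tolerance = 1e-9)
})

test_that("end-to-end isometry invariance: rescaling one specimen changes
           nothing downstream", {
  m <- gen_morphometrics(morpho_sim_config(
    n_per_morph = c(bipunctata = 12, kraussi = 12), seed = 13))
  vals2 <- m$values
  vals2[5, ] <- vals2[5, ] * 7.3
  m2 <- measurement_matrix(vals2, specimen_id = m$specimen_id,
                           morph = m$morph)
  s1 <- shape_transform(m); s2 <- shape_transform(m2)
  expect_equal(s1, s2, tolerance = 1e-10)
  p1 <- shape_pca(s1); p2 <- shape_pca(s2)
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(p1$scores, p2$scores, tolerance = 1e-10)
  r1 <- ratio_spectrum(s1, p1, n_boot = 50, seed = 1)
  r2 <- ratio_spectrum(s2, p2, n_boot = 50, seed = 1)
  expect_equal(r1$coefficient, r2$coefficient, tolerance = 1e-10)
})
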