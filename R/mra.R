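#' Isometric size (isosize) of each specimen
#'
#' Isosize is the geometric mean of all retained measurements of a
#' specimen, the scalar size measure of multivariate ratio analysis.
#' Scaling a specimen's measurements by `c > 0` scales its isosize by
#' exactly `c`.
#'
#' @param x A complete [measurement_matrix()] (impute first if needed).
#' @return Named numeric vector of isosizes (mm), one per specimen.
#' @export
compute_isosize <- function(x) {
  stopifnot(inherits(x, "measurement_matrix"))
  if (anyNA(x$values))
    stop("matrix has missing cells; run impute_missing() first")
  exp(rowMeans(log(x$values)))
}

#' Log-shape transform
#'
#' Divides each measurement by the specimen's isosize and takes natural
#' logs: `log(value) - log(isosize)`.  This removes isometric size
#' entirely, so every specimen's shape row sums to zero and exact scalar
#' multiples of a specimen have identical shape rows.
#'
#' @param x A complete [measurement_matrix()].
#' @param isosize Optional precomputed isosize vector.
#' @return Numeric matrix of log-shape values (specimens x characters).
#' @export
shape_transform <- function(x, isosize = compute_isosize(x)) {
  stopifnot(inherits(x, "measurement_matrix"))
  if (anyNA(x$values))
    stop("matrix has missing cells; run impute_missing() first")
  log(x$values) - log(isosize)
}

#' Principal component analysis of shape
#'
#' Eigendecomposition of the covariance matrix of log-shape values
#' (columns centred).  Because each shape row sums to zero, one eigenvalue
#' is numerically zero with an equal-weights eigenvector; it is retained
#' in the output.  Each eigenvector is oriented so that its
#' largest-magnitude coefficient is positive.
#'
#' @param shape Log-shape matrix from [shape_transform()].
#' @return An object of class `shape_pca`: list with `eigenvalues`
#'   (non-increasing), `eigenvectors` (columns, orthonormal, sign-fixed),
#'   `scores` (centred specimen scores), `variance_explained` (percent per
#'   component).
#' @export
shape_pca <- function(shape) {
  shape <- as.matrix(shape)
  n <- nrow(shape)
  if (n < 2L) stop("shape PCA needs at least 2 specimens")
  ctr <- scale(shape, center = TRUE, scale = FALSE)
  S <- crossprod(ctr) / (n - 1)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  for (k in seq_len(ncol(vecs))) {
    top <- which.max(abs(vecs[, k]))
    if (vecs[top, k] < 0) vecs[, k] <- -vecs[, k]
  }
  dimnames(vecs) <- list(colnames(shape),
                         paste0("PC", seq_len(ncol(vecs))))
  scores <- ctr %*% vecs
  structure(
    list(eigenvalues = vals, eigenvectors = vecs, scores = scores,
         variance_explained = 100 * vals / sum(vals)),
    class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  k <- min(4L, length(x$eigenvalues))
  cat("Shape PCA\n  variance explained (%):",
      paste(sprintf("%s %.1f", colnames(x$eigenvectors)[seq_len(k)],
                    x$variance_explained[seq_len(k)]), collapse = ", "),
      "...\n")
  invisible(x)
}

#' PCA ratio spectrum with bootstrap confidence intervals
#'
#' Arranges the eigenvector coefficients of one shape PC along an axis.
#' Characters at opposite extremes of the spectrum form the body ratios
#' with the largest influence on that component; characters close together
#' or in the middle form negligible ratios.  Uncertainty is assessed by a
#' nonparametric bootstrap over specimens: each replicate's eigenvector is
#' sign-aligned to the full-data coefficients by dot product, and
#' percentile intervals are taken at the requested confidence (the
#' interval is widened, if necessary, to contain the point coefficient).
#'
#' @param shape Log-shape matrix.
#' @param pca Optional [shape_pca()] of `shape`.
#' @param axis Component number (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param conf Confidence level in (0, 1); default 0.68.
#' @param seed Integer seed for resampling.
#' @param resampler Optional function `n -> indices` overriding bootstrap
#'   resampling (diagnostics; e.g. `seq_len` collapses the intervals onto
#'   the point coefficients).
#' @return An object of class `ratio_spectrum`: data frame with columns
#'   `character`, `coefficient`, `lower`, `upper`, ordered by coefficient
#'   (ties broken alphabetically by code); attributes `axis`, `conf`,
#'   `n_boot`.
#' @export
ratio_spectrum <- function(shape, pca = shape_pca(shape), axis = 1,
                           n_boot = 1000, conf = 0.68, seed = 1,
                           resampler = NULL) {
  shape <- as.matrix(shape)
  if (conf <= 0 || conf >= 1) stop("conf must be strictly between 0 and 1")
  if (axis < 1 || axis > ncol(pca$eigenvectors))
    stop("axis outside the available components")
  if (n_boot < 1) stop("n_boot must be at least 1")
  point <- pca$eigenvectors[, axis]
  n <- nrow(shape)
  draw <- resampler %||% function(n) sample.int(n, n, replace = TRUE)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- draw(n)
      ctr <- scale(shape[idx, , drop = FALSE], center = TRUE, scale = FALSE)
      e <- eigen(crossprod(ctr) / (length(idx) - 1), symmetric = TRUE)
      v <- e$vectors[, axis]
      if (sum(v * point) < 0) v <- -v
      v
    }, numeric(ncol(shape)))
  })
  alpha <- (1 - conf) / 2
  lims <- apply(boot, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
  out <- data.frame(
    character = colnames(shape),
    coefficient = unname(point),
    lower = pmin(lims[1L, ], point),
    upper = pmax(lims[2L, ], point),
    stringsAsFactors = FALSE)
  out <- out[order(-out$coefficient, out$character), ]
  rownames(out) <- NULL
  structure(out, class = c("ratio_spectrum", "data.frame"),
            axis = axis, conf = conf, n_boot = n_boot)
}

#' Plot a PCA ratio spectrum
#'
#' Coefficients on a vertical axis with horizontal bootstrap bars, the
#' conventional way of reading off influential body ratios.
#'
#' @param x A [ratio_spectrum()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ratio_spectrum <- function(x, ...) {
  graphics::plot(rep(0, nrow(x)), x$coefficient, xlim = c(-1, 2),
                 xaxt = "n", xlab = "", pch = 16,
                 ylab = sprintf("PC%d coefficient", attr(x, "axis")), ...)
  graphics::segments(-0.15, x$lower, -0.15, x$upper)
  graphics::text(0.15, x$coefficient, x$character, adj = 0, cex = 0.7)
  invisible(x)
}
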