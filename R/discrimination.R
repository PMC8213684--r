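#' Classify specimens by the standard wing ratio
#'
#' The traditional rule for the two-morph complex: the ratio of full hind
#' wing length to tegmen length is at least 2.5 in *bipunctata* and below
#' 2.5 in *kraussi*; the boundary belongs to *bipunctata*.  The historical
#' variant uses only the part of the hind wing protruding beyond the
#' tegmen with threshold 1.5; since `(hwi - teg)/teg = hwi/teg - 1`, the
#' two forms are algebraically equivalent.
#'
#' @param hwi_l Hind wing length(s), mm; with `protruding = TRUE`, the
#'   length of the protruding part only.
#' @param teg_l Tegmen length(s), mm.
#' @param protruding Interpret `hwi_l` as the protruding part (threshold
#'   1.5 instead of 2.5)?
#' @return Character vector of `"bipunctata"` / `"kraussi"`.
#' @examples
#' classify_standard_ratio(5.0, 2.0)   # ratio 2.5 -> bipunctata
#' classify_standard_ratio(4.98, 2.0)  # ratio 2.49 -> kraussi
#' @export
classify_standard_ratio <- function(hwi_l, teg_l, protruding = FALSE) {
  if (any(!is.finite(hwi_l)) || any(!is.finite(teg_l)) ||
      any(hwi_l <= 0) || any(teg_l <= 0))
    stop("wing and tegmen lengths must be finite and strictly positive")
  ratio <- hwi_l / teg_l + if (protruding) 1 else 0
  ifelse(ratio >= 2.5, "bipunctata", "kraussi")
}

# Pooled within-group covariance matrix for a two-level grouping.
pooled_within_cov <- function(L, groups) {
  lv <- levels(groups)
  parts <- lapply(lv, function(g) {
    Xg <- L[groups == g, , drop = FALSE]
    (nrow(Xg) - 1) * stats::cov(Xg)
  })
  Reduce(`+`, parts) / (nrow(L) - length(lv))
}

#' Extract the best discriminating body ratios for two groups
#'
#' For every unordered pair of characters, the log-ratio
#' `log(num) - log(den)` is scored by its standardised group separation
#' `delta = |mean difference| / pooled within-group SD`.  The first
#' extracted ratio maximises delta; each subsequent ratio maximises
#' `delta * (1 - max |rho|)`, where rho are the pooled within-group
#' correlations with the previously extracted ratios, so that successive
#' ratios are both discriminating and least redundant.  Because log-ratios
#' are differences of log values, delta is identical for a ratio and its
#' reciprocal and invariant to rescaling the units of any character; each
#' ratio is reported oriented so that the first group level has the larger
#' mean.  Ties are broken alphabetically by character code.
#'
#' @param x A complete [measurement_matrix()], or a matrix of log-scale
#'   (or log-shape) values.
#' @param groups Two-level factor (or labels) of length `nrow(x)`; if `x`
#'   is a measurement matrix, defaults to its morph labels.
#' @param k Number of ratios to extract (default 3; truncated with a
#'   warning if fewer pairs are available).
#' @param exclude Character codes to leave out of all pairs.
#' @return An object of class `ratio_extraction`: data frame with columns
#'   `numerator`, `denominator`, `delta`, `max_abs_corr_prev` (NA for the
#'   first ratio), plus attribute `corr_with_previous`, a list of the
#'   per-ratio correlation vectors.
#' @export
extract_ratios <- function(x, groups = NULL, k = 3, exclude = character(0)) {
  if (inherits(x, "measurement_matrix")) {
    if (anyNA(x$values))
      stop("matrix has missing cells; run impute_missing() first")
    groups <- groups %||% x$morph
    L <- log(x$values)
  } else {
    L <- as.matrix(x)
    if (is.null(groups)) stop("groups must be supplied for a plain matrix")
  }
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L)
    stop("exactly two groups required, got ", nlevels(groups))
  if (any(table(groups) < 2L))
    stop("each group needs at least 2 specimens")
  if (length(exclude) > 0L) {
    exclude <- canonical_codes(exclude)
    L <- L[, !colnames(L) %in% exclude, drop = FALSE]
  }
  p <- ncol(L)
  if (p < 2L) stop("need at least two characters after exclusions")

  lv <- levels(groups)
  m1 <- colMeans(L[groups == lv[1L], , drop = FALSE])
  m2 <- colMeans(L[groups == lv[2L], , drop = FALSE])
  S <- pooled_within_cov(L, groups)
  dm <- m1 - m2

  pairs <- utils::combn(colnames(L), 2L)
  ratio_stats <- apply(pairs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    v <- S[i, i] + S[j, j] - 2 * S[i, j]
    diff <- dm[i] - dm[j]
    delta <- if (v < 1e-12) 0 else abs(diff) / sqrt(v)
    # orient numerator-first so the first group level has the larger mean
    if (diff < 0) c(j, i, delta) else c(i, j, delta)
  })
  cand <- data.frame(numerator = ratio_stats[1L, ],
                     denominator = ratio_stats[2L, ],
                     delta = as.numeric(ratio_stats[3L, ]),
                     stringsAsFactors = FALSE)

  ratio_cov <- function(a, b) {
    # covariance between log-ratios a = (a1 - a2), b = (b1 - b2) under S
    S[a[1L], b[1L]] - S[a[1L], b[2L]] - S[a[2L], b[1L]] + S[a[2L], b[2L]]
  }
  n_avail <- nrow(cand)
  if (k > n_avail) {
    warning("only ", n_avail, " ratio pairs available; truncating k")
    k <- n_avail
  }
  chosen <- integer(0)
  corr_prev <- list()
  max_corr <- rep(NA_real_, k)
  ord <- order(cand$numerator, cand$denominator)  # alphabetical tie-break
  for (step in seq_len(k)) {
    remaining <- setdiff(ord, chosen)
    if (step == 1L) {
      score <- cand$delta
      rho <- NULL
    } else {
      rho_mat <- vapply(remaining, function(ci) {
        a <- c(cand$numerator[ci], cand$denominator[ci])
        va <- ratio_cov(a, a)
        vapply(chosen, function(cj) {
          b <- c(cand$numerator[cj], cand$denominator[cj])
          vb <- ratio_cov(b, b)
          if (va < 1e-12 || vb < 1e-12) return(0)
          abs(ratio_cov(a, b) / sqrt(va * vb))
        }, 0)
      }, numeric(length(chosen)))
      rho_mat <- matrix(rho_mat, nrow = length(chosen))
      rho <- apply(rho_mat, 2L, max)
      score <- rep(-Inf, n_avail)
      score[remaining] <- cand$delta[remaining] * (1 - rho)
    }
    pick <- remaining[which.max(score[remaining])]
    chosen <- c(chosen, pick)
    if (step > 1L) {
      ki <- match(pick, remaining)
      corr_prev[[step]] <- rho_mat[, ki]
      max_corr[step] <- rho[ki]
    } else {
      corr_prev[[1L]] <- numeric(0)
    }
  }
  out <- cand[chosen, , drop = FALSE]
  out$max_abs_corr_prev <- max_corr
  rownames(out) <- NULL
  structure(out, class = c("ratio_extraction", "data.frame"),
            corr_with_previous = corr_prev, exclude = unname(exclude),
            group_levels = lv)
}

#' @export
print.ratio_extraction <- function(x, ...) {
  cat("Best discriminating ratios (",
      paste(attr(x, "group_levels"), collapse = " vs "), ")\n", sep = "")
  ex <- attr(x, "exclude")
  if (length(ex) > 0L) cat("  excluded:", paste(ex, collapse = ", "), "\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %d. %s / %s   delta = %.2f%s\n", i,
                x$numerator[i], x$denominator[i], x$delta[i],
                if (is.na(x$max_abs_corr_prev[i])) "" else
                  sprintf("  (max |rho| with earlier = %.2f)",
                          x$max_abs_corr_prev[i])))
  }
  invisible(x)
}
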