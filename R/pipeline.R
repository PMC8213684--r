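#' Run the full morphometric delimitation pipeline
#'
#' Convenience wrapper chaining the standard stages on a measurement
#' matrix: imputation of missing cells (if any), isosize, log-shape
#' transform, shape PCA, PCA ratio spectrum of the first shape PC,
#' best-ratio extraction between the two morphs, and the allometry /
#' allometric-scaling ANCOVA of shape PC1 against log-isosize.  Specimens
#' labelled `intermediate` or `unassigned` take part in the unsupervised
#' stages (PCA, spectrum) but are left out of the group-aware stages.
#'
#' @param x A [measurement_matrix()].
#' @param k Number of ratios to extract (default 3).
#' @param exclude Characters to exclude from ratio extraction.
#' @param n_boot Bootstrap replicates for the ratio spectrum.
#' @param seed Seed for imputation and bootstrap.
#' @return A list of class `mra_analysis` with elements `matrix`,
#'   `imputation`, `isosize`, `shape`, `pca`, `spectrum`, `ratios`,
#'   `allometry`.
#' @export
mra_analysis <- function(x, k = 3, exclude = character(0), n_boot = 1000,
                         seed = 1) {
  stopifnot(inherits(x, "measurement_matrix"))
  imp <- impute_missing(x, seed = seed)
  m <- imp$matrix
  iso <- compute_isosize(m)
  shp <- shape_transform(m, iso)
  pca <- shape_pca(shp)
  spec <- ratio_spectrum(shp, pca, axis = 1, n_boot = n_boot, seed = seed)
  core <- m$morph %in% c("bipunctata", "kraussi")
  if (length(unique(m$morph[core])) == 2L && sum(core) >= 6L) {
    ratios <- extract_ratios(
      measurement_matrix(m$values[core, , drop = FALSE],
                         specimen_id = m$specimen_id[core],
                         population = m$population[core],
                         morph = m$morph[core]),
      k = k, exclude = exclude)
    allo <- allometry_analysis(pca$scores[core, 1L], iso[core],
                               m$morph[core])
  } else {
    ratios <- NULL
    allo <- NULL
  }
  structure(list(matrix = m, imputation = imp$report, isosize = iso,
                 shape = shp, pca = pca, spectrum = spec, ratios = ratios,
                 allometry = allo),
            class = "mra_analysis")
}

#' @export
print.mra_analysis <- function(x, ...) {
  print(x$matrix)
  if (x$imputation$n_cells_imputed > 0L) print(x$imputation)
  print(x$pca)
  top <- x$spectrum$character[1L]
  bot <- x$spectrum$character[nrow(x$spectrum)]
  cat(sprintf("  PC1 ratio spectrum extremes: %s (top) vs %s (bottom)\n",
              top, bot))
  if (!is.null(x$ratios)) print(x$ratios)
  if (!is.null(x$allometry)) print(x$allometry)
  invisible(x)
}
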