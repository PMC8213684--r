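#' Impute missing measurements by chained equations
#'
#' Single imputation of missing cells by chained linear regressions on the
#' log scale with predictive-mean matching (PMM).  Each incomplete
#' character is regressed on all other characters over the currently
#' completed data; a missing cell receives the observed value of one of the
#' `donors` specimens whose predicted values are closest to the prediction
#' for the missing cell.  Missing cells are initialised at the column mean
#' and the regressions are swept `iterations` times.  Working on logs and
#' matching to observed donors guarantees strictly positive imputations.
#'
#' Columns with no variation fall back to the column mean through the
#' regression intercept, so a constant column is imputed at its constant.
#'
#' @param x A [measurement_matrix()], possibly with `NA` cells.
#' @param iterations Number of chained-regression sweeps (default 10).
#' @param seed Integer seed; identical seed and input give identical output.
#' @param donors PMM donor-pool size (default 5).
#' @return A list with elements `matrix` (the completed
#'   [measurement_matrix()]) and `report` (class `imputation_report` with
#'   counts `n_cells_imputed`, `n_specimens_affected`, `iterations`,
#'   `seed`).
#' @export
impute_missing <- function(x, iterations = 10, seed = 1, donors = 5) {
  stopifnot(inherits(x, "measurement_matrix"),
            iterations >= 1, donors >= 1)
  vals <- x$values
  miss <- is.na(vals)
  report <- structure(
    list(n_cells_imputed = sum(miss),
         n_specimens_affected = sum(rowSums(miss) > 0L),
         iterations = as.integer(iterations), seed = as.integer(seed)),
    class = "imputation_report")
  if (!any(miss)) return(list(matrix = x, report = report))

  empty <- colSums(!miss) == 0L
  if (any(empty))
    stop("cannot impute: no observed values in column(s) ",
         paste(colnames(vals)[empty], collapse = ", "))

  L <- log(vals)
  # mean initialisation on the log scale
  for (j in which(colSums(miss) > 0L))
    L[miss[, j], j] <- mean(L[!miss[, j], j])

  with_seed(seed, {
    for (it in seq_len(iterations)) {
      for (j in which(colSums(miss) > 0L)) {
        obs <- !miss[, j]
        X <- cbind(1, L[, -j, drop = FALSE])
        fit <- stats::lm.fit(X[obs, , drop = FALSE], L[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0
        pred <- drop(X %*% beta)
        for (i in which(miss[, j])) {
          d <- abs(pred[obs] - pred[i])
          pool <- order(d)[seq_len(min(donors, sum(obs)))]
          donor <- pool[sample.int(length(pool), 1L)]
          L[i, j] <- L[obs, j][donor]
        }
      }
    }
  })

  vals[miss] <- exp(L[miss])
  out <- measurement_matrix(vals, specimen_id = x$specimen_id,
                            population = x$population, morph = x$morph)
  list(matrix = out, report = report)
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf(
    "Imputation: %d cells in %d specimens filled (%d sweeps, seed %d)\n",
    x$n_cells_imputed, x$n_specimens_affected, x$iterations, x$seed))
  invisible(x)
}
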