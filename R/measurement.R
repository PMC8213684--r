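#' Construct a measurement matrix
#'
#' The central data container: specimens in rows, retained morphometric
#' characters in columns, values are strictly positive lengths in mm.
#' Missing body parts are encoded as `NA`; the missing mask is simply
#' `is.na(x$values)`.
#'
#' @param values Numeric matrix (specimens x characters); column names must
#'   be retained character codes (case-insensitive, dots preserved).
#' @param specimen_id Unique specimen identifiers (default: rownames or
#'   `spec<i>`).
#' @param population Population label per specimen (recycled if length 1).
#' @param morph Morph label per specimen, one of [morph_levels()]
#'   (recycled if length 1).
#' @return An object of class `measurement_matrix`: a list with elements
#'   `values`, `specimen_id`, `population`, `morph`.
#' @export
measurement_matrix <- function(values, specimen_id = NULL,
                               population = "unknown",
                               morph = "unassigned") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("measurement matrix needs at least one specimen")
  if (is.null(colnames(values)))
    stop("measurement values need character codes as column names")
  canon <- canonical_codes(colnames(values))
  if (anyNA(canon)) {
    stop("unknown character code(s): ",
         paste(colnames(values)[is.na(canon)], collapse = ", "))
  }
  retained <- retained_characters()
  if (!all(canon %in% retained)) {
    stop("non-retained character(s) not allowed in a measurement matrix: ",
         paste(canon[!canon %in% retained], collapse = ", "))
  }
  if (anyDuplicated(canon))
    stop("duplicated character column(s): ",
         paste(canon[duplicated(canon)], collapse = ", "))
  colnames(values) <- unname(canon)

  if (is.null(specimen_id)) specimen_id <- rownames(values)
  if (is.null(specimen_id))
    specimen_id <- sprintf("spec%03d", seq_len(nrow(values)))
  specimen_id <- as.character(specimen_id)
  if (length(specimen_id) != nrow(values))
    stop("specimen_id length does not match the number of rows")
  if (anyDuplicated(specimen_id))
    stop("duplicate specimen id(s): ",
         paste(unique(specimen_id[duplicated(specimen_id)]), collapse = ", "))
  rownames(values) <- specimen_id

  population <- rep_len(as.character(population), nrow(values))
  morph <- rep_len(as.character(morph), nrow(values))
  bad_morph <- setdiff(unique(morph), morph_levels())
  if (length(bad_morph) > 0L)
    stop("unknown morph label(s): ", paste(bad_morph, collapse = ", "))

  bad <- which(!is.na(values) & values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "nonpositive measurement at specimen '%s', character '%s' (%g mm)",
      specimen_id[bad[1L, 1L]], colnames(values)[bad[1L, 2L]],
      values[bad[1L, , drop = FALSE]]))
  }

  structure(
    list(values = values, specimen_id = specimen_id,
         population = population, morph = morph),
    class = "measurement_matrix")
}

#' @export
print.measurement_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("Measurement matrix: %d specimens x %d characters (mm)\n",
              nrow(x$values), ncol(x$values)))
  cat("  morphs:     ",
      paste(sprintf("%s (%d)", names(table(x$morph)), table(x$morph)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  missing:    %d cells in %d specimens\n",
              n_miss, sum(rowSums(is.na(x$values)) > 0L)))
  invisible(x)
}

#' @export
dim.measurement_matrix <- function(x) dim(x$values)

#' Read a measurement matrix from delimited text
#'
#' Expects a header row `specimen_id,population,morph,<character codes...>`.
#' Empty fields become missing values.
#'
#' @param path File path.
#' @param sep Field delimiter (default comma).
#' @param unknown_columns `"error"` to reject columns that are not canonical
#'   character codes, `"ignore"` to drop them silently.
#' @return A [measurement_matrix()].
#' @export
read_measurements <- function(path, sep = ",",
                              unknown_columns = c("error", "ignore")) {
  unknown_columns <- match.arg(unknown_columns)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          strip.white = TRUE)
  meta_cols <- c("specimen_id", "population", "morph")
  if (!all(meta_cols %in% names(df)))
    stop("header must contain columns: ", paste(meta_cols, collapse = ", "))
  char_cols <- setdiff(names(df), meta_cols)
  canon <- canonical_codes(char_cols)
  known <- !is.na(canon) & canon %in% retained_characters()
  if (any(!known)) {
    if (unknown_columns == "error")
      stop("unknown character column(s): ",
           paste(char_cols[!known], collapse = ", "))
    char_cols <- char_cols[known]
  }
  if (length(char_cols) == 0L) stop("no character columns found")
  vals <- as.matrix(df[char_cols])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric measurement '%s' at row %d, column '%s'",
                 vals[bad[1L, , drop = FALSE]], bad[1L, 1L],
                 char_cols[bad[1L, 2L]]))
  nonpos <- which(!is.na(num) & num <= 0, arr.ind = TRUE)
  if (nrow(nonpos) > 0L)
    stop(sprintf("nonpositive measurement %s at row %d, column '%s'",
                 vals[nonpos[1L, , drop = FALSE]], nonpos[1L, 1L],
                 char_cols[nonpos[1L, 2L]]))
  colnames(num) <- char_cols
  measurement_matrix(num, specimen_id = df$specimen_id,
                     population = df$population, morph = df$morph)
}

#' Write a measurement matrix to delimited text
#'
#' Values are written with six decimals (raw data are mm from pixel
#' measurements); missing cells become empty fields.  A write/read/write
#' cycle is byte-stable for a fixed delimiter.
#'
#' @param x A [measurement_matrix()].
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "measurement_matrix"))
  vals <- x$values
  txt <- array("", dim = dim(vals))
  obs <- !is.na(vals)
  txt[obs] <- sprintf("%.6f", vals[obs])
  header <- paste(c("specimen_id", "population", "morph", colnames(vals)),
                  collapse = sep)
  rows <- apply(cbind(x$specimen_id, x$population, x$morph, txt), 1L,
                paste, collapse = sep)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}
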