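#' Default north-to-south region sequence
#'
#' The Central European regions used for altitudinal profiles, ordered
#' along the north--south axis: the Netherlands, the German federal states
#' from Mecklenburg-Vorpommern to Bavaria, then Austria, Switzerland,
#' Italy and Slovenia.
#'
#' @return Character vector of region codes.
#' @export
region_order_default <- function() {
  c("NL", "DEMV", "DEBB", "DEST", "DESN", "DETH", "DEHE", "DEBW", "DEBY",
    "AT", "CH", "IT", "SL")
}

validate_localities <- function(loc) {
  need <- c("locality_id", "lat", "lon", "altitude_m", "region", "morph",
            "count")
  miss <- setdiff(need, names(loc))
  if (length(miss) > 0L)
    stop("locality table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(abs(loc$lat) > 90) || any(abs(loc$lon) > 180))
    stop("coordinates outside valid ranges")
  if (any(!is.finite(loc$altitude_m))) stop("non-finite altitude(s)")
  bad <- setdiff(unique(loc$morph), c("bipunctata", "kraussi"))
  if (length(bad) > 0L)
    stop("unknown morph label(s) in locality table: ",
         paste(bad, collapse = ", "))
  invisible(loc)
}

#' Detect syntopic localities
#'
#' Records within `merge_radius` metres of each other (great-circle,
#' Haversine) are collapsed into one locality by connected components, so
#' the merge is symmetric, transitive and independent of record order.  A
#' merged locality is syntopic iff both morphs occur in it; its
#' coordinates and altitude are the means over its member records.
#'
#' @param localities A locality table (see [gen_localities()] for the
#'   format).
#' @param merge_radius Merge radius in metres (default 100).
#' @return An object of class `syntopy_report`: list with `localities`
#'   (one row per merged locality: coordinates, altitude, specimen tallies
#'   per morph, `category` in syntopic/bipunctata-only/kraussi-only) and
#'   `counts` (named category totals).
#' @export
detect_syntopy <- function(localities, merge_radius = 100) {
  validate_localities(localities)
  if (merge_radius < 0) stop("merge_radius must be non-negative")
  n <- nrow(localities)
  d <- geosphere::distm(cbind(localities$lon, localities$lat),
                        fun = geosphere::distHaversine)
  adj <- d <= merge_radius
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
  grp <- comp$membership
  rows <- lapply(seq_len(comp$no), function(g) {
    sub <- localities[grp == g, , drop = FALSE]
    nb <- sum(sub$count[sub$morph == "bipunctata"])
    nk <- sum(sub$count[sub$morph == "kraussi"])
    data.frame(
      locality = paste(sort(unique(sub$locality_id)), collapse = "+"),
      lat = mean(sub$lat), lon = mean(sub$lon),
      altitude_m = mean(sub$altitude_m),
      n_bipunctata = nb, n_kraussi = nk,
      category = if (nb > 0L && nk > 0L) "syntopic"
                 else if (nb > 0L) "bipunctata-only" else "kraussi-only",
      stringsAsFactors = FALSE)
  })
  locs <- do.call(rbind, rows)
  counts <- c(syntopic = sum(locs$category == "syntopic"),
              `bipunctata-only` = sum(locs$category == "bipunctata-only"),
              `kraussi-only` = sum(locs$category == "kraussi-only"))
  structure(list(localities = locs, counts = counts,
                 merge_radius = merge_radius),
            class = "syntopy_report")
}

#' @export
print.syntopy_report <- function(x, ...) {
  cat(sprintf(
    "Syntopy report (%d localities after merging at %g m)\n",
    nrow(x$localities), x$merge_radius))
  cat(sprintf("  syntopic: %d   bipunctata-only: %d   kraussi-only: %d\n",
              x$counts["syntopic"], x$counts["bipunctata-only"],
              x$counts["kraussi-only"]))
  invisible(x)
}

#' Altitudinal profile by region and morph
#'
#' Mean and SD of record altitudes per (region, morph) cell, ordered along
#' a stated north--south region sequence.  The SD is reported only for
#' cells with at least two records.
#'
#' @param localities A locality table.
#' @param region_order Region codes in display order; every record's
#'   region must appear here.
#' @return An object of class `altitude_profile`: data frame with columns
#'   `region`, `morph`, `n`, `mean_altitude_m`, `sd_altitude_m`.
#' @export
altitude_profile <- function(localities,
                             region_order = region_order_default()) {
  validate_localities(localities)
  unknown <- setdiff(unique(localities$region), region_order)
  if (length(unknown) > 0L)
    stop("region code(s) not in region_order: ",
         paste(sort(unknown), collapse = ", "))
  cells <- expand.grid(region = region_order,
                       morph = c("bipunctata", "kraussi"),
                       stringsAsFactors = FALSE)
  cells <- cells[order(match(cells$region, region_order), cells$morph), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- localities$region == cells$region[i] &
      localities$morph == cells$morph[i]
    if (!any(sel)) return(NULL)
    alt <- localities$altitude_m[sel]
    data.frame(region = cells$region[i], morph = cells$morph[i],
               n = length(alt), mean_altitude_m = mean(alt),
               sd_altitude_m = if (length(alt) >= 2L) stats::sd(alt)
                               else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("altitude_profile", "data.frame"),
            region_order = region_order)
}
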