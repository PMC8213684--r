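#' Configuration for the morphometric data generator
#'
#' The generator draws, for each specimen, a latent log-size `s` from a
#' normal distribution (morph-specific mean, shared spread) and sets
#' `log(value[char]) = base_log_mean[char] + slope[char] * s +
#' sign(morph) * planted_offset[char] / 2 + noise`, then exponentiates to
#' mm.  Slopes of 1 are isometry; deviations from 1 create static
#' allometry.  `planted_offsets` are bipunctata-minus-kraussi contrasts on
#' the log scale, applied half to each morph so `base_log_means` stay the
#' overall centre.  The default configuration plants a single
#' discriminating contrast of +0.35 log units on hind wing length
#' (`hwi.l`), overlapping size with bipunctata slightly larger, and weak
#' allometry on a few characters -- the structure of the two-morph complex.
#' The default base means put the hind-wing to tegmen ratio near 2.0 in
#' kraussi and near 2.85 in bipunctata, the classically reported
#' separation around the 2.5 threshold.
#'
#' @param n_per_morph Named counts, specimens per morph (default 100 each).
#' @param base_log_means Named per-character location, log-mm.
#' @param allometric_slopes Named per-character slope against latent
#'   log-size (1 = isometry).
#' @param size_sd Named per-morph SD of latent log-size.
#' @param size_offset Mean latent-size difference, bipunctata minus
#'   kraussi, log units.
#' @param planted_offsets Named per-character morph contrast on the log
#'   scale (default: +0.35 on `hwi.l` only).
#' @param residual_sd Per-character residual SD on the log scale (scalar or
#'   named vector).
#' @param missing_rate Fraction of cells deleted completely at random.
#' @param seed Integer seed.
#' @return A list of class `morpho_sim_config`.
#' @export
morpho_sim_config <- function(n_per_morph = c(bipunctata = 100, kraussi = 100),
                              base_log_means = NULL,
                              allometric_slopes = NULL,
                              size_sd = c(bipunctata = 0.06, kraussi = 0.06),
                              size_offset = 0.04,
                              planted_offsets = c(hwi.l = 0.35),
                              residual_sd = 0.025,
                              missing_rate = 0,
                              seed = 1) {
  chars <- retained_characters()
  if (is.null(base_log_means)) {
    mm <- c(bt3.l = 1.10, eye.b = 0.55, eye.h = 0.90, fl5.b = 0.09,
            fl5.l = 0.25, fm2.b = 1.05, fm2.l = 3.60, fm3.b = 2.30,
            fm3.l = 7.00, fro.h = 0.80, hea.b = 2.10, hwi.l = 7.90,
            prn.b = 3.20, prn.l = 9.50, teg.b = 0.90, teg.l = 3.30,
            vrt.b = 1.00)
    base_log_means <- log(mm[chars])
  }
  if (is.null(allometric_slopes)) {
    allometric_slopes <- stats::setNames(rep(1, length(chars)), chars)
    allometric_slopes[c("prn.l", "fm3.l")] <- c(1.10, 1.05)
    allometric_slopes[c("eye.b", "fl5.l")] <- c(0.90, 0.90)
  }
  full <- function(v, default = 0) {
    out <- stats::setNames(rep(default, length(chars)), chars)
    if (!is.null(names(v))) {
      cn <- canonical_codes(names(v))
      if (anyNA(cn)) stop("unknown character in config: ",
                          paste(names(v)[is.na(cn)], collapse = ", "))
      out[cn] <- v
    } else out[] <- rep_len(v, length(chars))
    out
  }
  cfg <- list(
    n_per_morph = n_per_morph,
    characters = chars,
    base_log_means = full(base_log_means),
    allometric_slopes = full(allometric_slopes, default = 1),
    size_sd = size_sd,
    size_offset = size_offset,
    planted_offsets = full(planted_offsets),
    residual_sd = full(residual_sd, default = residual_sd[[1L]]),
    missing_rate = missing_rate,
    seed = seed)
  stopifnot(all(cfg$n_per_morph >= 2), all(cfg$residual_sd > 0),
            missing_rate >= 0, missing_rate < 1)
  class(cfg) <- "morpho_sim_config"
  cfg
}

#' Generate a synthetic measurement matrix
#'
#' Draws specimens from the log-normal single-latent-size model described
#' in [morpho_sim_config()], applies MCAR deletion, and attaches the
#' generating morph labels as ground truth for recovery scoring.
#'
#' @param config A [morpho_sim_config()].
#' @return A [measurement_matrix()] whose `morph` holds the true labels.
#' @export
gen_morphometrics <- function(config = morpho_sim_config()) {
  stopifnot(inherits(config, "morpho_sim_config"))
  if (all(config$allometric_slopes == 0) && all(config$size_sd == 0) &&
      all(config$residual_sd == 0) && sum(config$n_per_morph) > 1)
    warning("degenerate configuration: all slopes and SDs are zero")
  morphs <- c("bipunctata", "kraussi")
  n <- config$n_per_morph[morphs]
  p <- length(config$characters)
  with_seed(config$seed, {
    morph <- rep(morphs, n)
    sgn <- ifelse(morph == "bipunctata", +0.5, -0.5)
    s <- stats::rnorm(sum(n),
                      mean = sgn * config$size_offset,
                      sd = config$size_sd[morph])
    L <- outer(s, config$allometric_slopes) +
      rep(config$base_log_means, each = sum(n)) +
      outer(sgn, config$planted_offsets) +
      matrix(stats::rnorm(sum(n) * p,
                          sd = rep(config$residual_sd, each = sum(n))),
             sum(n), p)
    colnames(L) <- config$characters
    vals <- exp(L)
    if (config$missing_rate > 0) {
      del <- matrix(stats::runif(length(vals)) < config$missing_rate,
                    nrow(vals), ncol(vals))
      # keep every column initialisable
      for (j in which(colSums(!del) == 0L)) del[1L, j] <- FALSE
      vals[del] <- NA_real_
    }
    measurement_matrix(vals,
                       specimen_id = sprintf("sim%04d", seq_len(sum(n))),
                       population = "synthetic", morph = morph)
  })
}

#' Configuration for the microhabitat niche generator
#'
#' Defaults emulate the observed syntopic population: vegetation cover
#' 70 +- 18 % around bipunctata and 40 +- 7 % around kraussi; vegetation
#' height 27 +- 12 cm and 16 +- 4 cm, with 14 and 34 adults respectively,
#' observed May--August.  Cover month effects default to zero; height month
#' effects default to a morph-by-month interaction concentrated in May and
#' August, each morph's effects summing to zero so morph means are
#' preserved.
#'
#' @param n_per_morph Named counts of observations per morph.
#' @param cover_mean_sd Named list, per morph `c(mean, sd)` of cover (%).
#' @param height_mean_sd Named list, per morph `c(mean, sd)` of height (cm).
#' @param month_effects List with matrices `cover` and `height`
#'   (morph x month additive offsets, months May..Aug).
#' @param seed Integer seed.
#' @return A list of class `niche_sim_config`.
#' @export
niche_sim_config <- function(n_per_morph = c(bipunctata = 14, kraussi = 34),
                             cover_mean_sd = list(bipunctata = c(70, 18),
                                                  kraussi = c(40, 7)),
                             height_mean_sd = list(bipunctata = c(27, 12),
                                                   kraussi = c(16, 4)),
                             month_effects = NULL,
                             seed = 1) {
  months <- c("May", "Jun", "Jul", "Aug")
  zero <- matrix(0, 2, 4, dimnames = list(c("bipunctata", "kraussi"), months))
  if (is.null(month_effects)) {
    height_fx <- zero
    height_fx["bipunctata", ] <- c(6, -6, -6, 6)
    height_fx["kraussi", ] <- c(-2, 2, 2, -2)
    month_effects <- list(cover = zero, height = height_fx)
  }
  month_effects <- lapply(month_effects, function(fx) {
    fx <- as.matrix(fx)
    stopifnot(dim(fx) == c(2L, 4L))
    dimnames(fx) <- list(c("bipunctata", "kraussi"), months)
    fx
  })
  cfg <- list(n_per_morph = n_per_morph, cover_mean_sd = cover_mean_sd,
              height_mean_sd = height_mean_sd, month_effects = month_effects,
              months = months, seed = seed)
  class(cfg) <- "niche_sim_config"
  cfg
}

#' Generate synthetic microhabitat observations
#'
#' Cover is drawn from a normal truncated to \[0, 100\] %, height from a
#' normal truncated to positive values, both by reject-and-redraw; months
#' are allocated in rotation within morph.  The pre-truncation location is
#' adjusted so the truncated distribution has exactly the configured mean
#' (the SD contracts slightly under truncation and is reported as
#' realised).
#'
#' @param config A [niche_sim_config()].
#' @return A data frame (`niche_table`) with columns `morph`, `month`,
#'   `cover`, `height`.
#' @export
gen_niche <- function(config = niche_sim_config()) {
  stopifnot(inherits(config, "niche_sim_config"))
  with_seed(config$seed, {
    rows <- lapply(names(config$n_per_morph), function(m) {
      n <- config$n_per_morph[[m]]
      month <- rep_len(config$months, n)
      cfx <- config$month_effects$cover[m, month]
      hfx <- config$month_effects$height[m, month]
      data.frame(
        morph = m, month = factor(month, levels = config$months),
        cover = rnorm_trunc(
          n,
          trunc_adjusted_location(config$cover_mean_sd[[m]][1L] + cfx,
                                  config$cover_mean_sd[[m]][2L], 0, 100),
          config$cover_mean_sd[[m]][2L], 0, 100),
        height = rnorm_trunc(
          n,
          trunc_adjusted_location(config$height_mean_sd[[m]][1L] + hfx,
                                  config$height_mean_sd[[m]][2L], 0, Inf),
          config$height_mean_sd[[m]][2L],
          lower = .Machine$double.eps),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("niche_table", "data.frame")
    out
  })
}

#' Generate a synthetic locality table
#'
#' Localities are scattered over a Central European window (latitude
#' 45.5--53.5 N, longitude 5.5--15.5 E) and assigned to regions by
#' latitude band along the north--south region sequence.  A locality hosts
#' both morphs with probability `syntopy_fraction`, otherwise one morph at
#' random; altitudes are drawn uniformly from the morph's configured range
#' (the range intersection, or midpoint-union if disjoint, for syntopic
#' localities).
#'
#' @param n_loc Number of localities.
#' @param syntopy_fraction Probability that a locality hosts both morphs.
#' @param altitude_ranges Named list, per morph `c(min, max)` altitude in m.
#' @param seed Integer seed.
#' @return A data frame (`locality_table`) with one row per
#'   (locality, morph): `locality_id`, `lat`, `lon`, `altitude_m`,
#'   `region`, `morph`, `count`.
#' @export
gen_localities <- function(n_loc = 286, syntopy_fraction = 0.05,
                           altitude_ranges = list(bipunctata = c(300, 2200),
                                                  kraussi = c(150, 1700)),
                           seed = 1) {
  stopifnot(n_loc >= 1, syntopy_fraction >= 0, syntopy_fraction <= 1)
  regions <- region_order_default()
  with_seed(seed, {
    lat <- stats::runif(n_loc, 45.5, 53.5)
    lon <- stats::runif(n_loc, 5.5, 15.5)
    band <- cut(-lat, breaks = length(regions), labels = regions)
    both <- stats::runif(n_loc) < syntopy_fraction
    lone <- sample(c("bipunctata", "kraussi"), n_loc, replace = TRUE)
    alt_for <- function(morph, syn) {
      r <- altitude_ranges[[morph]]
      if (syn) {
        lo <- max(vapply(altitude_ranges, `[`, 0, 1L))
        hi <- min(vapply(altitude_ranges, `[`, 0, 2L))
        if (lo < hi) r <- c(lo, hi)
      }
      stats::runif(1L, r[1L], r[2L])
    }
    rows <- lapply(seq_len(n_loc), function(i) {
      morphs <- if (both[i]) c("bipunctata", "kraussi") else lone[i]
      alt <- alt_for(morphs[1L], both[i])
      data.frame(locality_id = sprintf("loc%04d", i), lat = lat[i],
                 lon = lon[i], altitude_m = alt,
                 region = as.character(band[i]), morph = morphs,
                 count = pmax(1L, stats::rpois(length(morphs), 2)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("locality_table", "data.frame")
    out
  })
}
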