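#' Sequential (Type-I) analysis of variance table
#'
#' A thin, structured wrapper around `summary(aov())`: sequential sums of
#' squares in the order the factors are given, F statistics against the
#' residual mean square, two-sided p values from the F distribution.  The
#' sequential sums of squares plus the residual sum equal the total sum of
#' squares, and the degrees of freedom sum to `n - 1`.
#'
#' @param response Numeric response vector.
#' @param factors Named list of one or two label vectors (names become the
#'   table's term names).
#' @param interaction For two factors, include their interaction?
#' @return An object of class `anova_table`: data frame with columns
#'   `term`, `df`, `sum_sq`, `mean_sq`, `statistic`, `p_value`, the last
#'   row being the residuals.
#' @export
anova_table <- function(response, factors, interaction = FALSE) {
  if (!is.list(factors)) factors <- list(factor1 = factors)
  if (is.null(names(factors)) || any(names(factors) == ""))
    names(factors) <- paste0("factor", seq_along(factors))
  stopifnot(length(factors) %in% 1:2, is.numeric(response))
  factors <- lapply(factors, function(f) droplevels(factor(f)))
  if (any(vapply(factors, length, 0L) != length(response)))
    stop("factor lengths must match the response")
  if (interaction && length(factors) == 2L) {
    cells <- table(factors[[1L]], factors[[2L]])
    if (any(cells == 0L)) {
      idx <- which(cells == 0L, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "empty design cell (%s = %s, %s = %s); cannot fit the interaction",
        names(factors)[1L], rownames(cells)[idx[1L]],
        names(factors)[2L], colnames(cells)[idx[2L]]))
    }
  }
  dat <- data.frame(.y = response, factors)
  terms <- names(factors)
  rhs <- paste(terms, collapse = " + ")
  if (interaction && length(factors) == 2L)
    rhs <- paste(rhs, paste(terms, collapse = ":"), sep = " + ")
  fml <- stats::as.formula(paste(".y ~", rhs))
  if (length(response) <= sum(vapply(factors, nlevels, 0L)))
    stop("too few observations for the model degrees of freedom")
  fit <- stats::aov(fml, data = dat)
  tab <- summary(fit)[[1L]]
  out <- data.frame(
    term = trimws(rownames(tab)),
    df = tab$Df, sum_sq = tab$`Sum Sq`, mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`, p_value = tab$`Pr(>F)`,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"))
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Sequential ANOVA\n")
  df <- as.data.frame(x)
  df$sum_sq <- signif(df$sum_sq, 5)
  df$mean_sq <- signif(df$mean_sq, 5)
  df$statistic <- ifelse(is.na(df$statistic), "",
                         sprintf("%.2f", df$statistic))
  df$p_value <- ifelse(is.na(df$p_value), "",
                       format.pval(df$p_value, digits = 3))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Allometry and allometric-scaling analysis
#'
#' Regresses a shape axis (typically the first shape PC) on log-isosize
#' separately per group (static allometry within morphs), fits the
#' common-slope ANCOVA model `score ~ log(isosize) + group`, and reports
#' the covariance-adjusted group offset at common size with a normal-theory
#' 95% interval.  If two groups lie on one shared allometric line and are
#' displaced only along it (pure allometric scaling), the offset interval
#' covers zero; a genuine shape difference at common size excludes zero.
#' A one-way ANOVA of log-isosize between groups quantifies the size
#' difference itself.
#'
#' @param shape_scores Numeric vector, one shape-axis value per specimen.
#' @param isosize Isosize vector from [compute_isosize()].
#' @param groups Two-level factor or labels.
#' @param conf Confidence level of the offset interval (default 0.95).
#' @return An object of class `allometry_fit`: list with `per_group`
#'   (data frame: group, n, slope, intercept), `common_slope`, `offset`
#'   (estimate of level 2 minus level 1 at common size, with `se`,
#'   `lower`, `upper`), and `size_anova` (an [anova_table()] of
#'   log-isosize by group).
#' @export
allometry_analysis <- function(shape_scores, isosize, groups, conf = 0.95) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 specimens")
  ls <- log(isosize)
  for (g in levels(groups)) {
    if (stats::sd(ls[groups == g]) == 0)
      stop("isosize constant within group '", g, "'; slope undefined")
  }
  per_group <- do.call(rbind, lapply(levels(groups), function(g) {
    sel <- groups == g
    co <- stats::coef(stats::lm(shape_scores[sel] ~ ls[sel]))
    data.frame(group = g, n = sum(sel), slope = unname(co[2L]),
               intercept = unname(co[1L]), stringsAsFactors = FALSE)
  }))
  ancova <- stats::lm(shape_scores ~ ls + groups)
  est <- stats::coef(ancova)[3L]
  se <- sqrt(diag(stats::vcov(ancova)))[3L]
  tq <- stats::qt(1 - (1 - conf) / 2, df = ancova$df.residual)
  structure(
    list(per_group = per_group,
         common_slope = unname(stats::coef(ancova)[2L]),
         offset = c(estimate = unname(est), se = unname(se),
                    lower = unname(est - tq * se),
                    upper = unname(est + tq * se)),
         conf = conf,
         size_anova = anova_table(ls, stats::setNames(list(groups), "group"))),
    class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometry analysis\n  per-group slopes:\n")
  print(x$per_group, row.names = FALSE)
  cat(sprintf("  common slope: %.4f\n", x$common_slope))
  cat(sprintf(
    "  group offset at common size: %.4f  [%0.4f, %0.4f] (%.0f%%)\n",
    x$offset["estimate"], x$offset["lower"], x$offset["upper"],
    100 * x$conf))
  cat(sprintf("  size ANOVA: F_%d,%d = %.2f, p = %s\n",
              x$size_anova$df[1L], x$size_anova$df[2L],
              x$size_anova$statistic[1L],
              format.pval(x$size_anova$p_value[1L], digits = 3)))
  invisible(x)
}

#' Microhabitat niche analysis
#'
#' For vegetation cover and vegetation height: a two-way morph-by-month
#' sequential ANOVA with interaction, plus mean and SD summaries per morph.
#'
#' @param niche A niche table (data frame with columns `morph`, `month`,
#'   `cover`, `height`), e.g. from [gen_niche()].
#' @param anova Fit the ANOVAs?  With a single morph present this must be
#'   `FALSE` (summaries only).
#' @return An object of class `niche_analysis`: list with `summary`
#'   (per morph and variable: n, mean, sd) and, if requested,
#'   `cover_anova` and `height_anova` ([anova_table()] objects).
#' @export
niche_analysis <- function(niche, anova = TRUE) {
  stopifnot(all(c("morph", "month", "cover", "height") %in% names(niche)))
  morph <- droplevels(factor(niche$morph))
  summ <- do.call(rbind, lapply(c("cover", "height"), function(v) {
    do.call(rbind, lapply(levels(morph), function(m) {
      x <- niche[[v]][morph == m]
      data.frame(morph = m, variable = v, n = length(x),
                 mean = mean(x), sd = stats::sd(x),
                 stringsAsFactors = FALSE)
    }))
  }))
  out <- list(summary = summ)
  if (anova) {
    if (nlevels(morph) < 2L)
      stop("only one morph present; ANOVA impossible ",
           "(call with anova = FALSE for summaries)")
    fac <- list(morph = morph, month = niche$month)
    out$cover_anova <- anova_table(niche$cover, fac, interaction = TRUE)
    out$height_anova <- anova_table(niche$height, fac, interaction = TRUE)
  }
  class(out) <- "niche_analysis"
  out
}

#' @export
print.niche_analysis <- function(x, ...) {
  cat("Microhabitat niche summaries (mean +- SD)\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %-7s n = %2d   %.1f +- %.1f\n", s$morph[i],
                s$variable[i], s$n[i], s$mean[i], s$sd[i]))
  if (!is.null(x$cover_anova)) {
    cat("\nVegetation cover:\n"); print(x$cover_anova)
    cat("\nVegetation height:\n"); print(x$height_anova)
  }
  invisible(x)
}
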