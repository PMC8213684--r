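test_that("sequential sums of squares decompose the total exactly", {
  tetrixmra:::with_seed(14, {
    y <- rnorm(60)
    f1 <- sample(c("a", "b", "c"), 60, replace = TRUE)
    f2 <- sample(c("u", "v"), 60, replace = TRUE)
  })
  tab <- anova_table(y, list(first = f1, second = f2), interaction = TRUE)
  expect_equal(sum(tab$sum_sq), sum((y - mean(y))^2), tolerance = 1e-10)
  expect_equal(sum(tab$df), length(y) - 1L)
  expect_identical(tab$term, c("first", "second", "first:second",
                               "Residuals"))
})

test_that("two-group one-way F matches the closed-form summary-statistic
           value from the printed niche statistics", {
  tetrixmra:::with_seed(7, {
    g1 <- with_exact_moments(rnorm(14), 70, 18)
    g2 <- with_exact_moments(rnorm(34), 40, 7)
  })
  tab <- anova_table(c(g1, g2),
                     list(morph = rep(c("b", "k"), c(14, 34))))
  f_oracle <- f_from_summaries(14, 70, 18, 34, 40, 7)
  expect_equal(f_oracle, 8925 / (5829 / 46), tolerance = 1e-12)
  expect_equal(tab$statistic[1], f_oracle, tolerance = 1e-8)
  expect_equal(round(tab$statistic[1], 2), 70.43)
  expect_equal(tab$df, c(1L, 46L))
})

test_that("an exactly additive two-factor response has zero interaction and
           residual SS", {
  f1 <- rep(c("a", "b"), each = 8)
  f2 <- rep(c("u", "v", "w", "x"), times = 4)
  y <- ifelse(f1 == "a", 1, 5) + match(f2, c("u", "v", "w", "x")) * 2
  tab <- anova_table(y, list(f1 = f1, f2 = f2), interaction = TRUE)
  expect_lt(tab$sum_sq[tab$term == "f1:f2"], 1e-10)
  expect_lt(tab$sum_sq[tab$term == "Residuals"], 1e-10)
})

test_that("permuting group labels gives F with mean near 1", {
  tetrixmra:::with_seed(99, {
    y <- rnorm(200)
    fs <- replicate(200, sample(rep(c("a", "b"), each = 100)),
                    simplify = FALSE)
  })
  f_vals <- vapply(fs, function(f) anova_table(y, list(g = f))$statistic[1],
                   0)
  expect_lt(abs(mean(f_vals) - 1), 0.25)
})

test_that("empty design cells are refused by name when the interaction is
           requested", {
  y <- rnorm(6)
  f1 <- c("a", "a", "a", "b", "b", "b")
  f2 <- c("u", "u", "v", "u", "u", "u")  # cell (b, v) empty
  expect_error(anova_table(y, list(m = f1, t = f2), interaction = TRUE),
               "empty design cell.*b.*v")
})

test_that("allometry fit recovers an exact generating line and refuses
           degenerate groups", {
  iso <- exp(c(seq(0.1, 0.5, length.out = 10),
               seq(0.2, 0.6, length.out = 10)))
  groups <- rep(c("bipunctata", "kraussi"), each = 10)
  score <- ifelse(groups == "bipunctata", 0.3, -0.2) + 1.7 * log(iso)
  # zero-residual fit: lm's vcov warns that inference is degenerate
  fit <- suppressWarnings(allometry_analysis(score, iso, groups))
  expect_equal(fit$per_group$slope, c(1.7, 1.7), tolerance = 1e-10)
  expect_equal(fit$common_slope, 1.7, tolerance = 1e-10)
  expect_equal(unname(fit$offset["estimate"]), -0.5, tolerance = 1e-10)

  expect_error(allometry_analysis(score, rep(c(1, 2), each = 10), groups),
               "constant")
})

test_that("ANCOVA separates allometric scaling from genuine shape offsets", {
  scaling_cfg <- function(s) morpho_sim_config(
    planted_offsets = c(hwi.l = 0), size_offset = 0.1,
    n_per_morph = c(bipunctata = 60, kraussi = 60), seed = s)
  covers <- 0; excludes <- 0
  for (s in 1:20) {
    m <- gen_morphometrics(scaling_cfg(s))
    iso <- compute_isosize(m)
    fit <- shape_pca(shape_transform(m, iso))
    a <- allometry_analysis(fit$scores[, 1], iso, m$morph)
    if (a$offset["lower"] <= 0 && a$offset["upper"] >= 0)
      covers <- covers + 1

    m2 <- gen_morphometrics(morpho_sim_config(
      n_per_morph = c(bipunctata = 60, kraussi = 60), seed = s + 500))
    iso2 <- compute_isosize(m2)
    fit2 <- shape_pca(shape_transform(m2, iso2))
    a2 <- allometry_analysis(fit2$scores[, 1], iso2, m2$morph)
    if (a2$offset["lower"] > 0 || a2$offset["upper"] < 0)
      excludes <- excludes + 1
  }
  expect_gte(covers, 17)      # ~95% nominal coverage over 20 replicates
  expect_equal(excludes, 20)  # planted offset is unmissable
})
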