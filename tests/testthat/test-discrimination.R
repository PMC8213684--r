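test_that("standard-ratio classifier follows the printed rule with the
           boundary on the bipunctata side", {
  expect_equal(classify_standard_ratio(5.0, 2.0), "bipunctata")  # exactly 2.5
  expect_equal(classify_standard_ratio(4.98, 2.0), "kraussi")    # 2.49
  expect_equal(classify_standard_ratio(c(8, 6), c(3, 3)),
               c("bipunctata", "kraussi"))
  expect_error(classify_standard_ratio(-1, 2), "positive")
  expect_error(classify_standard_ratio(5, 0), "positive")
})

test_that("full-wing and protruding-part thresholds are equivalent over
           randomised positive inputs", {
  tetrixmra:::with_seed(2024, {
    hwi <- exp(runif(500, log(0.5), log(20)))
    teg <- exp(runif(500, log(0.5), log(20)))
  })
  full <- classify_standard_ratio(hwi, teg)
  prot <- classify_standard_ratio(hwi - teg + teg, teg)  # identity guard
  expect_identical(full, prot)
  # the protruding part is hwi - teg; restrict to positive protrusions
  pos <- hwi > teg
  prot2 <- classify_standard_ratio((hwi - teg)[pos], teg[pos],
                                   protruding = TRUE)
  expect_identical(prot2, full[pos])
  # monotone in the ratio
  ratio <- hwi / teg
  expect_true(all(ratio[full == "bipunctata"] >= 2.5))
  expect_true(all(ratio[full == "kraussi"] < 2.5))
})

test_that("extractor's first pick equals brute-force maximisation", {
  for (seed in c(1, 2, 3)) {
    m <- gen_morphometrics(morpho_sim_config(
      n_per_morph = c(bipunctata = 6, kraussi = 6), seed = seed))
    sub <- m$values[, c("hwi.l", "teg.l", "fm2.l", "fm3.l"), drop = FALSE]
    L <- log(sub)
    ex <- extract_ratios(L, groups = m$morph, k = 1)
    oracle <- brute_force_best_ratio(L, m$morph)
    expect_setequal(c(ex$numerator[1], ex$denominator[1]), oracle$pair)
    expect_equal(ex$delta[1], oracle$delta, tolerance = 1e-10)
  }
  # and on a wider matrix (all 17 characters, p <= 8 subset rule relaxed
  # by directly checking an 8-character subset)
  m8 <- gen_morphometrics(morpho_sim_config(seed = 4))
  L8 <- log(m8$values[, retained_characters()[1:8]])
  ex8 <- extract_ratios(L8, groups = m8$morph, k = 1)
  o8 <- brute_force_best_ratio(L8, m8$morph)
  expect_setequal(c(ex8$numerator[1], ex8$denominator[1]), o8$pair)
})

test_that("delta is reciprocal-symmetric and unit-rescaling invariant", {
  m <- toy_matrix(n = 16, seed = 10)
  L <- log(m$values)
  ex <- extract_ratios(L, groups = m$morph, k = 3)
  # rescale one character's units (multiply by 1000): deltas unchanged
  L2 <- L
  L2[, "teg.l"] <- L2[, "teg.l"] + log(1000)
  ex2 <- extract_ratios(L2, groups = m$morph, k = 3)
  expect_equal(ex$delta, ex2$delta, tolerance = 1e-10)
  expect_identical(ex$numerator, ex2$numerator)
  # reciprocal: swapping all columns' roles cannot change |delta|
  swapped <- extract_ratios(-L, groups = m$morph, k = 1)
  expect_equal(swapped$delta[1], ex$delta[1], tolerance = 1e-10)
})

test_that("planted-effect recovery: best ratio involves hwi.l across seeds,
           and deltas collapse once hwi.l is excluded", {
  hits <- 0
  for (seed in 1:25) {
    m <- gen_morphometrics(morpho_sim_config(
      n_per_morph = c(bipunctata = 50, kraussi = 50), seed = seed))
    ex <- extract_ratios(m, k = 1)
    if ("hwi.l" %in% c(ex$numerator[1], ex$denominator[1])) hits <- hits + 1
  }
  expect_equal(hits, 25)

  m <- gen_morphometrics(morpho_sim_config(seed = 1))
  with_wing <- extract_ratios(m, k = 1)
  without <- extract_ratios(m, k = 1, exclude = "hwi.l")
  expect_lt(without$delta[1], with_wing$delta[1] / 5)
  expect_false("hwi.l" %in% c(without$numerator, without$denominator))
})

test_that("identical groups give near-zero deltas (null case)", {
  cfg <- morpho_sim_config(planted_offsets = c(hwi.l = 0), size_offset = 0,
                           seed = 33)
  m <- gen_morphometrics(cfg)
  ex <- extract_ratios(m, k = 1)
  expect_lt(ex$delta[1], 1)
})

test_that("argument contract: group structure and k truncation", {
  m <- toy_matrix(n = 8, seed = 20)
  expect_error(extract_ratios(m, groups = rep("a", 8)), "two groups")
  expect_error(extract_ratios(m, groups = c("a", rep("b", 7))),
               "at least 2")
  expect_warning(ex <- extract_ratios(log(m$values), groups = m$morph,
                                      k = 100),
                 "truncat")
  expect_equal(nrow(ex), choose(4, 2))
})
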