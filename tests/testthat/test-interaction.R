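test_that("expected mixture LC50 follows the harmonic combination rule", {
  # frozen by direct evaluation of 1 / (r_A/LC_A + r_B/LC_B)
  expect_equal(expected_mixture_lc50(34.63, 279.37, 0.5, 0.5),
               61.6215484, tolerance = 1e-6)
  expect_equal(expected_mixture_lc50(299.62, 279.37, 0.5, 0.5),
               289.1408812, tolerance = 1e-6)
  # closed-form cases
  expect_identical(expected_mixture_lc50(42, 42, 0.3, 0.7), 42)
  expect_identical(expected_mixture_lc50(17.5, 999, 1, 0), 17.5)
  expect_equal(expected_mixture_lc50(10, 40, 0.5, 0.5), 16)  # harmonic mean
  expect_error(expected_mixture_lc50(10, 40, 0.6, 0.6), "sum to 1")
  expect_error(expected_mixture_lc50(-1, 40), "positive")
})

test_that("expected mixture LC50 lies between the component LC50s for any r", {
  set.seed(12)
  for (i in 1:50) {
    a <- stats::runif(1, 0.01, 500); b <- stats::runif(1, 0.01, 500)
    r <- stats::runif(1)
    m <- expected_mixture_lc50(a, b, r, 1 - r)
    expect_gte(m, min(a, b) - 1e-12)
    expect_lte(m, max(a, b) + 1e-12)
  }
})

test_that("synergism factor is the expected/observed ratio with reciprocal symmetry", {
  expect_equal(synergism_factor(20, 10), 2)
  expect_equal(synergism_factor(5, 5), 1)
  expect_equal(synergism_factor(61.62, 13.41) * synergism_factor(13.41, 61.62),
               1, tolerance = 1e-12)
  expect_error(synergism_factor(0, 3), "positive")
})

test_that("relative potency is a ratio of LC50s with the reference fixed at 1", {
  fx <- bti_fixtures()$datasets
  ref <- fit_logit(fx[["Cyt2Ba"]])
  trt <- fit_logit(fx[["Cry4Aa"]])
  pot <- relative_potency(ref, trt)
  expect_equal(pot$ratio,
               estimate_lc(ref, 0.5)$value / estimate_lc(trt, 0.5)$value)
  expect_lt(pot$fl_lower, pot$ratio)
  expect_gt(pot$fl_upper, pot$ratio)
  self <- relative_potency(ref, ref)
  expect_identical(self$ratio, 1)
  expect_identical(c(self$fl_lower, self$fl_upper), c(1, 1))
})

test_that("parallelism test has the right df, null behaviour and invariances", {
  fx <- bti_fixtures()$datasets
  pair <- fx[c("Cry10Aa", "Cyt2Ba")]
  t1 <- compare_slopes(pair)
  expect_identical(c(t1$df1, t1$df2), c(1L, 8L))
  expect_identical(t1$hypothesis, "equal slopes")
  expect_true(t1$p_value >= 0 && t1$p_value <= 1)

  # a dataset against an exact copy of itself: no slope difference
  copy <- fx[["Cry10Aa"]]
  copy$treatment_label <- "Cry10Aa-copy"
  t0 <- compare_slopes(list(fx[["Cry10Aa"]], copy))
  expect_lt(t0$F, 1e-8)

  # order invariance
  t1r <- compare_slopes(pair[2:1])
  expect_equal(t1r$F, t1$F, tolerance = 1e-9)

  # invariance to rescaling all concentrations by a common factor
  resc <- lapply(pair, function(d)
    bioassay_dataset(d$treatment_label, d$groups$concentration * 3.7,
                     d$groups$n_total, d$groups$n_dead))
  t1s <- compare_slopes(resc)
  expect_equal(t1s$F, t1$F, tolerance = 1e-7)

  # equal-lines hypothesis removes intercepts too
  t2 <- compare_slopes(pair, hypothesis = "equal lines")
  expect_identical(c(t2$df1, t2$df2), c(2L, 8L))

  trio <- compare_slopes(fx[c("Cry10Aa", "Cyt2Ba", "Cry10Aa+Cyt2Ba")])
  expect_identical(c(trio$df1, trio$df2), c(2L, 12L))

  bad <- bioassay_dataset("bad", c(1, 10), c(30, 30), c(30, 30))
  expect_error(compare_slopes(list(fx[["Cry10Aa"]], bad)), "not fittable")
})

test_that("single-concentration screen flags synergy candidates by margin", {
  fx <- bti_fixtures()$screen
  # rows: Cry10Aa / Cyt2Ba / Cry10Aa+Cyt2Ba, then Cry4Aa, Cry4Ba, Cry11Aa sets
  expect_true(screen_mixture(fx[1, ], fx[2, ], fx[3, ])$flagged)    # 93 vs 31
  expect_true(screen_mixture(fx[4, ], fx[5, ], fx[6, ])$flagged)    # 100 vs 31
  expect_false(screen_mixture(fx[7, ], fx[8, ], fx[9, ])$flagged)   # 43 vs 32
  expect_false(screen_mixture(fx[10, ], fx[11, ], fx[12, ])$flagged)# 46 vs 40

  even <- screening_record(c("a", "b", "a+b"), c(1, 1, 2), c(50, 40, 50),
                           c(1, 1, 1))
  expect_false(screen_mixture(even[1, ], even[2, ], even[3, ],
                              margin = 0.01)$flagged)
  expect_error(screen_mixture(fx[1, ], fx[2, ], fx[6, ]), "does not name")
  expect_error(screen_mixture(list(treatment_label = "x"), fx[2, ], fx[3, ]),
               "malformed")
})

test_that("synergy table orchestrates the whole pipeline", {
  fx <- bti_fixtures()$datasets
  tab <- synergy_table(fx)
  expect_s3_class(tab, "synergy_table")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$potency[tab$treatment == "Cyt2Ba"], 1)
  mix <- tab[!is.na(tab$lc50_expected), ]
  expect_equal(nrow(mix), 2L)
  expect_true(all(mix$synergism_factor > 1))
  expect_true(all(tab$fl_lower <= tab$lc50 & tab$lc50 <= tab$fl_upper))

  single <- synergy_table(fx["Cry4Aa"], reference = "Cry4Aa")
  expect_equal(nrow(single), 1L)
  expect_true(is.na(single$lc50_expected))
  expect_true(is.na(single$synergism_factor))

  orphan <- fx[["Cry4Aa+Cyt2Ba"]]
  expect_error(synergy_table(list(orphan), reference = "Cry4Aa+Cyt2Ba"),
               "lacks component")
})

test_that("synergy table recomputes expected LC50 for unequal proportions", {
  a <- simulation_spec(0.9, 50, replicates = 4, treatment_label = "A")
  b <- simulation_spec(0.7, 400, replicates = 4, treatment_label = "B")
  ms <- mixture_simulation_spec(a, b, r_a = 0.7, synergy = 1)
  ex <- simulate_mixture_experiment(ms, seed = 21)
  tab <- synergy_table(ex, reference = "A")
  fits <- lapply(ex[c("A", "B")], fit_logit)
  by_hand <- 1 / (0.7 / estimate_lc(fits$A, 0.5)$value +
                    0.3 / estimate_lc(fits$B, 0.5)$value)
  expect_equal(tab$lc50_expected[tab$treatment == "A+B"], by_hand,
               tolerance = 1e-9)
})
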