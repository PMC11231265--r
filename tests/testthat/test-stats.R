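test_that("concordance table counts the 2x2 cells and is label-symmetric", {
  labels <- validation_labels()
  ct <- concordance_table(labels)
  expect_equal(unlist(ct[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(7L, 1L, 0L, 13L))
  expect_equal(ct$n, 21L)

  # all agree -> b = c = 0
  agree <- tibble::tibble(ngs = c("positive", "negative"),
                          reference = c("positive", "negative"))
  cta <- concordance_table(agree)
  expect_equal(cta$b + cta$c, 0L)

  # swapping positive/negative swaps a<->d and b<->c
  flip <- function(x) ifelse(x == "positive", "negative", "positive")
  swapped <- dplyr::mutate(labels, ngs = flip(ngs), reference = flip(reference))
  cts <- concordance_table(swapped)
  expect_equal(c(cts$a, cts$b, cts$c, cts$d), c(ct$d, ct$c, ct$b, ct$a))

  expect_error(concordance_table(tibble::tibble(ngs = "positive", reference = "maybe")),
               class = "abl1kd_validation_error")
  expect_error(concordance_table(tibble::tibble(ngs = "positive")),
               class = "abl1kd_validation_error")
})

test_that("diagnostic metrics match the published 2x2 worked example", {
  dm <- diagnostic_metrics(tibble::tibble(a = 7, b = 1, c = 0, d = 13))
  val <- setNames(dm$value, dm$metric)
  expect_equal(unname(val["sensitivity"]), 100)
  expect_equal(unname(val["specificity"]), 100 * 13 / 14)
  expect_equal(unname(val["ppv"]), 87.5)
  expect_equal(unname(val["npv"]), 100)
  rnd <- setNames(dm$rendered, dm$metric)
  expect_equal(unname(rnd["specificity"]), 92.86)
  dm_int <- diagnostic_metrics(tibble::tibble(a = 7, b = 1, c = 0, d = 13), "integer")
  expect_equal(dm_int$rendered[dm_int$metric == "ppv"], 88)

  # balanced table: everything 50
  dm50 <- diagnostic_metrics(tibble::tibble(a = 1, b = 1, c = 1, d = 1))
  expect_true(all(dm50$value[dm50$metric != "concordance"] == 50))

  # degenerate: no positives anywhere -> sensitivity undefined, not 0
  dm0 <- diagnostic_metrics(tibble::tibble(a = 0, b = 0, c = 0, d = 10))
  v0 <- setNames(dm0$value, dm0$metric)
  expect_true(is.na(v0["sensitivity"]))
  expect_true(is.na(v0["ppv"]))
  expect_equal(unname(v0["specificity"]), 100)
  expect_equal(unname(v0["npv"]), 100)
  # all defined metrics in [0, 100]
  expect_true(all(dm0$value[!is.na(dm0$value)] >= 0 & dm0$value[!is.na(dm0$value)] <= 100))
})

test_that("percent rendering conventions behave at their edge cases", {
  expect_equal(render_percent(92.857142857, "half_up_2dp"), 92.86)
  expect_equal(render_percent(100 * 20 / 21, "truncate_2dp"), 95.23)
  expect_equal(render_percent(87.5, "integer"), 88)
  expect_equal(render_percent(100 * 8 / 63, "half_up_2dp"), 12.70)
  expect_equal(render_percent(c(5.915, 2.9575, 1.47875), "half_up_2dp"),
               c(5.92, 2.96, 1.48))
  expect_true(is.na(render_percent(NA_real_, "integer")))
})

test_that("expected dilution series halves from the initial VAF", {
  expect_equal(expected_dilution_vafs(11.83, 3), c(5.915, 2.9575, 1.47875))
  expect_equal(expected_dilution_vafs(8, 3), c(4, 2, 1))
  expect_length(expected_dilution_vafs(5, 0), 0)
  expect_error(expected_dilution_vafs(0, 3), class = "abl1kd_validation_error")
  # strictly decreasing and memoryless
  s <- expected_dilution_vafs(37.7, 5)
  expect_true(all(diff(s) < 0))
  expect_equal(s[-1], expected_dilution_vafs(37.7 / 2, 4))
})

test_that("dilution analysis pairs series and estimates the LOD", {
  da <- dilution_analysis(expected_dilution_vafs(11.83, 3),
                          c(3.91, 2.78, 2.32), initial_vaf = 11.83)
  expect_equal(attr(da, "lod_estimate"), 2.32)
  expect_equal(da$delta, c(3.91, 2.78, 2.32) - c(5.915, 2.9575, 1.47875))

  none <- dilution_analysis(c(4, 2), c(0, 0), detected = c(FALSE, FALSE))
  expect_true(is.na(attr(none, "lod_estimate")))

  same <- dilution_analysis(c(4, 2), c(4, 2))
  expect_true(all(same$delta == 0))

  expect_error(dilution_analysis(c(4, 2), c(4)), class = "abl1kd_validation_error")
})

test_that("reproducibility stats: absolute differences and OLS vs closed form", {
  pairs <- tibble::tibble(vaf_run1 = c(78.86, 4.17, 60.77),
                          vaf_run2 = c(80.25, 2.31, 56.14))
  rs <- reproducibility_stats(pairs)
  expect_equal(rs$abs_diff, c(1.39, 1.86, 4.63))

  # identical runs: slope 1, r2 1, zero differences
  same <- reproducibility_stats(tibble::tibble(vaf_run1 = c(10, 50, 80),
                                               vaf_run2 = c(10, 50, 80)))
  expect_equal(attr(same, "slope"), 1)
  expect_equal(attr(same, "r_squared"), 1)
  expect_true(all(same$abs_diff == 0))

  # OLS equals the closed-form normal equations on random inputs
  for (seed in 1:10) {
    xy <- withr::with_seed(seed, {
      x <- runif(sample(3:20, 1), 0, 100)
      list(x = x, y = 0.97 * x + rnorm(length(x), 0, 3))
    })
    rs2 <- reproducibility_stats(tibble::tibble(vaf_run1 = xy$x, vaf_run2 = xy$y))
    want <- oracle_ols(xy$x, xy$y)
    expect_equal(attr(rs2, "slope"), want$slope, tolerance = 1e-9)
    expect_equal(attr(rs2, "intercept"), want$intercept, tolerance = 1e-9)
    expect_equal(attr(rs2, "r_squared"), want$r_squared, tolerance = 1e-9)
  }

  # one pair: regression undefined, difference still reported
  one <- reproducibility_stats(tibble::tibble(vaf_run1 = 10, vaf_run2 = 12))
  expect_true(is.na(attr(one, "slope")))
  expect_equal(one$abs_diff, 2)

  # qualitative sample-level concordance
  status <- tibble::tibble(
    status_run1 = c("positive", "positive", "positive", "negative", "negative"),
    status_run2 = c("positive", "positive", "positive", "negative", "negative")
  )
  rs3 <- reproducibility_stats(pairs, status = status)
  expect_equal(attr(rs3, "concordance_pct"), 100)
})

test_that("cohort summary reproduces the designed spectrum shares", {
  reports <- reports_from_truth(default_cohort_spec(), CAT)
  cs <- cohort_summary(reports)
  expect_equal(cs$n_samples, 121L)
  expect_equal(cs$n_positive, 42L)
  expect_equal(cs$n_negative, 79L)
  expect_equal(render_percent(cs$positivity_pct, "half_up_2dp"), 34.71)
  expect_equal(render_percent(cs$negativity_pct, "half_up_2dp"), 65.29)
  expect_equal(cs$n_variants_total, 63L)
  expect_equal(cs$n_compound, 9L)
  top <- cs$spectrum
  expect_equal(top$n[top$protein_change == "T315I"], 14L)
  expect_equal(render_percent(top$pct[top$protein_change == "T315I"], "half_up_2dp"), 22.22)
  expect_equal(render_percent(top$pct[top$protein_change == "F317L"], "half_up_2dp"), 15.87)
  expect_equal(render_percent(top$pct[top$protein_change == "L248V"], "half_up_2dp"), 12.70)
  # conservation: spectrum counts sum to the variant total; shares to 100
  expect_equal(sum(top$n), cs$n_variants_total)
  expect_equal(sum(top$pct), 100)
  expect_equal(cs$vaf_min, 2.3)
  expect_equal(cs$vaf_max, 93.41)
  # compound + single = positive
  gl <- dplyr::bind_rows(lapply(reports, glance))
  expect_equal(sum(gl$classification == "single") + cs$n_compound, cs$n_positive)

  # degenerate cohorts
  neg1 <- cohort_summary(reports["S050"])
  expect_equal(neg1$positivity_pct, 0)
  expect_equal(nrow(neg1$spectrum), 0L)
  one <- cohort_summary(reports["S008"])
  expect_equal(one$spectrum$pct, 100)
  expect_error(cohort_summary(list()), class = "abl1kd_validation_error")
})
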