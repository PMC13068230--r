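test_that("enamel-to-diet conversion subtracts the enrichment and inverts", {
  cfg <- analysis_config()
  expect_equal(enamel_to_diet(-5.0, cfg)$diet_d13C, -19.1)
  expect_equal(enamel_to_diet(0.0, cfg)$diet_d13C, -14.1)
  set.seed(3)
  v <- rnorm(20, -10, 2)
  d <- enamel_to_diet(v, cfg)
  expect_equal(d$diet_d13C + cfg$enrichment_permil, v)
  expect_equal(d$band_hi - d$band_lo, rep(2 * cfg$enrichment_sd, 20))
})

test_that("diet classification follows the pasture-type thresholds", {
  cfg <- analysis_config()
  expect_equal(classify_diet(rep(-23.5, 5), cfg = cfg)$specimen_class, "open_C3")
  expect_equal(classify_diet(rep(-18.0, 5), cfg = cfg)$specimen_class,
               "water_stressed_or_C4")
  expect_equal(classify_diet(rep(-27.6, 5), cfg = cfg)$specimen_class,
               "closed_canopy")
  expect_equal(classify_diet(c(-20, -20.5), cfg = cfg)$class,
               rep("intermediate", 2))
  expect_error(classify_diet(c(-22, -22), d18O = c(1, 2, 3)), "aligned")
})

test_that("winter foddering is flagged from the seasonal d13C/d18O phasing", {
  # d13C at the d18O minimum exceeds d13C at the d18O maximum by 2 permil
  d18O <- c(2, 1, -1, -3, -1, 1)
  diet <- c(-24, -24, -23, -22, -23, -24)
  out <- classify_diet(diet, d18O)
  expect_true(out$winter_foddering)
  expect_equal(out$winter_summer_shift, 2)
  # antiphase reversed: no foddering signal
  out2 <- classify_diet(rev(diet), rev(-d18O))
  expect_false(out2$winter_foddering)
})

test_that("raising the water-stress threshold never adds stressed labels", {
  set.seed(8)
  diet <- runif(50, -30, -15)
  base <- classify_diet(diet, cfg = analysis_config())$class
  stricter <- classify_diet(diet, cfg = analysis_config(stressed_min = -18))$class
  expect_true(all(which(stricter == "water_stressed_or_C4") %in%
                  which(base == "water_stressed_or_C4")))
})

test_that("strontium assignment finds the covering units in midpoint order", {
  reg <- default_baselines()
  expect_true("terra_rossa" %in% assign_sr(0.70846, reg))
  expect_equal(assign_sr(0.70598, reg), "pliocene_basalt")
  expect_equal(assign_sr(0.69, reg), character())
  expect_error(assign_sr(0.708, reg, tolerance = -1), "non-negative")
})

test_that("widening the assignment tolerance only ever adds units", {
  reg <- default_baselines()
  set.seed(12)
  ratios <- runif(40, 0.703, 0.710)
  for (r in ratios) {
    narrow <- suppressMessages(assign_sr(r, reg, tolerance = 1e-4))
    wide <- suppressMessages(assign_sr(r, reg, tolerance = 5e-4))
    expect_true(all(narrow %in% wide))
  }
})

test_that("paired seasonal records join strontium to the d18O extremes", {
  summaries <- suppressWarnings(suppressMessages(
    summarize_sequences(hazor_sequences())))
  rec <- suppressMessages(
    build_paired_records(summaries, hazor_sr(), default_baselines()))
  r5750 <- rec[rec$specimen_id == "5750", ]
  expect_equal(r5750$sr_shift, 7e-5, tolerance = 1e-10)
  r5817 <- rec[rec$specimen_id == "5817", ]
  expect_false(is.na(r5817$sr_at_max))
  expect_true(is.na(r5817$sr_at_min))
  r5751 <- rec[rec$specimen_id == "5751", ]
  expect_true(is.na(r5751$sr_at_max) && is.na(r5751$sr_at_min))
  # a measurement for an unknown specimen is dropped with a warning
  sr_bad <- rbind(hazor_sr(),
                  tibble::tibble(specimen_id = "9999", anchor = "d18O_max",
                                 sr87_86 = 0.7080))
  expect_warning(build_paired_records(summaries, sr_bad), "9999")
})

test_that("group comparison matches the closed-form two-sample t", {
  rec <- tibble::tibble(
    specimen_id = letters[1:8],
    d18O_min = c(-1.2, -0.8, -1.5, -1.0, -3.9, -4.4, -3.6, -4.1))
  cmp <- compare_groups(rec, letters[1:4], letters[5:8])
  a <- rec$d18O_min[1:4]; b <- rec$d18O_min[5:8]
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(cmp$t_statistic, t_hand, tolerance = 1e-10)
  expect_equal(cmp$p_value, 2 * pt(-abs(t_hand), 6), tolerance = 1e-10)
  expect_equal(cmp$mean_difference, mean(a) - mean(b))

  # identical degenerate groups: no difference, p = 1
  rec2 <- tibble::tibble(specimen_id = c("a", "b", "c", "d"),
                         d18O_min = c(-2, -2, -2, -2))
  cmp2 <- compare_groups(rec2, c("a", "b"), c("c", "d"))
  expect_equal(cmp2$mean_difference, 0)
  expect_equal(cmp2$p_value, 1)

  expect_error(compare_groups(rec, "a", letters[5:8]), "fewer than 2")
  expect_error(compare_groups(rec, letters[1:4], letters[4:8]), "disjoint")
})

test_that("pooled and Welch variants agree under equal group variances", {
  set.seed(27)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)  # force equal variances
  rec <- tibble::tibble(specimen_id = as.character(1:60), d18O_min = c(x, y))
  cmp <- compare_groups(rec, as.character(1:30), as.character(31:60))
  expect_equal(cmp$p_value, cmp$p_welch, tolerance = 5e-4)
})

test_that("the winter-minima contrast signs toward the more radiogenic group", {
  summaries <- suppressWarnings(suppressMessages(
    summarize_sequences(hazor_sequences())))
  rec <- suppressMessages(build_paired_records(summaries, hazor_sr()))
  g <- fig_groups_default()
  cmp <- compare_groups(rec, g$group_a, g$group_b, labels = g$labels,
                        exclude = g$exclude)
  # animals on the more radiogenic cover/Dalwe basalts wintered lower and
  # warmer: enriched d18O minima
  expect_gt(cmp$mean_difference, 0)
  expect_lt(cmp$p_value, 0.05)
})

test_that("elevation offsets scale linearly with the lapse rate", {
  cfg <- analysis_config()
  expect_equal(elevation_offset(-0.26, cfg), 100)
  expect_equal(elevation_offset(-0.52, cfg), 200)
  expect_equal(elevation_offset(0, cfg), 0)
  expect_equal(elevation_offset(-0.28, cfg, lapse = "global"), 100)
  expect_error(elevation_offset(1, analysis_config(lapse_local = 0)), "non-zero")
})
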