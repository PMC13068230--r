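test_that("caprine and cattle+equid shares reproduce the reported frequencies", {
  freq <- taxon_frequencies(hazor_nisp(), hazor_grouping())
  pick <- function(g, p) freq$percent[freq$group == g & freq$period == p]
  expect_equal(round_half_up(pick("caprine", "early_IRIIA")), 81)
  expect_equal(round_half_up(pick("caprine", "late_IRIIA")), 63)
  expect_equal(round_half_up(pick("caprine", "IRIIB")), 53)
  expect_equal(round_half_up(pick("cattle_equid", "IRIIB")), 35)
  # shares within a period sum to 100 before rounding
  for (p in unique(freq$period)) {
    expect_equal(sum(freq$percent[freq$period == p]), 100, tolerance = 1e-9)
  }
})

test_that("identity-grouping percentages match the reproducible printed cells", {
  freq <- taxon_frequencies(hazor_nisp())
  pick <- function(g, p) freq$percent[freq$group == g & freq$period == p]
  printed <- list(
    c("Bos cf. taurus", "early_IRIIA", 15), c("Bos cf. taurus", "late_IRIIA", 14),
    c("Bos cf. taurus", "IRIIB", 21), c("Sus scrofa", "late_IRIIA", 4),
    c("Sus scrofa", "IRIIB", 4), c("Equus sp.", "late_IRIIA", 12),
    c("Equus sp.", "IRIIB", 14), c("Dama mesopotamica", "late_IRIIA", 4),
    c("Dama mesopotamica", "IRIIB", 5), c("Gazella cf. gazella", "late_IRIIA", 2),
    c("Gazella cf. gazella", "IRIIB", 2), c("Canis sp.", "late_IRIIA", 1))
  for (cell in printed) {
    expect_equal(round_half_up(pick(cell[1], cell[2])), as.numeric(cell[3]),
                 info = paste(cell[1], cell[2]))
  }
  # sub-1% non-zero shares render as "<1", zeros as "0"
  expect_equal(freq$display[freq$group == "Camelus sp." & freq$period == "IRIIB"],
               "<1")
  expect_equal(freq$display[freq$group == "Camelus sp." &
                            freq$period == "early_IRIIA"], "0")
})

test_that("degenerate and invalid frequency inputs are handled", {
  single <- matrix(10L, 1, 2, dimnames = list("Bos", c("p1", "p2")))
  freq <- taxon_frequencies(single)
  expect_equal(freq$percent, c(100, 100))
  empty <- matrix(c(1L, 0L), 1, 2, dimnames = list("Bos", c("p1", "p2")))
  expect_error(taxon_frequencies(empty), "empty period")
  expect_error(taxon_frequencies(hazor_nisp(), c("Ovis/Capra" = "caprine")),
               "does not cover")
})

test_that("chi-square matches the hand formula and chisq.test oracle", {
  m <- matrix(c(10, 20, 20, 10), 2, 2, byrow = TRUE)
  out <- chi_square(m)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(out$df, 1)

  # independence: identical column proportions give statistic 0
  ind <- outer(c(2, 3, 5), c(10, 20))
  expect_equal(chi_square(ind)$statistic, 0, tolerance = 1e-10)

  set.seed(55)
  for (i in 1:10) {
    r <- sample(2:12, 1); c <- sample(2:5, 1)
    tab <- matrix(rpois(r * c, 8) + 1, r, c)
    mine <- chi_square(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$residuals, unname(ref$residuals) * 1, tolerance = 1e-10,
                 ignore_attr = TRUE)
    # residual sum of squares identity
    expect_equal(sum(mine$residuals^2), mine$statistic, tolerance = 1e-12)
  }
})

test_that("chi-square retains zero rows and rejects doubly-empty margins", {
  m <- matrix(c(5, 7, 0, 0, 6, 4), 3, 2, byrow = TRUE)
  out <- chi_square(m)
  expect_equal(out$df, 2)
  expect_equal(out$residuals[2, ], c(0, 0), ignore_attr = TRUE)
  bad <- matrix(c(5, 0, 0, 0), 2, 2)
  expect_error(chi_square(bad), "zero row margin and a zero column")
})

test_that("the full assemblage association is significant", {
  out <- chi_square(hazor_nisp())
  expect_equal(out$df, 18)
  expect_gt(out$statistic, 0)
  expect_lt(out$p_value, 0.001)
})

test_that("wear codes resolve to age cohorts with overrides and fallbacks", {
  wear <- hazor_wear()
  dist <- suppressWarnings(age_cohorts(wear, wear_mapping("hazor_table1")))
  # the printed assignment for the goat mandible with code e-j is cohort 4
  expect_equal(wear_mapping("hazor_table1")[["e-j"]], 4L)
  expect_equal(sum(dist[, "4"]), 11)  # e-g, e-j, f and the override
  expect_equal(sum(dist[, "3"]), 3)   # the three b-d mandibles
  expect_equal(sum(dist[, "2"]), 1)

  over <- tibble::tibble(specimen_id = "x", period = "p", mws_code = "e-j",
                         cohort_override = 2L)
  expect_equal(unname(age_cohorts(over)[, "2"]), 1L)

  unk <- tibble::tibble(specimen_id = "y", period = "p", mws_code = "zz",
                        cohort_override = NA_integer_)
  expect_warning(d2 <- age_cohorts(unk), "unassigned")
  expect_equal(unname(d2[, "unassigned"]), 1L)
})
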