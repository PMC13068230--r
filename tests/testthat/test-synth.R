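test_that("generators are pure functions of truth and seed", {
  tr <- sequence_truth(noise_sd = 0.4)
  expect_identical(gen_sequence(tr, 9), gen_sequence(tr, 9))
  expect_false(identical(gen_sequence(tr, 9)$d18O, gen_sequence(tr, 10)$d18O))
  # the caller's RNG stream is untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(gen_sequence(tr, 3)); b <- runif(1)
  expect_identical(a, b)

  it <- itinerary_truth("cover_dalwe_basalt", "terra_rossa")
  expect_identical(gen_itinerary(it, 4), gen_itinerary(it, 4))
  pr <- c(0.5, 0.3, 0.2)
  expect_identical(gen_assemblage(pr, c(100, 200), seed = 2),
                   gen_assemblage(pr, c(100, 200), seed = 2))
})

test_that("noiseless synthetic sequences are recovered exactly by the fit", {
  tr <- sequence_truth(A = 2, X = 30, x0 = 12, M = -1, noise_sd = 0, n = 20,
                       crown_mm = 45)
  f <- fit_cosine(gen_sequence(tr, 1))
  expect_equal(f$A, 2, tolerance = 1e-6)
  expect_equal(f$x0 %% 30, 12, tolerance = 1e-6)
  expect_equal(f$X, 30, tolerance = 1e-6)
  expect_equal(f$M, -1, tolerance = 1e-6)
})

test_that("residual noise after fitting matches the generating noise level", {
  tr <- sequence_truth(A = 2, X = 30, M = -1, noise_sd = 0.5, n = 15,
                       crown_mm = 36)
  sds <- vapply(1:100, function(i) {
    ti <- tr
    ti$x0 <- (i %% 10) * 3
    f <- fit_cosine(gen_sequence(ti, seed = 500 + i))
    sqrt(f$rss / (f$n - 4))
  }, 0)
  expect_equal(mean(sds), 0.5, tolerance = 0.1)
})

test_that("wear truncation removes the earliest-formed crown", {
  tr_full <- sequence_truth(n = 10, crown_mm = 40, wear_mm = 0)
  tr_worn <- sequence_truth(n = 10, crown_mm = 40, wear_mm = 15)
  expect_equal(max(gen_sequence(tr_full, 1)$dist_erj_mm), 40)
  expect_equal(max(gen_sequence(tr_worn, 1)$dist_erj_mm), 25)
  expect_error(sequence_truth(crown_mm = 30, wear_mm = 30))
})

test_that("itinerary draws are assignable back to the generating units", {
  it <- itinerary_truth("cover_dalwe_basalt", "terra_rossa")
  ok <- vapply(1:100, function(i) {
    g <- gen_itinerary(it, seed = i)
    all(c("cover_dalwe_basalt" %in% assign_sr(g$sr_true[["d18O_max"]]),
          "terra_rossa" %in% assign_sr(g$sr_true[["d18O_min"]])))
  }, TRUE)
  expect_true(all(ok))
  expect_error(itinerary_truth("nowhere", "terra_rossa"), "absent")
})

test_that("a single-pasture itinerary shows negligible intra-tooth Sr shift", {
  it <- itinerary_truth("banias_spring", "banias_spring")  # point unit
  g <- gen_itinerary(it, seed = 6)
  expect_equal(abs(diff(g$sr$sr87_86)), 0, tolerance = 1e-12)
})

test_that("synthetic assemblages calibrate the chi-square near the null", {
  pr <- c(a = 0.4, b = 0.35, c = 0.25)
  pvals <- vapply(1:100, function(i) {
    m <- gen_assemblage(cbind(pr, pr, pr), c(1e4, 1e4, 1e4), seed = i)
    chi_square(m)$p_value
  }, 0)
  expect_gte(mean(pvals > 0.05), 0.9)
  expect_error(gen_assemblage(pr, c(-5)), "negative")
  expect_error(gen_assemblage(c(0.5, 0.4), 100), "sum to 1")
})

test_that("synthetic assemblages recover the generating proportions", {
  obs <- hazor_nisp()
  props <- sweep(obs, 2, colSums(obs), "/")
  m <- gen_assemblage(props, c(162, 275, 300), seed = 77)
  freq <- taxon_frequencies(m)
  target <- taxon_frequencies(obs)
  idx <- match(paste(freq$group, freq$period), paste(target$group, target$period))
  # multinomial sampling error at these totals stays within a few percent
  expect_lt(max(abs(freq$percent - target$percent[idx])), 8)
})

test_that("cohort generation recovers the birth-season window span", {
  g0 <- gen_cohort(5, center = 0.3, span = 0, seed = 21,
                   truth = sequence_truth(noise_sd = 0.2))
  fits0 <- fit_all(g0$sequences)
  expect_lt(circular_span(fits0$pos_max_norm[fits0$converged]), 0.06)

  g <- gen_cohort(50, center = 0.5, span = 0.5, seed = 22,
                  truth = sequence_truth(noise_sd = 0.3))
  fits <- fit_all(g$sequences)
  est <- circular_span(fits$pos_max_norm[fits$converged])
  expect_lt(abs(est - 0.5), 0.1)

  g1 <- gen_cohort(1, center = 0.2, span = 0.4, seed = 23)
  f1 <- fit_all(g1$sequences)
  expect_equal(circular_span(f1$pos_max_norm[f1$converged]), 0)
})
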