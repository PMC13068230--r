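test_that("noiseless cosine data are recovered essentially exactly", {
  x <- seq(45 / 20, 45, length.out = 20)
  y <- cosine_value(x, A = 2, x0 = 12, X = 30, M = -1)
  f <- fit_cosine(make_seq(x, y))
  expect_true(f$converged)
  expect_equal(f$A, 2, tolerance = 1e-6)
  expect_equal(f$x0, 12, tolerance = 1e-6)
  expect_equal(f$X, 30, tolerance = 1e-6)
  expect_equal(f$M, -1, tolerance = 1e-6)
  expect_lt(f$p_value, 1e-6)
})

test_that("the fit never loses to a brute-force (X, x0) lattice", {
  set.seed(5)
  for (i in 1:5) {
    x <- seq(2, 20, by = 2)
    y <- cosine_value(x, runif(1, 0.5, 3), runif(1, 0, 20), runif(1, 8, 25),
                      rnorm(1)) + rnorm(10, 0, 0.3)
    f <- fit_cosine(make_seq(x, y), fit_config(min_increments = 8))
    grid_rss <- grid_fit_rss(x, y, X_grid = seq(4, 36, by = 0.1))
    expect_lte(f$rss, grid_rss + 1e-8)
  }
})

test_that("short or flat sequences are reported undetermined, not fitted", {
  x <- seq(2, 14, by = 2)
  f <- fit_cosine(make_seq(x, cosine_value(x, 2, 5, 12, 0)))
  expect_false(f$converged)
  expect_match(f$reason, "increments")

  x2 <- seq(2, 30, by = 2)
  f2 <- fit_cosine(make_seq(x2, cosine_value(x2, 0.2, 5, 12, 0)))
  expect_false(f2$converged)
  expect_match(f2$reason, "range")
})

test_that("derived seasonal positions follow the half-period identity", {
  pos <- derive_positions(list(x0 = 8.2, X = 24.4))
  expect_equal(round_half_up(pos[["x_min"]], 1), 20.4)
  expect_equal(round_half_up(pos[["pos_max_norm"]], 2), 0.34)
  expect_equal(round_half_up(pos[["pos_min_norm"]], 2), 0.84)

  pos2 <- derive_positions(list(x0 = 26.1, X = 29.4))
  expect_equal(round_half_up(pos2[["pos_max_norm"]], 2), 0.89)

  # x0 = X/2 wraps the minimum to the crown origin
  pos3 <- derive_positions(list(x0 = 15, X = 30))
  expect_equal(pos3[["x_min"]], 0)

  expect_error(derive_positions(list(x0 = 1, X = 0)), "positive")

  # modular identity on accepted fits
  set.seed(31)
  for (i in 1:10) {
    x <- seq(2, 36, length.out = 15)
    y <- cosine_value(x, 2, runif(1, 0, 30), 30, 0) + rnorm(15, 0, 0.3)
    f <- fit_cosine(make_seq(x, y))
    expect_equal((f$x_min - f$x0) %% f$X, f$X / 2, tolerance = 1e-9)
    expect_true(f$pos_max_norm >= 0 && f$pos_max_norm < 1)
  }
})

test_that("shifting all distances shifts only the phase", {
  set.seed(7)
  x <- seq(2, 36, length.out = 15)
  y <- cosine_value(x, 2, 11, 30, -1) + rnorm(15, 0, 0.2)
  f0 <- fit_cosine(make_seq(x, y))
  for (shift in c(3.7, 12)) {
    fs <- fit_cosine(make_seq(x + shift, y))
    expect_equal(fs$A, f0$A, tolerance = 1e-4)
    expect_equal(fs$X, f0$X, tolerance = 1e-4)
    expect_equal(fs$M, f0$M, tolerance = 1e-4)
    expect_equal(fs$p_value, f0$p_value, tolerance = 1e-4)
    expect_equal(fs$x0 %% fs$X, (f0$x0 + shift) %% f0$X, tolerance = 1e-3)
  }
})

test_that("fit ANOVA is calibrated for a fixed-period design and anti-conservative under period search", {
  # matched-df oracle: with the period fixed a priori, the harmonic
  # regression F with (2, n-3) df is exactly F-distributed, so p is uniform
  set.seed(19)
  n <- 15
  p_fixed <- replicate(400, {
    x <- seq(2, 30, by = 2)
    y <- rnorm(n)
    th <- 2 * pi * x / 25
    rss <- sum(stats::lm.fit(cbind(1, cos(th), sin(th)), y)$residuals^2)
    tss <- sum((y - mean(y))^2)
    f <- ((tss - rss) / 2) / (rss / (n - 3))
    stats::pf(f, 2, n - 3, lower.tail = FALSE)
  })
  ks <- suppressWarnings(stats::ks.test(p_fixed, "punif"))
  expect_gt(ks$p.value, 0.001)

  # when the period is chosen by the search, the declared (3, n-4) test is
  # anti-conservative: null p-values pile up below 0.5
  set.seed(23)
  p_fit <- replicate(60, {
    x <- seq(2, 30, by = 2)
    f <- fit_cosine(make_seq(x, rnorm(n)))
    f$p_value
  })
  expect_lt(median(p_fit, na.rm = TRUE), 0.4)
})

test_that("parameter recovery holds under the study noise conditions", {
  # 200 seeded cohort members: A = 2 permil, X = 30 mm, noise 0.5 permil,
  # n = 15 increments spanning 1.2 annual cycles
  truth <- sequence_truth(A = 2, X = 30, M = -1, noise_sd = 0.5, n = 15,
                          crown_mm = 36)
  err_pos <- err_X <- numeric(200)
  set.seed(123)
  phases <- runif(200)
  for (i in 1:200) {
    ti <- truth
    ti$x0 <- phases[i] * 30
    f <- fit_cosine(gen_sequence(ti, seed = 1000 + i))
    d <- abs(f$pos_max_norm - phases[i]) %% 1
    err_pos[i] <- min(d, 1 - d)
    err_X[i] <- abs(f$X - 30)
  }
  expect_lt(median(err_pos), 0.05)
  expect_lt(median(err_X), 1.5)
})

test_that("minimal covering arcs match the exhaustive oracle and its invariances", {
  expect_equal(circular_span(c(0.49, 0.05, 0.34, 0.95, 0.21)), 0.54)
  expect_equal(circular_span(c(0.74, 0.32, 0.45)), 0.42)
  expect_equal(circular_span(0.3), 0)
  expect_error(circular_span(numeric()), "empty")
  expect_error(circular_span(c(0.2, 1.2)), "\\[0, 1\\)")

  set.seed(41)
  for (i in 1:25) {
    p <- runif(sample(2:6, 1))
    expect_equal(circular_span(p), span_oracle(p), tolerance = 1e-12)
    # rotation and reflection invariance
    rot <- (p + runif(1)) %% 1
    expect_equal(circular_span(rot), circular_span(p), tolerance = 1e-12)
    expect_equal(circular_span((1 - p) %% 1), circular_span(p), tolerance = 1e-12)
  }
})

test_that("circular offsets wrap correctly and degenerate means warn", {
  expect_equal(circular_offset(0.0, 0.25), 0.25)
  expect_equal(circular_offset(0.9, 0.1), 0.2)
  expect_equal(circular_offset(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_warning(out <- circular_offset(c(0, 0.5), 0.1), "undefined")
  expect_true(is.na(out))
})

test_that("cohort summaries use only accepted fits", {
  fits <- tibble::tibble(specimen_id = c("a", "b", "c"),
                         pos_max_norm = c(0.1, 0.3, NA),
                         converged = c(TRUE, TRUE, FALSE))
  cs <- cohort_seasonality(fits, c("a", "b", "c"), "demo")
  expect_equal(cs$n, 2)
  expect_equal(cs$span_years, 0.2)
  expect_error(cohort_seasonality(fits, "c"), "no accepted fits")
})
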