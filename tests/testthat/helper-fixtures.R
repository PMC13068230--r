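# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

make_seq <- function(x, d18O, d13C = rep(0, length(x)), id = "t",
                     taxon = "sheep/goat", period = "other") {
  out <- tibble::tibble(specimen_id = id, taxon = taxon, period = period,
                        dist_erj_mm = x, d13C = d13C, d18O = d18O)
  class(out) <- c("tooth_sequences", class(out))
  out
}

# long-format NISP rows for the Hazor table, for reader round-trips
nisp_long <- function(counts = hazor_nisp()) {
  data.frame(taxon = rep(rownames(counts), times = ncol(counts)),
             period = rep(colnames(counts), each = nrow(counts)),
             nisp = as.vector(counts))
}

# brute-force 2-D lattice least squares: for each (X, x0) solve A, M linearly
grid_fit_rss <- function(x, y, X_grid, x0_step = 0.1) {
  best <- Inf
  for (X in X_grid) {
    for (x0 in seq(0, X - x0_step, by = x0_step)) {
      z <- cos(2 * pi * (x - x0) / X)
      fit <- stats::lm.fit(cbind(1, z), y)
      rss <- sum(fit$residuals^2)
      if (rss < best) best <- rss
    }
  }
  best
}

# exhaustive minimal covering arc: try every position as the arc start
span_oracle <- function(p) {
  s <- sort(unique(p))
  if (length(s) == 1) return(0)
  widths <- vapply(seq_along(s), function(i) {
    rot <- (s - s[i]) %% 1
    max(rot)
  }, 0)
  min(widths)
}
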