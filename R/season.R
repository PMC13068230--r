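# Cosine seasonality model for intra-tooth d18O sequences.
#
# The model is value(x) = M + A * cos(2 * pi * (x - x0) / X), with amplitude
# A (permil), phase x0 (crown position of the modelled d18O maximum, mm from
# the ERJ), period X (mm of crown growth per annual cycle), and mean level M
# (permil). The position of the modelled minimum is x_min = (x0 + X/2) mod X,
# and normalized season positions are x0/X and x_min/X, fractions of the
# annual cycle. For fixed X the model is linear in (A cos phi, A sin phi, M),
# so the least-squares surface is searched over X only, with a closed-form
# solve at each grid node and a 1-D golden-section refinement.

#' Evaluate the cosine seasonality model
#'
#' @param x crown positions (mm from the ERJ).
#' @param A amplitude (permil), `A >= 0`.
#' @param x0 position of the modelled maximum (mm).
#' @param X period of the annual cycle (mm), `X > 0`.
#' @param M mean level (permil).
#' @return modelled values at `x`.
#' @export
cosine_value <- function(x, A, x0, X, M) {
  M + A * cos(2 * pi * (x - x0) / X)
}

# Closed-form least squares at fixed period: regress y on
# cos(2 pi x / X), sin(2 pi x / X) and an intercept.
solve_at_period <- function(x, y, X) {
  th <- 2 * pi * x / X
  Z <- cbind(1, cos(th), sin(th))
  fit <- stats::lm.fit(Z, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  rss <- sum(fit$residuals^2)
  list(M = unname(cf[1]), a = unname(cf[2]), b = unname(cf[3]), rss = rss)
}

#' Fit the cosine seasonality model
#'
#' Least-squares fit of `M + A cos(2 pi (x - x0) / X)` to one specimen's
#' d18O sequence. The period X is searched on a coarse grid between twice the
#' median band spacing and twice the crown extent (guarding against the
#' half-period local optimum), with the amplitude/phase/mean solved in closed
#' form at each node, then refined by 1-D optimization. The amplitude is
#' reported non-negative with `x0` reduced modulo X; the fit is tested
#' against the constant model with a regression ANOVA (see
#' [anova_fit_test()]).
#'
#' Specimens with fewer than `cfg$min_increments` increments or an observed
#' d18O range below `cfg$min_range_permil` are reported undetermined
#' (`converged = FALSE` with a reason), mirroring the practice of excluding
#' sequences too short to constrain a seasonal extreme.
#'
#' @param seqs one specimen's `tooth_sequences` rows, or a data frame with
#'   `dist_erj_mm` and the isotope column.
#' @param cfg a [fit_config()].
#' @param isotope column to fit; `"d18O"` carries the seasonal signal.
#' @param specimen_id optional specimen selector.
#' @return a list of class `cosine_fit` with elements `specimen_id, A, x0, X,
#'   M, x_min, pos_max_norm, pos_min_norm, rss, tss, n, p_value, converged,
#'   reason`.
#' @export
fit_cosine <- function(seqs, cfg = fit_config(), isotope = "d18O",
                       specimen_id = NULL) {
  s <- one_specimen(seqs, specimen_id)
  x <- s$dist_erj_mm
  y <- s[[isotope]]
  n <- length(y)
  id <- s$specimen_id[1] %||% NA_character_

  undetermined <- function(reason) {
    structure(list(specimen_id = id, A = NA_real_, x0 = NA_real_, X = NA_real_,
                   M = NA_real_, x_min = NA_real_, pos_max_norm = NA_real_,
                   pos_min_norm = NA_real_, rss = NA_real_, tss = NA_real_,
                   n = n, p_value = NA_real_, converged = FALSE,
                   reason = reason),
              class = "cosine_fit")
  }
  if (n < cfg$min_increments) {
    return(undetermined(sprintf("only %d increments (< %d required)",
                                n, cfg$min_increments)))
  }
  rng <- max(y) - min(y)
  if (rng < cfg$min_range_permil) {
    return(undetermined(sprintf("observed range %.2f permil (< %.2f required)",
                                rng, cfg$min_range_permil)))
  }

  spacing <- stats::median(diff(sort(x)))
  extent <- max(x) - min(x)
  bounds <- cfg$x_bounds %||% c(2 * spacing, 2 * extent)
  grid <- seq(bounds[1], bounds[2], by = cfg$x_grid_step)
  if (length(grid) < 2) grid <- bounds
  rss_grid <- vapply(grid, function(X) solve_at_period(x, y, X)$rss, 0)
  best <- which.min(rss_grid)
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(function(X) solve_at_period(x, y, X)$rss,
                         interval = c(lo, hi), tol = cfg$tol)
  X <- opt$minimum
  sol <- solve_at_period(x, y, X)
  A <- sqrt(sol$a^2 + sol$b^2)
  # M + a cos(th) + b sin(th) = M + A cos(th - phi), phi = atan2(b, a);
  # th = 2 pi x / X, so the modelled maximum sits at x0 = phi X / (2 pi).
  x0 <- (atan2(sol$b, sol$a) * X / (2 * pi)) %% X
  fit <- structure(
    list(specimen_id = id, A = A, x0 = x0, X = X, M = sol$M,
         x_min = NA_real_, pos_max_norm = NA_real_, pos_min_norm = NA_real_,
         rss = sol$rss, tss = sum((y - mean(y))^2), n = n,
         p_value = NA_real_, converged = TRUE, reason = ""),
    class = "cosine_fit")
  pos <- derive_positions(fit)
  fit$x_min <- pos[["x_min"]]
  fit$pos_max_norm <- pos[["pos_max_norm"]]
  fit$pos_min_norm <- pos[["pos_min_norm"]]
  fit$p_value <- anova_fit_test(y, fit = fit)
  fit
}

#' @export
print.cosine_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("cosine_fit <%s>: undetermined (%s)\n", x$specimen_id, x$reason))
  } else {
    cat(sprintf(
      "cosine_fit <%s>: A=%.2f x0=%.2f X=%.2f M=%.2f | x0/X=%.2f x_min/X=%.2f p=%.3g\n",
      x$specimen_id, x$A, x$x0, x$X, x$M, x$pos_max_norm, x$pos_min_norm,
      x$p_value))
  }
  invisible(x)
}

#' Derive seasonal positions from a fit
#'
#' The modelled maximum sits at `x_max = x0`; the modelled minimum at
#' `x_min = (x0 + X/2) mod X`. Normalized positions are the ratios to the
#' period X, fractions of the annual cycle in `[0, 1)`.
#'
#' @param fit a `cosine_fit`, or a list/row with `x0` and `X`.
#' @return named numeric `c(x_min, pos_max_norm, pos_min_norm)`.
#' @export
derive_positions <- function(fit) {
  x0 <- fit$x0
  X <- fit$X
  if (!is.finite(X) || X <= 0) stop("period X must be positive", call. = FALSE)
  x0 <- x0 %% X
  x_min <- (x0 + X / 2) %% X
  c(x_min = x_min, pos_max_norm = x0 / X, pos_min_norm = x_min / X)
}

#' Regression ANOVA on a cosine fit
#'
#' Tests the fitted seasonal model against the constant (mean-only) model:
#' `F = ((TSS - RSS) / 3) / (RSS / (n - 4))` on (3, n - 4) degrees of
#' freedom, treating amplitude, phase and period as the three parameters
#' beyond the mean. Perfect fits (RSS = 0) are reported at the smallest
#' representable p-value so the result stays in (0, 1].
#'
#' @param y observed values.
#' @param fitted fitted values (alternative to `fit`).
#' @param fit a converged `cosine_fit` (uses its stored RSS/TSS).
#' @return the p-value, or `NA` when `n <= 4`.
#' @export
anova_fit_test <- function(y, fitted = NULL, fit = NULL) {
  n <- length(y)
  if (n <= 4) return(NA_real_)
  if (!is.null(fit)) {
    rss <- fit$rss
    tss <- fit$tss
  } else {
    stopifnot(length(fitted) == n)
    rss <- sum((y - fitted)^2)
    tss <- sum((y - mean(y))^2)
  }
  if (rss <= .Machine$double.eps * tss) return(.Machine$double.xmin)
  f <- ((tss - rss) / 3) / (rss / (n - 4))
  max(stats::pf(f, 3, n - 4, lower.tail = FALSE), .Machine$double.xmin)
}

#' Fit all specimens in a sequence table
#'
#' @param seqs a multi-specimen `tooth_sequences` tibble.
#' @param cfg a [fit_config()].
#' @return a tibble with one row per specimen: the fitted parameters, derived
#'   positions, ANOVA p-value, and the `converged`/`reason` columns for
#'   undetermined specimens.
#' @export
fit_all <- function(seqs, cfg = fit_config()) {
  fits <- lapply(split(seqs, seqs$specimen_id), fit_cosine, cfg = cfg)
  rows <- lapply(fits, function(f) {
    tibble::tibble(specimen_id = f$specimen_id, n = f$n, A = f$A, x0 = f$x0,
                   X = f$X, M = f$M, x_min = f$x_min,
                   pos_max_norm = f$pos_max_norm, pos_min_norm = f$pos_min_norm,
                   p_value = f$p_value, converged = f$converged,
                   reason = f$reason)
  })
  out <- do.call(rbind, rows)
  out[order(out$specimen_id), ]
}

# ---- circular statistics over normalized season positions -------------------

check_positions <- function(p) {
  if (length(p) == 0) stop("empty position set", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0 | p >= 1)) {
    stop("positions must be finite fractions of a year in [0, 1)", call. = FALSE)
  }
  invisible(p)
}

#' Minimal circular arc covering a set of season positions
#'
#' The cohort spread of birth seasonality: positions are fractions of the
#' annual cycle on the unit circle; the span is 1 minus the largest gap
#' between circularly sorted positions (the shortest arc containing them
#' all). A single position has span 0.
#'
#' @param positions numeric vector of fractions of a year in `[0, 1)`.
#' @return span in years, in `[0, 1)`.
#' @export
circular_span <- function(positions) {
  check_positions(positions)
  s <- sort(unique(positions))
  gaps <- diff(c(s, s[1] + 1))
  1 - max(gaps)
}

#' Circular mean of season positions
#'
#' Vector-mean angle of the positions on the unit circle, as a fraction of a
#' year. When the resultant length is (numerically) zero the mean direction
#' is undefined and `NA` is returned with a warning.
#'
#' @param positions fractions of a year in `[0, 1)`.
#' @return circular mean in `[0, 1)`, or `NA`.
#' @export
circular_mean <- function(positions) {
  check_positions(positions)
  sbar <- mean(sin(2 * pi * positions))
  cbar <- mean(cos(2 * pi * positions))
  if (sqrt(sbar^2 + cbar^2) < 1e-12) {
    warning("resultant length ~ 0: circular mean undefined", call. = FALSE)
    return(NA_real_)
  }
  (atan2(sbar, cbar) / (2 * pi)) %% 1
}

#' Circular offset between two cohorts
#'
#' Absolute circular difference between the circular means of two groups of
#' season positions, in years, wrapped into `[0, 0.5]`.
#'
#' @param group_a,group_b fractions of a year in `[0, 1)`.
#' @return offset in years, or `NA` when either mean is undefined.
#' @export
circular_offset <- function(group_a, group_b) {
  ma <- circular_mean(group_a)
  mb <- circular_mean(group_b)
  if (is.na(ma) || is.na(mb)) return(NA_real_)
  d <- abs(ma - mb) %% 1
  min(d, 1 - d)
}

#' Cohort seasonality summary
#'
#' Summarizes the birth seasonality of a cohort from the accepted fits of its
#' members: the normalized maximum positions, their minimal covering arc
#' (span in years), and the circular mean.
#'
#' @param fits output of [fit_all()] (or a compatible tibble with
#'   `specimen_id`, `pos_max_norm`, `converged`).
#' @param members character vector of specimen ids in the cohort.
#' @param label cohort label.
#' @return a list with `label, members, positions, span_years,
#'   circular_mean, n`.
#' @export
cohort_seasonality <- function(fits, members, label = "cohort") {
  sub <- fits[fits$specimen_id %in% members & fits$converged, ]
  if (nrow(sub) == 0) stop("no accepted fits among cohort members", call. = FALSE)
  pos <- sub$pos_max_norm
  list(label = label, members = sub$specimen_id, positions = pos,
       span_years = circular_span(pos), circular_mean = circular_mean(pos),
       n = nrow(sub))
}
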