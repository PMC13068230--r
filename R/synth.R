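# Synthetic-data generators with known ground truth. Each generator is a
# pure function of (truth, seed): the caller's RNG state is untouched and
# identical inputs give identical outputs. The generators emulate the
# statistical structure the analysis assumes -- sinusoidal seasonal isotope
# sequences with band noise and wear truncation, two-pasture strontium
# itineraries, and multinomial taxon counts -- so every pipeline stage can be
# exercised offline against a known answer.

#' Ground truth for one synthetic tooth sequence
#'
#' @param specimen_id label.
#' @param A amplitude (permil).
#' @param X period of the annual cycle (mm of crown).
#' @param x0 crown position of the d18O maximum (mm); equivalently the birth
#'   phase is `x0 / X` as a fraction of the year.
#' @param M mean level (permil).
#' @param noise_sd Gaussian band-noise standard deviation (permil); the
#'   default 0.1 matches typical analytical precision, larger values
#'   stress-test the fit.
#' @param n number of increments.
#' @param crown_mm crown extent sampled (mm).
#' @param wear_mm crown length lost to wear, removed from the earliest-formed
#'   (largest-distance) end; mimics the erasure of seasonal peaks in older
#'   animals.
#' @param taxon,period labels carried through.
#' @return a list of class `sequence_truth`.
#' @export
sequence_truth <- function(specimen_id = "synth", A = 2, X = 30, x0 = 12,
                           M = -1, noise_sd = 0.1, n = 15, crown_mm = 36,
                           wear_mm = 0, taxon = "sheep/goat", period = "other") {
  stopifnot(A >= 0, X > 0, noise_sd >= 0, n >= 2,
            wear_mm >= 0, wear_mm < crown_mm)
  structure(list(specimen_id = specimen_id, A = A, X = X, x0 = x0, M = M,
                 noise_sd = noise_sd, n = n, crown_mm = crown_mm,
                 wear_mm = wear_mm, taxon = taxon, period = period),
            class = "sequence_truth")
}

#' Generate a synthetic intra-tooth sequence
#'
#' Samples `truth$n` evenly spaced increments over the worn crown (distances
#' from just above the ERJ up to `crown_mm - wear_mm`) and evaluates the
#' cosine model plus Gaussian band noise. The d13C track is generated in
#' antiphase to d18O (winter-enriched), with half the amplitude around a
#' -10 permil level, mirroring the inverse seasonal patterning of diet and
#' imbibed water.
#'
#' @param truth a [sequence_truth()].
#' @param seed integer seed; the generator is deterministic given
#'   `(truth, seed)`.
#' @return a `tooth_sequences` tibble for one specimen.
#' @export
gen_sequence <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "sequence_truth"))
  with_seed(seed, {
    hi <- truth$crown_mm - truth$wear_mm
    x <- seq(hi / truth$n, hi, length.out = truth$n)
    d18O <- cosine_value(x, truth$A, truth$x0, truth$X, truth$M) +
      stats::rnorm(truth$n, 0, truth$noise_sd)
    d13C <- cosine_value(x, truth$A / 2, truth$x0 + truth$X / 2, truth$X, -10) +
      stats::rnorm(truth$n, 0, truth$noise_sd)
    out <- tibble::tibble(specimen_id = truth$specimen_id,
                          taxon = truth$taxon, period = truth$period,
                          dist_erj_mm = x, d13C = d13C, d18O = d18O)
    class(out) <- c("tooth_sequences", class(out))
    out
  })
}

#' Ground truth for a seasonal pasture itinerary
#'
#' A two-season schedule: in each season the animal grazes one geological
#' unit (drawing its strontium from that unit's bioavailable interval) at a
#' location with a characteristic d18O level.
#'
#' @param summer_unit,winter_unit unit ids present in `registry`.
#' @param registry an `sr_registry`.
#' @param summer_d18O,winter_d18O seasonal d18O levels (permil).
#' @param sr_noise_sd measurement noise on ratios.
#' @param d18O_noise_sd measurement noise on the extremes (permil).
#' @return a list of class `itinerary_truth`.
#' @export
itinerary_truth <- function(summer_unit, winter_unit,
                            registry = default_baselines(),
                            summer_d18O = 2, winter_d18O = -3,
                            sr_noise_sd = 0, d18O_noise_sd = 0) {
  units <- c(summer_unit, winter_unit)
  if (!all(units %in% registry$unit_id)) {
    stop("itinerary references unit(s) absent from the registry: ",
         paste(setdiff(units, registry$unit_id), collapse = ", "), call. = FALSE)
  }
  stopifnot(sr_noise_sd >= 0, d18O_noise_sd >= 0)
  structure(list(summer_unit = summer_unit, winter_unit = winter_unit,
                 registry = registry, summer_d18O = summer_d18O,
                 winter_d18O = winter_d18O, sr_noise_sd = sr_noise_sd,
                 d18O_noise_sd = d18O_noise_sd),
            class = "itinerary_truth")
}

#' Generate strontium measurements from a pasture itinerary
#'
#' Draws the summer ratio uniformly within the summer unit's interval and the
#' winter ratio within the winter unit's interval (plus optional measurement
#' noise), anchored at the seasonal d18O extremes. On the noiseless draws,
#' [assign_sr()] recovers the generating unit.
#'
#' @param truth an [itinerary_truth()].
#' @param seed integer seed.
#' @param specimen_id label for the generated records.
#' @return a list with `sr` (measurement tibble, anchors `d18O_max`/
#'   `d18O_min`), `d18O_max`, `d18O_min`, and `sr_true` (noiseless ratios).
#' @export
gen_itinerary <- function(truth, seed = 1L, specimen_id = "synth") {
  stopifnot(inherits(truth, "itinerary_truth"))
  with_seed(seed, {
    reg <- truth$registry
    draw <- function(unit) {
      u <- reg[reg$unit_id == unit, ]
      stats::runif(1, u$sr_lo, u$sr_hi)
    }
    true_max <- draw(truth$summer_unit)  # summer graze at the d18O maximum
    true_min <- draw(truth$winter_unit)
    sr <- tibble::tibble(
      specimen_id = specimen_id,
      anchor = c("d18O_max", "d18O_min"),
      sr87_86 = c(true_max + stats::rnorm(1, 0, truth$sr_noise_sd),
                  true_min + stats::rnorm(1, 0, truth$sr_noise_sd)))
    list(sr = sr,
         d18O_max = truth$summer_d18O + stats::rnorm(1, 0, truth$d18O_noise_sd),
         d18O_min = truth$winter_d18O + stats::rnorm(1, 0, truth$d18O_noise_sd),
         sr_true = c(d18O_max = true_max, d18O_min = true_min))
  })
}

#' Generate a synthetic NISP assemblage
#'
#' Multinomial draws per period column with the given taxon proportions.
#'
#' @param proportions taxon-by-period matrix of proportions (each column sums
#'   to 1), or a single vector used for all periods.
#' @param totals per-period NISP totals (non-negative integers).
#' @param seed integer seed.
#' @return a taxon-by-period count matrix.
#' @export
gen_assemblage <- function(proportions, totals, seed = 1L) {
  if (is.vector(proportions)) {
    proportions <- matrix(proportions, ncol = length(totals),
                          nrow = length(proportions),
                          dimnames = list(names(proportions),
                                          names(totals) %||% paste0("P", seq_along(totals))))
  }
  stopifnot(ncol(proportions) == length(totals))
  if (any(totals < 0)) stop("negative period total", call. = FALSE)
  if (any(abs(colSums(proportions) - 1) > 1e-8)) {
    stop("per-period proportions must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    m <- vapply(seq_along(totals),
                function(j) as.integer(stats::rmultinom(1, totals[j], proportions[, j])),
                integer(nrow(proportions)))
    dimnames(m) <- list(rownames(proportions),
                        colnames(proportions) %||% names(totals))
    m
  })
}

#' Generate a birth cohort of synthetic sequences
#'
#' Draws `n_specimens` birth phases uniformly on a circular window
#' `center +/- span/2` (mod 1) and generates one tooth sequence per animal
#' with phase `x0 = phase * X`. As `n_specimens` grows, the
#' [circular_span()] of the recovered normalized maximum positions converges
#' to `span`.
#'
#' @param n_specimens number of animals.
#' @param center window center (fraction of year).
#' @param span window width (fraction of year, in `[0, 1)`).
#' @param truth a [sequence_truth()] template supplying A, X, M, noise, n,
#'   crown extent.
#' @param seed integer seed.
#' @return a list with `sequences` (multi-specimen `tooth_sequences`) and
#'   `phases` (true birth phases, fractions of a year).
#' @export
gen_cohort <- function(n_specimens, center = 0.5, span = 0.3,
                       truth = sequence_truth(), seed = 1L) {
  stopifnot(n_specimens >= 1, span >= 0, span < 1)
  with_seed(seed, {
    phases <- (center + stats::runif(n_specimens, -span / 2, span / 2)) %% 1
    seeds <- sample.int(.Machine$integer.max, n_specimens)
    seqs <- lapply(seq_len(n_specimens), function(i) {
      ti <- truth
      ti$specimen_id <- sprintf("synth%03d", i)
      ti$x0 <- phases[i] * ti$X
      gen_sequence(ti, seed = seeds[i])
    })
    out <- do.call(rbind, seqs)
    class(out) <- c("tooth_sequences", class(out))
    list(sequences = out, phases = phases)
  })
}
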