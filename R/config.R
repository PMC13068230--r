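#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline: the enamel
#' bioapatite-to-diet carbon enrichment, cosine-fit eligibility and search
#' settings, dietary classification thresholds, elevation lapse rates, and
#' display rounding. Defaults encode the study conditions used throughout the
#' package; all can be overridden per call.
#'
#' @param enrichment_permil enamel-bioapatite-to-diet d13C enrichment
#'   (permil); subtracted from enamel d13C to estimate dietary d13C.
#' @param enrichment_sd 1-sigma uncertainty of the enrichment (permil).
#' @param min_increments minimum number of increments for a cosine fit.
#' @param min_range_permil minimum observed d18O range (permil) for a fit.
#' @param x_grid_step grid step for the period search (mm).
#' @param alpha significance level for the fit ANOVA.
#' @param canopy_max upper bound (exclusive) of closed-canopy dietary d13C.
#' @param open_hi upper bound (inclusive) of open C3 dietary d13C.
#' @param stressed_min lower bound (inclusive) of water-stressed/C4 d13C.
#' @param foddering_min_shift minimum winter-over-summer d13C excess (permil)
#'   to flag winter foddering.
#' @param lapse_local local meteoric-water d18O lapse rate (permil per 100 m,
#'   negative: depletion with elevation).
#' @param lapse_global global lapse rate (permil per 100 m).
#' @param digits_permil display rounding for isotope values (decimal places).
#' @param digits_norm display rounding for normalized season positions.
#' @param seed default random seed for simulation helpers.
#' @return a list of class `"isoherd_config"`.
#' @export
analysis_config <- function(enrichment_permil = 14.1,
                            enrichment_sd = 0.5,
                            min_increments = 8,
                            min_range_permil = 1.0,
                            x_grid_step = 0.5,
                            alpha = 0.05,
                            canopy_max = -26,
                            open_hi = -21,
                            stressed_min = -19,
                            foddering_min_shift = 1.0,
                            lapse_local = -0.26,
                            lapse_global = -0.28,
                            digits_permil = 1,
                            digits_norm = 2,
                            seed = 1L) {
  stopifnot(canopy_max < open_hi, open_hi < stressed_min,
            alpha > 0, alpha < 1,
            enrichment_sd >= 0, min_increments >= 2,
            min_range_permil >= 0, x_grid_step > 0)
  structure(
    list(enrichment_permil = enrichment_permil,
         enrichment_sd = enrichment_sd,
         min_increments = min_increments,
         min_range_permil = min_range_permil,
         x_grid_step = x_grid_step,
         alpha = alpha,
         canopy_max = canopy_max,
         open_hi = open_hi,
         stressed_min = stressed_min,
         foddering_min_shift = foddering_min_shift,
         lapse_local = lapse_local,
         lapse_global = lapse_global,
         digits_permil = digits_permil,
         digits_norm = digits_norm,
         seed = seed),
    class = "isoherd_config")
}

#' Cosine-fit settings
#'
#' Settings for [fit_cosine()]. The underlying published model family carries
#' four extra parameters (a phase offset `p`, a linear trend `b`, and
#' attenuation positions `x_B`, `x_A`); this implementation fixes
#' `p = b = x_B = 0` and `x_A = 1e6` (attenuation disabled), reducing the
#' model to the pure four-parameter cosine. The slots are kept so the
#' reduction is explicit and extensible.
#'
#' @param min_increments minimum increments for eligibility.
#' @param min_range_permil minimum observed range (permil) for eligibility.
#' @param x_grid_step coarse grid step over the period X (mm).
#' @param x_bounds optional length-2 numeric, search bounds for X (mm); when
#'   `NULL`, bounds are `[2 * median band spacing, 2 * crown extent]`.
#' @param tol relative convergence tolerance for the 1-D refinement.
#' @param alpha ANOVA significance level.
#' @param p,b,x_B,x_A fixed extended-model parameters (see Details).
#' @return a list of class `"fit_config"`.
#' @export
fit_config <- function(min_increments = 8,
                       min_range_permil = 1.0,
                       x_grid_step = 0.5,
                       x_bounds = NULL,
                       tol = 1e-8,
                       alpha = 0.05,
                       p = 0, b = 0, x_B = 0, x_A = 1e6) {
  if (!is.null(x_bounds)) {
    stopifnot(length(x_bounds) == 2, all(x_bounds > 0), x_bounds[1] < x_bounds[2])
  }
  stopifnot(x_grid_step > 0, alpha > 0, alpha < 1)
  if (p != 0 || b != 0 || x_B != 0 || x_A != 1e6) {
    stop("extended model parameters (p, b, x_B, x_A) are fixed in this release",
         call. = FALSE)
  }
  structure(
    list(min_increments = min_increments,
         min_range_permil = min_range_permil,
         x_grid_step = x_grid_step,
         x_bounds = x_bounds,
         tol = tol,
         alpha = alpha,
         p = p, b = b, x_B = x_B, x_A = x_A),
    class = "fit_config")
}

#' Read/write a flat key-value configuration file
#'
#' The on-disk format is `key: value` lines (a flat YAML subset); keys mirror
#' the arguments of [analysis_config()].
#'
#' @param path file path.
#' @return for `read_config`, an `isoherd_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = ":")), "")
  known <- names(formals(analysis_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  args <- lapply(vals[keys %in% known], function(v) parse_numeric(v, "config value"))
  names(args) <- keys[keys %in% known]
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @param config an `isoherd_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "isoherd_config"))
  writeLines(sprintf("%s: %s", names(config), unlist(config)), path)
  invisible(path)
}
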