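# Input/output for the tabular formats used throughout the pipeline:
# intra-tooth isotope sequences, per-specimen strontium measurements,
# bioavailable-strontium baseline units, NISP contingency tables, and
# mandibular-wear records. All readers auto-detect comma vs tab delimiters,
# normalize typeset minus signs, and validate against the type invariants.

TAXON_VOCAB  <- c("sheep", "goat", "sheep/goat", "cattle", "gazelle", "other")
PERIOD_VOCAB <- c("early_IRIIA", "late_IRIIA", "IRIIB", "other")

# Canonical taxon labels from the codes used in faunal report tables.
#' Normalize taxon and period labels
#'
#' Maps common zooarchaeological shorthand (O, C, OC, Bos, Gazella, ...) onto
#' the controlled vocabularies `sheep, goat, sheep/goat, cattle, gazelle` and
#' `early_IRIIA, late_IRIIA, IRIIB`. Unknown labels are kept verbatim with a
#' warning; vocabularies are normalization targets, not filters.
#'
#' @param x character vector of labels.
#' @return character vector of normalized labels.
#' @export
normalize_taxon <- function(x) {
  map <- c("o" = "sheep", "ovis" = "sheep", "ovis aries" = "sheep",
           "c" = "goat", "c?" = "goat", "capra" = "goat", "capra hircus" = "goat",
           "oc" = "sheep/goat", "ovis/capra" = "sheep/goat",
           "sheep/goat" = "sheep/goat", "caprine" = "sheep/goat",
           "bos" = "cattle", "bos taurus" = "cattle", "bos cf. taurus" = "cattle",
           "gazella" = "gazelle", "gazella sp." = "gazelle")
  key <- tolower(trimws(x))
  out <- ifelse(key %in% names(map), unname(map[key]),
                ifelse(key %in% TAXON_VOCAB, key, x))
  odd <- !(tolower(out) %in% TAXON_VOCAB)
  if (any(odd)) {
    warning("taxa outside the controlled vocabulary kept verbatim: ",
            paste(unique(out[odd]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname normalize_taxon
#' @export
normalize_period <- function(x) {
  key <- tolower(gsub("[ -]", "_", trimws(x)))
  map <- c("early_iriia" = "early_IRIIA", "late_iriia" = "late_IRIIA",
           "iriib" = "IRIIB", "iriia" = "late_IRIIA")
  out <- ifelse(key %in% names(map), unname(map[key]), x)
  odd <- !(out %in% PERIOD_VOCAB)
  if (any(odd)) {
    warning("periods outside the controlled vocabulary kept verbatim: ",
            paste(unique(out[odd]), collapse = ", "), call. = FALSE)
  }
  out
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

read_table_raw <- function(path) {
  stopifnot(file.exists(path))
  utils::read.delim(path, sep = detect_delim(path), stringsAsFactors = FALSE,
                    check.names = FALSE, strip.white = TRUE)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read intra-tooth isotope sequences
#'
#' Reads a delimited table of per-increment enamel carbonate measurements with
#' one row per milled band: `specimen_id, taxon, period, band_index,
#' dist_erj_mm, d13C_vpdb, d18O_vpdb`. Distances are millimetres from the
#' enamel--root junction (ERJ) to the band midpoint; larger distances lie
#' closer to the crown apex and formed earlier. Increments are returned sorted
#' by distance within specimen.
#'
#' Values outside the plausible enamel-carbonate envelopes (d13C in
#' \[-20, 5\], d18O in \[-15, 10\] permil VPDB) raise a warning but are kept.
#'
#' @param path path to a CSV or TSV file.
#' @return a tibble of class `tooth_sequences`, sorted by specimen and
#'   distance.
#' @export
read_sequences <- function(path) {
  df <- read_table_raw(path)
  # tolerate the common column-name variants
  alias <- c(specimen = "specimen_id", distance = "dist_erj_mm",
             d13C = "d13C_vpdb", d18O = "d18O_vpdb")
  for (a in names(alias)) {
    if (!alias[[a]] %in% names(df) && a %in% names(df)) {
      names(df)[names(df) == a] <- alias[[a]]
    }
  }
  require_columns(df, c("specimen_id", "dist_erj_mm", "d13C_vpdb", "d18O_vpdb"), path)
  if (nrow(df) == 0) {
    warning("no increment rows in ", path, call. = FALSE)
    return(tibble::tibble(specimen_id = character(), taxon = character(),
                          period = character(), dist_erj_mm = numeric(),
                          d13C = numeric(), d18O = numeric()))
  }
  out <- tibble::tibble(
    specimen_id = as.character(df$specimen_id),
    taxon = if ("taxon" %in% names(df)) normalize_taxon(df$taxon) else "other",
    period = if ("period" %in% names(df)) normalize_period(df$period) else "other",
    dist_erj_mm = parse_numeric(df$dist_erj_mm, "distance", seq_len(nrow(df))),
    d13C = parse_numeric(df$d13C_vpdb, "d13C", seq_len(nrow(df))),
    d18O = parse_numeric(df$d18O_vpdb, "d18O", seq_len(nrow(df))))
  validate_sequences(out)
  out <- out[order(out$specimen_id, out$dist_erj_mm), ]
  message(sprintf("read %d increments across %d specimens from %s",
                  nrow(out), length(unique(out$specimen_id)), path))
  class(out) <- c("tooth_sequences", class(out))
  out
}

validate_sequences <- function(df) {
  if (!all(is.finite(df$dist_erj_mm))) stop("non-finite increment distances", call. = FALSE)
  if (!all(is.finite(df$d13C)) || !all(is.finite(df$d18O))) {
    stop("non-finite isotope values", call. = FALSE)
  }
  dup <- duplicated(df[, c("specimen_id", "dist_erj_mm")])
  if (any(dup)) {
    stop("duplicate (specimen, distance) pair(s): ",
         paste(unique(df$specimen_id[dup]), collapse = ", "), call. = FALSE)
  }
  if (any(df$d13C < -20 | df$d13C > 5)) {
    warning("d13C values outside the plausible enamel range [-20, 5] permil",
            call. = FALSE)
  }
  if (any(df$d18O < -15 | df$d18O > 10)) {
    warning("d18O values outside the plausible enamel range [-15, 10] permil",
            call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_sequences
#' @param seqs a `tooth_sequences` tibble.
#' @export
write_sequences <- function(seqs, path) {
  df <- as.data.frame(seqs)
  df$band_index <- stats::ave(df$dist_erj_mm, df$specimen_id,
                              FUN = function(x) rank(x, ties.method = "first"))
  df <- df[, c("specimen_id", "taxon", "period", "band_index",
               "dist_erj_mm", "d13C", "d18O")]
  names(df)[names(df) == "d13C"] <- "d13C_vpdb"
  names(df)[names(df) == "d18O"] <- "d18O_vpdb"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read per-specimen strontium measurements
#'
#' One row per measurement: `specimen_id, anchor, sr87_86`, where `anchor` is
#' `d18O_max` (summer extreme) or `d18O_min` (winter extreme). Ratios outside
#' the biogenic envelope (0.700, 0.720) raise a warning.
#'
#' @param path path to a CSV/TSV file.
#' @return a tibble with columns `specimen_id`, `anchor`, `sr87_86`.
#' @export
read_sr <- function(path) {
  df <- read_table_raw(path)
  require_columns(df, c("specimen_id", "anchor", "sr87_86"), path)
  out <- tibble::tibble(
    specimen_id = as.character(df$specimen_id),
    anchor = trimws(as.character(df$anchor)),
    sr87_86 = parse_numeric(df$sr87_86, "sr87_86", seq_len(nrow(df))))
  validate_sr(out)
  out
}

validate_sr <- function(df) {
  bad <- !df$anchor %in% c("d18O_max", "d18O_min")
  if (any(bad)) {
    stop("unknown anchor label(s): ", paste(unique(df$anchor[bad]), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(df[, c("specimen_id", "anchor")])
  if (any(dup)) {
    stop("duplicate (specimen, anchor) strontium measurement(s)", call. = FALSE)
  }
  out <- stats::na.omit(df$sr87_86)
  if (any(out <= 0.700 | out >= 0.720)) {
    warning("87Sr/86Sr ratio(s) outside the expected envelope (0.700, 0.720)",
            call. = FALSE)
  }
  invisible(df)
}

#' @rdname read_sr
#' @param sr a strontium measurement tibble.
#' @export
write_sr <- function(sr, path) {
  utils::write.csv(as.data.frame(sr), path, row.names = FALSE)
  invisible(path)
}

#' Bioavailable-strontium baseline registry
#'
#' `read_baselines()` reads a registry of named geological units, each with a
#' closed 87Sr/86Sr interval `[sr_lo, sr_hi]` of bioavailable values;
#' `default_baselines()` returns the registry for the Upper Jordan Valley /
#' Galilee / Golan study region: terra rossa soils over Cretaceous
#' limestones (0.70831--0.70883), rendzina soils (0.70790--0.70840), Pliocene
#' cover and Dalwe basalts (0.7074--0.7079), the wider Golan Pliocene basalt
#' range (0.70448--0.70770), and the Banias spring value (0.7072, a point
#' unit).
#'
#' @param path path to a CSV/TSV with columns `unit_id, name, sr_lo, sr_hi`
#'   and optionally `source_note`.
#' @return a tibble of class `sr_registry`.
#' @export
read_baselines <- function(path) {
  df <- read_table_raw(path)
  require_columns(df, c("unit_id", "name", "sr_lo", "sr_hi"), path)
  out <- tibble::tibble(
    unit_id = as.character(df$unit_id),
    name = as.character(df$name),
    sr_lo = parse_numeric(df$sr_lo, "sr_lo", seq_len(nrow(df))),
    sr_hi = parse_numeric(df$sr_hi, "sr_hi", seq_len(nrow(df))),
    source_note = if ("source_note" %in% names(df)) as.character(df$source_note) else "")
  as_sr_registry(out)
}

#' @rdname read_baselines
#' @param df a data frame with the registry columns.
#' @export
as_sr_registry <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"source_note" %in% names(df)) df$source_note <- ""
  if (any(duplicated(df$unit_id))) stop("duplicate unit_id in baseline registry", call. = FALSE)
  if (any(df$sr_lo > df$sr_hi)) {
    bad <- df$unit_id[df$sr_lo > df$sr_hi]
    stop("inverted interval (sr_lo > sr_hi) for unit(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("sr_registry", class(df))
  df
}

#' @rdname read_baselines
#' @export
default_baselines <- function() {
  as_sr_registry(tibble::tibble(
    unit_id = c("terra_rossa", "rendzina", "cover_dalwe_basalt",
                "pliocene_basalt", "banias_spring"),
    name = c("Terra rossa soils (Cretaceous limestones/dolomites)",
             "Rendzina soils (Cretaceous/Neogene chalks and marls)",
             "Pliocene cover and Dalwe basalts",
             "Golan Pliocene basalts (full range)",
             "Banias spring water (Jurassic unit)"),
    sr_lo = c(0.70831, 0.70790, 0.70740, 0.70448, 0.70720),
    sr_hi = c(0.70883, 0.70840, 0.70790, 0.70770, 0.70720),
    source_note = c("bioavailable plant values", "bioavailable plant values",
                    "bioavailable plant values", "bioavailable plant values",
                    "dissolved Sr, point value")))
}

#' @rdname read_baselines
#' @param registry an `sr_registry`.
#' @export
write_baselines <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
  invisible(path)
}

#' Read a NISP count table
#'
#' Reads a long-format table `taxon, period, nisp` and pivots it into a
#' taxon-by-period contingency matrix of NISP (Number of Identified
#' Specimens) counts.
#'
#' @param path path to a CSV/TSV file.
#' @return an integer matrix with taxa as rows and periods as columns.
#' @export
read_nisp <- function(path) {
  df <- read_table_raw(path)
  require_columns(df, c("taxon", "period", "nisp"), path)
  as_assemblage(df)
}

#' @rdname read_nisp
#' @param df long-format data frame with `taxon, period, nisp`.
#' @export
as_assemblage <- function(df) {
  counts <- parse_numeric(df$nisp, "nisp", seq_len(nrow(df)))
  if (any(counts < 0)) stop("negative NISP count", call. = FALSE)
  if (any(counts != floor(counts))) stop("non-integer NISP count", call. = FALSE)
  if (any(duplicated(df[, c("taxon", "period")]))) {
    stop("duplicated (taxon, period) cell", call. = FALSE)
  }
  taxa <- unique(as.character(df$taxon))
  periods <- unique(as.character(df$period))
  m <- matrix(0L, length(taxa), length(periods), dimnames = list(taxa, periods))
  m[cbind(match(df$taxon, taxa), match(df$period, periods))] <- as.integer(counts)
  if (sum(m) <= 0) stop("assemblage grand total must be positive", call. = FALSE)
  message("assemblage grand total NISP = ", sum(m))
  m
}

#' @rdname read_nisp
#' @param counts a taxon-by-period count matrix.
#' @export
write_nisp <- function(counts, path) {
  long <- data.frame(
    taxon = rep(rownames(counts), times = ncol(counts)),
    period = rep(colnames(counts), each = nrow(counts)),
    nisp = as.vector(counts))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read mandibular-wear records
#'
#' One row per aged mandible: `specimen_id, period, mws_code` and optionally
#' `cohort_override` (integer 1--5) for specimens whose cohort was assigned
#' directly.
#'
#' @param path path to a CSV/TSV file.
#' @return a tibble with the wear-record columns.
#' @export
read_wear <- function(path) {
  df <- read_table_raw(path)
  require_columns(df, c("specimen_id", "period", "mws_code"), path)
  if (any(!nzchar(trimws(as.character(df$mws_code))) &
          (!"cohort_override" %in% names(df) | is.na(df$cohort_override)))) {
    warning("empty wear code(s) without cohort override", call. = FALSE)
  }
  tibble::tibble(
    specimen_id = as.character(df$specimen_id),
    period = as.character(df$period),
    mws_code = trimws(as.character(df$mws_code)),
    cohort_override = if ("cohort_override" %in% names(df)) {
      as.integer(df$cohort_override)
    } else NA_integer_)
}
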