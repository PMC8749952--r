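# Single-point median calibration against the internal standard.
#
# The standard's tryptic peptides are equimolar, so the median of their XIC
# peak areas estimates the response of one "typical" peptide at the
# standard's molar amount. Dividing amount by median area gives a response
# factor (fmol per area unit) that converts any codigested peptide's area
# into a molar estimate.

# areas of the standard chimera's peptides detected in one run
standard_peptide_areas <- function(table, spec, run, exclude_reference = FALSE) {
  peptides <- spec$standard_peptides
  if (exclude_reference)
    peptides <- setdiff(peptides, spec$reference_pairs$scrambled)
  rows <- table$run_id == run &
    table$protein_id == spec$standard_protein_id &
    table$peptide_seq %in% peptides
  a <- table$xic_area[rows]
  names(a) <- table$peptide_seq[rows]
  a[a > 0]
}

# area of one specific peptide of one protein in one run (0 if absent)
peptide_area <- function(table, protein, peptide, run) {
  rows <- table$run_id == run & table$protein_id == protein &
    table$peptide_seq == peptide
  if (!any(rows)) return(0)
  sum(table$xic_area[rows])
}

#' Estimate the molar amount of the internal standard in one run
#'
#' Each native/scrambled reference pair compares the scrambled peptide
#' (part of the standard chimera) with its native counterpart from the
#' codigested reference protein of known amount. Because the two sequences
#' ionize near-identically, the scrambled/native area ratio equals the
#' standard/reference molar ratio. The standard amount is the reference
#' amount times the median of the per-pair ratios; pairs in which either
#' peptide was not detected (area 0) are skipped and reported.
#'
#' @param table an [observation_table()].
#' @param spec a [standard_spec()] with at least one reference pair.
#' @param run run label to calibrate.
#' @return list with `amount_fmol`, `per_pair_ratios` (named
#'   `native/scrambled`), and `skipped_pairs`.
#' @export
estimate_standard_amount <- function(table, spec, run) {
  stopifnot(inherits(table, "observation_table"), inherits(spec, "standard_spec"))
  if (!calibration_capable(spec))
    calibration_error("standard spec has no reference pairs; cannot estimate amount")
  if (!run %in% attr(table, "runs"))
    lookup_error(sprintf("run '%s' not present in table", run))
  pairs <- spec$reference_pairs
  ratios <- numeric(0)
  skipped <- character(0)
  for (i in seq_len(nrow(pairs))) {
    native_area <- peptide_area(table, spec$reference_protein_id,
                                pairs$native[i], run)
    scram_area <- peptide_area(table, spec$standard_protein_id,
                               pairs$scrambled[i], run)
    label <- paste0(pairs$native[i], "/", pairs$scrambled[i])
    if (native_area > 0 && scram_area > 0) {
      r <- scram_area / native_area
      names(r) <- label
      ratios <- c(ratios, r)
    } else {
      skipped <- c(skipped, label)
    }
  }
  if (!length(ratios))
    calibration_error(sprintf(
      "no usable reference pair in run '%s' (all native or scrambled areas are 0)",
      run
    ))
  list(
    amount_fmol = spec$reference_amount_fmol * stats::median(ratios),
    per_pair_ratios = ratios,
    skipped_pairs = skipped
  )
}

#' Normalized median abundance (NMA) of the standard in one run
#'
#' A calibrant quality statistic. The reference pairs define the expected
#' XIC area of one standard peptide: `k_ref`, the median native-peptide
#' area per fmol of reference protein, times the standard's estimated molar
#' amount. NMA is the median area of the standard's peptides (the scrambled
#' reference peptides, being the normalizers, are excluded from this
#' median) divided by that expectation. NMA = 1 means the median response
#' of the standard peptides matches the reference-derived response exactly,
#' i.e. the median is an unbiased calibrant; systematically poorly ionizing
#' standard peptides (e.g. sequence-reversed designs) depress it.
#'
#' @inheritParams estimate_standard_amount
#' @return a single dimensionless number.
#' @export
normalized_median_abundance <- function(table, spec, run) {
  est <- estimate_standard_amount(table, spec, run)
  native_areas <- vapply(
    spec$reference_pairs$native,
    function(p) peptide_area(table, spec$reference_protein_id, p, run),
    numeric(1)
  )
  native_areas <- native_areas[native_areas > 0]
  k_ref <- stats::median(native_areas) / spec$reference_amount_fmol
  expected_area <- est$amount_fmol * k_ref
  areas <- standard_peptide_areas(table, spec, run, exclude_reference = TRUE)
  if (!length(areas))
    calibration_error(sprintf(
      "no standard peptide detected in run '%s'", run
    ))
  stats::median(areas) / expected_area
}

#' Fraction of areas lying within a band around their median
#'
#' The near-median fraction: the share of peptide peak areas `a` with
#' `|a - m| / m <= band`, where `m` is the median of the areas. For a
#' well-behaved equimolar standard roughly half of the peptides fall
#' within the default +/-20% band.
#'
#' @param areas positive numeric vector of XIC peak areas.
#' @param band half-width of the relative band (default 0.20).
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' near_median_fraction(c(0.9, 1.0, 1.1, 2.0, 0.3))  # 0.6
near_median_fraction <- function(areas, band = 0.20) {
  areas <- areas[!is.na(areas)]
  if (!length(areas))
    validation_error("near_median_fraction needs at least one area")
  if (any(areas <= 0))
    validation_error("areas must be positive")
  m <- stats::median(areas)
  mean(abs(areas - m) / m <= band)
}

#' Calibrate one run: median single-point calibrant plus QC statistics
#'
#' Determines the standard's molar amount from the reference pairs
#' ([estimate_standard_amount()]), takes the median XIC area of the
#' standard's detected peptides (zeros, i.e. non-detections, excluded) as
#' the single-point calibrant, and derives the response factor
#' `amount / median_area` in fmol per area unit. Also computes the
#' normalized median abundance and the near-median fraction as calibrant
#' quality statistics. A warning is emitted when fewer than 30 standard
#' peptides are detected, below which the median's sampling spread no
#' longer sits on its plateau (see [median_spread_profile()]).
#'
#' @inheritParams estimate_standard_amount
#' @param standard_amount_fmol optionally bypass the reference-pair
#'   estimate with a known standard amount (fmol); NMA is then still
#'   computed from the pairs when available.
#' @return object of class `mbaq_calibration`.
#' @export
median_calibrant <- function(table, spec, run, standard_amount_fmol = NULL) {
  stopifnot(inherits(table, "observation_table"), inherits(spec, "standard_spec"))
  areas <- standard_peptide_areas(table, spec, run)
  if (!length(areas))
    calibration_error(sprintf("no standard peptide detected in run '%s'", run))
  if (length(areas) < 30L)
    warning(sprintf(
      "only %d standard peptide(s) detected in run '%s'; the median is most stable with >= 30",
      length(areas), run
    ), call. = FALSE)
  if (is.null(standard_amount_fmol)) {
    est <- estimate_standard_amount(table, spec, run)
    amount <- est$amount_fmol
    ratios <- est$per_pair_ratios
  } else {
    amount <- as.numeric(standard_amount_fmol)
    if (amount <= 0) validation_error("standard_amount_fmol must be positive")
    ratios <- numeric(0)
  }
  nma <- if (calibration_capable(spec)) {
    tryCatch(normalized_median_abundance(table, spec, run),
             mbaq_error = function(e) NA_real_)
  } else NA_real_
  median_area <- stats::median(areas)
  structure(
    list(
      run_id = run,
      standard_amount_fmol = amount,
      median_area = median_area,
      response_factor = amount / median_area,
      nma = nma,
      nm_fraction = near_median_fraction(areas),
      n_standard_peptides_detected = length(areas),
      per_pair_ratios = ratios
    ),
    class = "mbaq_calibration"
  )
}

#' @export
print.mbaq_calibration <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<mbaq_calibration> run '%s'\n",
      "  standard amount : %.4g fmol (%d reference pair ratio(s))\n",
      "  median area     : %.6g (n = %d standard peptides)\n",
      "  response factor : %.6g fmol per area unit\n",
      "  NMA             : %s | near-median fraction: %.2f\n"
    ),
    x$run_id, x$standard_amount_fmol, length(x$per_pair_ratios),
    x$median_area, x$n_standard_peptides_detected, x$response_factor,
    ifelse(is.na(x$nma), "n/a", sprintf("%.3f", x$nma)), x$nm_fraction
  ))
  invisible(x)
}

#' Calibrate every run of a table
#'
#' @inheritParams median_calibrant
#' @param runs run labels (default: all runs in the table).
#' @param pooled when TRUE, append a pooled calibration whose amount and
#'   median area are medians over the per-run values (run label "pooled").
#' @return named list of `mbaq_calibration`, one per run.
#' @export
calibrate_runs <- function(table, spec, runs = NULL, pooled = FALSE,
                           standard_amount_fmol = NULL) {
  runs <- runs %||% attr(table, "runs")
  out <- lapply(runs, function(r)
    median_calibrant(table, spec, r, standard_amount_fmol = standard_amount_fmol))
  names(out) <- runs
  if (pooled && length(out) > 1L) {
    amount <- stats::median(vapply(out, `[[`, numeric(1), "standard_amount_fmol"))
    med <- stats::median(vapply(out, `[[`, numeric(1), "median_area"))
    pooled_cal <- out[[1L]]
    pooled_cal$run_id <- "pooled"
    pooled_cal$standard_amount_fmol <- amount
    pooled_cal$median_area <- med
    pooled_cal$response_factor <- amount / med
    pooled_cal$nma <- stats::median(vapply(out, `[[`, numeric(1), "nma"))
    pooled_cal$nm_fraction <- stats::median(vapply(out, `[[`, numeric(1), "nm_fraction"))
    pooled_cal$n_standard_peptides_detected <-
      min(vapply(out, `[[`, integer(1), "n_standard_peptides_detected"))
    out$pooled <- pooled_cal
  }
  out
}

#' Write a calibration report
#'
#' One TSV row per run (run, amount_fmol, median_area, response_factor,
#' nma, nm_fraction, n_detected) plus a JSON sidecar with the same content
#' and the per-pair ratios for programmatic use.
#'
#' @param calibrations list of `mbaq_calibration` (see [calibrate_runs()]).
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return `path`, invisibly.
#' @export
write_calibration_report <- function(calibrations, path) {
  if (inherits(calibrations, "mbaq_calibration"))
    calibrations <- list(calibrations)
  df <- do.call(rbind, lapply(calibrations, function(cal) data.frame(
    run = cal$run_id,
    amount_fmol = cal$standard_amount_fmol,
    median_area = cal$median_area,
    response_factor = cal$response_factor,
    nma = cal$nma,
    nm_fraction = cal$nm_fraction,
    n_detected = cal$n_standard_peptides_detected,
    stringsAsFactors = FALSE
  )))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    lapply(calibrations, function(cal) cal[c(
      "run_id", "standard_amount_fmol", "median_area", "response_factor",
      "nma", "nm_fraction", "n_standard_peptides_detected", "per_pair_ratios"
    )]),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
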