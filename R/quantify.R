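# Protein quantification from calibrated peptide molar estimates.
#
# Each detected peptide's XIC area times the run's response factor gives an
# independent molar estimate of its source protein. TopN/Hi-3 averages the
# N most abundant peptides; BestN instead searches all size-2/3 subsets of
# the Top3 pool for the combination with the lowest coefficient of
# variation, discarding peptides whose ionization is uniquely favorable.

#' Coefficient of variation in percent
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, at least 2 values with positive mean.
#' @return nonnegative percent.
#' @export
#' @examples
#' cv_percent(c(10, 11))  # 6.734
cv_percent <- function(values) {
  if (length(values) < 2L)
    validation_error("cv_percent needs at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    validation_error("cv_percent needs a positive mean")
  100 * stats::sd(values) / m
}

#' Per-peptide molar estimates for one protein in one run
#'
#' Multiplies each detected peptide's XIC area by the response factor.
#' Peptides with area 0 (not detected in this run) are excluded.
#'
#' @param table an [observation_table()].
#' @param protein_id protein accession.
#' @param run run label.
#' @param response_factor fmol per area unit, from [median_calibrant()]
#'   (an `mbaq_calibration` object is also accepted).
#' @return named numeric vector, peptide sequence -> fmol.
#' @export
peptide_molar_estimates <- function(table, protein_id, run, response_factor) {
  stopifnot(inherits(table, "observation_table"))
  if (inherits(response_factor, "mbaq_calibration"))
    response_factor <- response_factor$response_factor
  rows <- table$run_id == run & table$protein_id == protein_id
  if (!any(rows))
    lookup_error(sprintf("protein '%s' has no observations in run '%s'",
                         protein_id, run))
  areas <- table$xic_area[rows]
  est <- areas * response_factor
  names(est) <- table$peptide_seq[rows]
  est[areas > 0]
}

#' Select the N most abundant peptides
#'
#' Ties at the selection boundary are broken lexicographically by peptide
#' sequence, so the selection is deterministic across platforms.
#'
#' @param estimates named numeric vector (peptide -> molar estimate).
#' @param n number of peptides to keep (default 3); fewer are returned when
#'   fewer exist.
#' @return character vector of selected peptide sequences, most abundant
#'   first.
#' @export
select_topn <- function(estimates, n = 3L) {
  if (!length(estimates))
    validation_error("select_topn needs at least one estimate")
  ord <- order(-estimates, names(estimates))
  names(estimates)[ord][seq_len(min(n, length(estimates)))]
}

#' Select the BestN peptide combination by coefficient of variation
#'
#' From the pool of the Top3 most abundant peptides, enumerates every
#' size-2 and size-3 subset and returns the one whose molar estimates have
#' the lowest CV. A protein with exactly two detected peptides keeps that
#' pair (its CV may exceed the threshold, in which case `qc_pass` is
#' FALSE). Proteins with a single peptide are excluded from quantification
#' upstream; calling this on one estimate raises a classed exclusion
#' condition rather than selecting anything.
#'
#' @param estimates named numeric vector of per-peptide molar estimates,
#'   length >= 2.
#' @param cv_threshold QC threshold on the percent CV (default 20).
#' @return list with `peptides` (character), `cv_percent`, `qc_pass`.
#' @export
#' @examples
#' select_bestn(c(a = 10, b = 11, c = 30))  # picks {a, b}, CV 6.73%
select_bestn <- function(estimates, cv_threshold = 20) {
  if (length(estimates) < 2L)
    mbaq_error("mbaq_exclusion",
               "protein identified with one peptide; excluded from quantification")
  pool <- select_topn(estimates, 3L)
  # size-3 candidates first so that on CV ties the larger subset wins
  subsets <- list()
  if (length(pool) >= 3L)
    subsets <- c(subsets, utils::combn(sort(pool), 3L, simplify = FALSE))
  subsets <- c(subsets, utils::combn(sort(pool), 2L, simplify = FALSE))
  cvs <- vapply(subsets, function(s) cv_percent(estimates[s]), numeric(1))
  best <- subsets[[which.min(cvs)]]
  list(
    peptides = best,
    cv_percent = min(cvs),
    qc_pass = min(cvs) < cv_threshold
  )
}

#' Mean/median concordance of a peptide set
#'
#' TRUE when the arithmetic mean and the median of the estimates differ by
#' less than `tol` of the median -- an optional extra filter for peptide
#' sets free of dominating outliers.
#'
#' @param estimates numeric vector, length >= 2.
#' @param tol relative tolerance (default 0.15).
#' @return logical.
#' @export
mean_median_consistency <- function(estimates, tol = 0.15) {
  if (length(estimates) < 2L)
    validation_error("mean_median_consistency needs at least 2 estimates")
  m <- stats::median(estimates)
  abs(mean(estimates) - m) / m < tol
}

#' Quantify one protein from its peptide molar estimates
#'
#' Selects peptides by the requested method and averages their molar
#' estimates. `bestn` minimizes CV over size-2/3 subsets of the Top3 pool;
#' `topn` averages the `n` most abundant peptides; `hi3` is `topn` with
#' n = 3.
#'
#' @param estimates named numeric vector of per-peptide molar estimates.
#' @param method one of `"bestn"`, `"topn"`, `"hi3"`.
#' @param cv_threshold QC threshold on percent CV (default 20).
#' @param n number of peptides for `topn` (default 3).
#' @param protein_id,run_id optional labels carried into the result.
#' @return object of class `protein_quant`: a list with `protein_id`,
#'   `run_id`, `method`, `selected_peptides`, `amount_fmol`, `cv_percent`,
#'   `n_peptides_available`, `qc_pass`.
#' @export
quantify_protein <- function(estimates, method = c("bestn", "topn", "hi3"),
                             cv_threshold = 20, n = 3L,
                             protein_id = NA_character_,
                             run_id = NA_character_) {
  method <- match.arg(method)
  if (!length(estimates))
    validation_error("quantify_protein needs at least one estimate")
  if (method == "bestn") {
    sel <- select_bestn(estimates, cv_threshold)
    peptides <- sel$peptides
    cv <- sel$cv_percent
    qc <- sel$qc_pass
  } else {
    if (method == "hi3") n <- 3L
    peptides <- select_topn(estimates, n)
    cv <- if (length(peptides) >= 2L) cv_percent(estimates[peptides]) else NA_real_
    qc <- !is.na(cv) && cv < cv_threshold
  }
  structure(
    list(
      protein_id = protein_id,
      run_id = run_id,
      method = method,
      selected_peptides = peptides,
      amount_fmol = mean(estimates[peptides]),
      cv_percent = cv,
      n_peptides_available = length(estimates),
      qc_pass = qc
    ),
    class = "protein_quant"
  )
}

#' @export
print.protein_quant <- function(x, ...) {
  cat(sprintf(
    "<protein_quant> %s [%s] %s: %.4g fmol from %d/%d peptide(s), CV %.2f%%, QC %s\n",
    x$protein_id, x$run_id, x$method, x$amount_fmol,
    length(x$selected_peptides), x$n_peptides_available,
    x$cv_percent, ifelse(x$qc_pass, "pass", "fail")
  ))
  invisible(x)
}

#' Quantify every analyte protein of a table
#'
#' Runs calibration and per-protein quantification over one or all runs.
#' Standard and reference proteins are never quantified. Peptides shared
#' between several proteins are flagged and excluded by default, since a
#' shared area cannot be attributed to one protein. Proteins identified
#' with a single peptide are excluded from quantification and reported in
#' the `excluded` attribute instead of being silently dropped.
#'
#' @param table an [observation_table()].
#' @param spec a [standard_spec()].
#' @param method `"bestn"` (default), `"topn"` or `"hi3"`.
#' @param runs run labels (default: all).
#' @param cv_threshold percent CV QC threshold (default 20).
#' @param n number of peptides for `topn`.
#' @param n_cells when given, a `copies_per_cell` column is added.
#' @param drop_shared_peptides exclude peptides observed under more than
#'   one protein accession (default TRUE).
#' @param standard_amount_fmol optional known standard amount bypassing the
#'   reference-pair estimate (see [median_calibrant()]).
#' @return data frame with one row per (protein, run): `protein_id`,
#'   `run_id`, `method`, `n_available`, `selected_peptides`
#'   (semicolon-joined), `amount_fmol`, `cv_percent`, `qc_pass` (and
#'   `copies_per_cell` when `n_cells` is given). Attributes: `excluded`
#'   (single-peptide proteins), `shared_peptides`, `calibrations`.
#' @export
quantify_table <- function(table, spec, method = c("bestn", "topn", "hi3"),
                           runs = NULL, cv_threshold = 20, n = 3L,
                           n_cells = NULL, drop_shared_peptides = TRUE,
                           standard_amount_fmol = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(table, "observation_table"), inherits(spec, "standard_spec"))
  runs <- runs %||% attr(table, "runs")
  shared <- character(0)
  if (drop_shared_peptides) {
    pp <- unique(data.frame(p = table$protein_id, s = table$peptide_seq))
    shared <- unique(pp$s[pp$s %in% pp$s[duplicated(pp$s)]])
    if (length(shared))
      table <- structure(
        table[!table$peptide_seq %in% shared, , drop = FALSE],
        runs = attr(table, "runs"), class = class(table)
      )
  }
  calibrations <- calibrate_runs(table, spec, runs,
                                 standard_amount_fmol = standard_amount_fmol)
  rows <- list()
  excluded <- list()
  for (run in runs) {
    rf <- calibrations[[run]]$response_factor
    in_run <- table$run_id == run & table$xic_area > 0 &
      !table$protein_id %in% c(spec$standard_protein_id,
                               spec$reference_protein_id)
    proteins <- unique(table$protein_id[in_run])
    for (prot in proteins) {
      est <- peptide_molar_estimates(table, prot, run, rf)
      if (length(est) < 2L) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          protein_id = prot, run_id = run, n_available = length(est),
          reason = "single peptide", stringsAsFactors = FALSE
        )
        next
      }
      q <- quantify_protein(est, method, cv_threshold, n,
                            protein_id = prot, run_id = run)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = q$protein_id,
        run_id = q$run_id,
        method = q$method,
        n_available = q$n_peptides_available,
        selected_peptides = paste(q$selected_peptides, collapse = ";"),
        amount_fmol = q$amount_fmol,
        cv_percent = q$cv_percent,
        qc_pass = q$qc_pass,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), run_id = character(0),
               method = character(0), n_available = integer(0),
               selected_peptides = character(0), amount_fmol = numeric(0),
               cv_percent = numeric(0), qc_pass = logical(0))
  if (!is.null(n_cells))
    out$copies_per_cell <- copies_per_cell(out$amount_fmol, n_cells)
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(protein_id = character(0), run_id = character(0),
               n_available = integer(0), reason = character(0))
  attr(out, "shared_peptides") <- shared
  attr(out, "calibrations") <- calibrations
  out
}

#' Percent error of an estimate against a reference value
#'
#' `100 * |estimate - reference| / reference`, the standard accuracy metric
#' when an independent (e.g. isotope-dilution) determination is taken as
#' the true value.
#'
#' @param estimate numeric vector.
#' @param reference positive numeric (recycled).
#' @return nonnegative percent, same length as `estimate`.
#' @export
#' @examples
#' percent_error(113, 149)  # 24.16
percent_error <- function(estimate, reference) {
  if (any(!is.finite(reference) | reference <= 0))
    validation_error("percent_error needs positive reference values")
  100 * abs(estimate - reference) / reference
}

#' Convert a molar amount to protein copies per cell
#'
#' @param amount_fmol molar amount in fmol (1 fmol = 1e-15 mol).
#' @param n_cells positive number of cells the amount was extracted from.
#' @return copies per cell, `amount_fmol * 1e-15 * N_A / n_cells`.
#' @export
#' @examples
#' copies_per_cell(1e-3, 1)  # 6.022e5
copies_per_cell <- function(amount_fmol, n_cells) {
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells <= 0)
    validation_error("n_cells must be a single positive number")
  amount_fmol * 1e-15 * AVOGADRO / n_cells
}

#' Concordance of two quantification tables with a known dilution ratio
#'
#' For each protein quantified in both tables, the ratio of its amounts is
#' compared with the expected dilution ratio; per-protein accuracy is
#' `100 * (1 - |ratio - expected| / expected)`. The summary reports the
#' mean (and median) accuracy over shared proteins.
#'
#' @param quants_a,quants_b outputs of [quantify_table()] (or any data
#'   frames with `protein_id` and `amount_fmol`); multiple runs per protein
#'   are averaged first.
#' @param expected_ratio anticipated amount_a / amount_b (e.g. 2 for a
#'   2-fold dilution of b).
#' @return list with `per_protein` (data frame: protein_id, amount_a,
#'   amount_b, ratio, accuracy_percent), `mean_accuracy`,
#'   `median_accuracy`, `mean_ratio`, and `missing` (proteins present in
#'   only one table).
#' @export
dilution_concordance <- function(quants_a, quants_b, expected_ratio) {
  if (!is.numeric(expected_ratio) || expected_ratio <= 0)
    validation_error("expected_ratio must be positive")
  avg <- function(q) {
    tapply(q$amount_fmol, q$protein_id, mean)
  }
  a <- avg(quants_a)
  b <- avg(quants_b)
  common <- intersect(names(a), names(b))
  missing <- union(setdiff(names(a), names(b)), setdiff(names(b), names(a)))
  if (!length(common))
    validation_error("no protein quantified in both tables")
  ratio <- as.numeric(a[common]) / as.numeric(b[common])
  accuracy <- 100 * (1 - abs(ratio - expected_ratio) / expected_ratio)
  per_protein <- data.frame(
    protein_id = common,
    amount_a = as.numeric(a[common]),
    amount_b = as.numeric(b[common]),
    ratio = ratio,
    accuracy_percent = accuracy,
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(
    per_protein = per_protein,
    mean_accuracy = mean(accuracy),
    median_accuracy = stats::median(accuracy),
    mean_ratio = mean(ratio),
    missing = missing
  )
}

#' Write a protein quantification table as TSV
#'
#' @param quants output of [quantify_table()].
#' @param path output TSV path.
#' @param excluded_path optional path for the excluded (single-peptide)
#'   protein table.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quants, path, excluded_path = NULL) {
  utils::write.table(quants, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(excluded_path))
    utils::write.table(attr(quants, "excluded") %||%
                         data.frame(), excluded_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
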