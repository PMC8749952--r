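# Peptide quantification tables, standard specifications and FASTA I/O.

#' Default column mapping for a Progenesis-style peptide measurement export
#'
#' Maps the logical fields the package needs (`run`, `protein`, `peptide`,
#' `area`, and optionally `rt`) to the column headers of the input CSV.
#' The default follows a long-format Progenesis-style peptide measurement
#' export; override any entry to match your tool's dialect.
#'
#' @return named character vector with entries `run`, `protein`, `peptide`,
#'   `area`, `rt`.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(
    run     = "Run",
    protein = "Accession",
    peptide = "Sequence",
    area    = "Raw abundance",
    rt      = "Retention time (min)"
  )
}

#' Construct an observation table
#'
#' The central container of the package: one row per (run, protein, peptide)
#' with its XIC peak area. An area of 0 means "not detected in this run"
#' (aligned exports report 0 for missing) and is retained in the table but
#' excluded from all median/CV computations downstream.
#'
#' @param run_id character, LC-MS/MS run labels.
#' @param protein_id character, protein accessions.
#' @param peptide_seq character, peptide sequences (canonical residues;
#'   modification annotations are stripped by [normalize_peptide()]).
#' @param xic_area numeric, nonnegative XIC peak areas (arbitrary
#'   intensity x time units).
#' @param rt_min optional numeric, retention times in minutes.
#' @param is_standard logical, whether the row belongs to the internal
#'   standard (or reference) protein rather than an analyte.
#' @return a data frame of class `observation_table` with a `runs` attribute
#'   holding the ordered set of run labels.
#' @export
observation_table <- function(run_id, protein_id, peptide_seq, xic_area,
                              rt_min = NA_real_, is_standard = FALSE) {
  peptide_seq <- normalize_peptide(peptide_seq)
  df <- data.frame(
    run_id = as.character(run_id),
    protein_id = as.character(protein_id),
    peptide_seq = peptide_seq,
    xic_area = as.numeric(xic_area),
    rt_min = as.numeric(rt_min),
    is_standard = as.logical(is_standard),
    stringsAsFactors = FALSE
  )
  validate_observation_table(df)
  structure(df,
    runs = unique(df$run_id),
    class = c("observation_table", "data.frame")
  )
}

validate_observation_table <- function(df) {
  if (nrow(df) == 0L)
    validation_error("observation table has no rows")
  if (anyNA(df$xic_area))
    validation_error("XIC areas contain missing values")
  if (any(df$xic_area < 0)) {
    bad <- which(df$xic_area < 0)[1L]
    validation_error(sprintf("negative XIC area in row %d", bad))
  }
  if (any(!grepl("^[A-Z]+$", df$peptide_seq)))
    validation_error("peptide sequences must be non-empty A-Z strings")
  bad_res <- setdiff(
    unique(strsplit(paste(df$peptide_seq, collapse = ""), "")[[1]]),
    CANONICAL_RESIDUES
  )
  if (length(bad_res))
    validation_error(sprintf(
      "peptide sequences contain non-canonical residue(s): %s",
      paste(bad_res, collapse = ", ")
    ))
  key <- paste(df$run_id, df$protein_id, df$peptide_seq, sep = "\r")
  if (anyDuplicated(key))
    validation_error("duplicate (run, protein, peptide) keys in table")
  invisible(df)
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf(
    "<observation_table> %d observations | %d runs | %d proteins (%d standard rows)\n",
    nrow(x), length(attr(x, "runs")),
    length(unique(x$protein_id)), sum(x$is_standard)
  ))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat(sprintf("... %d more rows\n", nrow(x) - 8L))
  invisible(x)
}

#' Read a peptide quantification table from CSV
#'
#' Reads a long-format CSV as exported by LC-MS label-free alignment
#' software (one row per run/protein/peptide, with its raw XIC peak area).
#' Duplicate (run, protein, peptide) rows -- typically charge states or
#' modified forms of the same sequence -- are aggregated by summing their
#' areas, with a warning.
#'
#' @param path CSV file path.
#' @param column_map named character vector mapping logical fields to
#'   column headers; see [default_column_map()]. The `rt` entry is optional.
#' @return an [observation_table()].
#' @export
read_peptide_table <- function(path, column_map = default_column_map()) {
  if (!file.exists(path))
    configuration_error(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (field in c("run", "protein", "peptide", "area")) {
    col <- column_map[[field]]
    if (is.null(col) || is.na(col))
      configuration_error(sprintf("column_map lacks an entry for '%s'", field))
    if (!col %in% names(raw))
      configuration_error(sprintf(
        "column '%s' (mapped to field '%s') not found in %s",
        col, field, path
      ))
  }
  area <- suppressWarnings(as.numeric(raw[[column_map[["area"]]]]))
  if (anyNA(area)) {
    bad <- which(is.na(area))[1L]
    validation_error(sprintf(
      "area column '%s' not parseable as a number in row %d",
      column_map[["area"]], bad
    ))
  }
  if (any(area < 0)) {
    bad <- which(area < 0)[1L]
    validation_error(sprintf("negative XIC area in row %d", bad))
  }
  rt_col <- column_map[["rt"]]
  rt <- if (!is.null(rt_col) && !is.na(rt_col) && rt_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[rt_col]]))
  } else {
    rep(NA_real_, nrow(raw))
  }
  df <- data.frame(
    run_id = as.character(raw[[column_map[["run"]]]]),
    protein_id = as.character(raw[[column_map[["protein"]]]]),
    peptide_seq = normalize_peptide(raw[[column_map[["peptide"]]]]),
    xic_area = area,
    rt_min = rt,
    stringsAsFactors = FALSE
  )
  key <- paste(df$run_id, df$protein_id, df$peptide_seq, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(sprintf(
      "%d duplicate (run, protein, peptide) row(s) in %s aggregated by summing areas",
      n_dup, path
    ), call. = FALSE)
    agg_area <- tapply(df$xic_area, key, sum)
    agg_rt <- tapply(df$rt_min, key, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    })
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    df$xic_area <- as.numeric(agg_area[key[first]])
    df$rt_min <- as.numeric(agg_rt[key[first]])
  }
  observation_table(df$run_id, df$protein_id, df$peptide_seq,
                    df$xic_area, df$rt_min)
}

#' Write a peptide quantification table to CSV
#'
#' Inverse of [read_peptide_table()]: the written file, read back with the
#' same column map, reproduces all (run, protein, peptide, area) tuples.
#'
#' @param table an [observation_table()].
#' @param path output CSV path.
#' @param column_map column headers to write; see [default_column_map()].
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path,
                                column_map = default_column_map()) {
  stopifnot(inherits(table, "observation_table"))
  out <- data.frame(
    table$run_id, table$protein_id, table$peptide_seq,
    table$xic_area, table$rt_min,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  names(out) <- unname(column_map[c("run", "protein", "peptide", "area", "rt")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mark the rows of a table that belong to the internal standard
#'
#' Sets `is_standard` to TRUE for observations of the standard chimera or
#' of the codigested reference protein named in the standard specification.
#'
#' @param table an [observation_table()].
#' @param spec a [standard_spec()].
#' @return the table with `is_standard` updated.
#' @export
mark_standard <- function(table, spec) {
  stopifnot(inherits(table, "observation_table"), inherits(spec, "standard_spec"))
  table$is_standard <-
    table$protein_id %in% c(spec$standard_protein_id, spec$reference_protein_id)
  table
}

#' Construct an internal-standard specification
#'
#' Describes the chimeric internal standard: the sequences of its equimolar
#' tryptic peptides, the native/scrambled reference-peptide pairs used to
#' determine its molar amount against a codigested reference protein of
#' known quantity, and that reference amount.
#'
#' @param standard_peptides character vector of the standard's peptide
#'   sequences (the scrambled reference peptides are among them).
#' @param reference_pairs data frame with columns `native` and `scrambled`,
#'   one row per reference pair; may have zero rows, in which case the spec
#'   is loadable but flagged incapable of amount calibration.
#' @param reference_amount_fmol molar amount (fmol) of the codigested
#'   reference protein. All molar amounts in this package are in fmol.
#' @param standard_protein_id accession under which the standard's peptides
#'   are reported.
#' @param reference_protein_id accession of the reference protein.
#' @return object of class `standard_spec`.
#' @export
standard_spec <- function(standard_peptides, reference_pairs,
                          reference_amount_fmol,
                          standard_protein_id = "STANDARD",
                          reference_protein_id = "REFERENCE") {
  standard_peptides <- normalize_peptide(standard_peptides)
  for (p in standard_peptides) assert_canonical(p, "standard peptide")
  if (is.null(reference_pairs) || nrow(as.data.frame(reference_pairs)) == 0L) {
    reference_pairs <- data.frame(native = character(0),
                                  scrambled = character(0),
                                  stringsAsFactors = FALSE)
  } else {
    reference_pairs <- as.data.frame(reference_pairs, stringsAsFactors = FALSE)
    if (!all(c("native", "scrambled") %in% names(reference_pairs)))
      validation_error("reference_pairs needs 'native' and 'scrambled' columns")
    reference_pairs$native <- normalize_peptide(reference_pairs$native)
    reference_pairs$scrambled <- normalize_peptide(reference_pairs$scrambled)
    for (p in c(reference_pairs$native, reference_pairs$scrambled))
      assert_canonical(p, "reference pair peptide")
    missing <- setdiff(reference_pairs$scrambled, standard_peptides)
    if (length(missing))
      validation_error(sprintf(
        "scrambled reference peptide(s) not among standard_peptides: %s",
        paste(missing, collapse = ", ")
      ))
  }
  if (!is.numeric(reference_amount_fmol) || length(reference_amount_fmol) != 1L ||
      is.na(reference_amount_fmol) || reference_amount_fmol <= 0)
    validation_error("reference_amount_fmol must be a single positive number")
  structure(
    list(
      standard_peptides = standard_peptides,
      reference_pairs = reference_pairs,
      reference_amount_fmol = as.numeric(reference_amount_fmol),
      standard_protein_id = as.character(standard_protein_id),
      reference_protein_id = as.character(reference_protein_id)
    ),
    class = "standard_spec"
  )
}

#' @export
print.standard_spec <- function(x, ...) {
  cat(sprintf(
    "<standard_spec> %d standard peptides | %d reference pairs | reference %.4g fmol (%s)\n",
    length(x$standard_peptides), nrow(x$reference_pairs),
    x$reference_amount_fmol, x$reference_protein_id
  ))
  if (!calibration_capable(x))
    cat("  note: no reference pairs -- amount calibration not possible\n")
  invisible(x)
}

#' Can this standard spec support amount calibration?
#'
#' @param spec a [standard_spec()].
#' @return TRUE when at least one native/scrambled reference pair is present.
#' @export
calibration_capable <- function(spec) {
  stopifnot(inherits(spec, "standard_spec"))
  nrow(spec$reference_pairs) > 0L
}

#' Read a standard specification from a YAML file
#'
#' The file holds keys `standard_peptides` (list of sequences),
#' `reference_pairs` (list of maps with `native` and `scrambled`),
#' `reference_amount_fmol`, and optionally `standard_protein_id` /
#' `reference_protein_id`.
#'
#' @param path YAML file path.
#' @return a [standard_spec()].
#' @export
read_standard_spec <- function(path) {
  if (!file.exists(path))
    configuration_error(sprintf("standard spec file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$standard_peptides))
    validation_error("standard spec lacks 'standard_peptides'")
  if (is.null(cfg$reference_amount_fmol))
    validation_error("standard spec lacks 'reference_amount_fmol'")
  pairs <- if (length(cfg$reference_pairs)) {
    data.frame(
      native = vapply(cfg$reference_pairs, `[[`, "", "native"),
      scrambled = vapply(cfg$reference_pairs, `[[`, "", "scrambled"),
      stringsAsFactors = FALSE
    )
  } else NULL
  standard_spec(
    standard_peptides = unlist(cfg$standard_peptides),
    reference_pairs = pairs,
    reference_amount_fmol = as.numeric(cfg$reference_amount_fmol),
    standard_protein_id = cfg$standard_protein_id %||% "STANDARD",
    reference_protein_id = cfg$reference_protein_id %||% "REFERENCE"
  )
}

#' Write a standard specification to YAML
#'
#' @param spec a [standard_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_standard_spec <- function(spec, path) {
  stopifnot(inherits(spec, "standard_spec"))
  pairs <- lapply(seq_len(nrow(spec$reference_pairs)), function(i) {
    list(native = spec$reference_pairs$native[i],
         scrambled = spec$reference_pairs$scrambled[i])
  })
  yaml::write_yaml(list(
    standard_protein_id = spec$standard_protein_id,
    reference_protein_id = spec$reference_protein_id,
    reference_amount_fmol = spec$reference_amount_fmol,
    standard_peptides = as.list(spec$standard_peptides),
    reference_pairs = pairs
  ), path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return data frame with columns `header` and `sequence`; sequences are
#'   uppercased with stop characters (`*`) stripped, record order preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    configuration_error(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0L)
    validation_error(sprintf("FASTA file is empty: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) validation_error(sprintf(
      "malformed FASTA %s: %s", path, conditionMessage(e)
    ))
  )
  if (length(set) == 0L)
    validation_error(sprintf("FASTA file has no records: %s", path))
  data.frame(
    header = names(set),
    sequence = gsub("\\*", "", toupper(as.character(set))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param headers character vector of record headers.
#' @param sequences character vector of sequences (same length).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(headers, sequences, path) {
  stopifnot(length(headers) == length(sequences), length(headers) > 0L)
  set <- Biostrings::BStringSet(as.character(sequences))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
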