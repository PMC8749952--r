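# Classed conditions and small shared helpers.

mbaq_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "mbaq_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

validation_error    <- function(message, ...) mbaq_error("mbaq_validation_error", message, ...)
configuration_error <- function(message, ...) mbaq_error("mbaq_configuration_error", message, ...)
calibration_error   <- function(message, ...) mbaq_error("mbaq_calibration_error", message, ...)
design_error        <- function(message, ...) mbaq_error("mbaq_design_error", message, ...)
lookup_error        <- function(message, ...) mbaq_error("mbaq_lookup_error", message, ...)

#' Check that a sequence uses only the 20 canonical residues
#' @keywords internal
assert_canonical <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    validation_error(sprintf("%s must be a non-empty string", what))
  bad <- setdiff(strsplit(sequence, "")[[1]], CANONICAL_RESIDUES)
  if (length(bad))
    validation_error(sprintf(
      "%s '%s' contains non-canonical residue(s): %s",
      what, sequence, paste(unique(bad), collapse = ", ")
    ))
  invisible(sequence)
}

#' Normalize a peptide sequence string from an export dialect
#'
#' Uppercases and strips modification annotations in square brackets or
#' parentheses (e.g. "PEPT(ox)IDEK" -> "PEPTIDEK"), so that charge states
#' and modified forms of the same sequence compare equal.
#' @keywords internal
normalize_peptide <- function(x) {
  x <- toupper(gsub("\\[[^]]*\\]|\\([^)]*\\)", "", as.character(x)))
  gsub("[^A-Z]", "", x)
}

# run an expression with a locally seeded RNG, restoring global state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
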