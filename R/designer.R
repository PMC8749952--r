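# Design of scrambled standard peptides: in-silico tryptic digestion,
# proteotypic filtering, sequence reversal and constrained scrambling with
# monoisotopic-mass / hydropathy bookkeeping, plus uniqueness screening
# against proteome databases.

#' Monoisotopic mass of a peptide
#'
#' Sum of monoisotopic residue masses plus one water (18.010565 Da).
#'
#' @param sequence peptide sequence (canonical residues).
#' @return mass in Da.
#' @export
#' @examples
#' mono_mass("G")  # 75.03203
mono_mass <- function(sequence) {
  assert_canonical(sequence, "peptide")
  sum(MONO_RESIDUE_MASS[strsplit(sequence, "")[[1]]]) + MASS_WATER
}

#' Mean Kyte-Doolittle hydropathy of a peptide
#'
#' Used as a proxy for chromatographic behavior when judging whether a
#' scrambled peptide will elute near its source.
#'
#' @param sequence peptide sequence (canonical residues).
#' @return dimensionless mean hydropathy index.
#' @export
#' @examples
#' hydropathy("III")  # 4.5
hydropathy <- function(sequence) {
  assert_canonical(sequence, "peptide")
  mean(KYTE_DOOLITTLE[strsplit(sequence, "")[[1]]])
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. Peptides with up
#' to `max_missed` internal uncleaved K/R sites are also produced.
#'
#' @param sequence protein sequence (canonical residues).
#' @param max_missed maximum missed cleavages (default 0).
#' @return data frame with columns `sequence`, `start`, `end` (1-based
#'   inclusive coordinates in the parent), `missed_cleavages`.
#' @export
#' @examples
#' digest_trypsin("MKRAAAK")$sequence  # "MK" "R" "AAAK"
digest_trypsin <- function(sequence, max_missed = 0L) {
  assert_canonical(sequence, "protein sequence")
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  # cleavage occurs after position i
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & res[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  base <- data.frame(start = starts, end = ends)
  out <- list()
  for (i in seq_len(nrow(base))) {
    for (mc in 0:max_missed) {
      j <- i + mc
      if (j > nrow(base)) break
      s <- base$start[i]
      e <- base$end[j]
      out[[length(out) + 1L]] <- data.frame(
        sequence = substr(sequence, s, e),
        start = s, end = e, missed_cleavages = mc,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$missed_cleavages), , drop = FALSE]
}

#' Filter digestion products down to proteotypic candidates
#'
#' Keeps fully tryptic peptides with no missed cleavage, a C-terminal K or
#' R, length within bounds, no cysteine or methionine at internal
#' positions, and no aspartate or glutamate at the N-terminus -- the usual
#' requirements for reliably and reproducibly observed peptides.
#'
#' @param peptides character vector of peptide sequences, or the data
#'   frame returned by [digest_trypsin()].
#' @param min_len,max_len length bounds (defaults 7 and 25).
#' @param require_tryptic_cterm require a C-terminal K/R (default TRUE;
#'   set FALSE when protein C-terminal peptides should be eligible).
#' @return list with `kept` (character vector) and `rejected` (data frame
#'   with `sequence` and semicolon-joined `reasons`).
#' @export
proteotypic_filter <- function(peptides, min_len = 7L, max_len = 25L,
                               require_tryptic_cterm = TRUE) {
  if (is.data.frame(peptides)) {
    mc <- peptides$missed_cleavages %||% rep(0L, nrow(peptides))
    seqs <- peptides$sequence
  } else {
    seqs <- as.character(peptides)
    mc <- rep(0L, length(seqs))
  }
  kept <- character(0)
  rej <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    reasons <- character(0)
    if (mc[i] > 0L) reasons <- c(reasons, "missed cleavage")
    if (n < min_len) reasons <- c(reasons, "too short")
    if (n > max_len) reasons <- c(reasons, "too long")
    last <- substr(s, n, n)
    if (require_tryptic_cterm && !last %in% c("K", "R"))
      reasons <- c(reasons, "non-tryptic C-terminus")
    if (n > 2L && grepl("[CM]", substr(s, 2L, n - 1L)))
      reasons <- c(reasons, "internal Cys/Met")
    if (substr(s, 1L, 1L) %in% c("D", "E"))
      reasons <- c(reasons, "N-terminal Asp/Glu")
    if (length(reasons)) {
      rej[[length(rej) + 1L]] <- data.frame(
        sequence = s, reasons = paste(reasons, collapse = ";"),
        stringsAsFactors = FALSE
      )
    } else {
      kept <- c(kept, s)
    }
  }
  list(
    kept = kept,
    rejected = if (length(rej)) do.call(rbind, rej) else
      data.frame(sequence = character(0), reasons = character(0))
  )
}

#' Reverse a peptide sequence keeping its C-terminal residue
#'
#' Reverses the first n-1 residues and keeps the C-terminal K/R in place,
#' so the product remains a tryptic-like peptide. (Reversal preserves
#' composition but not local sequence context; empirically such peptides
#' ionize very differently from their sources, which is why scrambling is
#' preferred for standard design.)
#'
#' @param sequence peptide with C-terminal K or R, length >= 2.
#' @return the reversed sequence.
#' @export
#' @examples
#' reverse_except_cterm("HLVDEPQNLIK")  # "ILNQPEDVLHK"
reverse_except_cterm <- function(sequence) {
  assert_canonical(sequence, "peptide")
  n <- nchar(sequence)
  if (n < 2L)
    validation_error("peptide must have at least 2 residues")
  last <- substr(sequence, n, n)
  if (!last %in% c("K", "R"))
    validation_error(sprintf(
      "peptide '%s' lacks a C-terminal K or R", sequence
    ))
  res <- strsplit(sequence, "")[[1]]
  paste0(paste(rev(res[-n]), collapse = ""), last)
}

scramble_result <- function(source_seq, product_seq, events,
                            unique_vs_db = NA, valid = TRUE,
                            violations = character(0)) {
  structure(
    list(
      source_seq = source_seq,
      product_seq = product_seq,
      events = events,
      mono_mass_delta = mono_mass(product_seq) - mono_mass(source_seq),
      hydropathy_delta = hydropathy(product_seq) - hydropathy(source_seq),
      unique_vs_db = unique_vs_db,
      valid = valid,
      violations = violations
    ),
    class = "scramble_result"
  )
}

format_event <- function(e) {
  if (e$type == "swap") sprintf("swap(%d,%d)", e$i, e$j)
  else sprintf("substitute(%d,%s>%s)", e$pos, e$from, e$to)
}

#' @export
print.scramble_result <- function(x, ...) {
  cat(sprintf(
    "<scramble_result> %s -> %s [%s]\n  mass delta %+.5f Da | hydropathy delta %+.3f | %s\n",
    x$source_seq, x$product_seq,
    paste(vapply(x$events, format_event, ""), collapse = ", "),
    x$mono_mass_delta, x$hydropathy_delta,
    if (x$valid) "valid" else paste("INVALID:", paste(x$violations, collapse = ", "))
  ))
  invisible(x)
}

#' Scramble a peptide under the standard-design rules
#'
#' Applies exactly two scrambling events to the source peptide: (1) a swap
#' of two non-C-terminal residues with different identities, and (2) a
#' conservative substitution drawn from the allowed table (S/T, D/E, N/Q,
#' F/Y, and aliphatic neighbours along G < A < V < L < I including V/I) at
#' a position preferring the middle third of the sequence, chosen so the
#' monoisotopic mass changes. The product keeps its length and C-terminal
#' residue, differs from the source, and carries a nonzero mass shift so it
#' can never be confused with the native peptide in a mass spectrum. The
#' search is randomized but fully deterministic given `seed`.
#'
#' @param sequence source peptide (canonical residues, C-terminal K/R).
#' @param seed integer seed controlling swap/substitution choice.
#' @param hydropathy_warn warn when the product's mean Kyte-Doolittle
#'   hydropathy moves by more than this (default 0.5), a proxy for a large
#'   retention-time shift.
#' @return a `scramble_result` (see [validate_scramble()] for the fields).
#' @export
scramble_peptide <- function(sequence, seed = 1L, hydropathy_warn = 0.5) {
  assert_canonical(sequence, "peptide")
  n <- nchar(sequence)
  if (n < 4L)
    design_error(sprintf("peptide '%s' too short to scramble", sequence))
  res <- strsplit(sequence, "")[[1]]
  if (!res[n] %in% c("K", "R"))
    validation_error(sprintf("peptide '%s' lacks a C-terminal K or R", sequence))
  violations <- character(0)

  # swap: two non-C-terminal positions with different residues
  interior <- seq_len(n - 1L)
  swap_pairs <- list()
  for (i in interior) for (j in interior) {
    if (i < j && res[i] != res[j])
      swap_pairs[[length(swap_pairs) + 1L]] <- c(i, j)
  }
  if (!length(swap_pairs))
    violations <- c(violations, "no two distinct non-terminal residues to swap")

  # substitution candidates with nonzero mass delta, middle third preferred
  center <- (n + 1) / 2
  third <- max(1, floor(n / 3))
  subs <- list()
  for (p in interior) {
    for (r in allowed_substitutes(res[p])) {
      delta <- MONO_RESIDUE_MASS[[r]] - MONO_RESIDUE_MASS[[res[p]]]
      if (abs(delta) > 1e-9)
        subs[[length(subs) + 1L]] <- list(
          pos = p, from = res[p], to = r,
          middle = abs(p - center) <= third / 2 + 0.5
        )
    }
  }
  if (!length(subs))
    violations <- c(violations,
                    "no allowed substitution with a nonzero mass shift")
  if (length(violations))
    design_error(sprintf(
      "cannot scramble '%s': %s", sequence, paste(violations, collapse = "; ")
    ), violations = violations)

  with_local_seed(seed, {
    middle_subs <- Filter(function(s) s$middle, subs)
    pool <- if (length(middle_subs)) middle_subs else subs
    sub <- pool[[sample.int(length(pool), 1L)]]
    # avoid swapping the substituted position so the two events are
    # independent and the inferred edit script is minimal
    ok_pairs <- Filter(function(pr) !sub$pos %in% pr, swap_pairs)
    if (!length(ok_pairs)) ok_pairs <- swap_pairs
    swap <- ok_pairs[[sample.int(length(ok_pairs), 1L)]]
    prod <- res
    prod[sub$pos] <- sub$to
    tmp <- prod[swap[1]]
    prod[swap[1]] <- prod[swap[2]]
    prod[swap[2]] <- tmp
    product <- paste(prod, collapse = "")
    out <- scramble_result(
      sequence, product,
      events = list(
        list(type = "swap", i = swap[1], j = swap[2]),
        list(type = "substitute", pos = sub$pos, from = sub$from, to = sub$to)
      )
    )
    if (abs(out$hydropathy_delta) > hydropathy_warn)
      warning(sprintf(
        "scramble of '%s' shifts mean hydropathy by %+.2f (> %.2f); retention time may move substantially",
        sequence, out$hydropathy_delta, hydropathy_warn
      ), call. = FALSE)
    out
  })
}

# Infer a minimal edit script between two equal-length sequences: pair up
# differing positions into swaps wherever the residues cross-match (each
# swap explains two positions in one event), the rest are substitutions.
# Exhaustive over the differing positions; peptides are short.
infer_events <- function(native_res, cand_res) {
  diff_pos <- which(native_res != cand_res)
  swap_ok <- function(i, j) {
    native_res[i] == cand_res[j] && native_res[j] == cand_res[i]
  }
  # returns the pairing (list of c(i, j)) with the most swaps
  best_pairing <- function(remaining) {
    if (length(remaining) < 2L) return(list())
    i <- remaining[1]
    best <- best_pairing(remaining[-1])  # i left as a substitution
    for (j in remaining[-1]) {
      if (swap_ok(i, j)) {
        cand <- c(list(c(i, j)), best_pairing(setdiff(remaining[-1], j)))
        if (length(cand) > length(best)) best <- cand
      }
    }
    best
  }
  swaps <- best_pairing(diff_pos)
  covered <- unlist(swaps)
  sub_pos <- setdiff(diff_pos, covered)
  c(
    lapply(swaps, function(pr) list(type = "swap", i = pr[1], j = pr[2])),
    lapply(sub_pos, function(p) list(
      type = "substitute", pos = p, from = native_res[p], to = cand_res[p]
    ))
  )
}

#' Validate a native/scrambled peptide pair against the scrambling rules
#'
#' Infers the minimal edit script (residue swaps and point substitutions)
#' transforming the native sequence into the candidate and checks the
#' design rules: at most `max_events` events in total, at most one swap,
#' every substitution drawn from the allowed conservative table, unchanged
#' C-terminal residue, a nonzero monoisotopic mass shift, and a product
#' that differs from its source.
#'
#' @param native source peptide sequence.
#' @param candidate scrambled candidate of the same length.
#' @param max_events maximum scrambling events (default 2).
#' @return a `scramble_result` with `valid` and `violations` filled in.
#' @export
#' @examples
#' validate_scramble("HLVDEPQNLIK", "HLVEEPNQLIK")$valid  # TRUE
validate_scramble <- function(native, candidate, max_events = 2L) {
  assert_canonical(native, "native peptide")
  assert_canonical(candidate, "candidate peptide")
  if (nchar(native) != nchar(candidate))
    validation_error("native and candidate differ in length")
  native_res <- strsplit(native, "")[[1]]
  cand_res <- strsplit(candidate, "")[[1]]
  n <- length(native_res)
  violations <- character(0)
  if (identical(native_res, cand_res))
    violations <- c(violations, "product equals source")
  if (native_res[n] != cand_res[n])
    violations <- c(violations, "C-terminal residue changed")
  events <- infer_events(native_res, cand_res)
  if (length(events) > max_events)
    violations <- c(violations, sprintf(
      "%d events exceed the maximum of %d", length(events), max_events
    ))
  n_swaps <- sum(vapply(events, function(e) e$type == "swap", logical(1)))
  if (n_swaps > 1L)
    violations <- c(violations, "more than one swap")
  for (e in events) {
    if (e$type == "substitute" &&
        !e$to %in% allowed_substitutes(e$from))
      violations <- c(violations, sprintf(
        "substitution %s>%s not in the allowed table", e$from, e$to
      ))
  }
  delta <- mono_mass(candidate) - mono_mass(native)
  if (abs(delta) < 1e-9)
    violations <- c(violations, "zero monoisotopic mass delta")
  scramble_result(native, candidate, events,
                  valid = length(violations) == 0L,
                  violations = violations)
}

#' Check a designed peptide for uniqueness against proteome databases
#'
#' A designed standard peptide must not occur in nature. The candidate is
#' searched as a substring of every protein in the supplied FASTA
#' databases and compared with every tryptic peptide (up to `max_missed`
#' missed cleavages) of those proteins; any hit disqualifies it.
#'
#' @param candidate peptide sequence.
#' @param proteome_fastas character vector of FASTA paths, or a list of
#'   data frames as returned by [read_fasta()].
#' @param max_missed missed cleavages for the tryptic comparison
#'   (default 1).
#' @return list with `unique` (logical) and `matches` (data frame with
#'   `header` and `type`, types `substring` and/or `tryptic_peptide`).
#' @export
uniqueness_check <- function(candidate, proteome_fastas, max_missed = 1L) {
  assert_canonical(candidate, "candidate peptide")
  if (missing(proteome_fastas) || !length(proteome_fastas))
    configuration_error("at least one proteome database is required")
  dbs <- lapply(proteome_fastas, function(db) {
    if (is.character(db)) read_fasta(db) else as.data.frame(db)
  })
  matches <- list()
  for (db in dbs) {
    for (i in seq_len(nrow(db))) {
      seqn <- db$sequence[i]
      if (grepl(candidate, seqn, fixed = TRUE))
        matches[[length(matches) + 1L]] <- data.frame(
          header = db$header[i], type = "substring", stringsAsFactors = FALSE
        )
      peps <- tryCatch(digest_trypsin(seqn, max_missed)$sequence,
                       mbaq_error = function(e) character(0))
      if (candidate %in% peps)
        matches[[length(matches) + 1L]] <- data.frame(
          header = db$header[i], type = "tryptic_peptide",
          stringsAsFactors = FALSE
        )
    }
  }
  matches <- if (length(matches)) unique(do.call(rbind, matches)) else
    data.frame(header = character(0), type = character(0))
  list(unique = nrow(matches) == 0L, matches = matches)
}

#' Design scrambled standard peptides for a peptide list
#'
#' Convenience wrapper: scrambles each input peptide ([scramble_peptide()])
#' with a per-peptide seed derived from `seed`, optionally screens each
#' product for uniqueness, and returns the results. Failures (peptides the
#' rule set cannot scramble) are reported, not fatal.
#'
#' @param peptides character vector of source peptides.
#' @param seed integer master seed.
#' @param proteome_fastas optional databases for [uniqueness_check()].
#' @param max_attempts reseeded retries per peptide when the product is
#'   not unique (default 10).
#' @return list of `scramble_result` (failed peptides carry
#'   `valid = FALSE` and their violations).
#' @export
design_standard_peptides <- function(peptides, seed = 1L,
                                     proteome_fastas = NULL,
                                     max_attempts = 10L) {
  out <- vector("list", length(peptides))
  names(out) <- peptides
  for (idx in seq_along(peptides)) {
    pep <- peptides[idx]
    result <- NULL
    for (attempt in seq_len(max_attempts)) {
      cand <- tryCatch(
        scramble_peptide(pep, seed = seed + 1000L * idx + attempt),
        mbaq_design_error = function(e) e
      )
      if (inherits(cand, "mbaq_design_error")) {
        result <- scramble_result(pep, pep, list(), valid = FALSE,
                                  violations = conditionMessage(cand))
        break
      }
      if (!is.null(proteome_fastas)) {
        uq <- uniqueness_check(cand$product_seq, proteome_fastas)
        cand$unique_vs_db <- uq$unique
        if (!uq$unique && attempt < max_attempts) next
        if (!uq$unique) {
          cand$valid <- FALSE
          cand$violations <- c(cand$violations, "product matches a database sequence")
        }
      }
      result <- cand
      break
    }
    out[[idx]] <- result
  }
  out
}

#' Write a design report
#'
#' One TSV row per designed peptide (source, product, events, mass delta,
#' hydropathy delta, uniqueness, validity); optionally also writes the
#' products as FASTA with the events annotated in the headers.
#'
#' @param results list of `scramble_result` (see
#'   [design_standard_peptides()]).
#' @param path output TSV path.
#' @param fasta_path optional FASTA output path for the valid products.
#' @return `path`, invisibly.
#' @export
write_design_report <- function(results, path, fasta_path = NULL) {
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    source = r$source_seq,
    product = r$product_seq,
    events = paste(vapply(r$events, format_event, ""), collapse = ";"),
    mono_mass_delta = r$mono_mass_delta,
    hydropathy_delta = r$hydropathy_delta,
    unique_vs_db = r$unique_vs_db,
    valid = r$valid,
    violations = paste(r$violations, collapse = ";"),
    stringsAsFactors = FALSE
  )))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(fasta_path)) {
    valid <- Filter(function(r) isTRUE(r$valid), results)
    if (length(valid))
      write_fasta(
        vapply(valid, function(r) sprintf(
          "%s scrambled_from=%s events=%s mass_delta=%+.5f",
          r$product_seq, r$source_seq,
          paste(vapply(r$events, format_event, ""), collapse = ";"),
          r$mono_mass_delta
        ), ""),
        vapply(valid, `[[`, "", "product_seq"),
        fasta_path
      )
  }
  invisible(path)
}
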