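# Ground-truth simulator for end-to-end validation of the calibration and
# quantification pipeline.
#
# The generator emulates the statistical structure of an aligned label-free
# experiment with a codigested equimolar standard: per-peptide ionization
# efficiencies drawn from a near-median mixture (a tight cluster within
# +/-20% of unity plus a spread tail covering ~10-fold), multiplicative
# lognormal replicate noise, protein amounts log-uniform over 3 orders of
# magnitude, and native/scrambled reference pairs whose responses agree to
# within 5%.

random_peptide <- function(len) {
  # proteotypic-looking: no Cys/Met, no N-terminal Asp/Glu, tryptic C-term
  inner_pool <- setdiff(CANONICAL_RESIDUES, c("C", "M"))
  first_pool <- setdiff(inner_pool, c("D", "E"))
  paste0(
    sample(first_pool, 1L),
    paste(sample(inner_pool, len - 2L, replace = TRUE), collapse = ""),
    sample(c("K", "R"), 1L)
  )
}

unique_peptides <- function(n, used = character(0)) {
  out <- character(0)
  while (length(out) < n) {
    p <- random_peptide(sample(8:16, 1L))
    if (!p %in% used && !p %in% out) out <- c(out, p)
  }
  out
}

# Near-median efficiency mixture: fraction `nm` lands within +/-20% of 1;
# the rest comes from a lognormal tail truncated to lie outside that band
# and capped so the overall spread stays within `spread_fold`. The tail
# sigma is ln(spread_fold)/4, i.e. +/-2 sigma spans the full fold-range.
draw_efficiencies <- function(n, nm_fraction, spread_fold) {
  in_band <- stats::runif(n) < nm_fraction
  eff <- numeric(n)
  eff[in_band] <- stats::runif(sum(in_band), 0.8, 1.2)
  n_out <- sum(!in_band)
  if (n_out) {
    sigma <- log(spread_fold) / 4
    cap <- log(spread_fold) / 2
    draws <- numeric(0)
    while (length(draws) < n_out) {
      x <- stats::rnorm(2L * n_out + 10L, 0, sigma)
      draws <- c(draws, x[abs(x) > log(1.2) & abs(x) <= cap])
    }
    eff[!in_band] <- exp(draws[seq_len(n_out)])
  }
  eff
}

#' Simulate a peptide quantification dataset with known ground truth
#'
#' Generates an [observation_table()] containing analyte proteins, an
#' equimolar internal-standard chimera and a codigested reference protein
#' with native/scrambled peptide pairs, together with the matching
#' [standard_spec()] and the ground truth used to generate it.
#'
#' Analyte amounts are log-uniform over `amount_range_fmol` (3 orders of
#' magnitude by default). Each peptide's XIC area is
#' `amount * efficiency * exp(noise)`, with efficiencies drawn once per
#' peptide from the near-median mixture and lognormal noise redrawn per
#' run. Native/scrambled reference responses agree within 5%.
#'
#' @param n_proteins number of analyte proteins (default 200).
#' @param peptides_per_protein peptides per analyte protein (default 5).
#' @param n_runs number of technical replicate runs (default 3, the
#'   usual replicate depth of the emulated experiments).
#' @param nm_target_fraction target fraction of standard peptides within
#'   +/-20% of the median (default 0.45).
#' @param spread_fold overall fold-spread of peptide efficiencies
#'   (default 10).
#' @param noise_sigma lognormal sigma of replicate noise (default 0.1).
#' @param dilution factor applied to analyte amounts only (default 1);
#'   simulate a dataset and its `dilution = 0.5` twin to test dilution
#'   concordance.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   dataset exactly.
#' @param noise_seed seed for the replicate noise only (default `seed`).
#'   Re-simulating with the same `seed` but a different `noise_seed` (and
#'   e.g. `dilution = 0.5`) yields a technical-replicate twin: same
#'   proteins, amounts and efficiencies, independent measurement noise.
#' @param n_standard_peptides equimolar chimera peptides besides the
#'   scrambled reference peptides (default 43).
#' @param n_reference_pairs native/scrambled reference pairs (default 5).
#' @param standard_amount_fmol true chimera amount (default 300 fmol).
#' @param reference_amount_fmol known reference-protein amount
#'   (default 1000 fmol).
#' @param amount_range_fmol range of analyte amounts (default 1 to 1000).
#' @param unit_efficiencies force every efficiency and pair factor to 1
#'   (with `noise_sigma = 0` the pipeline then recovers all amounts
#'   exactly; default FALSE).
#' @return list with `table`, `spec`, `truth`; `truth` holds
#'   `protein_amounts_fmol` (effective, i.e. after dilution),
#'   `peptide_efficiencies`, `standard_amount_fmol`, `noise_sigma`,
#'   `seed`.
#' @export
simulate_dataset <- function(n_proteins = 200L, peptides_per_protein = 5L,
                             n_runs = 3L, nm_target_fraction = 0.45,
                             spread_fold = 10, noise_sigma = 0.1,
                             dilution = 1.0, seed = 1L, noise_seed = seed,
                             n_standard_peptides = 43L,
                             n_reference_pairs = 5L,
                             standard_amount_fmol = 300,
                             reference_amount_fmol = 1000,
                             amount_range_fmol = c(1, 1000),
                             unit_efficiencies = FALSE) {
  if (n_proteins < 1L || peptides_per_protein < 1L || n_runs < 1L ||
      n_standard_peptides < 1L || n_reference_pairs < 1L)
    validation_error("all counts must be >= 1")
  if (nm_target_fraction <= 0 || nm_target_fraction > 1)
    validation_error("nm_target_fraction must be in (0, 1]")
  if (dilution <= 0) validation_error("dilution must be positive")
  with_local_seed(seed, {
    std_id <- "STD_CHIMERA"
    ref_id <- "REF_PROT"
    chimera_peps <- unique_peptides(n_standard_peptides)
    native_peps <- unique_peptides(n_reference_pairs, used = chimera_peps)
    scrambled_peps <- unique_peptides(
      n_reference_pairs, used = c(chimera_peps, native_peps)
    )
    used <- c(chimera_peps, native_peps, scrambled_peps)
    spec <- standard_spec(
      standard_peptides = c(chimera_peps, scrambled_peps),
      reference_pairs = data.frame(native = native_peps,
                                   scrambled = scrambled_peps),
      reference_amount_fmol = reference_amount_fmol,
      standard_protein_id = std_id,
      reference_protein_id = ref_id
    )

    eff <- function(n) {
      if (unit_efficiencies) rep(1, n)
      else draw_efficiencies(n, nm_target_fraction, spread_fold)
    }
    noise <- function(n) {
      if (noise_sigma == 0) rep(1, n) else exp(stats::rnorm(n, 0, noise_sigma))
    }

    chimera_eff <- eff(n_standard_peptides)
    ref_eff <- eff(n_reference_pairs)
    pair_factor <- if (unit_efficiencies) rep(1, n_reference_pairs) else
      stats::runif(n_reference_pairs, 0.95, 1.05)

    protein_ids <- sprintf("P%04d", seq_len(n_proteins))
    amounts <- 10^stats::runif(
      n_proteins, log10(amount_range_fmol[1]), log10(amount_range_fmol[2])
    )
    effective <- amounts * dilution
    names(effective) <- protein_ids
    analyte_peps <- unique_peptides(n_proteins * peptides_per_protein, used)
    analyte_eff <- eff(length(analyte_peps))

    # structural draws above come from `seed`; replicate noise below from
    # `noise_seed`, so twins can share structure with independent noise
    set.seed(noise_seed)
    rows <- list()
    for (r in seq_len(n_runs)) {
      run <- sprintf("run%02d", r)
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run, protein_id = std_id, peptide_seq = chimera_peps,
        xic_area = standard_amount_fmol * chimera_eff *
          noise(n_standard_peptides),
        stringsAsFactors = FALSE
      )
      # a native/scrambled pair coelutes and shares its replicate noise, so
      # the realized area ratio stays within the ~5% pair factor
      pair_noise <- noise(n_reference_pairs)
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run, protein_id = ref_id, peptide_seq = native_peps,
        xic_area = reference_amount_fmol * ref_eff * pair_noise,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run, protein_id = std_id, peptide_seq = scrambled_peps,
        xic_area = standard_amount_fmol * ref_eff * pair_factor * pair_noise,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        run_id = run,
        protein_id = rep(protein_ids, each = peptides_per_protein),
        peptide_seq = analyte_peps,
        xic_area = rep(effective, each = peptides_per_protein) *
          analyte_eff * noise(length(analyte_peps)),
        stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, rows)
    table <- mark_standard(
      observation_table(df$run_id, df$protein_id, df$peptide_seq, df$xic_area),
      spec
    )
    efficiency_map <- data.frame(
      protein_id = c(rep(std_id, n_standard_peptides),
                     rep(ref_id, n_reference_pairs),
                     rep(protein_ids, each = peptides_per_protein)),
      peptide_seq = c(chimera_peps, native_peps, analyte_peps),
      efficiency = c(chimera_eff, ref_eff, analyte_eff),
      stringsAsFactors = FALSE
    )
    list(
      table = table,
      spec = spec,
      truth = list(
        protein_amounts_fmol = effective,
        peptide_efficiencies = efficiency_map,
        standard_amount_fmol = standard_amount_fmol,
        noise_sigma = noise_sigma,
        dilution = dilution,
        seed = as.integer(seed)
      )
    )
  })
}

#' Compare recovered protein amounts with the simulation ground truth
#'
#' @param quants output of [quantify_table()] (runs are averaged per
#'   protein first).
#' @param truth the `truth` element of [simulate_dataset()], or a named
#'   numeric vector of true amounts (fmol).
#' @return list with `per_protein` (data frame: protein_id, estimate,
#'   truth, percent_error), `median_error`, `mean_error`, `n`.
#' @export
truth_recovery_report <- function(quants, truth) {
  true_amounts <- if (is.list(truth) && !is.null(truth$protein_amounts_fmol))
    truth$protein_amounts_fmol else truth
  est <- tapply(quants$amount_fmol, quants$protein_id, mean)
  common <- intersect(names(est), names(true_amounts))
  if (!length(common))
    validation_error("no protein shared between quantification and truth")
  err <- percent_error(as.numeric(est[common]),
                       as.numeric(true_amounts[common]))
  list(
    per_protein = data.frame(
      protein_id = common,
      estimate_fmol = as.numeric(est[common]),
      truth_fmol = as.numeric(true_amounts[common]),
      percent_error = err,
      stringsAsFactors = FALSE, row.names = NULL
    ),
    median_error = stats::median(err),
    mean_error = mean(err),
    n = length(common)
  )
}

#' Write simulation ground truth as TSV
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  df <- data.frame(
    protein_id = names(truth$protein_amounts_fmol),
    amount_fmol = as.numeric(truth$protein_amounts_fmol),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
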