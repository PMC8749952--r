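# Fixtures are built in code; no binary files.

# a minimal calibratable table: one run, a 5-peptide standard chimera,
# 2 reference pairs and one 3-peptide analyte protein
toy_spec <- function(reference_amount_fmol = 1000) {
  standard_spec(
    standard_peptides = c("AAAGTLYK", "VVDLLAPYAK", "GGTGSGLQK",
                          "SSYVAFTDTER", "LLQDFFNGK",
                          "HLVEEPNQLIK", "YLYDVAR"),
    reference_pairs = data.frame(
      native = c("HLVDEPQNLIK", "YLYEIAR"),
      scrambled = c("HLVEEPNQLIK", "YLYDVAR")
    ),
    reference_amount_fmol = reference_amount_fmol,
    standard_protein_id = "STD",
    reference_protein_id = "REF"
  )
}

# chimera peptide areas `std_areas` (named by the 5 non-reference standard
# peptides), native/scrambled pair areas given explicitly
toy_table <- function(std_areas = c(AAAGTLYK = 90, VVDLLAPYAK = 100,
                                    GGTGSGLQK = 110, SSYVAFTDTER = 200,
                                    LLQDFFNGK = 30),
                      native_areas = c(HLVDEPQNLIK = 1000, YLYEIAR = 1000),
                      scrambled_areas = c(HLVEEPNQLIK = 100, YLYDVAR = 100),
                      analyte_areas = c(PEPTIDEK = 50, SAMPLEPR = 100,
                                        TINYPEPK = 20),
                      run = "r1") {
  observation_table(
    run_id = run,
    protein_id = c(rep("STD", length(std_areas)),
                   rep("REF", length(native_areas)),
                   rep("STD", length(scrambled_areas)),
                   rep("PROT1", length(analyte_areas))),
    peptide_seq = c(names(std_areas), names(native_areas),
                    names(scrambled_areas), names(analyte_areas)),
    xic_area = c(std_areas, native_areas, scrambled_areas, analyte_areas)
  )
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

# random named estimate vectors for oracle tests
random_estimates <- function(n) {
  est <- round(stats::runif(n, 1, 100), 2)
  names(est) <- paste0("PEP", seq_len(n), sample(c("K", "R"), n, replace = TRUE))
  est
}

# independent brute-force oracle for BestN: enumerate every size-2/3
# subset of the Top3 pool directly and scan for the minimum CV
bestn_oracle <- function(est) {
  pool <- names(sort(est, decreasing = TRUE))
  pool <- utils::head(pool[order(-est[pool], pool)], 3)
  best <- NULL
  for (size in c(3L, 2L)) {
    if (length(pool) < size) next
    for (s in utils::combn(sort(pool), size, simplify = FALSE)) {
      cv <- 100 * stats::sd(est[s]) / mean(est[s])
      if (is.null(best) || cv < best$cv) best <- list(peptides = s, cv = cv)
    }
  }
  best
}
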