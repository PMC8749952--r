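test_that("standard amount is the reference amount times the median pair ratio", {
  # identity ratios
  tab <- toy_table(native_areas = c(HLVDEPQNLIK = 100, YLYEIAR = 100),
                   scrambled_areas = c(HLVEEPNQLIK = 100, YLYDVAR = 100))
  est <- estimate_standard_amount(tab, toy_spec(1000), "r1")
  expect_equal(est$amount_fmol, 1000)

  # ratios {0.8, 1.0, 1.2} -> median 1.0; checked against a brute-force
  # sort-based median of the ratios
  spec3 <- standard_spec(
    standard_peptides = c("AAAGTLYK", "SAAGTLYK", "TAAGTLYK"),
    reference_pairs = data.frame(
      native = c("NAAGTLYK", "QAAGTLYK", "WAAGTLYK"),
      scrambled = c("AAAGTLYK", "SAAGTLYK", "TAAGTLYK")
    ),
    reference_amount_fmol = 2000,
    standard_protein_id = "STD", reference_protein_id = "REF"
  )
  tab3 <- observation_table(
    run_id = "r1",
    protein_id = c(rep("REF", 3), rep("STD", 3)),
    peptide_seq = c("NAAGTLYK", "QAAGTLYK", "WAAGTLYK",
                    "AAAGTLYK", "SAAGTLYK", "TAAGTLYK"),
    xic_area = c(100, 100, 100, 80, 100, 120)
  )
  est3 <- estimate_standard_amount(tab3, spec3, "r1")
  ratios <- c(0.8, 1.0, 1.2)
  expect_equal(est3$amount_fmol, 2000 * sort(ratios)[2])
  expect_equal(sort(unname(est3$per_pair_ratios)), ratios)
})

test_that("pairs with a missing side are skipped; all-missing is an error", {
  tab <- toy_table(native_areas = c(HLVDEPQNLIK = 0, YLYEIAR = 1000),
                   scrambled_areas = c(HLVEEPNQLIK = 100, YLYDVAR = 100))
  est <- estimate_standard_amount(tab, toy_spec(1000), "r1")
  expect_equal(length(est$per_pair_ratios), 1L)
  expect_equal(est$skipped_pairs, "HLVDEPQNLIK/HLVEEPNQLIK")

  tab0 <- toy_table(native_areas = c(HLVDEPQNLIK = 0, YLYEIAR = 0))
  expect_error(estimate_standard_amount(tab0, toy_spec(), "r1"),
               class = "mbaq_calibration_error")
})

test_that("the median calibrant divides amount by the median detected area", {
  spec <- standard_spec(
    standard_peptides = c("AAAGTLYK", "SAAGTLYK", "TAAGTLYK"),
    reference_pairs = NULL, reference_amount_fmol = 1,
    standard_protein_id = "STD"
  )
  tab <- observation_table(
    run_id = "r1", protein_id = "STD",
    peptide_seq = c("AAAGTLYK", "SAAGTLYK", "TAAGTLYK"),
    xic_area = c(2, 4, 6)
  )
  expect_warning(
    cal <- median_calibrant(tab, spec, "r1", standard_amount_fmol = 300),
    "most stable with >= 30"
  )
  expect_equal(cal$median_area, 4)
  expect_equal(cal$response_factor, 75)
  expect_equal(cal$n_standard_peptides_detected, 3L)

  # a single detected peptide is its own median
  tab1 <- observation_table("r1", "STD", "AAAGTLYK", 8)
  expect_warning(cal1 <- median_calibrant(tab1, spec, "r1",
                                          standard_amount_fmol = 400))
  expect_equal(cal1$median_area, 8)
  expect_equal(cal1$response_factor, 50)

  # all-equal areas: the median is that value; zeros are excluded
  tabc <- observation_table(
    run_id = "r1", protein_id = "STD",
    peptide_seq = c("AAAGTLYK", "SAAGTLYK", "TAAGTLYK"),
    xic_area = c(7, 7, 0)
  )
  expect_warning(calc <- median_calibrant(tabc, spec, "r1",
                                          standard_amount_fmol = 7))
  expect_equal(calc$median_area, 7)
  expect_equal(calc$n_standard_peptides_detected, 2L)

  # nothing detected
  tab0 <- observation_table("r1", "OTHER", "AAAGTLYK", 5)
  expect_error(median_calibrant(tab0, spec, "r1", standard_amount_fmol = 1),
               class = "mbaq_calibration_error")
})

test_that("NMA is 1 when the standard peptides match the reference-derived response", {
  # expected area = 100 (amount 100 fmol, k_ref 1 area unit per fmol);
  # chimera areas {90,100,110,200,30} have median 100
  tab <- toy_table()
  expect_equal(normalized_median_abundance(tab, toy_spec(), "r1"), 1.0)

  # scaling only the chimera-peptide areas scales NMA linearly
  tab45 <- toy_table(std_areas = 0.45 * c(AAAGTLYK = 90, VVDLLAPYAK = 100,
                                          GGTGSGLQK = 110, SSYVAFTDTER = 200,
                                          LLQDFFNGK = 30))
  expect_equal(normalized_median_abundance(tab45, toy_spec(), "r1"), 0.45)
})

test_that("NMA of symmetrically dispersed standards converges to unity", {
  set.seed(11)
  spec <- toy_spec()
  nmas <- vapply(1:1000, function(i) {
    # responses symmetric (in log) around the reference-derived response
    areas <- 100 * exp(stats::rnorm(5, 0, 0.3))
    names(areas) <- c("AAAGTLYK", "VVDLLAPYAK", "GGTGSGLQK",
                      "SSYVAFTDTER", "LLQDFFNGK")
    tab <- toy_table(std_areas = areas)
    normalized_median_abundance(tab, spec, "r1")
  }, numeric(1))
  expect_lt(abs(median(nmas) - 1.0), 0.05)
  expect_lt(abs(mean(nmas) - 1.0), 0.05)
})

test_that("near-median fraction counts areas within the relative band", {
  expect_equal(near_median_fraction(c(0.9, 1.0, 1.1, 2.0, 0.3)), 0.6)
  expect_equal(near_median_fraction(rep(3.2, 7)), 1.0)
  # band 0 with distinct values and odd n keeps only the median itself
  expect_equal(near_median_fraction(c(1, 2, 3, 4, 5), band = 0), 1 / 5)
  expect_error(near_median_fraction(numeric(0)),
               class = "mbaq_validation_error")
  expect_error(near_median_fraction(c(1, -1)),
               class = "mbaq_validation_error")
})

test_that("global area rescaling leaves amounts, NMA and fractions invariant", {
  set.seed(21)
  for (i in 1:25) {
    std <- stats::runif(5, 10, 300)
    names(std) <- c("AAAGTLYK", "VVDLLAPYAK", "GGTGSGLQK",
                    "SSYVAFTDTER", "LLQDFFNGK")
    nat <- stats::runif(2, 100, 2000)
    names(nat) <- c("HLVDEPQNLIK", "YLYEIAR")
    scr <- stats::runif(2, 10, 500)
    names(scr) <- c("HLVEEPNQLIK", "YLYDVAR")
    ana <- stats::runif(3, 5, 500)
    names(ana) <- c("PEPTIDEK", "SAMPLEPR", "TINYPEPK")
    c_scale <- stats::runif(1, 0.01, 50)
    spec <- toy_spec()
    t1 <- toy_table(std, nat, scr, ana)
    t2 <- toy_table(std * c_scale, nat * c_scale, scr * c_scale,
                    ana * c_scale)
    cal1 <- suppressWarnings(median_calibrant(t1, spec, "r1"))
    cal2 <- suppressWarnings(median_calibrant(t2, spec, "r1"))
    expect_equal(cal2$standard_amount_fmol, cal1$standard_amount_fmol)
    expect_equal(cal2$nma, cal1$nma)
    expect_equal(cal2$nm_fraction, cal1$nm_fraction)
    expect_equal(cal2$response_factor, cal1$response_factor / c_scale)
    est1 <- peptide_molar_estimates(t1, "PROT1", "r1", cal1)
    est2 <- peptide_molar_estimates(t2, "PROT1", "r1", cal2)
    expect_equal(est2, est1)
  }
})

test_that("one wild outlier moves the median by at most the gap to its neighbour", {
  cases <- list(
    c(10, 20, 30, 40, 50),
    c(1, 1, 2, 3, 5),
    c(7, 7, 7, 7, 7),
    c(0.1, 0.5, 1, 2, 10)
  )
  for (areas in cases) {
    m <- median(sort(areas))  # brute-force sort oracle
    for (idx in 1:5) {
      polluted <- areas
      polluted[idx] <- 1e9
      m2 <- median(sort(polluted))
      gap <- max(diff(sort(areas)))
      expect_lte(abs(m2 - m), gap + 1e-12)
    }
  }
})

test_that("calibration reports round-trip through TSV and JSON sidecar", {
  cal <- suppressWarnings(calibrate_runs(toy_table(), toy_spec()))
  path <- tempfile(fileext = ".tsv")
  write_calibration_report(cal, path)
  tsv <- read.delim(path)
  expect_equal(nrow(tsv), 1L)
  expect_equal(tsv$amount_fmol, cal$r1$standard_amount_fmol)
  sidecar <- sub("\\.tsv$", ".json", path)
  expect_true(file.exists(sidecar))
  parsed <- jsonlite::read_json(sidecar)
  expect_equal(parsed[[1]]$median_area, cal$r1$median_area)
})
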