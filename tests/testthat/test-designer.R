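test_that("monoisotopic mass and hydropathy use standard residue tables", {
  expect_equal(mono_mass("G"), 75.03203, tolerance = 1e-6)
  expect_error(mono_mass(""), class = "mbaq_validation_error")
  expect_error(mono_mass("ABZ"), class = "mbaq_validation_error")
  # composition invariance
  expect_equal(mono_mass("AK"), mono_mass("KA"))

  expect_equal(hydropathy("III"), 4.5)
  expect_equal(hydropathy("RRR"), -4.5)
  expect_error(hydropathy(""), class = "mbaq_validation_error")
})

test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_equal(digest_trypsin("MKRAAAK")$sequence, c("MK", "R", "AAAK"))
  # K followed by P is not a cleavage site
  expect_equal(digest_trypsin("AKPGR")$sequence, "AKPGR")
  expect_error(digest_trypsin("AKBR"), class = "mbaq_validation_error")
  expect_error(digest_trypsin(""), class = "mbaq_validation_error")

  # missed cleavages extend peptides over internal K/R sites
  d1 <- digest_trypsin("MKRAAAK", max_missed = 1)
  expect_true(all(c("MKR", "RAAAK") %in% d1$sequence))
  expect_equal(sort(unique(d1$missed_cleavages)), c(0L, 1L))

  # coordinates point back into the parent sequence
  parent <- "SAMPLEKSEQVENCERTRYPTIC"
  d <- digest_trypsin(parent)
  expect_true(all(substring(parent, d$start, d$end) == d$sequence))
})

test_that("zero-missed-cleavage peptides reassemble the parent protein", {
  set.seed(61)
  for (i in 1:25) {
    parent <- paste(sample(CANONICAL_RESIDUES, sample(20:80, 1),
                           replace = TRUE), collapse = "")
    d <- digest_trypsin(parent)
    d0 <- d[d$missed_cleavages == 0, ]
    expect_equal(paste(d0$sequence[order(d0$start)], collapse = ""), parent)
  }
})

test_that("proteotypic filtering applies the residue and length rules", {
  out <- proteotypic_filter(c(
    "DLGEEHFK",     # N-terminal Asp
    "YLYEIAR",      # clean
    "ACDEFGHIK",    # internal Cys
    "SHORTK",       # 6 residues
    "YLYEIARYLYEIARYLYEIARYLYEIAR",  # 28 residues
    "AGGGGGGF"      # no tryptic C-terminus
  ))
  expect_equal(out$kept, "YLYEIAR")
  expect_equal(nrow(out$rejected), 5L)
  expect_match(out$rejected$reasons[out$rejected$sequence == "DLGEEHFK"],
               "N-terminal Asp/Glu")
  expect_match(out$rejected$reasons[out$rejected$sequence == "ACDEFGHIK"],
               "internal Cys/Met")

  # digest output: missed-cleavage peptides are rejected
  d <- digest_trypsin("LLQDFFNGKAAAGTLYKSSYVAFTDTER", max_missed = 1)
  fd <- proteotypic_filter(d)
  expect_true(all(c("LLQDFFNGK", "AAAGTLYK", "SSYVAFTDTER") %in% fd$kept))
  expect_true(any(grepl("missed cleavage", fd$rejected$reasons)))
})

test_that("reversal keeps the C-terminal residue in place", {
  expect_equal(reverse_except_cterm("HLVDEPQNLIK"), "ILNQPEDVLHK")
  expect_equal(reverse_except_cterm("AGK"), "GAK")
  expect_equal(reverse_except_cterm("AK"), "AK")
  expect_error(reverse_except_cterm("AGT"), class = "mbaq_validation_error")
})

test_that("the designed reference pairs validate under the scrambling rules", {
  pairs <- list(
    c("HLVDEPQNLIK", "HLVEEPNQLIK"),   # substitution D>E plus one swap
    c("LGEYGFQNALIVR", "LGDYGFNNALIVR"), # two substitutions E>D, Q>N
    c("YLYEIAR", "YLYDVAR"),           # two substitutions E>D, I>V
    c("DAFLGSFLYEYSR", "DAFIGTFLYEYSR")  # two substitutions L>I, S>T
  )
  for (p in pairs) {
    res <- validate_scramble(p[1], p[2])
    expect_true(res$valid)
    expect_lte(length(res$events), 2L)
    expect_equal(substr(res$product_seq, nchar(res$product_seq),
                        nchar(res$product_seq)),
                 substr(res$source_seq, nchar(res$source_seq),
                        nchar(res$source_seq)))
    expect_gt(abs(res$mono_mass_delta), 0)
  }
  # the documented mass shift of the first pair
  res1 <- validate_scramble("HLVDEPQNLIK", "HLVEEPNQLIK")
  expect_equal(res1$mono_mass_delta, 14.01565, tolerance = 1e-5)
  types1 <- sort(vapply(res1$events, `[[`, "", "type"))
  expect_equal(types1, c("substitute", "swap"))
})

test_that("rule violations are itemized rather than silently accepted", {
  # identity: no change, zero mass delta
  same <- validate_scramble("YLYEIAR", "YLYEIAR")
  expect_false(same$valid)
  expect_true(any(grepl("equals source", same$violations)))
  expect_true(any(grepl("zero monoisotopic", same$violations)))

  # a three-event edit (swap plus two substitutions) exceeds the limit
  three <- validate_scramble("LGEYFGQNALIVR", "LGDYGFNNALIVR")
  expect_false(three$valid)
  expect_equal(length(three$events), 3L)
  expect_true(any(grepl("exceed the maximum", three$violations)))

  # substitution outside the conservative table
  bad <- validate_scramble("YLYEIAR", "YLYWIAR")
  expect_false(bad$valid)
  expect_true(any(grepl("not in the allowed table", bad$violations)))

  # changed C-terminus
  cterm <- validate_scramble("YLYEIAR", "YLYEIAK")
  expect_false(cterm$valid)
  expect_true(any(grepl("C-terminal", cterm$violations)))

  expect_error(validate_scramble("AAK", "AAAK"),
               class = "mbaq_validation_error")
})

test_that("generated scrambles satisfy every rule and round-trip validate", {
  set.seed(71)
  inner <- setdiff(CANONICAL_RESIDUES, c("C", "M"))
  n_checked <- 0
  for (i in 1:300) {
    pep <- paste0(
      paste(sample(setdiff(inner, c("D", "E")), 1), collapse = ""),
      paste(sample(inner, sample(6:14, 1), replace = TRUE), collapse = ""),
      sample(c("K", "R"), 1)
    )
    res <- tryCatch(
      suppressWarnings(scramble_peptide(pep, seed = i)),
      mbaq_design_error = function(e) NULL
    )
    if (is.null(res)) next
    n_checked <- n_checked + 1
    expect_equal(nchar(res$product_seq), nchar(res$source_seq))
    expect_lte(length(res$events), 2L)
    expect_equal(substr(res$product_seq, nchar(pep), nchar(pep)),
                 substr(pep, nchar(pep), nchar(pep)))
    expect_gt(abs(res$mono_mass_delta), 0)
    expect_false(res$product_seq == res$source_seq)
    # round-trip: the generated product passes validation
    check <- validate_scramble(pep, res$product_seq)
    expect_true(check$valid)
  }
  expect_gt(n_checked, 250)
})

test_that("scrambling is deterministic given a seed and fails on degenerate input", {
  a <- suppressWarnings(scramble_peptide("VVDLLAPYAK", seed = 5))
  b <- suppressWarnings(scramble_peptide("VVDLLAPYAK", seed = 5))
  expect_identical(a$product_seq, b$product_seq)
  expect_identical(a$events, b$events)

  # all-identical residues before the C-terminus: nothing to swap
  expect_error(scramble_peptide("AAAAK"), class = "mbaq_design_error")
})

test_that("uniqueness screening finds substring and tryptic matches", {
  fasta <- write_temp_fasta(c(
    ">toy1 synthetic protein",
    "MKAAAGTLYKSSYVAFTDTERGGG",
    ">toy2 synthetic protein",
    "PPPPHLVDEPQNLIKRRR"
  ))
  hit <- uniqueness_check("AAAGTLYK", fasta)
  expect_false(hit$unique)
  expect_true("tryptic_peptide" %in% hit$matches$type)
  expect_true("substring" %in% hit$matches$type)

  native <- uniqueness_check("HLVDEPQNLIK", fasta)
  expect_false(native$unique)

  novel <- uniqueness_check("WWWWWWTK", fasta)
  expect_true(novel$unique)
  expect_equal(nrow(novel$matches), 0L)

  expect_error(uniqueness_check("AAAGTLYK", character(0)),
               class = "mbaq_configuration_error")
})

test_that("batch design writes a usable report", {
  peptides <- c("VVDLLAPYAK", "SSYVAFTDTER", "AAAAK")
  results <- suppressWarnings(design_standard_peptides(peptides, seed = 2))
  expect_equal(length(results), 3L)
  expect_true(results[[1]]$valid)
  expect_false(results[[3]]$valid)  # degenerate peptide reported, not fatal

  tsv <- tempfile(fileext = ".tsv")
  fasta <- tempfile(fileext = ".fasta")
  write_design_report(results, tsv, fasta_path = fasta)
  rep <- read.delim(tsv)
  expect_equal(nrow(rep), 3L)
  expect_equal(sum(rep$valid), 2L)
  fa <- read_fasta(fasta)
  expect_equal(nrow(fa), 2L)
})
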