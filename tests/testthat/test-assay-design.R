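test_that("cut sites follow the 3-bp-upstream-of-PAM and midpoint rules", {
  g_plus <- crispr_guide(c(100, 120), "+")
  expect_equal(predict_cut_sites(nuclease_spec("crispr",
                                               guides = list(g_plus))),
               117L)
  g_minus <- crispr_guide(c(100, 120), "-")
  expect_equal(predict_cut_sites(nuclease_spec("crispr",
                                               guides = list(g_minus))),
               103L)
  # dual nickase: one site per guide
  dual <- nuclease_spec("crispr", guides = list(g_plus,
                                                crispr_guide(c(150, 170),
                                                             "-")))
  expect_equal(predict_cut_sites(dual), c(117L, 153L))
  # TALEN midpoint, floored on odd spacers
  tal <- nuclease_spec("talen", arms = list(c(100, 118), c(133, 151)))
  expect_equal(predict_cut_sites(tal), 125L)
  odd <- nuclease_spec("fokI_dcas9", arms = list(c(100, 118), c(134, 151)))
  expect_equal(predict_cut_sites(odd), 126L)
  expect_error(nuclease_spec("talen", arms = list(c(100, 140),
                                                  c(133, 151))),
               "overlap")
})

test_that("cut-site prediction is strand-mirror symmetric", {
  L <- 500L
  set.seed(71)
  for (i in 1:20) {
    s <- sample(0:(L - 25), 1)
    fwd <- crispr_guide(c(s, s + 20), "+")
    mir <- crispr_guide(c(L - (s + 20), L - s), "-")
    cut_f <- predict_cut_sites(nuclease_spec("crispr",
                                             guides = list(fwd)))
    cut_m <- predict_cut_sites(nuclease_spec("crispr",
                                             guides = list(mir)))
    expect_equal(cut_m, L - cut_f)
  }
})

test_that("layout validation applies the five design rules", {
  mk <- function(...) {
    args <- list(
      amplicon = c(90, 310), fwd_primer = c(90, 110),
      rev_primer = c(290, 310), ref_probe = c(250, 270),
      hdr_probe = c(190, 212), nhej_probes = list(c(190, 215)),
      cut_sites = 200L, donor_span = c(150, 210), edit_pos = 200L)
    dots <- list(...)
    for (nm in names(dots)) args[[nm]] <- dots[[nm]]
    do.call(assay_layout, args)
  }
  rep1 <- validate_layout(mk())
  expect_true(attr(rep1, "all_pass"))
  flanks <- rep1$message[rep1$rule == "cut_site_flanks"]
  expect_match(flanks, "90/90")  # 200-110 and 290-200

  # (a) cut too close to a primer
  r <- validate_layout(mk(cut_sites = 160L))
  expect_false(r$pass[r$rule == "cut_site_flanks"])
  # (b) both primers inside the donor span
  r <- validate_layout(mk(donor_span = c(80, 320)))
  expect_false(r$pass[r$rule == "primer_outside_donor"])
  # (c) reference probe inside the cut exclusion window
  r <- validate_layout(mk(ref_probe = c(210, 230)))
  expect_false(r$pass[r$rule == "ref_probe_distant"])
  # (d) NHEJ probe off the cut site
  r <- validate_layout(mk(nhej_probes = list(c(240, 260))))
  expect_false(r$pass[r$rule == "nhej_probe_on_cut"])
  # (e) HDR probe missing the edit position
  r <- validate_layout(mk(hdr_probe = c(150, 180)))
  expect_false(r$pass[r$rule == "hdr_probe_on_edit"])
  # structural invariants enforced at construction
  expect_error(mk(fwd_primer = c(95, 110)), "amplicon ends")
  expect_error(mk(ref_probe = c(250, 350)), "within the amplicon")
})

test_that("widening the amplicon never breaks the flank rule while <= 125", {
  for (pad in c(0, 5, 10, 15)) {
    lay <- assay_layout(amplicon = c(90 - pad, 310 + pad),
                        fwd_primer = c(90 - pad, 110 - pad),
                        rev_primer = c(290 + pad, 310 + pad),
                        ref_probe = c(250, 270),
                        nhej_probes = list(c(190, 215)),
                        cut_sites = 200L)
    r <- validate_layout(lay)
    expect_true(r$pass[r$rule == "cut_site_flanks"], info = pad)
  }
})

test_that("nearest-neighbor Tm agrees with an independent oracle", {
  expect_lt(abs(melting_temperature("AGCGTACCGGTTAGCCATGC") -
                  tm_oracle("AGCGTACCGGTTAGCCATGC")), 0.5)
  set.seed(72)
  for (s in random_dna(25, len = sample(12:30, 1)))
    expect_lt(abs(melting_temperature(s) - tm_oracle(s)), 0.5)
})

test_that("Tm respects duplex symmetry and GC stability ordering", {
  set.seed(73)
  for (s in random_dna(10, len = 22)) {
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(s, "")[[1]]), collapse = ""))
    expect_equal(melting_temperature(s), melting_temperature(rc))
  }
  expect_gt(melting_temperature("GGGGGGGGGGGG"),
            melting_temperature("AAAAAAAAAAAA"))
  expect_error(melting_temperature("ACGTNACGT"), "A, C, G, T")
  expect_error(melting_temperature("ACGTACG"), "at least 8")
})

test_that("dark probes are recommended only for near-WT cross-reactive probes", {
  wt <- "ACGTGGCCTTAACCGGTACA"
  probe1 <- make_synthetic_allele(wt, edit_substitution(10, "G"))  # 1 mm
  r1 <- dark_probe_recommended(probe1, wt)
  expect_true(r1$recommended)
  expect_equal(r1$mismatches, 1)
  expect_lte(r1$delta_tm, 8)
  # heavily mismatched probe: no cross-reactivity concern
  probe4 <- "ACGTGCTAGTATCCGGTACA"
  r4 <- dark_probe_recommended(probe4, wt)
  expect_false(r4$recommended)
  expect_gt(r4$mismatches, 1)
  # identical probe: maximal cross-reactivity
  expect_true(dark_probe_recommended(wt, wt)$recommended)
  # margin boundary is inclusive
  r_at <- dark_probe_recommended(probe1, wt, tm_margin = r1$delta_tm)
  expect_true(r_at$recommended)
  r_below <- dark_probe_recommended(probe1, wt,
                                    tm_margin = r1$delta_tm - 1e-6)
  expect_false(r_below$recommended)
  expect_error(dark_probe_recommended("ACGTACGTA", "ACGTACGT"),
               "equal length")
})

test_that("reference FASTA files round-trip through Biostrings", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">locus1", "ACGTACGTGGCC", ">locus2", "tttgggccc"), p)
  seqs <- read_reference_fasta(p)
  expect_equal(seqs[["locus1"]], "ACGTACGTGGCC")
  expect_equal(seqs[["locus2"]], "TTTGGGCCC")
  expect_error(read_reference_fasta(tempfile()), "not found")
})
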