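test_that("template mixes validate rates and convert copies/concentrations", {
  expect_error(template_mix(-0.1, 0, 0), "must be")
  m <- mix_from_copies(30000, 0, 0, 15000)
  expect_equal(m$lambda_wt, 2)
  expect_equal(lambda_total(m), 2)
  expect_equal(lambda_to_concentration(1.7, droplet_volume_nl = 0.85), 2000)
  expect_equal(concentration_to_lambda(2000, droplet_volume_nl = 0.85), 1.7)
  expect_equal(copies_from_ng(100), 30000)
})

test_that("spike_in_mix reproduces the requested composition", {
  expect_equal(unname(unlist(spike_in_mix(30000, 0, 0, 15000))),
               c(2, 0, 0))
  m <- spike_in_mix(27000, 0.05, 0.05, 15000)
  expect_equal(unname(unlist(m)), c(1.8, 0.1, 0.1))
  # total expected copies and fractional composition
  expect_equal(lambda_total(m) * 15000, 30000)
  expect_equal(m$lambda_hdr / lambda_total(m), 0.05)
  expect_error(spike_in_mix(0, 0.5, 0.5, 1000), "sum to < 1")
  expect_error(spike_in_mix(1000, 0.6, 0.5, 1000), "sum to < 1")
})

test_that("an empty mix yields baseline-only droplets with all-zero truth", {
  w <- simulate_well(template_mix(0, 0, 0), 500, noise_free_model(),
                     seed = 1)
  expect_equal(nrow(w$droplets), 500)
  expect_true(all(w$droplets$ch1_amplitude == 1000))
  expect_true(all(w$droplets$ch2_amplitude == 1000))
  expect_true(all(w$droplets$truth_wt == 0 & w$droplets$truth_hdr == 0 &
                    w$droplets$truth_nhej == 0))
})

test_that("noise-free single-class wells are exactly at their levels", {
  w <- simulate_well(template_mix(lambda_wt = 0.1), 20000,
                     noise_free_model(), seed = 2)
  occ <- w$droplets$truth_wt > 0
  expect_true(any(occ))
  expect_true(all(w$droplets$ch1_amplitude[occ] == 5000))
  expect_true(all(w$droplets$ch2_amplitude[occ] == 5000))
  expect_true(all(w$droplets$ch1_amplitude[!occ] == 1000))
})

test_that("void fraction follows the Poisson law at large n", {
  lam <- c(0.5, 0.005, 0.02)
  n <- 1e6
  w <- simulate_well(template_mix(lam[1], lam[2], lam[3]), n,
                     noise_free_model(), seed = 3)
  p0 <- exp(-sum(lam))
  empty <- with(w$droplets, truth_wt == 0 & truth_hdr == 0 &
                  truth_nhej == 0)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(empty) - p0), 3 * se)
})

test_that("class occupancies load independently", {
  w <- simulate_well(template_mix(0.5, 0.2, 0.3), 3e5, noise_free_model(),
                     seed = 4)
  d <- w$droplets
  pairs <- list(c("truth_wt", "truth_hdr"), c("truth_wt", "truth_nhej"),
                c("truth_hdr", "truth_nhej"))
  for (p in pairs) {
    tab <- table(d[[p[1]]] > 0, d[[p[2]]] > 0)
    expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
  }
})

test_that("identical seeds reproduce wells and leave caller RNG alone", {
  set.seed(99)
  before <- .Random.seed
  w1 <- simulate_well(template_mix(1, 0.1, 0.1), 5000, seed = 7)
  expect_identical(before, .Random.seed)
  w2 <- simulate_well(template_mix(1, 0.1, 0.1), 5000, seed = 7)
  expect_identical(w1$droplets, w2$droplets)
  w3 <- simulate_well(template_mix(1, 0.1, 0.1), 5000, seed = 8)
  expect_false(identical(w1$droplets, w3$droplets))
})

test_that("rain displaces both channels toward baseline without touching truth", {
  m <- noise_free_model(rain_fraction = 0.5)
  w <- simulate_well(template_mix(lambda_wt = 1), 10000, m, seed = 5)
  d <- w$droplets
  occ <- d$truth_wt > 0
  expect_true(all(d$ch1_amplitude[occ] >= 1000 &
                    d$ch1_amplitude[occ] <= 5000))
  expect_true(any(d$ch1_amplitude[occ] < 5000))  # some droplets rained
  # same displacement fraction on both channels (diagonal rain)
  u1 <- (d$ch1_amplitude[occ] - 1000) / 4000
  u2 <- (d$ch2_amplitude[occ] - 1000) / 4000
  expect_equal(u1, u2, tolerance = 1e-12)
})

test_that("multi-probe assays retain partial HEX on NHEJ-only droplets", {
  m <- noise_free_model(n_nhej_probes = 2, p_partial_retention = 1)
  w <- simulate_well(template_mix(0.5, 0, 0.2), 20000, m, seed = 6)
  d <- w$droplets
  nhej_only <- d$truth_wt == 0 & d$truth_nhej > 0
  expect_true(any(nhej_only))
  expect_true(all(d$ch2_amplitude[nhej_only] == 3000))
  expect_true(all(d$ch2_amplitude[d$truth_wt > 0] == 5000))
  # single-probe mode never produces the partial level
  w1 <- simulate_well(template_mix(0.5, 0, 0.2), 20000, noise_free_model(),
                      seed = 6)
  expect_true(all(w1$droplets$ch2_amplitude %in% c(1000, 5000)))
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_well(template_mix(1, 0, 0), 0), "n_droplets")
  expect_error(amplitude_model(fam_ref_level = 9500),
               "fam_hdr_level > fam_ref_level")
  expect_error(amplitude_model(hex_partial_level = 500),
               "hex_partial_level >= baseline_hex")
})

test_that("synthetic control alleles apply point edits and indels", {
  expect_equal(make_synthetic_allele("ACGTACGT", edit_substitution(3, "A")),
               "ACGAACGT")
  expect_equal(make_synthetic_allele("ACGTACGT", edit_deletion(4)),
               "ACGTCGT")
  expect_equal(make_synthetic_allele("ACGTACGT",
                                     edit_insertion(4, "GATC")),
               "ACGTGATCACGT")
  # 1-bp insertion NHEJ control
  expect_equal(make_synthetic_allele("ACGTACGT", edit_insertion(4, "T")),
               "ACGTTACGT")
  expect_error(make_synthetic_allele("ACGT", edit_substitution(4, "A")),
               "outside")
  expect_error(make_synthetic_allele("ACGT", edit_deletion(3, width = 2)),
               "outside")
  expect_error(make_synthetic_allele("ACNT", edit_deletion(1)),
               "A, C, G, T")
})
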