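test_that("threshold logic routes droplets to the documented clusters", {
  g <- gate_config(2500, 7000, 2500)
  w <- well_data(data.frame(
    ch1_amplitude = c(9500, 5000, 5000, 800, 800),
    ch2_amplitude = c(800, 800, 5000, 800, 5000)))
  gw <- suppressWarnings(assign_clusters(w, g))
  expect_equal(as.character(gw$labels),
               c("hdr_plus", "nhej", "wt_plus", "empty", "anomalous"))
  expect_equal(gw$counts$n_anomalous, 1)
  expect_warning(assign_clusters(w, g), "no cluster definition")
})

test_that("every droplet gets exactly one label and counts sum to total", {
  w <- simulate_well(template_mix(1.5, 0.1, 0.2), 20000, seed = 11)
  gw <- assign_clusters(w, default_gates())
  expect_equal(length(gw$labels), 20000)
  expect_false(any(is.na(gw$labels)))
  expect_equal(total_droplets(gw$counts), 20000)
})

test_that("zero-noise gating reproduces truth-implied clusters exactly", {
  w <- simulate_well(template_mix(2, 0.05, 0.1), 30000, noise_free_model(),
                     seed = 12)
  gw <- assign_clusters(w, default_gates(noise_free_model()))
  expect_equal(as.character(gw$labels), as.character(truth_clusters(w)))
})

test_that("multi-probe NHEJ droplets with partial HEX stay in the NHEJ gate", {
  m <- noise_free_model(n_nhej_probes = 2, p_partial_retention = 1)
  # hex_low raised between the partial (3000) and full (5000) HEX levels
  g <- gate_config(3000, 7000, 4000)
  w <- simulate_well(template_mix(1, 0.02, 0.3), 30000, m, seed = 13)
  gw <- assign_clusters(w, g)
  expect_equal(as.character(gw$labels), as.character(truth_clusters(w)))
  # enumerate occupancy patterns explicitly: (wt, hdr, nhej) -> cluster
  amp <- function(wt, hdr, nhej) {
    fam <- if (hdr > 0) 9000 else if (wt + nhej > 0) 5000 else 1000
    hex <- if (wt > 0) 5000 else if (nhej > 0) 3000 else 1000
    c(fam, hex)
  }
  cases <- expand.grid(wt = 0:1, hdr = 0:1, nhej = 0:1)
  expected <- with(cases, ifelse(hdr > 0, "hdr_plus",
                          ifelse(wt > 0, "wt_plus",
                          ifelse(nhej > 0, "nhej", "empty"))))
  amps <- t(mapply(amp, cases$wt, cases$hdr, cases$nhej))
  wv <- well_data(data.frame(ch1_amplitude = amps[, 1],
                             ch2_amplitude = amps[, 2]))
  expect_equal(as.character(assign_clusters(wv, g)$labels), expected)
})

test_that("raising fam_high never increases the HDR+ count", {
  w <- simulate_well(template_mix(1.8, 0.1, 0.1), 20000, seed = 14)
  counts <- vapply(seq(5500, 9500, by = 500), function(th)
    assign_clusters(w, gate_config(3000, th, 3000))$counts$n_hdr_plus,
    integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gates fit from noise-free controls land at cluster midpoints", {
  neg <- simulate_well(template_mix(lambda_wt = 1), 10000,
                       noise_free_model(), seed = 15)
  pos <- simulate_well(template_mix(1, 0.3, 0), 10000, noise_free_model(),
                       seed = 16)
  g <- fit_gates_from_controls(neg, pos)
  expect_equal(g$fam_low, 3000)
  expect_equal(g$hex_low, 3000)
  expect_equal(g$fam_high, 7000)
})

test_that("gates fit from noisy controls misclassify under 0.1% of droplets", {
  neg <- simulate_well(template_mix(lambda_wt = 1), 15000, seed = 17)
  pos <- simulate_well(template_mix(1, 0.3, 0), 15000, seed = 18)
  g <- fit_gates_from_controls(neg, pos)
  w <- simulate_well(template_mix(1.5, 0.1, 0.2), 20000, seed = 19)
  gw <- assign_clusters(w, g)
  err <- mean(as.character(gw$labels) != as.character(truth_clusters(w)))
  expect_lt(err, 0.001)
})

test_that("degenerate single-cluster controls are flagged for manual gating", {
  empty_only <- simulate_well(template_mix(0, 0, 0), 5000,
                              amplitude_model(), seed = 20)
  pos <- simulate_well(template_mix(1, 0.3, 0), 5000, seed = 21)
  expect_error(fit_gates_from_controls(empty_only, pos),
               "supply manual gates")
})
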