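test_that("the CI non-overlap rule picks the lowest consecutively detected point", {
  # background with zero spike-positive droplets: CI upper bound is 0
  bg <- quantify_classes(cluster_counts(8000, 0, 52000, 0))
  expect_equal(bg$ci_high[["nhej"]], 0)
  mk_points <- function(ci_low)
    data.frame(fraction = c(5, 2.5, 1.25, 0.625, 0.3),
               ci_low = ci_low, ci_high = ci_low + 0.1,
               lambda = ci_low + 0.05, est_fraction = NA)
  r <- lod_by_ci_nonoverlap(mk_points(c(0.1, 0.1, 0.1, 0, 0)), bg, "nhej")
  expect_equal(r$lod_fraction, 1.25)
  expect_false(r$at_lowest)
  expect_equal(r$detection$detected, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # an isolated detection below a gap does not set the LoD
  r2 <- lod_by_ci_nonoverlap(mk_points(c(0.1, 0.1, 0, 0.1, 0)), bg, "nhej")
  expect_equal(r2$lod_fraction, 2.5)
  # all points detected: LoD reported at (i.e. at most) the lowest fraction
  r3 <- lod_by_ci_nonoverlap(mk_points(rep(0.1, 5)), bg, "nhej")
  expect_equal(r3$lod_fraction, 0.3)
  expect_true(r3$at_lowest)
  # nothing detected
  r4 <- lod_by_ci_nonoverlap(mk_points(rep(0, 5)), bg, "nhej")
  expect_true(is.na(r4$lod_fraction))
  # unsorted input rejected
  bad <- mk_points(rep(0.1, 5))
  bad$fraction <- rev(bad$fraction)
  expect_error(lod_by_ci_nonoverlap(bad, bg, "nhej"), "descending")
})

test_that("dilution series validates its fraction ladder", {
  expect_error(run_dilution_series(fractions = c(1, 2)), "decreasing")
  expect_error(run_dilution_series(fractions = c(2, 0)), "percentages")
})

test_that("noise-free series recovers spike fractions within 3 SE down to 0.1%", {
  fr <- 5 / 2^(0:5)  # 5% .. 0.156%
  s <- run_dilution_series(fractions = fr, spike_class = "nhej",
                           model = noise_free_model(), seed = 51)
  for (i in seq_along(fr)) {
    q <- s$quants[[i]]
    se_pct <- freq_se_pct(q, "nhej")
    expect_lt(abs(s$points$est_fraction[i] - fr[i]), 3 * se_pct)
  }
  # linearity of estimated vs true fraction over the detectable range
  fit <- stats::lm(est_fraction ~ fraction, data = s$points)
  expect_gt(stats::coef(fit)[["fraction"]], 0.9)
  expect_lt(stats::coef(fit)[["fraction"]], 1.1)
})

test_that("a 5% spike point is detected far above background", {
  s <- run_dilution_series(fractions = 5, spike_class = "hdr", seed = 52)
  r <- lod_by_ci_nonoverlap(s)
  expect_true(r$detection$detected[1])
  expect_lt(abs(s$points$est_fraction[1] - 5), 0.5)
})

test_that("merging more wells per point does not worsen the median LoD", {
  med_lod <- function(wpp) {
    lods <- vapply(1:12, function(i) {
      s <- run_dilution_series(fractions = 5 / 2^(0:8),
                               spike_class = "nhej",
                               wells_per_point = wpp, wt_only_wells = 2,
                               n_droplets = 8000, seed = 7000 + i)
      lod_by_ci_nonoverlap(s)$lod_fraction
    }, numeric(1))
    stats::median(lods, na.rm = TRUE)
  }
  expect_lte(med_lod(4), med_lod(1))
})

test_that("a misgating rate produces nonzero WT-only background", {
  s <- run_dilution_series(fractions = c(5, 2.5), spike_class = "nhej",
                           misgating_rate = 0.002, seed = 53)
  expect_gt(s$background$lambda[["nhej"]], 0)
  expect_gt(s$background$ci_high[["nhej"]], 0)
  s0 <- run_dilution_series(fractions = c(5, 2.5), spike_class = "nhej",
                            seed = 53)
  expect_equal(s0$background$lambda[["nhej"]], 0)
})

test_that("replicated LoD experiments are reproducible under one master seed", {
  e1 <- run_lod_experiment("hdr", seed = 54, replicates = 2,
                           fractions = c(5, 2.5, 1.25), n_droplets = 5000)
  e2 <- run_lod_experiment("hdr", seed = 54, replicates = 2,
                           fractions = c(5, 2.5, 1.25), n_droplets = 5000)
  expect_identical(e1$lods, e2$lods)
  expect_equal(e1$median_lod, stats::median(e1$lods))
})
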