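#' Simulate a serial-dilution sensitivity experiment
#'
#' Reproduces the assay-validation design in silico: a 2-fold serial
#' dilution of synthetic HDR or NHEJ template spiked into a constant WT
#' genomic background, several wells merged per dilution point, plus
#' WT-only wells that measure the assay background. Each point is
#' simulated, gated, merged and quantified with the subset Poisson
#' estimators.
#'
#' The spike fraction is a percentage of total copies, so a point at
#' fraction `f` adds `background_copies * f / (100 - f)` spike copies per
#' well on top of the constant background.
#'
#' @param fractions Spike fractions in percent, strictly decreasing, `> 0`
#'   (default a 2-fold ladder from 5% down to ~0.02%).
#' @param spike_class `"nhej"` or `"hdr"`.
#' @param background_copies WT template copies per well (default 30,000,
#'   i.e. ~100 ng genomic DNA).
#' @param n_droplets Droplets per well (default 15,000).
#' @param wells_per_point Wells merged per dilution point (default 2).
#' @param wt_only_wells WT-only background wells merged (default 4).
#' @param model An [amplitude_model()].
#' @param gates A [gate_config()] (defaults to [default_gates()] of
#'   `model`).
#' @param seed Optional integer seed governing all randomness.
#' @param misgating_rate Probability that a reference-cluster droplet is
#'   falsely called into the spike cluster, modelling real WT-only
#'   background; default 0 (no false calls).
#' @param droplet_volume_nl Droplet volume for concentration reporting.
#' @return An object of class `dilution_series`: `spike_class`, `points`
#'   (data frame with per-point true fraction, class rate and CI, and
#'   estimated fraction), `background` (the merged WT-only
#'   [quantify_classes()] estimate), and the per-point `quants`.
#' @seealso [lod_by_ci_nonoverlap()], [run_lod_experiment()]
#' @export
run_dilution_series <- function(fractions = 5 / 2^(0:8),
                                spike_class = c("nhej", "hdr"),
                                background_copies = 30000,
                                n_droplets = 15000, wells_per_point = 2,
                                wt_only_wells = 4,
                                model = amplitude_model(),
                                gates = default_gates(model), seed = NULL,
                                misgating_rate = 0,
                                droplet_volume_nl = 0.85) {
  spike_class <- match.arg(spike_class)
  if (length(fractions) < 1L || any(!is.finite(fractions)) ||
      any(fractions <= 0) || any(fractions >= 100))
    stop("fractions must be percentages in (0, 100)")
  if (is.unsorted(rev(fractions), strictly = TRUE))
    stop("fractions must be strictly decreasing")
  assert_scalar_number(background_copies, "background_copies", lower = 0)
  n_droplets <- assert_count(n_droplets, "n_droplets", minimum = 1)
  wells_per_point <- assert_count(wells_per_point, "wells_per_point", 1)
  wt_only_wells <- assert_count(wt_only_wells, "wt_only_wells", 1)
  assert_scalar_number(misgating_rate, "misgating_rate", 0, 1)

  lam_wt <- background_copies / n_droplets
  n_wells <- length(fractions) * wells_per_point + wt_only_wells

  with_rng_seed(seed, {
    well_seeds <- sample.int(.Machine$integer.max - 1L, n_wells)
    k <- 0L
    simulate_counts <- function(mix) {
      k <<- k + 1L
      gw <- assign_clusters(
        simulate_well(mix, n_droplets, model, seed = well_seeds[k]), gates)
      misgate(gw$counts, spike_class, misgating_rate)
    }
    quants <- lapply(fractions, function(f) {
      spike_copies <- background_copies * f / (100 - f)
      lam_s <- spike_copies / n_droplets
      mix <- template_mix(
        lambda_wt = lam_wt,
        lambda_hdr = if (spike_class == "hdr") lam_s else 0,
        lambda_nhej = if (spike_class == "nhej") lam_s else 0)
      counts <- lapply(seq_len(wells_per_point),
                       function(i) simulate_counts(mix))
      quantify_classes(merge_wells(counts), droplet_volume_nl)
    })
    bg_counts <- lapply(seq_len(wt_only_wells), function(i)
      simulate_counts(template_mix(lambda_wt = lam_wt)))
    background <- quantify_classes(merge_wells(bg_counts),
                                   droplet_volume_nl)

    points <- data.frame(
      fraction = fractions,
      wells = wells_per_point,
      lambda = vapply(quants, function(q) q$lambda[[spike_class]],
                      numeric(1)),
      ci_low = vapply(quants, function(q) q$ci_low[[spike_class]],
                      numeric(1)),
      ci_high = vapply(quants, function(q) q$ci_high[[spike_class]],
                       numeric(1)),
      est_fraction = vapply(quants, function(q) {
        tot <- sum(q$lambda)
        if (tot > 0) 100 * q$lambda[[spike_class]] / tot else 0
      }, numeric(1)))

    structure(list(spike_class = spike_class, points = points,
                   background = background, quants = quants,
                   n_droplets = n_droplets,
                   background_copies = background_copies),
              class = "dilution_series")
  })
}

# Move false-positive droplets from the reference cluster into the spike
# cluster to emulate real WT-only background misgating.
misgate <- function(counts, spike_class, rate) {
  if (rate <= 0) return(counts)
  if (spike_class == "nhej") {
    k <- stats::rbinom(1L, counts$n_empty, rate)
    cluster_counts(counts$n_empty - k, counts$n_nhej + k,
                   counts$n_wt_plus, counts$n_hdr_plus, counts$n_anomalous)
  } else {
    k <- stats::rbinom(1L, counts$n_wt_plus, rate)
    cluster_counts(counts$n_empty, counts$n_nhej,
                   counts$n_wt_plus - k, counts$n_hdr_plus + k,
                   counts$n_anomalous)
  }
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series (%s spike): %d points, background %s\n",
              toupper(x$spike_class), nrow(x$points),
              sprintf("lambda %.3g [%.3g, %.3g]",
                      x$background$lambda[[x$spike_class]],
                      x$background$ci_low[[x$spike_class]],
                      x$background$ci_high[[x$spike_class]])))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Limit of detection by 95% CI non-overlap
#'
#' A dilution point is detected when the lower bound of its class-rate CI
#' exceeds the upper CI bound of the WT-only background for the same class.
#' The limit of detection is the smallest tested fraction that is detected
#' with all larger fractions also detected (the consecutive-detection rule
#' prevents an isolated false positive from defining the LoD). If even the
#' smallest tested fraction is detected, the LoD is reported as at most
#' that fraction (`at_lowest = TRUE`).
#'
#' @param points A `dilution_series` from [run_dilution_series()], or its
#'   `points` data frame (sorted by strictly descending fraction).
#' @param background The WT-only [quantify_classes()] estimate (taken from
#'   the series when one is supplied).
#' @param spike_class Class of interest (taken from the series when one is
#'   supplied).
#' @return An object of class `lod_result`: `spike_class`, `lod_fraction`
#'   (`NA` if nothing was detected), `at_lowest`, `background_ci_high`, and
#'   a `detection` data frame of per-point flags.
#' @export
lod_by_ci_nonoverlap <- function(points, background = NULL,
                                 spike_class = NULL) {
  if (inherits(points, "dilution_series")) {
    background <- background %||% points$background
    spike_class <- spike_class %||% points$spike_class
    points <- points$points
  }
  if (is.null(background) || !inherits(background, "quant_estimate"))
    stop("background must be a quant_estimate")
  spike_class <- match.arg(spike_class, c("nhej", "hdr"))
  if (!is.data.frame(points) ||
      !all(c("fraction", "ci_low") %in% names(points)))
    stop("points must have columns 'fraction' and 'ci_low'")
  if (is.unsorted(rev(points$fraction), strictly = TRUE))
    stop("points must be sorted by strictly descending fraction")

  bg_high <- background$ci_high[[spike_class]]
  detected <- points$ci_low > bg_high
  run <- cumprod(detected) > 0   # consecutive detections from the top
  n_det <- sum(run)
  structure(list(spike_class = spike_class,
                 lod_fraction = if (n_det > 0) points$fraction[n_det]
                                else NA_real_,
                 at_lowest = n_det == nrow(points),
                 background_ci_high = bg_high,
                 detection = data.frame(fraction = points$fraction,
                                        detected = detected)),
            class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  lod <- if (is.na(x$lod_fraction)) "not reached within tested range"
         else if (x$at_lowest)
           sprintf("<= %g%% (lowest tested fraction detected)",
                   x$lod_fraction)
         else sprintf("%g%%", x$lod_fraction)
  cat(sprintf("Limit of detection (%s, CI non-overlap): %s\n",
              toupper(x$spike_class), lod))
  cat(sprintf("  background lambda CI upper bound: %.4g\n",
              x$background_ci_high))
  invisible(x)
}

#' Replicated limit-of-detection experiment
#'
#' Runs [run_dilution_series()] plus [lod_by_ci_nonoverlap()] over several
#' replicate ladders whose seeds derive from one master seed, and
#' summarizes the LoD as the median across replicates. At the detection
#' edge a single ladder's LoD rides on a handful of droplets, so the
#' replicate median is the stabler summary of the procedure's sensitivity.
#'
#' @param spike_class `"nhej"` or `"hdr"`.
#' @param seed Master integer seed.
#' @param replicates Number of replicate ladders (default 5).
#' @param ... Passed to [run_dilution_series()].
#' @return A list of class `lod_experiment`: `spike_class`, `lods`
#'   (per-replicate LoD fractions), `median_lod`, and the `results` list of
#'   `lod_result` objects.
#' @export
run_lod_experiment <- function(spike_class = c("nhej", "hdr"), seed = NULL,
                               replicates = 5, ...) {
  spike_class <- match.arg(spike_class)
  replicates <- assert_count(replicates, "replicates", minimum = 1)
  seeds <- with_rng_seed(seed,
    sample.int(.Machine$integer.max - 1L, replicates))
  results <- lapply(seeds, function(s)
    lod_by_ci_nonoverlap(
      run_dilution_series(spike_class = spike_class, seed = s, ...)))
  lods <- vapply(results, `[[`, numeric(1), "lod_fraction")
  structure(list(spike_class = spike_class, lods = lods,
                 median_lod = stats::median(lods, na.rm = TRUE),
                 results = results),
            class = "lod_experiment")
}

#' @export
print.lod_experiment <- function(x, ...) {
  cat(sprintf("LoD experiment (%s): median LoD %g%% over %d replicates\n",
              toupper(x$spike_class), x$median_lod, length(x$lods)))
  cat("  per-replicate LoD (%):", paste(signif(x$lods, 3), collapse = ", "),
      "\n")
  invisible(x)
}
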