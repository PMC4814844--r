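#' Rectangular gate thresholds for two-channel cluster assignment
#'
#' Three thresholds partition the amplitude plane into the four assay
#' clusters: `fam_low` separates FAM-negative from FAM+ droplets,
#' `fam_high` separates FAM+ from FAM++ (HDR), and `hex_low` separates
#' HEX-negative from HEX-positive. For assays with multiple NHEJ probes the
#' NHEJ cluster does not entirely lose HEX fluorescence, so `hex_low` must
#' be placed between the partial and full HEX levels.
#'
#' @param fam_low,fam_high,hex_low Finite thresholds, `fam_low < fam_high`.
#' @return An object of class `gate_config`.
#' @seealso [assign_clusters()], [fit_gates_from_controls()],
#'   [default_gates()]
#' @export
gate_config <- function(fam_low, fam_high, hex_low) {
  assert_scalar_number(fam_low, "fam_low")
  assert_scalar_number(fam_high, "fam_high")
  assert_scalar_number(hex_low, "hex_low")
  if (fam_low >= fam_high) stop("require fam_low < fam_high")
  structure(list(fam_low = fam_low, fam_high = fam_high, hex_low = hex_low),
            class = "gate_config")
}

#' @export
print.gate_config <- function(x, ...) {
  cat(sprintf("Gates: FAM low %g / high %g; HEX low %g\n",
              x$fam_low, x$fam_high, x$hex_low))
  invisible(x)
}

#' Midpoint gates implied by an amplitude model
#'
#' Places each threshold halfway between the adjacent noise-free cluster
#' levels of `model`; for multi-probe models `hex_low` sits between the
#' partial-HEX and full-HEX levels instead of between baseline and full.
#'
#' @param model An [amplitude_model()].
#' @return A [gate_config()].
#' @export
default_gates <- function(model = amplitude_model()) {
  stopifnot(inherits(model, "amplitude_model"))
  hex_floor <- if (model$n_nhej_probes >= 2L) model$hex_partial_level
               else model$baseline_hex
  gate_config(fam_low  = (model$baseline_fam + model$fam_ref_level) / 2,
              fam_high = (model$fam_ref_level + model$fam_hdr_level) / 2,
              hex_low  = (hex_floor + model$hex_wt_level) / 2)
}

#' Droplet counts per gated cluster
#'
#' The sufficient statistic for all downstream quantification: counts of
#' droplets in the empty (double-negative), NHEJ (FAM+ HEX-), WT+
#' (FAM+ HEX+) and HDR+ (FAM++) clusters, plus droplets matching no cluster
#' definition (FAM- HEX+), which are excluded from quantification.
#'
#' @param n_empty,n_nhej,n_wt_plus,n_hdr_plus,n_anomalous Non-negative
#'   droplet counts.
#' @return An object of class `cluster_counts`.
#' @export
cluster_counts <- function(n_empty, n_nhej = 0, n_wt_plus = 0,
                           n_hdr_plus = 0, n_anomalous = 0) {
  structure(list(n_empty = assert_count(n_empty, "n_empty"),
                 n_nhej = assert_count(n_nhej, "n_nhej"),
                 n_wt_plus = assert_count(n_wt_plus, "n_wt_plus"),
                 n_hdr_plus = assert_count(n_hdr_plus, "n_hdr_plus"),
                 n_anomalous = assert_count(n_anomalous, "n_anomalous")),
            class = "cluster_counts")
}

#' @export
print.cluster_counts <- function(x, ...) {
  cat(sprintf(paste0("Cluster counts: empty %d, NHEJ %d, WT+ %d, HDR+ %d",
                     " (anomalous %d; total %d)\n"),
              x$n_empty, x$n_nhej, x$n_wt_plus, x$n_hdr_plus, x$n_anomalous,
              total_droplets(x)))
  invisible(x)
}

#' @rdname cluster_counts
#' @param x A `cluster_counts`.
#' @export
total_droplets <- function(x) {
  stopifnot(inherits(x, "cluster_counts"))
  x$n_empty + x$n_nhej + x$n_wt_plus + x$n_hdr_plus + x$n_anomalous
}

#' @export
as.data.frame.cluster_counts <- function(x, ...) {
  data.frame(n_empty = x$n_empty, n_nhej = x$n_nhej,
             n_wt_plus = x$n_wt_plus, n_hdr_plus = x$n_hdr_plus,
             n_anomalous = x$n_anomalous)
}

#' Assign droplets to the four assay clusters
#'
#' Applies rectangular gates: a droplet is HDR+ if `ch1 >= fam_high`
#' (any droplet positive for HDR is FAM++ regardless of its HEX signal);
#' otherwise NHEJ if `ch1 >= fam_low` and `ch2 < hex_low`; otherwise WT+ if
#' `ch1 >= fam_low` and `ch2 >= hex_low`; otherwise empty if both channels
#' are below their low thresholds. FAM-negative but HEX-positive droplets
#' match no cluster definition and are counted as anomalous (with a
#' warning) and excluded from quantification totals.
#'
#' @param well A [well_data()].
#' @param gates A [gate_config()].
#' @return A list of class `gated_well` with elements `counts`
#'   (a [cluster_counts()]), `labels` (per-droplet factor), `well_id`,
#'   `sample_id`.
#' @export
assign_clusters <- function(well, gates) {
  stopifnot(inherits(well, "well_data"), inherits(gates, "gate_config"))
  d <- well$droplets
  if (nrow(d) == 0L) stop("empty well: no droplets to gate")
  ch1 <- d$ch1_amplitude
  ch2 <- d$ch2_amplitude
  lab <- rep("anomalous", nrow(d))
  lab[ch1 < gates$fam_low & ch2 < gates$hex_low] <- "empty"
  lab[ch1 >= gates$fam_low & ch2 < gates$hex_low] <- "nhej"
  lab[ch1 >= gates$fam_low & ch2 >= gates$hex_low] <- "wt_plus"
  lab[ch1 >= gates$fam_high] <- "hdr_plus"
  labels <- factor(lab, levels = c("empty", "nhej", "wt_plus", "hdr_plus",
                                   "anomalous"))
  n <- tabulate(labels, nbins = 5L)
  if (n[5] > 0L)
    warning(sprintf(
      "well %s: %d FAM-/HEX+ droplet(s) match no cluster definition; %s",
      well$well_id, n[5], "counted as anomalous and excluded"))
  structure(list(counts = cluster_counts(n[1], n[2], n[3], n[4], n[5]),
                 labels = labels, well_id = well$well_id,
                 sample_id = well$sample_id),
            class = "gated_well")
}

#' @export
print.gated_well <- function(x, ...) {
  cat(sprintf("Gated well '%s' (sample '%s')\n", x$well_id, x$sample_id))
  print(x$counts)
  invisible(x)
}

## Automatic gate fitting -----------------------------------------------

# Exact least-squares split of a 1-D sample into two groups (Otsu-style):
# scans every ordered split point and minimizes total within-group SS.
split_two_groups <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) stop("need at least 2 values to split")
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  k <- seq_len(n - 1L)
  ss_low <- cs2[k] - cs[k]^2 / k
  ss_high <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  kb <- which.min(ss_low + ss_high)
  list(mean_low = cs[kb] / kb,
       mean_high = (cs[n] - cs[kb]) / (n - kb),
       sd_within = sqrt((ss_low[kb] + ss_high[kb]) / n),
       n_low = kb, n_high = n - kb)
}

#' Fit gate thresholds from control wells
#'
#' Estimates thresholds from an unmodified negative-control well (empty and
#' WT+ clusters only) and a positive-control well with known modification
#' (additionally containing FAM++ droplets). Per channel, droplets are
#' split into low/high groups by the exact two-group least-squares 1-D
#' partition; each threshold is the midpoint between the adjacent group
#' means. `fam_low` and `hex_low` come from the negative well; `fam_high`
#' from the FAM-positive droplets of the positive well.
#'
#' Degenerate input (a channel whose two fitted groups are not clearly
#' separated, e.g. a single cluster) raises an error; supply manual gates
#' via [gate_config()] in that case.
#'
#' @param negative_well,positive_well [well_data()] objects.
#' @param min_separation_sd Required separation of group means, in units of
#'   the pooled within-group SD (default 4).
#' @return A [gate_config()].
#' @export
fit_gates_from_controls <- function(negative_well, positive_well,
                                    min_separation_sd = 4) {
  stopifnot(inherits(negative_well, "well_data"),
            inherits(positive_well, "well_data"))
  fit1 <- function(x, what) {
    s <- split_two_groups(x)
    sep <- s$mean_high - s$mean_low
    if (!(sep > min_separation_sd * s$sd_within) || sep <= 0)
      stop("degenerate ", what, " distribution (single cluster?): ",
           "automatic gate fitting failed; supply manual gates",
           call. = FALSE)
    (s$mean_low + s$mean_high) / 2
  }
  fam_low <- fit1(negative_well$droplets$ch1_amplitude,
                  "negative-control FAM")
  hex_low <- fit1(negative_well$droplets$ch2_amplitude,
                  "negative-control HEX")
  pos_fam <- positive_well$droplets$ch1_amplitude
  pos_fam <- pos_fam[pos_fam >= fam_low]
  if (length(pos_fam) < 2L)
    stop("positive control has no FAM-positive droplets above fam_low")
  fam_high <- fit1(pos_fam, "positive-control FAM+/FAM++")
  gate_config(fam_low = fam_low, fam_high = fam_high, hex_low = hex_low)
}
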