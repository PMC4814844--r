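#' Per-well droplet data
#'
#' Container for one ddPCR well: a data frame with one row per droplet
#' holding the two channel amplitudes (`ch1_amplitude` = FAM,
#' `ch2_amplitude` = HEX) and, for simulated wells, the ground-truth copy
#' occupancy columns `truth_wt`, `truth_hdr`, `truth_nhej`.
#'
#' @param droplets A data frame with numeric columns `ch1_amplitude` and
#'   `ch2_amplitude` (and optional integer truth columns as above).
#' @param well_id,sample_id Identifier strings.
#' @param metadata Named list of free-form labels (locus, nuclease, donor
#'   strand, replicate, ...).
#' @return An object of class `well_data`.
#' @seealso [simulate_well()], [assign_clusters()], [read_amplitude_csv()]
#' @export
well_data <- function(droplets, well_id = "A01", sample_id = "sample1",
                      metadata = list()) {
  if (!is.data.frame(droplets) || nrow(droplets) < 1L)
    stop("droplets must be a data frame with at least one row")
  for (col in c("ch1_amplitude", "ch2_amplitude")) {
    if (!col %in% names(droplets) || !is.numeric(droplets[[col]]))
      stop("droplets must have numeric column ", col)
    if (any(!is.finite(droplets[[col]])))
      stop("non-finite amplitude in column ", col)
  }
  has_truth <- all(c("truth_wt", "truth_hdr", "truth_nhej") %in%
                     names(droplets))
  if (has_truth) {
    tr <- droplets[c("truth_wt", "truth_hdr", "truth_nhej")]
    if (any(vapply(tr, function(v) any(v < 0 | v != floor(v)), logical(1))))
      stop("truth occupancy counts must be non-negative integers")
  }
  structure(list(well_id = as.character(well_id),
                 sample_id = as.character(sample_id),
                 droplets = droplets,
                 metadata = metadata,
                 has_truth = has_truth),
            class = "well_data")
}

#' @export
print.well_data <- function(x, ...) {
  cat(sprintf("ddPCR well '%s' (sample '%s'): %d droplets%s\n",
              x$well_id, x$sample_id, nrow(x$droplets),
              if (x$has_truth) ", with simulation truth" else ""))
  invisible(x)
}

#' @export
dim.well_data <- function(x) dim(x$droplets)

#' Ground-truth cluster of each simulated droplet
#'
#' Maps the stored truth occupancy of a simulated well to the cluster the
#' assay chemistry implies: any HDR copy makes the droplet FAM++ (`hdr_plus`);
#' otherwise a droplet with NHEJ but no WT copies is FAM+ HEX-low (`nhej`);
#' otherwise any WT copy gives FAM+ HEX+ (`wt_plus`); otherwise `empty`.
#'
#' @param well A [well_data()] carrying truth columns.
#' @return Factor with levels `empty`, `nhej`, `wt_plus`, `hdr_plus`.
#' @export
truth_clusters <- function(well) {
  stopifnot(inherits(well, "well_data"))
  if (!well$has_truth)
    stop("well carries no simulation truth occupancy")
  d <- well$droplets
  lab <- rep("empty", nrow(d))
  lab[d$truth_wt > 0L] <- "wt_plus"
  lab[d$truth_wt == 0L & d$truth_nhej > 0L] <- "nhej"
  lab[d$truth_hdr > 0L] <- "hdr_plus"
  factor(lab, levels = c("empty", "nhej", "wt_plus", "hdr_plus"))
}

#' Scatter plot of a well's droplets
#'
#' @param x A [well_data()].
#' @param gates Optional [gate_config()] whose thresholds are drawn and used
#'   to color droplets by cluster.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.well_data <- function(x, gates = NULL, ...) {
  d <- x$droplets
  col <- "grey40"
  if (!is.null(gates)) {
    lab <- assign_clusters(x, gates)$labels
    pal <- c(empty = "black", nhej = "dodgerblue3", wt_plus = "forestgreen",
             hdr_plus = "darkorange2", anomalous = "red")
    col <- pal[as.character(lab)]
  }
  graphics::plot(d$ch2_amplitude, d$ch1_amplitude, pch = 20, cex = 0.3,
                 col = col, xlab = "Ch2 (HEX) amplitude",
                 ylab = "Ch1 (FAM) amplitude",
                 main = sprintf("Well %s (%s)", x$well_id, x$sample_id), ...)
  if (!is.null(gates)) {
    graphics::abline(h = c(gates$fam_low, gates$fam_high), lty = 2)
    graphics::abline(v = gates$hex_low, lty = 2)
  }
  invisible(x)
}
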