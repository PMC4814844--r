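#' Template mixture: mean template copies per droplet by allele class
#'
#' A `template_mix` holds the true mean number of wild-type (WT), HDR and
#' NHEJ template copies loaded per droplet. Under random partitioning the
#' per-droplet copy number of each class is Poisson with these rates, which
#' is the model inverted by [quantify_classes()].
#'
#' @param lambda_wt,lambda_hdr,lambda_nhej Mean copies per droplet for the
#'   WT, HDR and NHEJ allele classes (dimensionless, `>= 0`).
#' @return An object of class `template_mix`.
#' @seealso [spike_in_mix()], [mix_from_copies()], [simulate_well()]
#' @examples
#' template_mix(lambda_wt = 1.8, lambda_hdr = 0.1, lambda_nhej = 0.1)
#' @export
template_mix <- function(lambda_wt = 0, lambda_hdr = 0, lambda_nhej = 0) {
  assert_scalar_number(lambda_wt, "lambda_wt", lower = 0)
  assert_scalar_number(lambda_hdr, "lambda_hdr", lower = 0)
  assert_scalar_number(lambda_nhej, "lambda_nhej", lower = 0)
  structure(list(lambda_wt = lambda_wt, lambda_hdr = lambda_hdr,
                 lambda_nhej = lambda_nhej),
            class = "template_mix")
}

#' @export
print.template_mix <- function(x, ...) {
  cat("Template mix (mean copies/droplet):\n")
  cat(sprintf("  WT   %g\n  HDR  %g\n  NHEJ %g\n",
              x$lambda_wt, x$lambda_hdr, x$lambda_nhej))
  cat(sprintf("  total %g\n", lambda_total(x)))
  invisible(x)
}

#' @rdname template_mix
#' @param x A `template_mix`.
#' @export
lambda_total <- function(x) {
  stopifnot(inherits(x, "template_mix"))
  x$lambda_wt + x$lambda_hdr + x$lambda_nhej
}

#' Build a template mix from per-well copy totals
#'
#' @param copies_wt,copies_hdr,copies_nhej Expected total template copies of
#'   each class loaded into the well.
#' @param n_droplets Number of droplets the well is partitioned into.
#' @return A [template_mix()].
#' @export
mix_from_copies <- function(copies_wt, copies_hdr = 0, copies_nhej = 0,
                            n_droplets) {
  assert_scalar_number(copies_wt, "copies_wt", lower = 0)
  assert_scalar_number(copies_hdr, "copies_hdr", lower = 0)
  assert_scalar_number(copies_nhej, "copies_nhej", lower = 0)
  n_droplets <- assert_count(n_droplets, "n_droplets", minimum = 1)
  template_mix(copies_wt / n_droplets, copies_hdr / n_droplets,
               copies_nhej / n_droplets)
}

#' Spike-in mixture with a given fractional composition
#'
#' Mimics the validation experiment in which synthetic HDR and NHEJ alleles
#' are spiked into a constant WT genomic background at known fractions of
#' the total copy pool. Given the WT copy total and the desired HDR/NHEJ
#' fractions of the *total* copies, returns the per-droplet rates.
#'
#' @param wt_copies Total WT template copies per well.
#' @param hdr_fraction,nhej_fraction Desired fractions (in `[0, 1)`, summing
#'   to `< 1`) of total copies contributed by the HDR and NHEJ alleles.
#' @param n_droplets Droplets per well.
#' @return A [template_mix()] whose expected copy totals have the requested
#'   composition; total copies equal `wt_copies / (1 - hdr - nhej)`.
#' @examples
#' spike_in_mix(27000, 0.05, 0.05, 15000)  # rates (1.8, 0.1, 0.1)
#' @export
spike_in_mix <- function(wt_copies, hdr_fraction, nhej_fraction, n_droplets) {
  assert_scalar_number(wt_copies, "wt_copies", lower = 0)
  assert_scalar_number(hdr_fraction, "hdr_fraction", lower = 0)
  assert_scalar_number(nhej_fraction, "nhej_fraction", lower = 0)
  n_droplets <- assert_count(n_droplets, "n_droplets", minimum = 1)
  if (hdr_fraction >= 1 || nhej_fraction >= 1 ||
      hdr_fraction + nhej_fraction >= 1)
    stop("spike fractions must each lie in [0, 1) and sum to < 1")
  total <- wt_copies / (1 - hdr_fraction - nhej_fraction)
  template_mix(wt_copies / n_droplets,
               total * hdr_fraction / n_droplets,
               total * nhej_fraction / n_droplets)
}

#' Convert between per-droplet rates and concentrations
#'
#' ddPCR concentrations are reported in copies per microlitre of analyzed
#' sample; with monodisperse droplets of volume `droplet_volume_nl` the
#' conversion is `concentration = lambda / volume`.
#'
#' @param lambda Mean copies per droplet.
#' @param concentration Copies per microlitre.
#' @param droplet_volume_nl Droplet volume in nanolitres (default 0.85).
#' @return A numeric scalar (vectorized over the first argument).
#' @export
lambda_to_concentration <- function(lambda, droplet_volume_nl = 0.85) {
  assert_scalar_number(droplet_volume_nl, "droplet_volume_nl", lower = 1e-9)
  lambda / (droplet_volume_nl * 1e-3)
}

#' @rdname lambda_to_concentration
#' @export
concentration_to_lambda <- function(concentration, droplet_volume_nl = 0.85) {
  assert_scalar_number(droplet_volume_nl, "droplet_volume_nl", lower = 1e-9)
  concentration * droplet_volume_nl * 1e-3
}

#' Approximate genome copies in a mass of human genomic DNA
#'
#' @param ng Nanograms of genomic DNA.
#' @param copies_per_ng Haploid genome copies per nanogram (default 300,
#'   so 100 ng corresponds to ~30,000 copies).
#' @return Expected genome copy number.
#' @export
copies_from_ng <- function(ng, copies_per_ng = 300) {
  assert_scalar_number(copies_per_ng, "copies_per_ng", lower = 0)
  if (any(!is.finite(ng)) || any(ng < 0)) stop("ng must be >= 0")
  ng * copies_per_ng
}
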