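#' Two-channel droplet amplitude model
#'
#' Parameterizes how template occupancy maps to end-point fluorescence in
#' the two channels read per droplet (Ch1 = FAM, Ch2 = HEX). The assay uses
#' a FAM reference probe (binds all alleles away from the cut site), a FAM
#' HDR "gain" probe (binds only the precise edit, raising FAM+ droplets to
#' FAM++), and one or more HEX NHEJ "drop-off" probes over the cut site(s)
#' (their signal is lost when an indel destroys the binding site).
#'
#' Co-occupied droplets take the class maximum per channel (saturating
#' end-point PCR), not the sum. For assays with more than one NHEJ probe an
#' indel typically destroys only the probe spanning its cut, so NHEJ-only
#' droplets may retain partial HEX signal: each NHEJ allele retains a
#' secondary probe site with probability `p_partial_retention`, and a
#' droplet whose NHEJ alleles are all it contains then sits at
#' `hex_partial_level` instead of baseline. This branch is active only when
#' `n_nhej_probes >= 2`.
#'
#' @param baseline_fam,baseline_hex Baseline (empty-droplet) fluorescence,
#'   arbitrary units.
#' @param fam_ref_level FAM amplitude of droplets carrying any WT or NHEJ
#'   allele (reference probe only; FAM+).
#' @param fam_hdr_level FAM amplitude of droplets carrying an HDR allele
#'   (reference + HDR probe; FAM++). Must exceed `fam_ref_level`.
#' @param hex_wt_level HEX amplitude of droplets carrying a WT allele.
#' @param hex_partial_level HEX amplitude of NHEJ-only droplets that retain
#'   a secondary NHEJ-probe site (multi-probe assays).
#' @param noise_sd_fam,noise_sd_hex Gaussian noise SD added per channel.
#' @param rain_fraction Fraction of droplets displaced uniformly from their
#'   cluster level toward baseline along both channels ("rain").
#' @param n_nhej_probes Number of NHEJ drop-off probes in the assay.
#' @param p_partial_retention Probability that an NHEJ allele retains a
#'   secondary probe site (used only when `n_nhej_probes >= 2`).
#' @return An object of class `amplitude_model`.
#' @seealso [simulate_well()], [default_gates()]
#' @export
amplitude_model <- function(baseline_fam = 1000, fam_ref_level = 5000,
                            fam_hdr_level = 9000, baseline_hex = 1000,
                            hex_wt_level = 5000, hex_partial_level = 3000,
                            noise_sd_fam = 300, noise_sd_hex = 300,
                            rain_fraction = 0, n_nhej_probes = 1,
                            p_partial_retention = 0.5) {
  for (nm in c("baseline_fam", "fam_ref_level", "fam_hdr_level",
               "baseline_hex", "hex_wt_level", "hex_partial_level"))
    assert_scalar_number(get(nm), nm)
  assert_scalar_number(noise_sd_fam, "noise_sd_fam", lower = 0)
  assert_scalar_number(noise_sd_hex, "noise_sd_hex", lower = 0)
  assert_scalar_number(rain_fraction, "rain_fraction", lower = 0, upper = 1)
  assert_scalar_number(p_partial_retention, "p_partial_retention",
                       lower = 0, upper = 1)
  n_nhej_probes <- assert_count(n_nhej_probes, "n_nhej_probes", minimum = 1)
  if (!(fam_hdr_level > fam_ref_level && fam_ref_level > baseline_fam))
    stop("require fam_hdr_level > fam_ref_level > baseline_fam")
  if (!(hex_wt_level > hex_partial_level && hex_partial_level >= baseline_hex))
    stop("require hex_wt_level > hex_partial_level >= baseline_hex")
  structure(list(baseline_fam = baseline_fam, fam_ref_level = fam_ref_level,
                 fam_hdr_level = fam_hdr_level, baseline_hex = baseline_hex,
                 hex_wt_level = hex_wt_level,
                 hex_partial_level = hex_partial_level,
                 noise_sd_fam = noise_sd_fam, noise_sd_hex = noise_sd_hex,
                 rain_fraction = rain_fraction,
                 n_nhej_probes = n_nhej_probes,
                 p_partial_retention = p_partial_retention),
            class = "amplitude_model")
}

#' @export
print.amplitude_model <- function(x, ...) {
  cat("Amplitude model (a.u.):\n")
  cat(sprintf("  FAM: baseline %g, FAM+ %g, FAM++ %g (noise SD %g)\n",
              x$baseline_fam, x$fam_ref_level, x$fam_hdr_level,
              x$noise_sd_fam))
  cat(sprintf("  HEX: baseline %g, partial %g, HEX+ %g (noise SD %g)\n",
              x$baseline_hex, x$hex_partial_level, x$hex_wt_level,
              x$noise_sd_hex))
  cat(sprintf("  rain fraction %g; NHEJ probes %d (partial retention p=%g)\n",
              x$rain_fraction, x$n_nhej_probes, x$p_partial_retention))
  invisible(x)
}
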