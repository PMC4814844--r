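#' Simulate one ddPCR well with known ground truth
#'
#' Draws per-droplet template occupancy independently for each allele class
#' from a Poisson law with the class rate (in the fixed order WT, HDR,
#' NHEJ), then assigns end-point amplitudes by occupancy logic: any HDR copy
#' puts the droplet at `fam_hdr_level` (FAM++); otherwise any WT or NHEJ
#' copy gives `fam_ref_level` (FAM+); otherwise FAM baseline. HEX is
#' `hex_wt_level` if any WT copy is present; otherwise, in multi-probe mode,
#' `hex_partial_level` if an NHEJ allele retains a secondary probe site;
#' otherwise HEX baseline. Rain displacement and Gaussian noise are applied
#' after level assignment; the drawn occupancy is stored as ground truth.
#'
#' @param mix A [template_mix()] of true per-droplet rates (all `>= 0`).
#' @param n_droplets Number of droplets to generate (`>= 1`; a typical well
#'   yields ~15,000 accepted droplets).
#' @param model An [amplitude_model()].
#' @param seed Optional integer seed; identical seeds give identical wells.
#'   The caller's RNG state is left untouched.
#' @param well_id,sample_id,metadata Passed to [well_data()].
#' @return A [well_data()] with truth occupancy columns.
#' @examples
#' w <- simulate_well(spike_in_mix(27000, 0.05, 0.05, 15000), 15000, seed = 1)
#' table(truth_clusters(w))
#' @export
simulate_well <- function(mix, n_droplets, model = amplitude_model(),
                          seed = NULL, well_id = "A01",
                          sample_id = "sample1", metadata = list()) {
  stopifnot(inherits(mix, "template_mix"), inherits(model, "amplitude_model"))
  n <- assert_count(n_droplets, "n_droplets", minimum = 1)
  with_rng_seed(seed, {
    wt   <- stats::rpois(n, mix$lambda_wt)
    hdr  <- stats::rpois(n, mix$lambda_hdr)
    nhej <- stats::rpois(n, mix$lambda_nhej)

    fam <- rep(model$baseline_fam, n)
    fam[wt > 0L | nhej > 0L] <- model$fam_ref_level
    fam[hdr > 0L] <- model$fam_hdr_level

    hex <- rep(model$baseline_hex, n)
    if (model$n_nhej_probes >= 2L) {
      # indel at one cut site leaves the other probe(s) intact with prob p,
      # per allele; the droplet retains partial HEX if any allele does
      retain <- stats::runif(n) <
        (1 - (1 - model$p_partial_retention)^nhej)
      hex[wt == 0L & nhej > 0L & retain] <- model$hex_partial_level
    }
    hex[wt > 0L] <- model$hex_wt_level

    if (model$rain_fraction > 0) {
      rainy <- stats::runif(n) < model$rain_fraction
      u <- stats::runif(n)
      fam[rainy] <- model$baseline_fam +
        u[rainy] * (fam[rainy] - model$baseline_fam)
      hex[rainy] <- model$baseline_hex +
        u[rainy] * (hex[rainy] - model$baseline_hex)
    }
    if (model$noise_sd_fam > 0)
      fam <- fam + stats::rnorm(n, 0, model$noise_sd_fam)
    if (model$noise_sd_hex > 0)
      hex <- hex + stats::rnorm(n, 0, model$noise_sd_hex)

    well_data(data.frame(ch1_amplitude = fam, ch2_amplitude = hex,
                         truth_wt = wt, truth_hdr = hdr, truth_nhej = nhej),
              well_id = well_id, sample_id = sample_id, metadata = metadata)
  })
}

## Synthetic control alleles --------------------------------------------

#' Edit specifications for synthetic control alleles
#'
#' Constructors for the edits used to build synthetic positive-control
#' alleles: a point substitution at the desired edit site (HDR control), or
#' a small deletion/insertion at the predicted cut site (NHEJ control;
#' 1-bp deletions and 1-bp or 4-bp insertions are all readily detected by
#' drop-off probes). All positions are 0-based; insertions are placed
#' immediately before position `pos`.
#'
#' @param pos 0-based position of the edit.
#' @param base Replacement base (substitution).
#' @param width Number of bases to delete (deletion; default 1).
#' @param insert Inserted sequence (insertion).
#' @return An object of class `edit_spec`.
#' @export
edit_substitution <- function(pos, base) {
  pos <- assert_count(pos, "pos")
  base <- check_dna(base, "base")
  if (nchar(base) != 1L) stop("base must be a single nucleotide")
  structure(list(type = "substitution", pos = pos, base = base),
            class = "edit_spec")
}

#' @rdname edit_substitution
#' @export
edit_deletion <- function(pos, width = 1) {
  structure(list(type = "deletion", pos = assert_count(pos, "pos"),
                 width = assert_count(width, "width", minimum = 1)),
            class = "edit_spec")
}

#' @rdname edit_substitution
#' @export
edit_insertion <- function(pos, insert) {
  structure(list(type = "insertion", pos = assert_count(pos, "pos"),
                 insert = check_dna(insert, "insert")),
            class = "edit_spec")
}

#' Build a synthetic control allele from a WT amplicon
#'
#' Applies an [edit_substitution()], [edit_deletion()] or [edit_insertion()]
#' to a wild-type amplicon sequence, producing the synthetic HDR- or
#' NHEJ-positive control allele used for assay validation and spike-ins.
#'
#' @param wt_amplicon WT amplicon sequence (character, A/C/G/T).
#' @param edit An `edit_spec`.
#' @return The edited sequence as a character string.
#' @examples
#' make_synthetic_allele("ACGTACGT", edit_substitution(3, "A"))  # "ACGAACGT"
#' make_synthetic_allele("ACGTACGT", edit_deletion(4))           # "ACGTCGT"
#' @export
make_synthetic_allele <- function(wt_amplicon, edit) {
  seq <- check_dna(wt_amplicon, "wt_amplicon")
  if (!inherits(edit, "edit_spec")) stop("edit must be an edit_spec")
  L <- nchar(seq)
  switch(edit$type,
    substitution = {
      if (edit$pos >= L) stop("substitution position outside the amplicon")
      paste0(substr(seq, 1, edit$pos), edit$base,
             substr(seq, edit$pos + 2, L))
    },
    deletion = {
      if (edit$pos + edit$width > L)
        stop("deleted range extends outside the amplicon")
      paste0(substr(seq, 1, edit$pos),
             substr(seq, edit$pos + edit$width + 1, L))
    },
    insertion = {
      if (edit$pos > L) stop("insertion position outside the amplicon")
      paste0(substr(seq, 1, edit$pos), edit$insert,
             substr(seq, edit$pos + 1, L))
    },
    stop("unknown edit type")
  )
}
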