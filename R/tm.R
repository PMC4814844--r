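# Unified nearest-neighbor thermodynamics (SantaLucia 1998): per-dimer
# stacking enthalpies (kcal/mol) and entropies (cal/mol/K) for a duplex
# read 5'->3' on one strand; complementary dimers share values.
.NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation with a terminal G.C or A.T pair
.INIT_DH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.INIT_DS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)
.GAS_R <- 1.9872  # cal/mol/K

# Effective monovalent cation concentration (mM): free divalent cations
# (beyond those chelated by dNTPs) are folded in via the square-root
# convention used by primer-design thermodynamic settings.
effective_monovalent_mM <- function(monovalent_mM, divalent_mM, dntp_mM) {
  monovalent_mM + 120 * sqrt(max(divalent_mM - dntp_mM, 0))
}

nn_sums <- function(seq) {
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  dimers <- paste0(bases[-length(bases)], bases[-1])
  list(dh = sum(.NN_DH[dimers]) + .INIT_DH[[bases[1]]] +
         .INIT_DH[[bases[length(bases)]]],
       ds = sum(.NN_DS[dimers]) + .INIT_DS[[bases[1]]] +
         .INIT_DS[[bases[length(bases)]]],
       n_stacks = length(dimers))
}

tm_from_sums <- function(dh, ds, n_bases, seq, monovalent_mM, divalent_mM,
                         dntp_mM, oligo_conc_nM) {
  ct <- oligo_conc_nM * 1e-9
  symmetric <- identical(seq, revcomp_chr(seq))
  if (symmetric) ds <- ds - 1.4      # self-complementary symmetry term
  x <- if (symmetric) 1 else 4       # CT divisor for duplex formation
  na_eff <- effective_monovalent_mM(monovalent_mM, divalent_mM,
                                    dntp_mM) / 1000
  ds_salt <- ds + 0.368 * (n_bases - 1) * log(na_eff)
  dh * 1000 / (ds_salt + .GAS_R * log(ct / x)) - 273.15
}

#' Nearest-neighbor duplex melting temperature
#'
#' Computes the duplex Tm of an oligonucleotide against its perfect
#' complement by summing SantaLucia-1998 unified nearest-neighbor stacking
#' enthalpies/entropies with duplex-initiation terms, applying the
#' SantaLucia entropy salt correction (`0.368 * (N-1) * ln[Na+]`), and the
#' two-state formula `Tm = dH / (dS + R ln(CT/x))`. Divalent cations in
#' excess of dNTPs are folded into an effective monovalent concentration
#' (`+120 * sqrt(divalent - dNTP)` mM). Defaults match common
#' probe-design thermodynamic settings: 50 mM monovalent, 3.0 mM divalent,
#' 0 mM dNTPs.
#'
#' @param seq Oligo sequence, 5' to 3', A/C/G/T only, length `>= 8`.
#' @param monovalent_mM Monovalent cation concentration (mM).
#' @param divalent_mM Divalent cation concentration (mM).
#' @param dntp_mM dNTP concentration (mM).
#' @param oligo_conc_nM Total oligo concentration (nM; default 50).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' melting_temperature("AGCGTACCGGTTAGCCATGC")
#' @export
melting_temperature <- function(seq, monovalent_mM = 50, divalent_mM = 3.0,
                                dntp_mM = 0, oligo_conc_nM = 50) {
  seq <- check_dna(seq, "seq", min_len = 8L)
  assert_scalar_number(monovalent_mM, "monovalent_mM", lower = 1e-6)
  assert_scalar_number(divalent_mM, "divalent_mM", lower = 0)
  assert_scalar_number(dntp_mM, "dntp_mM", lower = 0)
  assert_scalar_number(oligo_conc_nM, "oligo_conc_nM", lower = 1e-6)
  s <- nn_sums(seq)
  tm_from_sums(s$dh, s$ds, nchar(seq), seq, monovalent_mM, divalent_mM,
               dntp_mM, oligo_conc_nM)
}

#' Should a dark probe be added for this HDR probe?
#'
#' An HDR (gain) probe that differs from the wild-type sequence by very
#' little can cross-hybridize to WT alleles; a dark (non-extendible,
#' 3'-phosphorylated) oligo matching the WT sequence then blocks that
#' cross-reactivity. A dark probe is recommended when the probe differs
#' from WT over its footprint by at most one base AND its approximate Tm
#' against the WT sequence is within `tm_margin` degrees (inclusive) of
#' its matched Tm.
#'
#' The mismatched Tm is approximated by dropping nearest-neighbor stacks
#' that involve a mismatched position (no full mismatch tables), keeping
#' the same initiation and salt terms; this underestimates residual
#' stability but ranks cross-reactivity correctly for probe-design
#' purposes.
#'
#' @param hdr_probe_seq HDR probe sequence (5' to 3').
#' @param wt_local_seq WT sequence aligned over the probe footprint (same
#'   length).
#' @param tm_margin Tm closeness margin in degrees C (default 8;
#'   inclusive).
#' @param ... Salt/concentration settings passed to the Tm calculation.
#' @return A list with `recommended`, `mismatches`, `tm_matched`, `tm_wt`,
#'   `delta_tm`, `rationale`.
#' @export
dark_probe_recommended <- function(hdr_probe_seq, wt_local_seq,
                                   tm_margin = 8, ...) {
  probe <- check_dna(hdr_probe_seq, "hdr_probe_seq", min_len = 8L)
  wt <- check_dna(wt_local_seq, "wt_local_seq", min_len = 8L)
  if (nchar(probe) != nchar(wt))
    stop("probe and WT sequences must be aligned to equal length")
  assert_scalar_number(tm_margin, "tm_margin", lower = 0)

  pb <- strsplit(probe, "", fixed = TRUE)[[1]]
  wb <- strsplit(wt, "", fixed = TRUE)[[1]]
  match_pos <- pb == wb
  mismatches <- sum(!match_pos)

  tm_matched <- melting_temperature(probe, ...)

  # NN sum over stacks whose two positions both match the WT strand
  n <- length(pb)
  dimers <- paste0(pb[-n], pb[-1])
  keep <- match_pos[-n] & match_pos[-1]
  dh <- sum(.NN_DH[dimers[keep]]) + .INIT_DH[[pb[1]]] + .INIT_DH[[pb[n]]]
  ds <- sum(.NN_DS[dimers[keep]]) + .INIT_DS[[pb[1]]] + .INIT_DS[[pb[n]]]
  dots <- list(...)
  tm_wt <- tm_from_sums(dh, ds, n, probe,
                        monovalent_mM = dots$monovalent_mM %||% 50,
                        divalent_mM = dots$divalent_mM %||% 3.0,
                        dntp_mM = dots$dntp_mM %||% 0,
                        oligo_conc_nM = dots$oligo_conc_nM %||% 50)
  delta <- tm_matched - tm_wt
  recommended <- mismatches <= 1L && delta <= tm_margin
  list(recommended = recommended, mismatches = mismatches,
       tm_matched = tm_matched, tm_wt = tm_wt, delta_tm = delta,
       rationale = sprintf(
         "%d mismatch(es); Tm matched %.1f C vs WT-bound %.1f C (delta %.1f, margin %g): dark probe %s",
         mismatches, tm_matched, tm_wt, delta, tm_margin,
         if (recommended) "recommended" else "not needed"))
}
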