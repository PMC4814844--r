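# Independent nearest-neighbor Tm oracle: the same published unified duplex
# parameters, but coded from scratch as 4x4 lookup matrices filled via
# reverse-complement symmetry, with an explicit base-by-base loop. Used to
# cross-check melting_temperature() without sharing its code path.
tm_oracle <- function(seq, monovalent_mM = 50, divalent_mM = 3, dntp_mM = 0,
                      oligo_conc_nM = 50) {
  b <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  dH <- matrix(NA_real_, 4, 4, dimnames = list(b, b))
  dS <- matrix(NA_real_, 4, 4, dimnames = list(b, b))
  vals <- list(AA = c(-7.9, -22.2), AT = c(-7.2, -20.4),
               TA = c(-7.2, -21.3), CA = c(-8.5, -22.7),
               GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
               GA = c(-8.2, -22.2), CG = c(-10.6, -27.2),
               GC = c(-9.8, -24.4), GG = c(-8.0, -19.9))
  for (d in names(vals)) {
    x <- strsplit(d, "")[[1]]
    dH[x[1], x[2]] <- vals[[d]][1]
    dS[x[1], x[2]] <- vals[[d]][2]
    dH[comp[x[2]], comp[x[1]]] <- vals[[d]][1]
    dS[comp[x[2]], comp[x[1]]] <- vals[[d]][2]
  }
  s <- strsplit(toupper(seq), "")[[1]]
  H <- 0; S <- 0
  for (i in seq_len(length(s) - 1L)) {
    H <- H + dH[s[i], s[i + 1]]
    S <- S + dS[s[i], s[i + 1]]
  }
  for (end in c(s[1], s[length(s)])) {
    H <- H + if (end %in% c("G", "C")) 0.1 else 2.3
    S <- S + if (end %in% c("G", "C")) -2.8 else 4.1
  }
  selfcomp <- identical(paste(rev(unname(comp[s])), collapse = ""),
                        paste(s, collapse = ""))
  if (selfcomp) S <- S - 1.4
  na_M <- (monovalent_mM + 120 * sqrt(max(divalent_mM - dntp_mM, 0))) / 1000
  S <- S + 0.368 * (length(s) - 1L) * log(na_M)
  ct <- oligo_conc_nM * 1e-9
  H * 1000 / (S + 1.9872 * log(ct / if (selfcomp) 1 else 4)) - 273.15
}

random_dna <- function(n, len = 20) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}
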