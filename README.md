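# dropedit

Droplet digital PCR (ddPCR) quantification of genome-editing outcomes:
simultaneous measurement of homology-directed repair (HDR) and
nonhomologous end-joining (NHEJ) allele frequencies at an endogenous
locus.

## Who this is for

Anyone designing or analyzing a drop-off/gain-probe ddPCR editing assay:
a FAM reference probe counts all template copies, a FAM "gain" probe
binds only the precise HDR edit (raising those droplets to FAM++), and a
HEX "drop-off" probe over the nuclease cut site loses signal when an
NHEJ indel destroys its binding site. Droplets then fall into four
clusters — empty, NHEJ (FAM+ HEX−), WT+ (FAM+ HEX+) and HDR+ (FAM++) —
and Poisson partition statistics on droplet subsets recover each class's
concentration down to roughly one event in 1,000 genome copies.

## The statistics at the core

With droplets loaded at mean rate λ copies/droplet, the negative
fraction estimates e^(−λ), so λ̂ = −ln(N_neg/N_total). Because clusters
overlap in content (a WT+NHEJ droplet looks like a WT droplet), each
class uses a droplet subset in which it alone drives positivity:

| class | N_neg | N_total |
|---|---|---|
| NHEJ | N_empty | N_empty + N_NHEJ |
| HDR | N_empty + N_NHEJ + N_WT+ | all four clusters |
| WT | N_empty + N_NHEJ | N_empty + N_NHEJ + N_WT+ |

Allelic frequencies are the three rates normalized to 100%. 95% CIs use
the delta-method SE √((N_total−N_neg)/(N_total·N_neg)); the limit of
detection of a dilution series is the smallest spike fraction whose rate
CI clears the WT-only background CI (with all larger fractions also
detected). The package also simulates droplet data with known ground
truth, fits gates from control wells, validates probe/primer layouts
(SantaLucia-1998 nearest-neighbor melting temperatures included), and
summarizes multi-condition editing studies (SEM, t-tests, five-tier
ranking, R²).

## Worked example

Simulate a well whose template pool is 27,000 WT copies plus synthetic
HDR and NHEJ alleles at 5% each (30,000 total copies in 15,000
droplets), gate it, and quantify:

```r
library(dropedit)

mix <- spike_in_mix(wt_copies = 27000, hdr_fraction = 0.05,
                    nhej_fraction = 0.05, n_droplets = 15000)
well  <- simulate_well(mix, n_droplets = 15000, seed = 7)
gated <- assign_clusters(well, default_gates())
gated$counts
#> Cluster counts: empty 2058, NHEJ 204, WT+ 11238, HDR+ 1500 (anomalous 0; total 15000)

quantify_classes(gated$counts)
#> ddPCR quantification (15000 droplets, 0.85 nL/droplet):
#>  class  lambda          se  ci_low ci_high copies concentration frequency
#>     wt 1.78600 0.019183654 1.74900  1.8240  26797        2102.0      89.9
#>    hdr 0.10540 0.002721655 0.10000  0.1107   1580         124.0       5.3
#>   nhej 0.09451 0.006619819 0.08154  0.1075   1418         111.2       4.8
```

Both 5% spikes are recovered (5.3% and 4.8%) within sampling error; the
`copies` column says the well carried ≈1,580 HDR and ≈1,418 NHEJ of
≈29,800 total copies. The same estimator applied to a real edited sample
whose gated counts give 79 HDR, 677 NHEJ and 11,971 WT copies reports
0.6% HDR and 5.3% NHEJ:

```r
round(frequencies_from_copies(79, 677, 11971), 1)
#>  hdr nhej   wt
#>  0.6  5.3 94.1
```

Detection limits, by replicated 2-fold dilution ladders (5% → 0.02%
spike in a 30,000-copy background, two merged wells per point, four
WT-only wells, 95% CI non-overlap):

```r
run_lod_experiment("nhej", seed = 1)
#> LoD experiment (NHEJ): median LoD 0.078125% over 5 replicates
#>   per-replicate LoD (%): 0.0781, 0.0391, 0.0781, 0.0781, 0.0391
```

A thin CLI over the same functions (subcommands `simulate`, `gate`,
`quantify`, `lod`, `study`, `design-check`, `pipeline`) is installed at
`system.file("cli", "dropedit.R", package = "dropedit")`; see
`run_pipeline()` for the YAML configuration it consumes.

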