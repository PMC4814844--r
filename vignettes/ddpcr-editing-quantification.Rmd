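---
title: "Quantifying HDR and NHEJ editing outcomes from droplet digital PCR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying HDR and NHEJ editing outcomes from droplet digital PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropedit)
```

## The assay and its model

Genome editing with a sequence-specific nuclease activates two competing
repair pathways at the target locus: homology-directed repair (HDR), which
copies a donor template and installs the intended point edit, and
nonhomologous end-joining (NHEJ), which leaves a heterogeneous pool of small
insertions and deletions at the cut site. A practical editing experiment
needs both allele classes measured at once, at frequencies well below 1%.

A two-channel droplet digital PCR (ddPCR) design does this with three
probes inside a single amplicon:

* a **FAM reference probe** away from the cut site binds every allele
  class and counts total template;
* a **FAM HDR (gain) probe** over the edit site binds only precisely
  edited alleles, lifting those droplets to a higher FAM amplitude
  (FAM++);
* one or more **HEX NHEJ (drop-off) probes** with wild-type sequence over
  the cut site(s) lose their binding site when an indel forms, so NHEJ
  alleles show FAM without HEX.

After partitioning a genomic DNA sample into droplets, end-point PCR, and
two-channel reading, the droplets fall into four clusters:

| cluster | signal | content |
|---|---|---|
| empty | FAM-, HEX- | no template |
| NHEJ | FAM+, HEX- (or partial HEX) | NHEJ alleles only |
| WT+ | FAM+, HEX+ | any WT allele (possibly with NHEJ) |
| HDR+ | FAM++ | any HDR allele (possibly with WT/NHEJ) |

Template loading is modelled as independent Poisson counts per droplet for
each class, with rates $\lambda_{WT}, \lambda_{HDR}, \lambda_{NHEJ}$
(mean copies/droplet). Everything downstream — estimation, confidence
intervals, detection limits — rests on that partitioning model.

## Subset Poisson estimators

The standard digital-PCR estimator for a single species is
$\hat\lambda = -\ln(N_{neg}/N_{total})$. Here the clusters overlap in
content (a WT+NHEJ droplet is indistinguishable from a pure WT droplet),
so each class is estimated on a droplet **subset** within which it alone
determines positivity:

* **NHEJ**: $N_{neg} = N_{empty}$, $N_{total} = N_{empty} + N_{NHEJ}$.
  Conditioning on "no WT and no HDR template" leaves droplets whose NHEJ
  occupancy is still Poisson($\lambda_{NHEJ}$), by independence.
* **HDR**: $N_{neg} = N_{empty} + N_{NHEJ} + N_{WT+}$, $N_{total}$ = all
  four clusters, because *any* droplet with an HDR copy is FAM++.
* **WT**: $N_{neg} = N_{empty} + N_{NHEJ}$,
  $N_{total} = N_{empty} + N_{NHEJ} + N_{WT+}$ (HDR+ droplets are
  excluded since their WT content is masked).

`quantify_classes()` implements exactly these subsets;
`tests/testthat/test-acceptance.R` verifies them against a direct
evaluation of the formulas over every cluster composition with up to 50
droplets, and against simulation truth at $10^6$ droplets across rates
0.01–2. Allelic frequencies are the rates normalized to 100%:

```{r}
q <- quantify_classes(cluster_counts(n_empty = 6421, n_nhej = 296,
                                     n_wt_plus = 8204, n_hdr_plus = 79))
round(q$frequency, 1)
```

**Confidence intervals.** The 95% CI on each rate uses the delta-method
standard error of the log negative fraction,
$SE = \sqrt{(N_{total}-N_{neg})/(N_{total}\,N_{neg})}$, as a normal
interval truncated at zero. This is the conventional large-count interval
for digital PCR; at very small positive-droplet counts (fewer than ~4) it
is conservative — its lower bound only clears zero once four or more
positive droplets are seen — which directly shapes the detection limit
below.

**Copies and concentration.** "Copies" are reported as
$\hat\lambda \times$ (all analyzed droplets) and concentration as
$\hat\lambda / V_{droplet}$. The droplet volume defaults to 0.85 nL and is
configurable; frequencies are volume-invariant, absolute concentrations
are not. A conversion of 300 genome copies per ng of human DNA (so 100 ng
≈ 30,000 copies) is likewise a configurable convention.

## The droplet simulator

`simulate_well()` generates droplets with known ground truth, which is
what makes the estimators testable end to end. Choices worth knowing:

* Occupancy per class is drawn Poisson, in the fixed order WT, HDR, NHEJ,
  from one seeded generator per well, so a seed fully reproduces a well.
* Amplitudes saturate: a co-occupied droplet takes the class maximum per
  channel, not the sum (end-point PCR plateaus). Defaults place baseline
  at 1000, FAM+ at 5000, FAM++ at 9000, HEX+ at 5000, and partial HEX at
  3000 a.u., with Gaussian noise of SD 300 per channel — levels chosen so
  midpoint gates are unambiguous at this noise.
* **Rain** (droplets of intermediate amplitude) is modelled as a
  configurable fraction of droplets displaced uniformly from their
  cluster level toward baseline, the same displacement on both channels.
  Real rain has richer structure; the model is enough to stress gating.
* **Multi-probe assays**: with two NHEJ probes (dual nickase designs), an
  indel usually destroys only the probe over its own cut, so NHEJ-only
  droplets retain partial HEX. Each NHEJ allele retains a secondary probe
  site with probability `p_partial_retention` (default 0.5, active only
  when `n_nhej_probes >= 2`); `hex_low` must then sit between the partial
  and full HEX levels.
* A typical well is simulated at 15,000 accepted droplets — a convention
  for this instrument class, not a published value.

What the simulator does **not** emulate: droplet volume variability,
PCR-efficiency differences between alleles, probe cross-hybridization,
or systematic inter-well drift. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to every
artifact of real chemistry; the misgating rate in the dilution module is
the one knob provided for modelling real false calls.

## Gating

Gates are rectangular thresholds (`fam_low`, `fam_high`, `hex_low`):
published two-dimensional droplet plots show axis-aligned clusters, and
threshold gates are reproducible where hand-drawn polygons are not. A
droplet is HDR+ if FAM ≥ `fam_high` — any HDR-positive droplet is gated
HDR+ regardless of HEX — else NHEJ/WT+/empty by the low thresholds.
FAM−/HEX+ droplets match no cluster definition; they are counted as
anomalous, excluded from quantification, and warned about.

`fit_gates_from_controls()` estimates thresholds from a negative
(unmodified) and a positive (known-edit) control well using the exact
1-D two-group least-squares split per channel, with thresholds at the
midpoints of the group means. The fit refuses to return gates when the
two groups are separated by less than four within-group standard
deviations (a single-cluster channel); configured gates always override
fitting. On simulated controls at default noise the fitted gates
misclassify fewer than 0.1% of truth-labelled droplets.

## Detection limits by CI non-overlap

`run_dilution_series()` rebuilds the validation experiment: a 2-fold
ladder of synthetic-allele spike fractions (default 5% down to ~0.02%)
in a constant 30,000-copy WT background, two merged 15,000-droplet wells
per point, and four merged WT-only wells as background. A point is
**detected** when the lower 95% bound of its class rate exceeds the upper
95% bound of the WT-only background rate (comparison on the rate scale);
the limit of detection is the smallest fraction detected with all larger
fractions also detected, so an isolated false positive cannot define it.

With a clean background the delta-method interval makes detection
equivalent to observing at least four spike-cluster droplets. At the
0.078% rung the expected NHEJ-cluster count is ~6, so a single ladder's
LoD is decided by a handful of droplets and varies between adjacent rungs
from seed to seed. `run_lod_experiment()` therefore runs several
replicate ladders (default 5) under one master seed and reports the
median LoD, which is the package's headline sensitivity summary:
typically ~0.08% for NHEJ and ~0.02% for HDR under the default
conditions — consistent with a drop-off/gain probe assay detecting one
event in 1,000 genomes. HDR is the more sensitive channel because its
estimator uses all droplets and every HDR-positive droplet counts,
whereas NHEJ-positive droplets that also carry WT template are absorbed
into the WT+ cluster (a factor $e^{-\lambda_{WT}}$ of NHEJ droplets is
usable).

## Assay design rules

`validate_layout()` checks a layout (0-based, half-open coordinates;
cut sites are inter-base indices) against the rules a quantitative
editing assay needs:

1. cut sites mid-amplicon, 75–125 bp from each inner primer boundary;
2. at least one primer outside the donor span, so unintegrated donor
   cannot amplify and masquerade as edited genome;
3. the reference probe clear of a 30 bp exclusion window around every cut
   site (configurable — "distant from the cut site" has no published
   number) and clear of the donor span;
4. every NHEJ probe strictly spanning a cut site;
5. the HDR probe covering the edit position.

`predict_cut_sites()` places CRISPR cuts 3 bp upstream of the PAM (the
mirror-symmetric convention on the minus strand, where the published rule
is silent) and TALEN/FokI-dCas9 cuts at the floored midpoint of the
spacer between binding intervals.

Melting temperatures use the SantaLucia-1998 unified nearest-neighbor
parameters with the entropy salt correction
$\Delta S \mathrel{+}= 0.368\,(N-1)\ln[\mathrm{Na}^+]$, divalent cations
folded into an effective monovalent concentration
($+120\sqrt{[\mathrm{Mg}^{2+}]-[\mathrm{dNTP}]}$ mM), and defaults of
50 mM monovalent / 3.0 mM divalent / 0 mM dNTPs / 50 nM oligo. The test
suite checks the implementation against an independently coded parameter
table to 0.5 °C. `dark_probe_recommended()` flags HDR probes that differ
from wild type by at most one base *and* whose approximate WT-bound Tm is
within 8 °C (inclusive, configurable) of their matched Tm; the mismatch
Tm drops nearest-neighbor stacks touching a mismatched position rather
than using full mismatch tables — an approximation that ranks
cross-reactivity correctly without claiming thermodynamic accuracy.

## Study summaries

`summarize_condition()` reports mean ± SEM over replicates (the reference
design is n = 6: two transfections in triplicate) and a two-tailed,
equal-variance two-sample Student's t-test between the HDR and NHEJ
replicate sets — the classical reading of "Student's t-test"; whether the
original analysis paired replicates is unstated, and the pooled test is
the conservative default. Identical constant replicate sets return
p = 1 by convention. `tier_classify()` implements the five-tier
condition ranking (tier 1: >0.1% HDR and HDR ≥ NHEJ … tier 5: ≤0.1% HDR
and NHEJ > 2×HDR) with boundary ties assigned to the better tier and the
2-fold band ignoring the 0.1% threshold, exactly as the rule is stated.
`correlation_r2()` includes zero-valued observations, returning the
squared Pearson correlation.

## Numerical choices and degenerate inputs

* Saturated wells (no empty droplets) and saturated subsets raise errors
  rather than returning infinities.
* All-empty wells return zero rates with frequencies flagged `NA`.
* Background subtraction (`subtract_background()`) clamps at zero:
  a negative corrected frequency means "undetectable", not a negative
  rate.
* Percentages are kept at full precision internally; display rounds to
  one decimal, matching field reporting.
* Derived seeds (per-well, per-replicate) are drawn from a master seed
  inside a state-preserving RNG scope, so seeded calls never perturb the
  caller's random stream.

## Problem sizes used by the test suite

Tests aim at the smallest sizes that make their statistical assertions
sharp: estimator-consistency checks use single $10^6$-droplet wells over
rates 0.01–2; the exhaustive estimator-vs-formula comparison enumerates
all ~293,000 cluster compositions up to 50 droplets; dilution ladders use
the default experimental geometry (15,000 droplets/well, two wells per
point); the LoD-monotonicity check uses 12 replicate ladders of reduced
wells. These are the package's chosen verification sizes, stated here so
they can be scaled up by anyone wanting tighter Monte-Carlo bounds.

## Limitations

* The Poisson model assumes monodisperse droplets and perfect
  partitioning; real volume CVs bias absolute concentrations (not
  frequencies).
* Rectangular gates cannot separate heavy rain from true intermediate
  clusters; no density-based clustering is attempted.
* The mismatch-Tm approximation underestimates duplex stability with
  internal mismatches; it is a screening heuristic.
* Copies are referenced to analyzed droplets; mapping to a 20 µl
  reaction volume is left to the concentration output and the configured
  droplet volume.
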