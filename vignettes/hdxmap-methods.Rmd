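---
title: "Differential HDX-MS interaction mapping with hdxmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential HDX-MS interaction mapping with hdxmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxmap)
```

## The measurement and the statistic

Backbone amide hydrogens exchange with solvent deuterium at rates that
report on structure: an amide buried in an interface or hydrogen-bonded in
a helix exchanges orders of magnitude more slowly than one in a disordered
loop. In a differential HDX-MS experiment a protein is labeled in D2O
either free or in complex with a partner, quenched after a series of
labeling times, digested with pepsin, and the centroid mass shift of every
peptide is measured. Regions that become protected upon binding take up
less deuterium in the bound state; the difference localizes the interface.

`hdxmap` analyzes such experiments at the peptide level:

* **%HDX** of a peptide is its deuteron count #D (centroid shift divided by
  the 2H-1H mass difference, 1.006277 Da) over the maximum number of
  backbone amides theoretically able to exchange, times 100. The maximum
  excludes the peptide's first residue (its amide deuterium back-exchanges
  essentially instantly) and every proline, which has no amide hydrogen.
  `skip_first = 2` is available because some workflows also exclude
  position 2; the convention is recorded in every output header.
* **Delta-HDX** of a peptide is the difference of replicate-mean %HDX
  between the two states, computed at each labeling time, taking the
  signed value whose magnitude is largest over the times. Ties go to the
  earliest timepoint, where the measurement is least back-exchange-biased.
* a peptide is **called significant** when three criteria hold at once:
  |Delta-HDX| strictly above 10%, an unpaired two-tailed t-test on the
  replicate deuteron counts with p strictly below 0.05, and an absolute
  mean mass difference of at least 0.5 Da (inclusive). The %HDX criterion
  is strict and the Da criterion inclusive, following the more precise of
  the two printed formulations of the rule. The effect-size criteria make
  the call robust against the multiplicity of peptides and timepoints, for
  which no formal correction is applied; the number of tests is recorded
  in the results metadata.

The t-test is Student's pooled-variance test by default (`var_equal =
FALSE` gives Welch); with three replicates per state there is little power
to distinguish the two. When every replicate is identical (a noiseless
simulation), the p-value is defined as 1 for equal means and 0 otherwise.

### Which replicates enter the t-test

The test is computed on the replicate deuteron counts at the Delta-HDX
(maximal-difference) timepoint, matching the max-over-times logic of the
statistic itself (`t_test_scope = "any"` instead accepts the smallest
p-value over timepoints). Selecting the maximal timepoint and testing
there inflates the nominal level under the null — with four timepoints the
selected test is the one most likely to look extreme — so the pipeline's
null calibration is assessed under a single-timepoint design, where the
selection is trivial and the test attains its nominal 5% level exactly.
Under the full four-timepoint design the two effect-size gates (10%,
0.5 Da) dominate the operating characteristics, and the test suite checks
that a 1000-peptide null experiment at realistic noise yields zero
significant calls. The t-test is scale-invariant, so testing #D, %HDX or
raw Da values per peptide gives identical p-values; the suite asserts
this.

## From peptides to residues

Residue-level maps are built by averaging: residue r receives the mean
Delta-HDX of every peptide whose exchange-contributing span covers r (the
span excludes the skipped N-terminal position(s) and prolines, the same
convention as the %HDX denominator). All peptides contribute by default —
this reproduces the smooth per-residue traces used for visual inspection —
with `contributing = "significant_only"` as an option. Residues covered by
no peptide are `NA` with coverage 0, never silently zero, and residues
whose covering peptides disagree in sign are flagged (`mixed_sign`)
because a signed mean there conflates protection with deprotection.

Averaging over covering peptides is a smoothing operation: a true step
edge at an interface boundary becomes a ramp roughly one peptide length
wide, and the value directly over the boundary is close to half the
region's interior plateau. Two consequences drive the region-extraction
design:

* `half_plateau_threshold()` estimates the plateau robustly (97th
  percentile of |track values|, floored at the 10% calling threshold) and
  cuts at half of it, which places run boundaries near the true interface
  edge regardless of how strong the protection is. A fixed absolute cutoff
  sits at an arbitrary fraction of the plateau and biases boundaries
  inward or outward depending on signal strength.
* a proline (or any uncovered residue) inside an interface cannot report
  exchange and would split one physical region into two. `extract_regions`
  therefore absorbs isolated uncovered residues flanked by same-sign
  above-threshold neighbours (`bridge_gaps = 1` by default); the bridge
  never crosses a sign change and region means are computed over covered
  residues only. Regions shorter than `min_len = 2` are dropped as
  single-residue speckle.

On simulated 563-residue experiments with a strong interface planted at
residues 88–114 (protection factor x100, the default peptide map and
noise; see below) this recovers the planted region with a Jaccard overlap
of at least 0.8 in essentially every run; with a fixed 10% cutoff and no
bridging the same data recover it in only about three runs of four. The
test suite runs 20 such seeded experiments and requires at least 18
recoveries.

For structure coloring, `write_bfactor_pdb` writes each residue's track
value into the temperature-factor column (61–66) of the chosen chain,
clipped to the field's printable range [-99.99, 999.99]; atoms of
uncovered residues get B = 0.00 *and* occupancy 0.00 as an explicit "no
data" sentinel a viewer can select on. Every other byte of the file is
preserved, so the output stays faithful to the input model. A numbering
`offset` bridges construct numbering (a fragment crystallized from residue
77 onward) and full-length positions.

## The synthetic experiment generator

Because no deposited uptake data accompany the analysis this package
implements, every stage is validated against simulated experiments with
known ground truth. The generator works in the EX2 limit, where the
observed exchange rate of residue i is its intrinsic rate over its
protection factor and the deuterium fraction after time t is

    d_i(t) = f_D2O * (1 - exp(-k_int,i * t / P_i))

A peptide's noiseless centroid shift is 1.006277 Da times the sum of
d_i over its exchangeable residues, times a back-exchange retention
factor; replicates add independent Gaussian noise on the shift.

Defaults, with the reasoning behind each:

| parameter | default | why |
|---|---|---|
| `d2o_fraction` | 0.8 | the labeling buffer contains 80% D2O, which caps %HDX at 80 |
| `timepoints` | 3, 30, 300, 3000 s | the labeling series of the experiment modeled |
| `k_int` | log-uniform over 1e-2..1e2 s^-1 | spans rates resolvable within the 3–3000 s window; a constant-rate option exists for closed-form checks. Residue-specific intrinsic-rate prediction is out of scope |
| `n_replicates` | 3 | the minimum giving a usable t-test, typical of HDX practice |
| `noise_sd` | 0.1 Da | typical centroid repeatability; deliberately small against the 0.5 Da significance floor |
| `back_exchange` | 1.0 | no correction is modeled by default; configurable in (0, 1] |
| peptide map | `mean_len` 10, `step` 4, `len_jitter` 2 | pepsin-like overlapping coverage, median length ~10, every residue covered several times |

Interface regions are planted as `(start, end, factor)` triples with
`pf_bound = pf_free * factor`; protection (factor > 1) produces an uptake
decrease, deprotection (factor < 1) an increase and requires an elevated
free-state protection factor, since protection factors cannot drop below
1. The set of residues where the states differ is stored as the ground
truth against which recovery is scored.

What the generator deliberately does **not** emulate: EX1/bimodal
exchange, isotope envelopes (inputs are centroids), pH- and
temperature-dependent intrinsic rates, sequence-dependent back-exchange,
carry-over or chromatographic artifacts, and peptide-dependent noise.
Passing the simulation suite therefore demonstrates that the statistics,
bookkeeping and region logic are correct under the stated kinetic model —
not that any particular real dataset satisfies that model.

## Companion computations

**Crosslink candidate matching.** Proteins are digested in silico with
trypsin specificity (cleave after K/R, not before P, up to 2 missed
cleavages by default — a crosslinked lysine necessarily blocks cleavage).
Candidates are all peptide pairs in which both partners retain a
crosslinkable amine (lysine side chains, the protein N-terminus; a
C-terminal lysine only at the protein C-terminus, since a crosslinked
lysine could not have been cleaved). The candidate mass adds the BS3
linker (138.06808 Da); an observation is confirmed when an observed
neutral mass matches within a ppm tolerance *and* a partner sits
4.025108 Da higher — the signature of the 1:1 light/heavy d0/d4 reagent
mix. The heavy-form delta is taken as 4 x (2H-1H); hydrolyzed dead-end
links (+156.07864 Da) are supported behind a flag, off by default.
Matching is on neutral monoisotopic masses; charge deconvolution and
MS/MS-level verification are upstream concerns. The matcher is tested for
exact agreement with a brute-force loop over every (observed, candidate)
pair.

**Stoichiometry from SEC-MALS.** Sequence masses use average residue
masses (MALS measures average molar mass); molar extinction coefficients
at 280 nm follow the Gill–von Hippel composition rule (5500 per Trp, 1490
per Tyr, 125 per cystine, reduced by default). `infer_stoichiometry`
enumerates all copy-number vectors up to `max_copies = 4` per component
(enough for the trimer-scale species the method targets, and desk-scale:
at most 5^6 vectors), ranks by absolute mass residual, and breaks ties by
fewer total copies, then lexicographically for determinism. Small-integer
combinations are promiscuous — several vectors often land within a few kDa
of the measurement — so an optional UV term,
`uv_weight * |eps_pred - eps_obs| / eps_obs`, lets an absorbance-based
extinction coefficient arbitrate, which is exactly how a 99 kDa measured
mass is pinned to a 1:1:1 complex predicted at 102 kDa rather than to
some two-component coincidence.

## Numerical and interface conventions

* Coordinates are 1-based inclusive everywhere; only the PDB writer
  applies an offset.
* TSV/CSV outputs round %HDX to 2 decimals, Da to 4, masses to 5 —
  stable diffs without losing measurement precision — and begin with a
  commented metadata header (package version, seed, configuration)
  sufficient to reproduce the file; readers skip `#` lines. Re-running any
  stage with identical inputs, configuration and seed reproduces outputs
  byte for byte.
* %HDX above the labeling ceiling (possible under noise) is retained, not
  clipped; uptake values more negative than 3 x the expected noise are
  flagged on input.
* Excluded peptides (missing timepoints, fewer than two replicates, no
  exchangeable amides) always produce warnings and are counted in the fit
  object.

## Problem sizes used by the test suite

The suite simulates at sizes chosen to exercise every code path while
keeping a full run in the tens of seconds: the null-calibration
experiment uses ~1000 peptides at one timepoint; region recovery runs 20
seeded 563-residue experiments at four timepoints; crosslink fixtures stay
under 1000 candidates so the brute-force oracle remains exact and fast.
The acceptance script (`scripts/acceptance.R`) regenerates its three
benchmark quantities from scratch at the same scales.

## Known limitations

* Peptide-mean projection caps boundary resolution at roughly half a
  peptide length; sub-peptide localization would require overlap
  deconvolution, which is out of scope.
* The signed per-residue mean conflates protection and deprotection where
  both kinds of peptides overlap; such residues are flagged rather than
  resolved.
* No false-discovery control across peptides; the three-criterion rule is
  an effect-size gate, not an error-rate guarantee.
* The crosslink module stops at candidate-level mass evidence; it does
  not score fragment spectra or estimate an FDR from decoy databases.
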