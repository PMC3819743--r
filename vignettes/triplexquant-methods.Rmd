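---
title: "Methods: triplex dimethyl labeling quantification, nMD-score localization, and motif scanning"
author: "triplexquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplex dimethyl labeling quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triplexquant)
```

## The experimental model

`triplexquant` implements the computational half of a triplex
stable-isotope dimethyl labeling phosphoproteomics experiment. Peptide
primary amines (the N-terminal alpha-amine and every lysine epsilon-amine)
are converted to dimethylamines by reductive amination. Three isotopic
reagent combinations give three mass variants of every peptide:

* **light** (CH2O / NaBH3CN): +C2H4 per amine, +28.031300 Da
  (nominally +28 Da);
* **intermediate** (CD2O / NaBH3CN): +C2D4, +32.056407 Da (+32 Da);
* **heavy** (13CD2O / NaBD3CN): +13C2D6 − H2, +36.075670 Da (+36 Da).

Adjacent channels therefore differ by a nominal 4 Da *per labeled amine*.
The three samples are mixed and measured together; relative quantification
compares the integrated extracted-ion-chromatogram (XIC) areas of the
three precursor variants. Five induction timepoints (0 h, 10 min, 30 min,
1 h, 2 h) are covered by two triplexes, with 30 min measured in both as a
bridge between the "early" and "late" groups (`experiment_design()`).

The package states only nominal +28/+32/+36 values for reporting; all mass
matching uses the exact monoisotopic per-site deltas above, because at
10 ppm tolerance the 0.006 Da difference between the two adjacent spacings
(4.025107 vs 4.019263 Da) is already informative at tryptic peptide
masses.

## Stage by stage

### In silico digestion and mass arithmetic

Digestion cleaves after K/R, suppresses cleavage before proline (the usual
Mascot-style convention), and allows up to two missed cleavages by
default. Peptide masses are the sum of residue monoisotopic masses plus
water, fixed carbamidomethyl (+57.021464 Da) on cysteine, +79.966331 Da
(HPO3) per phosphosite, and the channel shift times the label-site count.
With `max_missed = 0` the emitted peptides concatenate exactly back to the
protein — a property the test suite asserts.

### Triplet matching

`match_triplets()` reassembles the three channel features of a peptide
from observed masses alone: a candidate triple must show mass spacings of
`n × 4.025107` and `n × 4.019263` Da for some label-site count `n`
(ppm error measured against the heavier mass of each pair, default
tolerance 10 ppm) and co-elute within `rt_window`. Assignment is greedy by
ascending summed pairwise ppm error, ties broken by retention-time spread
and then feature ids, so the result is deterministic; each feature joins
at most one triplet and leftovers are reported as orphans. Greedy rather
than globally optimal assignment was chosen because it is deterministic
and, at realistic feature densities, indistinguishable from the exhaustive
O(n³) search — the tests verify exact equivalence on every instance with
up to 50 features.

### Ratio computation and LOWESS normalization

Each triplet yields the two triplex ratios (intermediate/light,
heavy/intermediate) in MA form: `M = log2(a1/a2)`,
`A = (log2 a1 + log2 a2)/2`. Systematic intensity-dependent bias — the
reason a single global rescaling ("slope = 1" on a ratio scatter plot) is
not sufficient — is removed by robust locally weighted regression of `M`
on `A` (`stats::lowess`, span 0.4, 3 robustness iterations, defaults
standard for MA-trend normalization); `M_normalized = M − fit(A)`. The
premise is the usual one: most peptides do not change between the
compared samples, so the local trend of `M` against `A` estimates bias,
not biology. The correction is a per-record shift that depends on `A`
only, so ratio rankings at a given abundance are untouched. Groups with
fewer than 10 records are refused rather than fitted.

### Protein roll-up and regulation calls

The protein log2 ratio is the arithmetic mean of its member peptide
normalized ratios, with the standard deviation as dispersion and a
two-sided one-sample t-test against zero for proteins with at least two
peptides (single-peptide proteins report `p = NA`). P-values are
Benjamini–Hochberg adjusted within each ratio comparison; a protein is
flagged up/down when `|mean log2 ratio| >= log2(1.5)` and adjusted
`p <= 0.05`. The 1.5-fold default and BH adjustment are package choices
where the workflow convention is unstated.

### Phosphosite localization and FLR control

For each phosphopeptide spectrum the Mascot delta score
`MD = top − runner-up` and its normalized form `nMD = MD / top` summarize
localization confidence on `[0, 1]`; a tie carries no evidence
(`nMD = 0`). Two operating modes exist:

* **fixed**: discard PSMs with `nMD < 0.36` (the literature cutoff giving
  about 1% false localization rate); the boundary value is retained.
* **calibrated**: given a calibration set with known correctness labels,
  `calibrate_flr_threshold()` returns the smallest threshold whose
  retained set has an incorrect fraction at or below the target FLR
  (default 1%). The threshold is monotone in the target, and held-out
  simulations verify that the empirical FLR of an independent PSM set
  stays within three binomial standard errors of the target.

The calibration labels come from simulation: the package does not
re-implement the decoy-amino-acid construction used to derive site-level
FLR from real spectra, so on real data the fixed-threshold mode is the
operational one, with calibration available whenever labeled or decoy-
derived correctness calls exist.

### Kinase motif and promoter PWM scanning

Accepted unique sites are expanded to 13-residue windows (half-width 6,
`-`-padded at termini) and matched against a consensus-motif library
(CK2, CK1, PKA, GSK3 and the proline-directed p38 MAPK / JNK / CDK class
by default; the library is an editable two-column text file). Matching is
per-position set membership; padding satisfies only wildcards. This is a
deliberate stand-in for network-context kinase prediction services:
counts are *motif-compatible* sites, not kinase activity calls.

Promoter analysis parses JASPAR-format count matrices, builds log-odds
PWMs (`p = (count + 0.25) / (colsum + 1)` against a uniform background),
scans both strands of each promoter (windows containing `N` skipped,
coordinates always on the forward strand) and reports, per factor, the
fraction of genes with at least one hit at a relative score of at least
0.80 — the quantity behind a "present in more than 80% of the selected
genes" style criterion. The shipped SP1/MYC/NFKB matrices are
consensus-derived synthetic stand-ins (see the file name
`synthetic_tf_pfms.jaspar`); real JASPAR text drops in unchanged.

## The synthetic-data generator

Every stage is testable without any download because
`simulate_experiment()` produces the full observable layer with known
truth:

* **XIC areas**: per-peptide log2 baseline ~ N(20, 2); planted per-protein
  log2 fold changes accumulate across the four consecutive timepoint
  ratios; multiplicative log-normal noise (default sd 0.15 in log2);
  a smooth sigmoid bias in mean log intensity (amplitude 0.5 log2 units,
  width 1.5), scaled per channel, injected so LOWESS has a real trend to
  remove. No functional form for real instrument bias is claimed — a
  centered sigmoid is simply a smooth, bounded, monotone curve.
* **Masses**: exact labeled monoisotopic mass plus a *bounded* ppm error
  (truncated Gaussian, sd 1 ppm, hard cut 3 ppm), reflecting a
  well-calibrated high-resolution instrument; 5% of channel features are
  dropped to exercise orphan handling.
* **PSM scores**: top score ~ Gamma(shape 5, rate 1/6); gap to the
  runner-up exponential with mean 10 (correct localization) versus 3
  (incorrect), capped at the top score; 10% of assignments are placed on
  a wrong S/T/Y. These parameters were fixed once so that the 1%-FLR
  calibrated nMD cutoff lands in the 0.3–0.7 region where published nMD
  thresholds sit; they are calibration knobs of the generator, not claims
  about any instrument.
* **Phosphosites**: residue classes drawn at the canonical mammalian
  pS/pT/pY proportions 87.5/11.5/0.8 (renormalized to sum to one).

Truth tables (site list, regulation profiles, PSM correctness) are
written separately from the observable tables and no pipeline stage reads
them. What passing tests show is therefore internal correctness and
statistical calibration *under this generative model* — i.i.d. residues,
single-protein peptides, no chromatographic co-elution structure, no
charge-state or isotope-envelope ambiguity — not performance on real
LC-MS data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally (digest offsets, truth
  sites, motif hit starts) and 1-based in reported residue positions.
* `lowess` fits are interpolated back to the original points
  (`approx`, ties averaged, range-clamped); a constant `M` input
  normalizes to exactly zero.
* Zero-dispersion protein groups cannot be t-tested and report `p = NA`
  rather than a fabricated zero.
* `calibrate_flr_threshold()` scans candidate cutoffs ascending from 0,
  so an all-correct calibration set yields threshold 0, and an
  unattainable target returns threshold 1 with a warning flag rather than
  silently passing everything.
* Greedy matching tie-breaks (error, then rt spread, then ids) make the
  whole pipeline bit-for-bit reproducible under a fixed seed; the run
  report records the seed and every effective parameter.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the stochastic checks are statistically
meaningful: 20,000 simulated PSMs (10,000 calibration / 10,000 held out)
for FLR control, 5,000 peptides for normalization checks, 500–600 planted
triplets for recovery, instances of up to 50 features for exact oracle
equivalence, and 100 random 500-nt promoters for scanner cross-checks.
Dataset-scale headline counts of any real study (thousands of proteins,
hundreds of phosphoproteins) are functions of a particular sample and
instrument and are deliberately not simulation targets.

## Known limitations

* PSM generation is simulated; no search engine scoring, spectra, or FDR
  machinery is included (the generator's `decoy` column is a placeholder
  for pipelines that carry decoy PSMs).
* One site per PSM: multiply phosphorylated peptides are emitted as
  separate single-site PSMs.
* No retention-time alignment across runs and no charge-state grouping in
  triplet matching.
* Kinase motif counts are consensus-compatibility counts; network-context
  kinase assignment and GO/pathway annotation are out of scope.
* Promoter scanning uses caller-supplied (here synthetic) promoter
  sequences; genome retrieval and conservation filtering are out of
  scope.
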