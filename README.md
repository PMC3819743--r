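# triplexquant

Quantitative phosphoproteomics for **triplex stable-isotope dimethyl
labeling** experiments, written for analysts who need the full
computational chain behind a light/intermediate/heavy dimethyl design:
from in silico tryptic digestion and labeled mass arithmetic, through
channel-triplet assembly and LOWESS ratio normalization, to
phosphosite localization at a controlled false localization rate and
downstream motif analysis — plus a synthetic-data generator so every
stage is testable with known ground truth.

## What it computes

Dimethyl labeling converts each peptide primary amine (N-terminus and
lysine ε-amines) into a dimethylamine. The three isotopic reagent
combinations add +28.031300, +32.056407 and +36.075670 Da per amine
(nominally +28/+32/+36; adjacent channels differ by 4 Da per labeled
amine). The core quantities:

* **Triplet matching** — features of one peptide in the three channels
  are recognized from observed masses alone: spacings of
  *n*·4.025107 and *n*·4.019263 Da (for *n* labeled amines) within a ppm
  tolerance, greedily assigned by ascending mass error.
* **Ratios and normalization** — per triplet,
  `M = log2(a_num/a_den)`, `A = (log2 a1 + log2 a2)/2`; a robust
  locally weighted regression of `M` on `A` removes the
  intensity-dependent bias, so unregulated peptides center at `M = 0`
  (the MA equivalent of forcing the ratio-scatter slope to 1).
* **Protein roll-up** — protein log2 ratio = mean of member peptide
  normalized ratios, one-sample t-test against 0, Benjamini–Hochberg
  adjustment, up/down flags at a 1.5-fold / 0.05 default.
* **Localization** — normalized Mascot delta score
  `nMD = (top − runner-up)/top`; PSMs below the threshold are discarded.
  The threshold is either the literature value 0.36 (fixed mode) or
  calibrated as the smallest cutoff holding a target false localization
  rate (default 1%) on labeled calibration PSMs.
* **Motif analysis** — 13-residue flanking windows of accepted sites
  scanned against kinase consensus motifs (CK2, CK1, PKA, GSK3,
  proline-directed p38/JNK/CDK); promoters scanned with JASPAR-style
  PWMs on both strands, reporting the fraction of genes with at least
  one hit (the "present in ≥80% of genes" criterion).

## Worked example

```r
library(triplexquant)

proteome <- generate_proteome(60, c(200, 400), seed = 1)
sites    <- plant_phosphosites(proteome, 120, seed = 2)
profiles <- plant_regulation(proteome, frac_regulated = 0.25, seed = 3)
sim <- simulate_experiment(proteome, sites, profiles, seed = 4)

res <- match_triplets(sim$features[sim$features$experiment == 1, ])
nrow(res$triplets); nrow(res$orphans)
#> [1] 915
#> [1] 289

ratios <- lowess_normalize(compute_ratios(res$triplets, sim$features))
pq <- flag_regulated(rollup_proteins(ratios))
head(subset(pq, regulated_flag != "none"), 4)
#>    protein_id         ratio_name n_peptides mean_log2_ratio   p_adjusted regulated_flag
#> 61   SYNP0001 intermediate/light         10       0.8513554 6.539017e-06             up
#> 7    SYNP0007 heavy/intermediate         26      -0.8063009 2.140082e-13           down
#> 67   SYNP0007 intermediate/light         26       0.7179551 1.840748e-13             up
#> 17   SYNP0017 heavy/intermediate         13       0.7867396 6.395350e-08             up
```

915 of the simulated channel trios are reassembled into quantifiable
triplets (features missing a channel partner become orphans, never
silently dropped). After normalization, proteins whose planted log2
fold exceeds the 1.5-fold threshold at adjusted p ≤ 0.05 are flagged;
`SYNP0007`, for example, rises then falls across the triplex, giving an
up call on intermediate/light and a down call on heavy/intermediate.

Localization with a calibrated threshold:

```r
cal <- simulate_psm_scores(5000, seed = 5)
sc  <- nmd_score(cal$top_score, cal$runner_up_score)
thr <- calibrate_flr_threshold(sc$nmd, cal$is_correct, target_flr = 0.01)
thr$threshold; thr$confidence
#> [1] 0.5570569
#> [1] 0.9901873

loc <- filter_localized(sim$psms, thr$threshold)
site_inventory(loc)
#> $n_unique_sites
#> [1] 31
#> $n_proteins
#> [1] 26
#> $residue_fractions
#>          S          T          Y
#> 0.93548387 0.06451613 0.00000000
```

The calibrated cutoff retains assignments with about 99% localization
confidence; the inventory counts unique (protein, position) sites and
their pS/pT/pY split.

`run_pipeline(pipeline_config(...))` chains all stages (simulate →
match → quantify → localize → kinase motifs → promoter PWM scan) and
writes every stage table plus a JSON run report;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

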