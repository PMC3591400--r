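---
title: "Quantitative analysis of GeLC-SILAC experiments with gelsilac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative analysis of GeLC-SILAC experiments with gelsilac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelsilac)
```

## The experimental design this package models

In a SILAC comparison, one cell population grows on normal ("light")
lysine and arginine and the other on 13C6-labeled ("heavy") versions, so
every tryptic peptide from the two conditions differs by a fixed
+6.020129 Da per K/R and both forms are quantified in the same MS run as
a light/heavy intensity ratio. In the GeLC variant the pooled 1:1 protein
mixture is separated by SDS-PAGE first; the lane is sliced top-down into
numbered gel bands, each band is digested and run separately, and a
protein's peptides therefore appear in the (often adjacent) bands that
match its molecular weight. Two membrane fractions (F1, F2), enriched
differently, give two partially overlapping proteomes.

`gelsilac` implements everything downstream of peptide identification and
peptide-level quantification: its inputs are rows of *peptide evidence*
(fraction, band, sequence, charge, accession(s), identification
probability, light and heavy intensities), and its outputs are
protein-level log2 L/H ratios, p-values, FDR estimates, band-resolved
proteoform ratios, and category summaries. Search engines and the
probability models that score identifications are upstream tools; their
output probabilities are consumed as given.

## The analysis model

For one fraction the pipeline is:

1. **Peptide filter.** Records with identification probability below
   0.70 are removed (the threshold value is retained: `>= 0.70` stays).
2. **Protein grouping.** All evidence for an accession is pooled across
   bands. An accession whose peptide-sequence set is a strict subset of
   another's is absorbed into that group (parsimony). A peptide sequence
   still attributable to more than one group is flagged non-unique: it
   supports identification but is excluded from the unique-peptide count
   and from quantification. The group probability is the maximum
   contributing peptide probability (an externally computed protein
   probability can be supplied instead); groups below 0.95 are dropped.
   Groups with at least 3 distinct unique peptide sequences — charge and
   modification variants of one sequence count once — form the
   *unambiguous* tier; 1–2-peptide groups are *low evidence*.
3. **Quantification.** Peptide log2(L/H) ratios are averaged per band,
   and the protein ratio is the **unweighted mean of the per-band
   means**. Averaging band-level ratios (rather than pooling peptides)
   is the primary mode because each band is an independent LC-MS
   measurement of the protein; a pooled mode is available. A peptide
   observed with no heavy signal carries the one-channel sentinel
   (`+Inf`, printed "+"): a protein whose peptides are all one-channel
   is reported as "+" — over-expressed beyond any measurable ratio —
   while mixed groups report the finite mean and the sentinel count.
4. **Normalization and significance.** Unregulated proteins should
   scatter around the log2 of the true mixing proportion, which is only
   nominally 1:1. Subtracting the per-fraction median of the finite
   unambiguous-tier ratios centers that bulk at 0. A scale `sigma` is
   fitted to the normalized ratios and each protein gets a two-sided
   Z-statistic p-value, `p = 2 * (1 - pnorm(|ratio| / sigma))`.
   One-channel proteins are significant by convention (p printed
   "0.000") but never enter the median or the scale fit. Proteins with
   `p < 0.05` in the unambiguous tier are reported, over-expressed
   first, ranked by ratio magnitude with sentinels on top.
5. **FDR and merging.** With a decoy-augmented database, the per-tier
   FDR is `100 * decoys / targets`. The two fractions' unambiguous
   identifications are merged into a union table with per-fraction
   presence, and each fraction's report carries the companion fraction's
   ratio and p-value ("ni." when not identified there).

Band positions also carry molecular-weight information, which
`proteoform_quant()` uses to separate co-accessioned molecular forms: a
protein's occupied bands are split into contiguous runs (a gap of more
than one empty band starts a new run; runs whose MW windows come within
2 kDa are re-merged), each run is quantified on its own with an MW
estimate from the log-linear lane calibration, and the whole-protein
pooled ratio is reported alongside. The motivating case is a lysosomal
protease whose unprocessed precursor (~37 kDa) is up-regulated while the
proteolytically matured enzyme (~27 kDa) is not: pooling the two forms
dilutes the signal into an intermediate, non-significant ratio, whereas
the band-resolved estimates recover both.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `peptide_p_min` | 0.70 | minimum peptide identification probability |
| `protein_p_min` | 0.95 | minimum protein (group) probability |
| `min_unique_peptides` | 3 | unambiguous-tier threshold |
| `alpha` | 0.05 | significance level on the raw p-value |
| `estimator` | `"SD"` | null scale: sample SD or Gaussian-consistent MAD |
| `reject_outliers` | `FALSE` | drop peptide ratios > 3 MAD from the band median |
| `ratio_mode` | `"band_mean"` | mean-of-band-means vs pooled peptide mean |

Threshold boundaries are inclusive (`>=`), so a probability of exactly
0.95 is retained. No multiple-testing correction is applied to the
primary call — the design thresholds the raw p at `alpha` — but a
Benjamini–Hochberg column is emitted for orientation.

The scale estimator deserves a word: with a small regulated minority the
sample SD is mildly inflated by the very proteins one wants to detect,
which makes calls slightly conservative; the MAD option resists that
inflation. SD is the default because the null calibration property
(5% calls on null data at `alpha = 0.05`) is exact for it and because
regulated fractions in this design are small.

## The synthetic-data generator

Real GeLC-SILAC raw data are large and live in external repositories, so
the package ships a generator whose defaults encode the conditions the
analysis is built for, and every statistical guarantee in the test suite
is stated under those conditions:

* **Mostly-null proteome.** `frac_regulated = 0.05`; regulated effect
  magnitudes uniform on 0.8–4.5 log2 units (the span differential
  tables in this kind of experiment actually report), random sign.
* **Peptide counts.** Poisson with mean 6 quantified peptides per
  protein (minimum 1); protein MWs uniform on 10–250 kDa.
* **Ratio noise.** Normal on the log2 scale, `noise_sd = 0.3` per
  peptide. Protein-ratio histograms in such experiments are Gaussian;
  the peptide-level law is not observable from published tables, and a
  lognormal intensity model is the standard assumption.
* **Mixing offset.** A global log2 shift (default 0 in the generator;
  the calibration checks use 0.2–0.5) stands in for imperfect 1:1
  pooling and must be removed by median normalization.
* **Band placement.** Each peptide lands in the band whose MW window
  contains its protein, spilling into an adjacent band with probability
  0.15 — diffuse migration over a couple of neighboring slices is what
  gel data show.
* **One-channel dropout.** Ratios at or beyond ±5 log2 units lose the
  minor channel; 2^5 = 32-fold is where the weaker SILAC partner
  typically falls below detection.
* **Identification scores.** Targets draw from Beta(20, 2); decoy
  evidence draws from Beta(2, 8) with a 3% contamination from the
  target component, representing the rare chance match to a
  high-quality spectrum. Decoy proteins carry 1 + Poisson(0.4)
  peptides: decoy hits are single-spectrum flukes, not consistent
  multi-peptide identifications. These choices make the decoy FDR
  concentrate in the 1–2-peptide tier with no 3-peptide decoys at
  realistic database sizes, the qualitative behavior observed in
  practice.
* **Proteoform scenario.** Forms at 37.3 and 27.5 kDa with true log2
  ratios +1.5 and 0, 12 and 18 peptide observations spread over 2 and 3
  bands, and 60% of peptide sequences shared between forms. The
  background proteome used when testing form significance has
  peptide noise 0.85, chosen so the protein-ratio spread is ~0.4 log2
  units — the spread implied by a significance cutoff near |log2| = 0.8
  at alpha 0.05, which is where published tables of this design put it.

What the generator does **not** emulate: spectrum-level structure
(XICs, isotope envelopes, interference), intensity-dependent noise,
correlated peptide behavior within a protein (mis-cleavage families,
shared elution), retention-time effects, and protein-abundance-dependent
identification rates. Passing tests therefore demonstrate that the
*statistical machinery* is correct under its stated model, not that the
model captures every pathology of real gel data.

## Numerical and design choices

* One-channel sentinels are `+Inf`/`-Inf` internally, so "is finite"
  cleanly separates measurable ratios from sentinels everywhere;
  reports render them "+"/"-".
* Digestion follows the Keil rule (no cleavage before proline), I/L are
  distinct, and B/Z/X/U are rejected with the offending character
  named. Peptide length bounds (6–40) are applied where digests feed
  simulations, not in the digestion primitive itself.
* Decoy shuffling is a seeded Fisher–Yates permutation of the whole
  chain; a K/R-preserving mode (same tryptic skeleton) is available via
  `keep_kr = TRUE`.
* The MAD outlier rule (off by default) replaces manual ratio curation
  with a reproducible criterion: drop peptides more than 3
  Gaussian-consistent MADs from their band median, only in bands with
  at least 3 finite peptides, and never when the MAD is zero.
* Proteoform clustering breaks at gaps of more than one empty band;
  one missing band is tolerated because a protein routinely skips a
  slice within its smear.
* `fit_scale()` refuses degenerate input (fewer than 3 finite ratios,
  or zero spread) rather than returning an unusable sigma.
* Reproducibility: every stochastic function takes a mandatory seed and
  restores the caller's RNG state; the pipeline writes a manifest
  (config, counts per stage, fitted sigmas) and re-running with the
  same inputs reproduces reports byte for byte.

## Scale of the shipped checks

The test suite and the acceptance script run the generator at 300–2000
proteins per experiment (about 2000–12000 peptide rows), sizes at which
the binomial/normal-theory bounds they assert are sharp while a full run
stays under a minute on a laptop core. The distribution-calibration
check uses 2000 null proteins; parameter recovery uses 1000; the decoy
study uses 1000 targets plus 1000 decoys.

## Known limitations

* Protein probabilities default to a max-peptide proxy; a proper
  protein-level probability model is upstream scope, and externally
  computed probabilities can be passed through.
* Peptides are unweighted within a band; if peptide signal intensities
  carry usable precision information, that information is ignored.
* The two fractions are analyzed independently; no shared-protein
  shrinkage or meta-analysis across fractions is attempted beyond the
  side-by-side report columns.
* Band MW calibration is log-linear between two anchors; real gels
  deviate at the extremes, so MW estimates for very large or very small
  proteins are indicative only.

## A short worked example

```{r example, eval = FALSE}
lane <- gel_lane("F1")
truth <- generate_truth(500, frac_regulated = 0.1, seed = 1)
evidence <- simulate_evidence(truth, lane, seed = 2)
result <- run_pipeline(list(F1 = evidence))
head(result$significant$F1)
result$sigma$F1
```
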