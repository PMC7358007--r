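---
title: "Characterizing a transchromosomic trisomy model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a transchromosomic trisomy model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdosage)
```

## The problem

A transchromosomic (Tc) mouse carries a human chromosome arm as an extra,
freely segregating element on an artificial-chromosome vector. Validating
such a model is a computational exercise with four parts: map deletions on
the transferred arm from read depth; verify that human genes are expressed
at the dosage expected for one extra copy; establish that the chromosome is
retained in essentially all cells (no mosaicism); and define the behavioral
statistics against which cognitive phenotypes are scored. `tcdosage`
implements each part and, because the underlying sequencing data of any
particular animal are not shipped with the package, pairs them with a
synthetic-data generator that plants ground truth for every stage.

## Deletion mapping on a single-copy chromosome

The transchromosome is present in one copy, so a true deletion has
essentially zero coverage; the only depth signal inside a deletion is
mismapping background. The caller therefore works on a binned profile
(default 10 kb bins) normalized by the median of positive-depth bins
(`normalize_depth()`, so covered bins sit at 1.0) and reports maximal runs
of bins with normalized depth below a threshold:

* `threshold = 0.25` — far above the ~2% background expected in a true
  deletion yet far below the single-copy level, so the call is insensitive
  to the exact background rate;
* `min_bins = 3` — suppresses single-bin dropouts (mappability holes);
* `merge_gap_bins = 1` — one spuriously high bin does not split a deletion.

A call's `n_bins` is its full bin span including bridged gaps, and the
span test applies to that merged run. Calls are bin-aligned: boundaries are
accurate to one bin, which is the resolution limit of the input. A gene is
counted as deleted if it overlaps a call by at least 1 bp (any-overlap
convention — conservative, and stated rather than guessed, because a
published gene count rarely states its convention). An exactly abutting
gene is not deleted. Coordinates are 1-based inclusive in memory, exactly
as printed in genome browsers; BED and bedGraph adapters convert to 0-based
half-open on write and back on read, and both directions are tested.

Arm lengths are reported as `end − start` bp (the difference of the two
printed boundary coordinates) and as Mb rounded half-up, matching how such
spans are quoted.

## Dosage accounting

Expression is quantified as FPKM, `count × 10⁹ / (length × library size)`,
and averaged over replicates within genotype before any ratio is formed
(with two replicates per genotype, per-ratio noise would otherwise dominate;
the per-replicate route remains available by calling `fpkm_table()` without
averaging). For a human gene *h* with mouse ortholog *m*:

* `R_h = F_h(Tc) / F_m(Eu)`, `R_m = F_m(Tc) / F_m(Eu)`,
  `R_tot = (F_h + F_m)(Tc) / F_m(Eu)`, so `R_tot = R_h + R_m` is an exact
  identity (tested to 1e-12).
* Pairs enter the analysis only if the euploid ortholog has mean FPKM ≥ 1
  (inclusive). This filter *is* the guard against unstable denominators:
  ratios for unfiltered genes are an error, never an `Inf` or `NaN`, and no
  pseudocounts are used.
* Dosage bands are `<1.3` (low), `1.3–1.7` (expected for a single extra
  copy), `>1.7` (high); ortholog bands are `<0.8`, `80–120%`, `>1.2`. The
  outer inequalities are strict as printed; the middle bands are closed
  because the printed ranges name their endpoints. KRTAP-family genes are
  excluded from pair analysis (they are silent in brain in both species).
* Expression tiers use strict cutoffs: off ≤ 0.5 < medium ≤ 5 < high FPKM.
* Genome-wide trans-effects are threshold counts among host genes with
  euploid FPKM ≥ 1: down if `Tc/Eu < 0.8`, up if `> 1.2`, ratios exactly at
  a threshold counted neither way. These are deliberately not significance
  tests — no dispersion model or multiple-testing correction is applied,
  because the quantity of interest is the published count itself.

In pipeline reports the dosage-band occupancies are computed over *intact*
pairs: a pair whose human gene lies in a called deletion is structurally
disomic (`R_h = 0`, `R_tot ≈ 1`) and would otherwise be misread as
biological low-dosage. The all-pair summary is reported alongside.

## Retention and mosaicism

Retention per tissue is `n_positive / n_cells` over (typically 200) scored
cells with a Wilson score interval. Wilson rather than Wald because the
data live at p̂ → 1 where the Wald interval collapses and overshoots; the
Wilson interval keeps 93–97% empirical coverage at p = 0.95, n = 200 (tested
over 2000 replicates). Pooling sums counts before estimating. The
mosaicism screen is a one-sided exact binomial test of p < 0.9 per tissue at
α = 0.05 — exploratory plumbing, since the non-mosaicism claim in this kind
of study is descriptive (a per-tissue minimum, here read as: every tissue's
retention estimate stays high), not a formal test.

## Behavioral statistics

The probe-trial target zone of a circular water maze is the largest circle
inscribed in the platform quadrant. Tangency to both bounding radii puts
its centre at (r, r) with radius r, and internal tangency to the tank wall
gives `r√2 + r = R`, hence `r = R(√2 − 1)` and an area fraction of
`(√2 − 1)² = 3 − 2√2 ≈ 0.1716` — the 17% chance level, independent of tank
size. The analytic value is cross-checked by Monte-Carlo disc integration
in the tests and the acceptance script. The open-field centre zone is the
square ratio `(21.6/37)² ≈ 34%`.

Retained memory is computed per animal — each animal's day-1 fraction of
time in the old target zone is its own 100% — then averaged per day, so the
statistic is invariant to multiplying an animal's fractions by any positive
constant. A zero day-1 baseline is an error by construction (and the
generator resamples baselines away from zero). Transmission of the
transchromosome is summarized as a proportion with Wilson interval and a
two-sided exact binomial test against the Mendelian 50%. The worked
husbandry numbers use 43 positives of 90 pups: a printed rate of 48% of 90
implies 43.2 animals, and 43/90 = 47.8% is the nearest attainable count.

## The synthetic-data generator

The generator's defaults are the study conditions the package is built
around, fixed once:

| parameter | default | rationale |
|---|---|---|
| span | 13,021,348–46,691,226 bp (~33.7 Mb) | the characterized arm |
| genes | 213 PCG + 487 non-PCG, 49 KRTAP | the arm's annotation census |
| planted deletions | 4 intervals, ~29% of span | the reference deletion load |
| `ortholog_fraction` | 160/213 | PCGs with host orthologs |
| `dosage_log_mean`, `dosage_log_sd` | log 1.5, 0.36 | log-normal `R_tot`: median 1.5; σ = 0.36 puts ~35/29/36% in the <1.3 / 1.3–1.7 / >1.7 bands (closed form, not fitted) |
| `trans_down_frac`, `trans_up_frac` | 712/13976, 1191/13976 | observed genome-wide dysregulation fractions |
| `n_host_genes` | 4000 | desk-scale stand-in for the ~14k expressed host genes; fractions unchanged |
| `depth_mean`, `depth_noise`, `bin_size` | 100 reads/bin, 0.05, 10 kb | negative-binomial depth; deletions get Poisson background at 2% of `depth_mean` |
| `nb_dispersion` | 0.01 | replicate-to-replicate count dispersion of inbred littermates; at this level threshold-crossing noise stays small relative to the planted trans-effect fractions |
| `retention_p`, `cells_per_tissue`, `n_tissues` | 0.96, 200, 8 | per-cell detection scoring |
| `n_replicates` | 2 | expression replicates per genotype |

Counts are negative-binomial around expected counts derived from planted
FPKM targets (`dispersion = 0` gives deterministic rounded counts, used by
the zero-noise recovery tests). For each pair, `R_tot` is drawn log-normal
and split into `R_m` (near 1) and `R_h = R_tot − R_m`; when the drawn
`R_tot` falls below `R_m` the ortholog absorbs the difference, so the
planted total ratio is always realized and `R_h` is never negative. Human
genes in deleted regions and all KRTAP genes emit zero counts. Orthologs
are assigned to non-KRTAP protein-coding genes only: the pair analysis is a
PCG analysis, and almost no non-coding genes have orthologs in this setting.
Depth bins count as inside a deletion when their midpoint is, so bin-aligned
planted deletions are recovered with exact boundaries at zero noise.

All randomness derives from one seed with fixed per-stage offsets, so a
single stage can be re-run reproducibly and identical configurations give
byte-identical outputs (tested).

What the generator does *not* emulate: real mappability structure and GC
bias in depth (deletion background is homogeneous Poisson), correlated
expression between neighbouring genes, tissue-specific expression,
overdispersion heterogeneity across genes, segregation-distorted
transmission, or tracking noise in behavioral data beyond bounded uniform
jitter. Passing the recovery tests therefore demonstrates the correctness
of the estimators under the stated model, not their robustness to artefacts
of any particular sequencing pipeline.

## Problem sizes and interfaces

The shipped tests run the generator at full annotation scale (700 genes,
~3400 depth bins) for the pipeline checks, 2000 gene pairs for dosage-class
recovery, 2000 replicates for interval coverage, 10⁶ points for Monte-Carlo
geometry, and ≤ 50-bin random profiles (several hundred) for caller-oracle
equivalence — sizes at which every property is tight yet the suite stays
fast. The package's interface is its R functions; `run_pipeline()` binds
the stages, takes one configuration object carrying the seed, writes the
report bundle (JSON plus TSV/BED/bedGraph tables) when given an output
directory, and tags any stage failure with the stage name. A shell
subcommand wrapper was deliberately not added: the audience works in R, and
`scripts/acceptance.R` shows the one-command reproduction path.

## Known limitations

* Deletion boundaries are bin-resolution; sub-bin breakpoints are not
  refined.
* The dosage analysis assumes a shared transcript length per ortholog pair
  when planting ratios; real pairs differ in length, which cancels in
  ratios of the same gene but not in cross-gene comparisons of absolute
  FPKM.
* `count_dysregulated()` is a descriptive threshold count; with few
  replicates and high dispersion it will count noise crossings, which is
  faithful to the statistic it reproduces but should not be read as
  differential expression.
* The mosaicism screen tests each tissue marginally; it does not model
  between-tissue heterogeneity.
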