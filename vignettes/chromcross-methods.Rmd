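---
title: "Methods: classifying chromatin cross-talk at ZCWPW1 binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying chromatin cross-talk at ZCWPW1 binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcross)
```

## The scientific question

During mouse meiosis, PRDM9 deposits H3K4me3/H3K36me3 at recombination
hotspots and the reader ZCWPW1 binds these marks. The analysis this package
implements asks what happens to two other chromatin features at ZCWPW1
binding sites when *Zcwpw1* is knocked out: H3K9 acetylation (H3K9ac
ChIP-seq) and chromatin accessibility (ATAC-seq). Each ZCWPW1 site is
classified as

* **marked** (overlaps a WT H3K9ac peak by ≥ 1 bp) and then **H1** (mark
  lost in the knockout) or **H2** (mark retained);
* **open** (covers ≥ 20 % of some WT ATAC peak) and then **A1**
  (accessibility lost) or **A2** (retained);
* a **promoter** site when it touches a strand-aware TSS window.

The headline quantities are the group fractions (H1/marked, A1/open), the
joint-loss fraction (A1 sites that are also H1) and the promoter share of
each group. Hotspot-class sites are expected to populate H1/A1 and
promoter-class sites H2/A2, because promoter acetylation and accessibility
do not depend on ZCWPW1.

## Peak calling model

Real pipelines call peaks with MACS2; this package uses a transparent
windowed equivalent with the same statistical logic, so every step is
testable:

1. A `window` (default 200 bp) slides by `step` (50 bp) along each
   chromosome; the window count is the summed per-bp coverage.
2. The background expectation λ per window is genome-wide mean coverage ×
   window, or — for the ATAC configuration — the maximum of that and a
   *local* λ estimated from ± 10 kb flanks (window excluded). The floor at
   the genome-wide value prevents depleted neighbourhoods from inflating
   significance.
3. The p-value is the upper Poisson tail P(X ≥ count | λ). Fractional
   counts (tracks need not be integer-valued) test exceedance of
   ⌈count⌉, so a zero count gives p = 1 exactly.
4. Significance is a raw p threshold or a Benjamini–Hochberg q threshold
   over all scanned windows genome-wide, mirroring the `-p`/`-q`
   distinction of the original analyses (`-p 0.001` for ZCWPW1, `-q 0.05`
   for H3K9ac, `-q 0.01` for ATAC and CUT&Tag).
5. Significant windows separated by ≤ `merge_gap` (100 bp) merge into one
   peak. The peak's **fold enrichment** is the maximum constituent window
   count divided by that window's λ; since the original fold-enrichment
   definition (summit vs region mean) is not specified anywhere, the
   max-window convention is used and recorded here. Peaks must *strictly*
   exceed the retention threshold ("larger than 3/4/10" is read as a
   strict inequality): FE > 3 for ZCWPW1, > 4 for ATAC, > 10 for CUT&Tag.

The fold-enrichment filter is what suppresses false positives under the
permissive raw-p ZCWPW1 configuration: a window barely reaching p < 0.001
at a typical λ has FE ≈ 2 and is discarded.

### Calibration

`test-acceptance.R` and `scripts/acceptance.R` verify on 20 seeded
pure-background 2-Mb genomes that the fraction of windows flagged at BH
q < 0.05 stays below 5 %, and that 1-kb sites planted at 5× background are
recovered with ≥ 95 % recall under the ATAC preset.

## Signal tracks and matrices

Normalized signal is fold change of treatment coverage over a background
expectation. The denominator is **floored** at the pseudocount
(`max(control, pseudocount)`) rather than incremented: a track equal to its
control is then exactly 1.0 and a doubled track exactly 2.0, while empty
control regions stay bounded. The same floor convention is used for the
knockout mean in the loss ratios (pseudocount 0.01), which keeps the
"at least 2-fold" rule exactly inclusive: WT mean 2.0 over KO mean 1.0 is a
loss.

Heatmap matrices average the signal in 40-bp bins across peak center
± 2 kb (100 bins). The center is the interval midpoint
`floor((start0 + end0)/2)` — no caller-specific summit is needed. Bins
clipped by a chromosome edge average only their covered bases; bins fully
outside are 0; bedGraph gaps read as signal 0, which is correct for
fold-change tracks that tile the genome. Heatmap row order is descending by
a per-site statistic: either the mean of per-sample row means ("average
signal in all samples" — defined here as the mean of row means, since the
alternative order of averaging is equivalent for equal bin counts and the
original is ambiguous) or the median of one named sample. Ties break by
genomic position, making the permutation deterministic.

## Classification rules and their one open interpretation

The openness rule measures the 20 % on the *ATAC peak's* length (the
quoted object); the alternative normalization by the ZCWPW1 peak's length
is available via `frac_of = "site"`. A site qualifies if **any single**
partner peak satisfies the thresholds — overlaps are never summed across
partners.

The accessibility-loss rule is stated explicitly in the source analyses
(WT ATAC peak present and WT signal ≥ 2-fold over knockout). The
H3K9ac-loss rule is not; this package applies the symmetric composite rule
— retained only if a knockout H3K9ac peak still overlaps the site **and**
the WT/KO mean-signal ratio stays below 2 — with each criterion
independently toggleable (`use_peaks`, `use_ratio`). This symmetry is an
interpretation, flagged as such.

Promoters default to TSS −2000/+500 bp, strand-aware, a conventional
choice since no window is defined in the source; it is configurable
everywhere it is used. Percentages in reports are recomputed from counts
and rounded half-up to the printed precision (whole percents for group
fractions, one decimal for promoter fractions); counts are always reported
alongside.

## What the simulator emulates — and what it does not

`simulate_experiment()` builds a 3 × 2-Mb genome with 240 non-overlapping
600-bp sites: 200 hotspot-class and 40 promoter-class (TSS at their
centers, plus 100 background TSS). Coverage is drawn per 10-bp cell as
Poisson(rate) and expanded, so window counts at the caller's 200/50-bp
grid are exactly Poisson — the simulator deliberately matches the caller's
background model so that calibration tests measure the statistics, not a
model mismatch. The background is 0.05 reads/bp (λ = 10 per 200-bp
window); WT enrichments are ZCWPW1 10× (5× at promoter-class sites, which
are genuinely weaker), H3K9ac 8×, ATAC 8×, DMC1 10× at hotspots only.
Genotype effects scale the enrichment with the antibody background as a
floor: the *Zcwpw1* knockout zeroes ZCWPW1 enrichment and multiplies
H3K9ac/ATAC enrichment by 0.2 at the designated losing sites; *Prdm9*
knockout removes all hotspot enrichment; *Spo11* knockout only removes
DMC1.

Loss assignments are planted as exact rounded counts over the eligible
sets, so the configured fractions (0.74 of marked sites lose H3K9ac, 0.67
of open sites lose ATAC — the study's printed group fractions) are ground
truth rather than a sampling expectation; end-to-end recovery then tests
the pipeline, not binomial noise. Because promoter-class sites never lose
their marks, the loss fraction can only be realized if hotspot sites make
up a large enough share of the eligible sets; the defaults (85 % of
hotspot sites marked, 45 % open) satisfy this and make the promoter share
of group H2 emerge near the published ~73 %. Each coverage track draws
from its own deterministically derived child seed, so adding an assay
never perturbs another track's values.

Not emulated: read-level artifacts (duplicates, mappability, GC),
fragment-size structure, replicate variance beyond Poisson, the
whole-testis cell-mixture dilution that lowers the real marked fraction to
45 %, and sequence composition. Passing recovery tests therefore
demonstrates the correctness of the statistical logic at realistic effect
sizes, not robustness to alignment-level artifacts.

## RIME filtering

A protein is a positive interactor in a replicate if the target pulldown
reaches −10·log10 P ≥ 20, ≥ 1 unique peptide and ≥ 5 spectral counts (all
inclusive, per replicate), and the protein is absent from every IgG
control of the same batch — any IgG identification excludes, with no score
threshold on the control, following the unqualified exclusion rule of the
source protocol. Three-replicate results are summarized as the seven Venn
region counts plus the union ("detected in at least one sample").

## Problem sizes and runtime choices

The default simulation (16 tracks × 6 Mb), peak calling on four tracks and
classification complete in well under a minute each on one CPU; the
calibration suites use 20 seeds × 2 Mb. These sizes were chosen as the
smallest at which the planted fractions are estimated to within a couple
of percentage points; everything scales linearly in genome size and track
count.

## Known limitations

* The caller is a window scanner: peak boundaries are window-quantized and
  can extend ~one window beyond a sharp signal edge; summits are window
  midpoints.
* Local λ is a flank mean, not MACS2's multi-scale maximum; peaks inside
  broad enriched domains are therefore slightly easier to call here.
* `classification_report` enforces partition identities and will refuse
  inconsistent counts rather than repair them.
* Real-data group counts from the deposited sequencing archives are out of
  scope; the printed count pairs are used as direct inputs where the
  percentages are recomputed.

## A worked run

```{r, eval = FALSE}
res <- run_pipeline(sim_config(seed = 42))
res$report
res$evaluation$accuracy
```
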