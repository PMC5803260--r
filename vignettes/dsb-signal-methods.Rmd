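---
title: "Quantifying chromatin signal around induced double-strand breaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin signal around induced double-strand breaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscape)
```

## The analysis problem

Restriction-enzyme DSB-induction systems (AsiSI in DIvA cells) create
double-strand breaks at sequence-specified positions, so that protein
recruitment and RNA:DNA-hybrid (R-loop) dynamics around breaks can be
quantified genome-wide from ChIP-seq and DRIP-seq coverage. Only a subset
of the annotated recognition sites is cleaved in cells ("cut" sites); the
remainder ("uncut") serve as matched internal controls. breakscape
implements the quantification layer of such studies:

* windowed signal statistics centered on break sites (`window_count`,
  `quantify_sites`), with read-depth normalization per million reads;
* an unpaired Mann-Whitney U comparison of cut versus uncut site
  populations (`compare_cut_uncut`) and a paired signed-rank comparison of
  conditions at the same sites (`compare_conditions_paired`);
* stratification of sites into transcription-level classes
  (`stratify_by_transcription`), binned heatmap matrices
  (`heatmap_matrix`), averaged site-centered profiles (`average_profile`)
  and metagene profiles with scaled gene bodies (`metagene_profile`);
* the qPCR assay quantifications used alongside sequencing: resection
  ssDNA% from differential restriction digestion, repair kinetics
  (percent of sites still broken), translocation frequency by
  delta-delta-Ct with two control regions, and DRIP-qPCR percent input;
* a synthetic-data module that generates genomes, break annotations,
  coverage tracks and Ct tables with known ground truth, so the whole
  pipeline is testable end to end without any sequencing data.

## Coordinate and normalization conventions

All coordinates are 0-based, half-open internally; conversion happens only
at format boundaries (BED and bedGraph are both 0-based half-open, so the
conversion is the identity; readers validate record by record with line
numbers). Chromosome names are matched exactly — no `"chr"` aliasing; a
mismatch is an error, never a silent drop. Coverage tracks carry a
`library_size`; `normalize_track` rescales values by `1e6 / library_size`
(total-read-count normalization). When no library size is supplied the
track total is used, with a warning.

Windows are `[center - halfwidth, center + halfwidth)` and are truncated
at chromosome ends rather than dropping the site; the `mean` statistic
uses the truncated width, and averaged profiles track per-offset
denominators so truncation does not bias them. Heatmap bins instead pad
truncated windows with zeros against the full bin width, which keeps the
conservation identity `sum(bin means) * bin width = window sum` exact for
every row. The site anchor is the midpoint of the annotated recognition
interval, rounded down (the 8 bp AsiSI motif has no distinguished base).

## The cut/uncut test

Cut and uncut sites are different genomic populations, so the unpaired
two-sided Mann-Whitney U test is the appropriate comparison; a paired
signed-rank variant is provided for before/after contrasts at the same
sites. The U statistic uses midranks. With at most 8 observations per
group the p-value is computed by exact enumeration of all label
assignments — valid under ties, where the classical exact distribution is
not — and otherwise by the normal approximation with tie correction and a
continuity correction. No multiple-testing correction is applied across
tracks or figures; each p-value is reported as-is and the report says so.

Quartiles everywhere (boxplot summaries, class medians) use linear
interpolation between order statistics (`stats::quantile` type 7).
Outliers are values strictly outside the Tukey fences (quartile ±1.5 IQR);
whiskers are the extreme data values inside the fences.

## Stratification, heatmaps and profiles

`stratify_by_transcription` orders sites by a transcription score
(typically total RNA PolII signal in a ±5 kb window) and cuts the ordering
into contiguous classes of near-equal size, labeled low to high; 80 sites
in 4 classes gives exactly 20 per class, and any remainder goes to the
lowest classes. Ties are broken by site id, making the partition
deterministic.

Heatmap matrices use 500 bp bins over a ±5 kb window by default (20 bins),
rows sorted by decreasing cleavage efficiency or by a supplied score.
The bin statistic is the mean signal, not the sum.

Metagene profiles use 200 bp bins over 3 kb flanks (15 bins each side) and
100 gene-body bins scaled to percent of gene length. Body bin `b` of a
plus-strand gene of length `L` covers gene bases
`[floor((b-1)L/100), floor(bL/100))`. Bins are computed in genomic
coordinates and the 130-bin vector is reversed for minus-strand genes, so
bin 1 is always 5'-most; on minus-strand genes the body partition is the
mirror image of the plus-strand rule, which makes strand mirroring exact.
Genes shorter than the body bin count, and genes whose flanked span leaves
the chromosome, are excluded with a reported count. Genes are aggregated
with equal weight by default (`weight = "length"` is available); the
damaged-gene subset is selected by `genes_near_dsb`, which takes genes
overlapping a cut site or within strictly less than 1 kb of one.

## qPCR assays

All assays assume perfect amplification efficiency (doubling per cycle);
the Ct simulator exposes efficiency as a parameter but the assay formulas
fix it at 2, matching standard practice when amplicon efficiencies are not
separately calibrated. All assay quantities are scale-free in absolute Ct.

* **Resection ssDNA%**: `1 / (2^(Ct_digested - Ct_undigested - 1) + 0.5) *
  100`. The raw value ranges over (0, 200); values are clamped to
  [0, 100] for reporting, with the raw value available. Results are
  normalized to the undamaged control's ssDNA%.
* **Repair kinetics**: the readout is the percentage of sites that remain
  broken. No closed form is standard, so the package adopts the
  input-normalized two-power ratio `s(t) = 2^(Ct_input - Ct_pulldown)`,
  reported as `100 * s(t) / s(reference)`; the reference time point reads
  100 by construction and values above 100 are flagged. Normalization to
  input is applied at every time point, which also cancels DNA-amount
  differences between samples.
* **Translocation frequency**: delta-delta-Ct with two control regions;
  the per-condition control Ct is the arithmetic mean of the two control
  Cts (the geometric mean of their quantities), the standard
  multi-reference-gene rule.
* **DRIP-qPCR**: percent input, `100 * input_fraction * 2^(Ct_input -
  Ct_ip)`, is the default quantification; enrichment relative to a
  negative-control region can be formed from two percent-input values.

Replicate aggregation happens after per-replicate assay computation (mean
and s.e.m. of per-replicate values with the sample standard deviation),
never on pooled Cts, matching how biological replicates are summarized.

## What the simulator emulates — and what it does not

The generator's defaults describe the study geometry at a reduced scale:
one 2 Mb chromosome, 60 non-overlapping genes (30% silent, the rest with
lognormal expression, meanlog 2, sdlog 1), 120 annotated break sites of
which 20 are cut, with 75% of cut sites inside expressed genes and minimum
3 kb spacing between sites. Two presets preserve the site geometries
of the AsiSI system: `"dsb80"` (200 sites, 80 cut, 6 Mb) for the
four-by-twenty stratification, and `"asisi"` (1211 annotated sites, 80
cut, 20 Mb). The commonly cited totals for this system are internally
inconsistent (1211 annotated versus 80 cut + 1139 uncut = 1219); the
simulator exposes both and does not resolve which is correct — pass
`n_sites = 1219` for the alternative.

Signal structure, per track:

* senataxin-like ChIP, damaged: a symmetric boxcar peak of half-width
  1 kb at each cut site in an expressed gene, height `amplitude (4) x
  cleavage efficiency x expression / reference expression`; undamaged:
  background only. The boxcar is used because it is integrable in closed
  form, which makes amplitude-recovery tests exact; peak shapes are not
  parameterized by the underlying experiments.
* RNA PolII: gene-body signal proportional to expression, independent of
  condition.
* DRIP: gene-body signal proportional to expression with stronger TSS and
  TTS boxcar peaks; damage adds a multiplicative gain (1.5) over ±5 kb of
  each cut site, a central multiplicative depletion (strength 0.6) over
  ±1 kb when the site lies in an expressed gene, and damping (0.7) of the
  damaged gene's body signal. Setting `senataxin_activity = 0` removes
  the central depletion, emulating helicase knockdown. A 10% minority of
  silent or intergenic cut sites receives a reduced gain (30% of the
  full effect), emulating hybrid formation at a few untranscribed sites.

Noise is Poisson per base by default (counts with the mean signal as
rate); a Gaussian alternative and a noise-free mode exist for speed and
for closed-form tests. Background is 0.5 signal/bp (2 in the reduced
statistical-test configurations, where a higher floor makes the windowed
sums comfortably non-degenerate). Every stage draws from its own RNG
stream derived from the master seed and the stage name, so identical
configurations give bit-identical outputs and adding a stage never
perturbs another stage's draws.

The simulator does **not** emulate read-level artifacts (fragment size,
duplicates, mappability, GC bias), replication or cell-cycle structure,
chromatin-domain spreading, or inter-site interactions. Passing tests on
synthetic data therefore demonstrate correctness of the quantification
arithmetic and the qualitative damage phenomenology, not performance on
real sequencing libraries.

One property of the generator deserves emphasis: because cut sites are
deliberately placed in active genes, baseline (undamaged) DRIP signal at
cut sites is systematically higher than at uncut sites through
transcription alone. An undamaged cut/uncut comparison is therefore *not*
a null comparison under the default geometry — it is confounded by design,
as it is in the real system. The exchangeable null used for calibration
removes the expression structure (all-silent genome); the damage effect
proper is isolated by the per-site damaged/undamaged ratio.

## Numerical and design choices

* Exact Mann-Whitney enumeration switches to the normal approximation
  above 8 observations per group (enumeration of `choose(16, 8)` label
  assignments is instantaneous; beyond that the approximation is
  standard).
* Whether a windowed "count" sums normalized per-base coverage or read
  starts is ambiguous in ChIP-seq practice; the package sums normalized
  coverage and exposes the statistic (`sum` / `mean`) as an argument.
* Statistical calibration (type-I error of the cut/uncut test under a
  null generator, 500 replicates) and power (100 replicates at the
  default effect) run on a reduced configuration — 300 kb, 30 genes, 40
  sites, 10 cut, background 2/bp, ±1 kb windows — chosen so the full
  calibration loop runs in seconds while preserving the default genic
  cut-site fraction.
* Pipeline outputs are plain TSVs plus a JSON manifest (config, seed,
  version, md5 checksums); TSV outputs are byte-identical across reruns
  of the same config. Simulated raw tracks are written as bedGraph only
  on request, since base-resolution Poisson tracks RLE-encode to tens of
  megabytes.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
gm <- simulate_genome(cfg)

setx_dam <- normalize_track(simulate_chip_coverage(gm, "senataxin",
                                                   "damaged"))
setx_und <- normalize_track(simulate_chip_coverage(gm, "senataxin",
                                                   "undamaged"))
q <- quantify_sites(list(damaged = setx_dam, undamaged = setx_und),
                    gm$sites, halfwidth = 5000, statistic = "sum")
compare_cut_uncut(q, "damaged")
compare_cut_uncut(q, "undamaged")

out <- run_pipeline(cfg, tempfile("breakscape_run"))
out$tests$senataxin_damaged$p_value
```

## Known limitations

* The repair-kinetics and DRIP-qPCR formulas are documented
  interpretations of named readouts whose exact equations are not
  standardized; both are exposed as explicit, testable closed forms.
* The exact enumeration of the Mann-Whitney null is quadratic in the
  binomial coefficient and deliberately capped at 8 per group.
* The simulator's effect sizes are stylized (boxcar peaks, multiplicative
  gains); they support exact recovery tests but do not attempt to match
  empirical peak shapes.
* bigwig input is not supported; tracks interchange as bedGraph text.
  Converting bigwig to bedGraph upstream (e.g. with standard UCSC or
  rtracklayer tooling) is lossless for this purpose.
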