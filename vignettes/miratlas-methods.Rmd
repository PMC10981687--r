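---
title: "Models and methods behind miratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind miratlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miratlas)
```

# The problem

The *C. elegans* embryo develops through an invariant cell lineage: every
wild-type embryo produces the same genealogy of cells, and a cell's
lineage identity (its Sulston name) determines its fate. This makes it
possible to build single-cell expression atlases by imaging: a
promoter-driven, nucleus-localized fluorescent reporter is recorded by 3D
time-lapse microscopy, every nucleus is traced and named, and the
reporter intensity per nucleus per time point becomes a lineage-resolved
readout of that promoter's transcriptional activity. `miratlas`
implements the downstream analysis of such data for a panel of miRNA
promoter reporters: per-cell quantification, an integrated
terminal-cell-by-reporter atlas, cell clustering with bootstrap
confidence, tissue-specificity calling, miRNA seed-site target analysis
(preferential targeting and leaky transcription), and TF-binding
enrichment at miRNA promoters.

Because raw imaging data are not practical at desk scale, the package
includes a first-class synthetic-data module that generates every input
the pipeline consumes with known ground truth. All tests and the
acceptance analyses run against those generators.

# Lineage model

`celegans_lineage()` builds a deterministic full-size model of the traced
embryonic lineage: 671 terminal cells, of which 113 are flagged as
programmed cell deaths, leaving 558 cells annotated at the L1 stage; the
11-tissue classification carries the canonical census (neuron 202, glia
40, hypodermis 48, seam 20, P cell 12, pharynx 95, intestine 20,
rectum-anus 15, body wall muscle 87, coelomocyte 4, excretory 6; the
germline and a few remaining cells are unassigned). Terminal counts,
death counts and tissue counts are the modeled quantities; the branch
topology below each founder and the division timings are synthetic,
because the census constrains counts, not shapes or clock times.
Death-flagged leaves are counted among the terminals, which is the
reading that reconciles the 671 traced terminals with the 558 L1 cells.

Cell tracks — the ordered mother-to-daughter chains from a 4-cell-stage
origin (ABa, ABp, EMS, P2) to one terminal cell — are the unit over which
embryonic expression is summarized. Time is kept in frame units
(1 frame = 75 s); conversion to minutes is presentation only.

`synthetic_lineage()` produces reduced lineages of the same form. Tissue
blocks are laid over the terminal cells with sizes proportional to the
canonical census by default, because real tissue sizes are strongly
unequal and equal-size blocks create artificial symmetry in downstream
clustering.

# Imaging and quantification

The imaging model is: measured nucleus intensity
`signal * attenuation(z) + background + noise`, annulus intensity
`background + independent noise`, with
`attenuation(z) = exp(-z / lambda) * ramp^z` — exponential decay with
depth, partially compensated by the 3%-per-plane laser ramp
(`ramp = 1.03` by default over 30 planes). The reporter is a
histone-fusion, so its signal is cumulative: active cells gain `rate`
units per frame and daughters inherit the mother's signal concentration
unchanged at division. Defaults (`background_mean` 30, `background_sd`
2, `measurement_sd` 1, `lambda` 20 planes, `rate` 5/frame) put planted
signals roughly an order of magnitude above the post-calibration
detection threshold, which mirrors a well-exposed reporter rather than a
marginal one.

Quantification proceeds exactly in the order a practitioner would apply:

1. `subtract_background()`: nucleus minus annulus, negatives retained
   (they are only zeroed by the cutoff later, keeping averages unbiased);
2. `correct_depth_attenuation()`: division by the model attenuation;
3. `calibrate_cutoff()`: the expression cutoff is the `1 - target_fdr`
   empirical quantile (inverse ECDF) of negative-control cell-timepoint
   values, with `target_fdr = 1e-4` (an 0.01% false-discovery rate of
   expression calls); the conventional fixed cutoff of 3.2 intensity
   units can be imposed via `override`;
4. `summarize_cell_expression()`: the per-cell time-averaged corrected
   intensity, set to zero below the cutoff. The cutoff is applied to the
   per-cell average, not per frame, matching the per-cell expression
   table used downstream.

Because the reporter accumulates, promoter *activity* in a cell is
inferred from a within-cell intensity rise (`infer_increased_expression`):
cells with at least 12 traced time points are tested by a two-sided
Mann-Whitney between the early window (first 10 frames if more than 20
are traced, otherwise the first half) and the remaining frames,
Benjamini-Hochberg corrected across the tested cells, with a call
requiring Q < 0.05 *and* a higher late median (the direction gate makes
the two-sided test one-sided in effect). The onset cell of an expressing
track is classified as increased by rule. R's `wilcox.test` supplies the
exact small-sample distribution and the tie-corrected normal
approximation otherwise; an all-tied trace is reported at p = 1.

# Atlas construction and clustering

Per reporter and stage, expression is normalized to percentile ranks:
zeros stay zero, nonzero values map to `100 * rank / n_nonzero` with
average ranks for ties, making the embryonic and L1 acquisitions
comparable and the atlas invariant to monotone intensity rescaling.
Embryonic expression is averaged along each cell track, counting a
reporter as expressed only when it is on in at least two consecutive
generations (isolated one-generation signals are treated as noise). The
integrated value per terminal cell is the maximum of the embryonic track
rank and the L1 rank — "expressed at either stage" semantics. The
alternative reading of the integration sentence (maximum over multiple
tracks reaching equivalent cells) is available by integrating
user-supplied track sets, and a two-column concatenation can be built
from the returned per-stage matrices, but the maximum is the default.

Cells are clustered on `1 - tau_b` distance (tie-corrected Kendall, since
atlas columns are zero-rich) with average linkage. Cluster confidence
uses multiscale bootstrap: columns are resampled at ten scales from 0.5
to 1.4, per-node recovery frequencies `BP_r` are recorded, the model
`qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)` is fitted by weighted least
squares (only scales with `0 < BP < 1` carry information; profiles that
are recovered essentially always or never map directly to AU 100 or 0),
and `AU = 100 * (1 - pnorm(v - c))`. Supported clusters are the maximal
nodes with AU at or above 90, selected top-down so they are disjoint;
remaining cells are singletons.

One design point deserves emphasis: the root node is always recovered by
construction, so its AU is 100 by convention, and including it as a
candidate would always return a single all-cells cluster. `extract_clusters`
therefore excludes the exact root unless `include_root = TRUE`.

A known regime effect follows from the bootstrap theory: in a
feature-poor atlas (few reporter columns), a union of two tissue clades
is itself a stable clade whose recovery *rises* with resampling scale, so
the AU extrapolation assigns it a high value and top-down extraction
stops there rather than at its pure children. With the study-scale panel
(54 reporters over 11 tissues) such coarse unions are unstable and
extraction yields fine, largely tissue-pure clusters; with a desk-scale
6-reporter, 4-tissue panel, roughly one coarse mixed union per run
survives, capping pooled tissue purity near 0.83 rather than 0.9. The
package reports this honestly; it is a property of the small-panel
regime, not of the implementation (the pure tissue nodes themselves reach
AU ≥ 90).

# Tissue specificity

A feature is tissue-specific if any of three criteria holds: (1)
quantitative expression in the tissue's cells exceeds the rest with fold
change > 2 (on means with a +0.1 pseudocount, since the paper-style fold
change is undefined on zero baselines) and Q < 0.01 by two-sided
Mann-Whitney; (2) the expressing fraction exceeds the outside fraction
with fold > 1.25 and Q < 0.01 by two-sided Fisher; (3) all expressing
cells (at least three) lie in a single tissue, regardless of Q. BH
correction is applied per feature across tissues (the per-tissue
alternative is a flag). Calls are labeled pan- or sub-tissue at 70%
coverage. "Expressed" means a positive post-cutoff atlas value; for
transcriptomes, detection is TPM > 0 by default with a stringent
threshold of 5 available. Criterion 3 is invariant to monotone
rescaling, which the tests check directly.

Protein-coding tissue-specific genes (TSGs) are called by the identical
machinery on late-embryo expression values: per terminal cell, the
maximum of the terminal's and its mother's TPM, with the latest covered
ancestor standing in for uncovered terminals.

Intra-family divergence compares each within-family miRNA pair's
similarity (Kendall tau over cells by default) to the union of both
members' similarities to all out-of-family miRNAs; a pair is
high-similarity if it reaches the top 20% of that comparison set. The
comparison-set convention is configurable because the underlying
definition admits several readings.

# Targeting, leakiness, regulation

Seed sites follow the canonical definitions from the miRNA 5' region
(positions 1–8): 7mer-m8 is the reverse complement of positions 2–8,
7mer-A1 the reverse complement of 2–7 followed by A, 8mer the reverse
complement of 2–8 followed by A. Coordinates are 0-based half-open on
the sense strand; U and T are interchangeable on input; each locus is
classified by its most specific type. The gene universe keeps one UTR
per gene (the longest) and drops UTRs under 50 nt.

The preferential-targeting statistic per (miRNA, cell track, TSG type)
is O/E: the share of that TSG type among the miRNA's targets transcribed
in the track, over its share among all transcribed universe genes, then
normalized by the per-(miRNA, type) median across tracks (absorbing
UTR-length and composition differences; normalized medians are exactly 1
by construction). Calls compare the miRNA's own-tissue tracks against
the other tracks in the profile: median > 1, median fold > 1.25,
two-sided Mann-Whitney p < 0.01, groups of at least 3. Because the
normalization removes purely global preferences, only context-dependent
targeting structure is callable — which is what the statistic is for.
Whether profiles are restricted to miRNA-expressing tracks is a flag
(`mirna_tracks`); the orchestration default uses all tracks, because
planted reporters in synthetic data are nearly perfectly specific and
would otherwise leave no comparison group.

Leaky transcription of a TSG is quantified both as its detection
frequency in tracks of other tissues (CT_other) and as its mean level in
CT_other relative to focus-tissue tracks; per-track leakiness averages,
over non-own tissue types, the detected fraction of that type's TSGs.
Binding-site density counts distinct miRNAs with at least one site per
UTR kilobase (multiple sites of one miRNA count once), and the
leakiness-density coupling is tested by Spearman correlation plus a
high/low-strata Mann-Whitney.

TF ChIP peaks are assigned to promoters by any-overlap (half-open
intervals; midpoint containment behind a flag) with strand-aware windows
from TSS−2000 to TSS+100 (2100 bp), implemented on `IRanges` overlaps and
cross-checked against a per-base scan in the tests. TF datasets with
fewer than 100 peaks are excluded by default (the threshold is relaxed in
small synthetic runs, where no dataset reaches 100 peaks). Binding
frequencies per gene class are compared across TFs by paired Wilcoxon
signed-rank; same-tissue TF-to-miRNA wiring is tested one-sided by
Fisher.

# Synthetic data: what it does and does not emulate

The generators are pure functions of configuration and seed, and every
one refuses to run without a seed. They emulate: cumulative
histone-fusion accumulation with inheritance at division, depth
attenuation with the laser ramp, shared-background subtraction (so
control net values have variance `2 * measurement_sd^2`), planted
pan-tissue reporter programs with 10% sporadic off-tissue terminal
activity (real promoter reporters are statistically, not absolutely,
restricted), log-normal track transcriptomes with planted TSGs and a
tunable leak fraction, random-background UTRs with planted seed sites
(the emitted target table is the scanner's own output on the emitted
FASTA, so the two cannot drift apart), and strand-aware ChIP peaks inside
or outside promoter windows.

They do not emulate: pixel-level imaging (no segmentation, no nucleus
radius estimation), fluorophore maturation delay, channel bleed-through,
mRNA stability effects on the increased-expression inference, or
annulus contamination by neighboring nuclei. Consequently, passing tests
demonstrate that the analysis recovers planted structure under the
stated noise model, not that it is robust to those unmodeled artifacts.

# Problem sizes and numerical choices

The packaged analyses use a 64-terminal, 4-tissue lineage with 6 planted
and 6 silent reporters, 200 bootstrap replicates per scale for cluster
confidence, 300-gene transcriptomes, and about one million
cell-timepoints for cutoff calibration — sizes at which every stage's
behavior is measurable in minutes on one core. Tie-breaking in the
agglomeration follows the stable order of `stats::hclust`; quantile
calibration uses the inverse-ECDF (type 1) quantile so the empirical
exceedance never overshoots the target rate; fold changes on zero
baselines use a +0.1 pseudocount; degenerate inputs (all-zero reporter
columns, constant rows, empty groups, undefined expected frequencies)
are flagged or warned rather than silently dropped.

# Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1, profile = "small", n_boot = 100)
res <- run_pipeline(cfg)
res$calls[, c("feature", "tissue", "pan_or_sub", "criteria")]
res$purity$fraction_pure
mean(res$leakiness$profiles$freq_other)
```

The `run_pipeline()` orchestration simulates all inputs, calibrates the
cutoff on a simulated negative control, quantifies each reporter, builds
the integrated atlas, clusters with AU confidence, calls specificity and
TSGs, and computes the targeting, leakiness and TF-binding statistics;
every stage's tables are returned (and written as TSV when `out` is
given).

# Known limitations

Besides the synthetic-data simplifications above: the AU extrapolation
is unreliable for nodes whose recovery profile rises steeply from zero
(a known property of multiscale bootstrap in feature-poor data); the
increased-expression inference cannot distinguish new transcription from
inherited stable reporter mRNA; and the preferential-targeting caller is
blind to globally uniform targeting preferences by construction of the
normalization.
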