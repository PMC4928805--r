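---
title: "Promoter chromatin states: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter chromatin states: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstates)
```

# The analysis in one paragraph

Histone modifications at gene promoters are predictive of transcription:
H3K4me3 and H3K9ac mark active promoters, H3K27me3 marks repressed ones, and
promoters carrying both are "bivalent". Given aligned ChIP-seq tags for these
marks in two conditions (here labelled LLC-NR, anti-VEGF-sensitive, and
LLC-R, resistant), the pipeline quantifies each promoter's occupancy per
mark, classifies every promoter into one of four chromatin states per
condition, tabulates how states redistribute between conditions, and relates
all of it to gene expression (FPKM). Promoters are additionally stratified by
their CpG content, computed from sequence, because CpG-rich and CpG-poor
promoters are regulated differently.

# Model and procedure

## Promoter definition

A promoter is the window from 1 kb upstream to 0.5 kb downstream of the TSS,
strand-oriented and clipped at chromosome ends. Coordinates are 0-based
half-open (BED convention) everywhere inside the package; GTF input is
converted at the boundary. The TSS of a plus-strand gene is its annotated
start; for a minus-strand gene it is the annotated end coordinate. With
multiple transcripts per gene the first listed is used: the analysis is
gene-level and a single promoter per gene keeps the state bookkeeping
one-to-one.

## CpG classes

For each promoter sequence every 500-bp window (step 1 bp) is scored with

* GC content = (#G + #C) / #non-N bases, and
* CpG O/E = (N~CpG~ · L) / (N~C~ · N~G~) — the Gardiner-Garden & Frommer
  convention, with L the window length and N~CpG~ the count of CG
  dinucleotides.

HCP: some window has GC ≥ 0.55 and O/E ≥ 0.6. LCP: no window has O/E ≥ 0.4.
ICP: everything else. The scan is implemented with cumulative sums (exact,
O(L) per promoter) and is tested against an exhaustive per-window oracle.
Promoters shorter than 500 bp after clipping are judged on the whole
available sequence rather than silently dropped; windows that are more than
half N are ignored (GC denominators always exclude N). A coarser `step` is
available for speed and documented as approximate.

## Peak model

Fixed-width peak fitting, in the GeneTrack tradition: each tag midpoint
contributes a unit-height Gaussian, signal(x) = Σ exp(−(x−t)²/2σ²), so
smoothed height reads as an effective count of overlapping tags. Peaks are
selected greedily: take the global maximum at or above `min_occupancy`,
suppress every position closer than `exclusion` to it, repeat. Returned
peaks are therefore pairwise ≥ `exclusion` apart — the invariant the caller
asserts and tests enforce against an O(n²) reference implementation. Ties at
equal height go to the leftmost coordinate, which makes the caller fully
deterministic.

Single-end tags with strand information are first shifted by half the
dominant plus/minus cross-correlation lag (searched in 0–500 bp) to
approximate fragment midpoints; without strand information the shift is 0.

## Occupancy, thresholds and states

Two quantifications are computed for every (promoter, mark, condition):
the raw tag count in the window, and the sum of fitted peak occupancies
whose centers fall inside it. Both are normalized to tags per million using
the observed library sizes, so values are comparable between conditions.
State calls use the raw counts by default (simpler provenance); the
peak-sum calls are always computed alongside and their agreement is reported.

With M(mark) the arithmetic mean occupancy over *all* promoters (zero rows
included — every annotated gene stays in the universe), a promoter is

* **active** if K4 ≥ 2·M(K4) or K9ac ≥ 2·M(K9ac), and K27 < M(K27);
* **bivalent** if an active mark clears its 2·M cutoff and K27 ≥ M(K27);
* **repressive** if K27 ≥ M(K27) but no active mark clears its cutoff;
* **none** otherwise.

All cutoffs are inclusive (≥); only the active state's K27 condition is
strict. Writing A for the active-mark clause and R for the K27 clause, the
four states are exactly the truth table over (A, R), so the classification
is a partition — tested exhaustively on a 5×5×5 occupancy grid. Calls are
invariant to rescaling any mark column together with its M, which is why the
choice of normalization constant cannot change a state.

Thresholds are computed within each condition by default (each condition's
own mean), since the mean is defined over "all promoters" of a sample; a
pooled mode (one M per mark across conditions) is available as a
configuration flag for users who prefer a shared reference.

## Transitions and expression

The 4×4 transition table counts promoters by (state in NR, state in R); row
proportions condition on the starting state, and empty rows report NA rather
than 0/0. Gene lists are derived by category — by default *gain_active*
(not active → active) and *lose_repressive* (repressive → none or active) —
overall and per CpG class, for use with external GO/KEGG tooling; the
universe file is written alongside.

Expression analyses: Spearman rank correlation (average ranks on ties)
between each mark's occupancy column and FPKM; two-sided pooled-variance
Student's t between expression of state groups, with the conventional
significance tiers (** ≤ 0.01, * ≤ 0.05); per-gene log2 fold changes
log2((x_R + c)/(x_NR + c)) with pseudocount c = 1 normalized unit for both
occupancy and FPKM (zeros are common; the symmetric pseudocount maps 0→0);
and a strand-oriented H3K36me3 metagene profile over gene bodies (40
equal-width bins TSS→TES, tags per million, averaged within state groups).

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `upstream` / `downstream` | 1000 / 500 | bp | the promoter window definition |
| `window` | 500 | bp | CpG-class window; the classes are defined at this scale |
| `step` | 1 | bp | exact scan; larger = approximate |
| `sigma` | 20 | bp | kernel width ≈ tag-position jitter; small enough to resolve adjacent nucleosomes |
| `exclusion` | 147 | bp | nucleosomal DNA width; minimum peak spacing |
| `min_occupancy` | 2 | smoothed tags | a peak needs ≥ 2 effective overlapping tags |
| `pseudocount` | 1 | normalized units | guards zeros in fold changes |
| `threshold_mode` | per-condition | — | M is defined over one sample's promoters |
| `state_method` | raw_count | — | simplest provenance; peak_sum computed for comparison |

The smoothing σ and occupancy threshold are declared package defaults, not
values inferred from any reference tool; both are configurable.

# The synthetic-data generator

`simulation_config()` fixes the study conditions: 2000 genes on 4
chromosomes of 2.5 Mb, promoter enrichment 8× the local background
(background 0.04 tags/bp ⇒ 60 expected background and 480 expected planted
tags per 1.5-kb promoter), one master seed driving every draw, and planted
per-gene ground truth (CpG class, state per condition, FPKM) serialized next
to the generated files. Tag counts are Poisson; planted promoter tags sit on
a TSS-centered nucleosome grid with 50-bp Gaussian jitter; expression is
log-normal around per-state means; H3K36me3 is drawn over gene bodies in
proportion to FPKM. This is deliberately the simplest model that exercises
the thresholding — it is not biological.

Two structural facts shaped the default state frequencies and expression
means, and they are worth recording because they apply to the real method
too:

* **Detectability bound.** The active call requires occupancy ≥ 2·M. If a
  fraction f of promoters carries an active mark at enrichment e over
  background b, then M = b + f·e and detection requires e(1 − 2f) > b: at
  8× enrichment the active-mark-high fraction must stay below ~0.44, with
  practical Poisson margins below ~0.40 — in *both* conditions. Because the
  transition matrix funnels bivalent promoters into the active state, the
  resistant condition is the binding one. Defaults: NR state probabilities
  (.34 active, .36 repressive, .04 bivalent, .26 none); transition rows
  active (.96, 0, 0, .04), repressive (.04, .74, .02, .20), bivalent
  (.80, 0, .20, 0), none (.02, .10, .02, .86). The bivalent row encodes the
  characteristic 80/20 resolution to the active state; the active row keeps
  resistant-condition active promoters a subset of the sensitive ones.
* **Rank-correlation ceiling.** With discrete states, the Spearman
  correlation between a near-binary occupancy column and expression is
  bounded by √(3pq) times the rank separation of the groups. A clearly
  negative H3K27me3–FPKM correlation therefore requires the active class
  (high expression, low K27) to hold a substantial share of genes; with the
  defaults above and expression log-means (3.2, 1.3, 1.0, 1.0) for
  (active, bivalent, repressive, none), sd 0.45, the realized correlations
  are ≈ +0.65 for the active marks and ≈ −0.37 for H3K27me3.

Sequence composition: the background is i.i.d. at GC 0.48 with CG
dinucleotides thinned to ~0.1 of expectation. The thinning is stronger than
the genome-wide CpG depletion of a mammalian genome (~0.2) because the LCP
rule takes a *maximum* over ~1000 overlapping windows per promoter: at O/E
0.2 the windowed maximum crosses the 0.4 cutoff in a large fraction of
plain-background promoters, which would corrupt the planted LCP labels; at
0.1 the misplant rate is a few percent. HCP promoters receive an embedded
600-bp segment at GC ≈ 0.62, O/E ≈ 1; ICP promoters a segment at GC ≈ 0.45,
O/E ≈ 0.5; LCP promoters are plain background. The config's `library_size`
(2×10⁶) is the nominal normalization constant recorded with a run; the
pipeline normalizes by observed per-file totals, and state calls are
invariant to that scale.

What the generator does **not** emulate: read sequences and quality,
mappability and GC bias, duplicate reads, input/IgG background structure,
continuous (rather than state-driven) occupancy variation, and
transcript-level structure. Passing the end-to-end tests therefore shows the
pipeline recovers planted structure under its own model assumptions — it is
not evidence about antibody quality or alignment artefacts in real data.

## Problem sizes used by the tests

The shipped test-suite runs the generator at its default scale (2000 genes,
10 Mb) once for the end-to-end recovery checks, at ~80–600 genes for unit
and determinism checks, and a 500-gene all-bivalent planting for the
transition-recovery check; these sizes were chosen so the planted-parameter
recovery claims have tight sampling error while the whole suite stays quick
to run. The transition-recovery check is evaluated on the generator's
planted state draws (through `transition_table()`), where the 3-binomial-SE
bound is exact; routing it through occupancy classification would add
non-binomial classification error, which is the end-to-end check's job.

# Numerical choices and degenerate inputs

* Smoothing is an FFT convolution (padded to a highly composite length), so
  identical inputs give bit-identical signals; values carry ~1e-12 relative
  roundoff, far below any threshold in use.
* Peak ties break to the leftmost coordinate; candidate ordering is
  (height desc, position asc), which reproduces the iterative greedy exactly.
* Empty tag sets, empty promoters and empty peak lists quantify as explicit
  zeros; the occupancy table is complete over the promoter universe.
* A constant vector in the Spearman correlation returns NA with a warning;
  a zero-pooled-variance t comparison returns t = 0, p = 1 when means are
  equal (and ±Inf, p = 0 when they are not).
* `estimate_fragment_shift()` warns and returns 0 when a strand is empty or
  strand information is absent.
* All generator randomness flows from one integer seed (sub-seeds are fixed
  offsets); re-runs are byte-identical, which the manifest's checksums make
  checkable.

# Known limitations

* The four-state model is a deliberate caricature: no input subtraction, no
  statistical enrichment testing, no broad-domain calling (H3K36me3 is
  handled as gene-body coverage, not peaks), no HMM-style segmentation.
* Mean-based thresholds are sensitive to the promoter universe: adding or
  removing genes moves every M. That is inherent to the method, and the
  reason the universe ("all promoters") is fixed and recorded.
* CpG classes are recomputed from sequence for whatever annotation is
  supplied; counts will differ between annotation versions, so published
  class totals from other annotations are not directly comparable.
* GO/KEGG enrichment is exported as ranked gene lists plus a universe file,
  never computed internally.

# A small worked run

```{r example, message = FALSE}
dir <- tempfile("promstates-demo-")
cfg <- simulation_config(seed = 7, n_genes = 120, n_chroms = 2,
                         chrom_length = 3e5)
bundle <- simulate_chipseq_experiment(cfg, dir)
res <- run_pipeline(pipeline_config(
  genome = bundle$paths$genome, genes = bundle$paths$genes,
  tags = bundle$paths$tags, expression = bundle$paths$expression,
  outdir = file.path(dir, "out")))
glance(res)
res$transitions$proportions
```

```{r plots, fig.width = 6, fig.height = 3.5}
autoplot(res$transitions)
plot_state_expression(res$expression_by_state)
```
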