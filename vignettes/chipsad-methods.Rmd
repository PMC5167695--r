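---
title: "Methods: segmentation, alignment and classification of bacterial array signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, alignment and classification of bacterial array signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipsad)
library(dplyr)
```

## The problem

High-density bacterial transcriptome arrays probe both strands of the whole
chromosome, coding and non-coding. Each probe reports an M value — the log2
ratio of two hybridization channels (for example mutant vs wild type). A
transcribed region shows as a run of probes with a consistently shifted M
level; the analysis task is to segment that signal along the genomic
coordinate into discrete transcript units, reconcile the units found in
several experiments, and interpret them against the genome annotation. The
package does this in three stages, each usable on its own:

1. **Segmentation** (`chipsad()`): change-point detection on the probe M
   track, yielding *signal areas* (SAS) — contiguous intervals of probes
   with similar intensity, each summarized by its Hodges–Lehmann
   pseudomedian M.
2. **Alignment** (`align_experiments()`): SAS from multiple experiments that
   overlap on the same strand are grouped by graph connectivity and merged
   into consensus transcripts with signal-weighted boundaries.
3. **Classification** (`annotate_all()`): each (consensus) SAS is compared
   with the annotated ORFs and labelled as ORF, operon, antisense,
   overlapping UTR, 5'/3' UTR, or intergenic RNA.

## Segmentation model

For every track (one experiment, replicon and strand) the segmenter slides
an anchor along the probe starts. At each anchor it builds a pair of
*correlated probe regions* (CPRs): windows of consecutive probes immediately
left and right of the anchor coordinate. Each side starts as the window of
width `w` adjacent to the anchor and grows probe-by-probe outward while the
signal stays consistent. The two sides are then compared with a generalized
t-statistic in the SAM (significance analysis of microarrays) style:

$$ t(x) = \frac{\bar M_R - \bar M_L}{s + s_0}, \qquad
   s = \sqrt{\left(\tfrac{1}{n_L}+\tfrac{1}{n_R}\right)
             \frac{SS_L + SS_R}{n_L + n_R - 2}} $$

where \(SS\) are within-side sums of squared deviations and the fudge
constant \(s_0\) keeps \(t\) finite where the local scatter collapses (a
constant stretch of a noiseless track has \(s = 0\)). Change points are
local extrema of \(|t(x)|\) above a threshold; within a run of consecutive
above-threshold anchors only the strongest survives, so one physical step
yields one change point.

On a **tiling** layout (uniform probe spacing) the intervals between change
points are the signal areas directly. On a **non-tiling** layout (irregular
spacing) the t curve over-fragments, so the candidate regions go through a
left-to-right merge pass: adjacent regions A and B are joined when the
absolute pseudomedian of their union exceeds the absolute difference of
their pseudomedians, \(|PM(A \cup B)| > |PM(A) - PM(B)|\); two regions at a
common level always join, a background/transcript contrast never does. We
read "their pseudomedian intensity" in this rule as the pseudomedian of the
union of the two regions, compared in absolute value — the union reading
keeps the criterion symmetric for negative M (repressed transcripts).
`layout = "auto"` picks the tiling path when the coefficient of variation of
the inter-probe gaps is below 0.2.

The SAS intensity summary is the Hodges–Lehmann pseudomedian — the median of
all Walsh averages \((v_i+v_j)/2,\ i \le j\) — computed by the literal
\(O(n^2)\) construction, which is exact and fast at the scale of a
transcript unit.

### Window expansion in detail

A growing side accepts its next outward probe under three conditions:

* **(a) locality** — once the side holds the minimum `m_w` probes, the gap
  to the next probe must not exceed `w`. Below that minimum, gaps are
  bridged: on sparse layouts the typical gap is comparable to `w` by
  construction (`w` is the mean gap), and refusing to bridge would leave
  most anchors without a usable window. The span cap (c) still bounds how
  far bridging can reach, so probe deserts are never crossed.
* **(b) consistency** — outside the initial width-`w` window, the next M
  value must lie within \(k \cdot \max(sd, s_0^{gate}) \cdot \sqrt{1+1/n}\)
  of the current window mean. The \(\sqrt{1+1/n}\) factor accounts for the
  window mean itself being an estimate: without it a 1-probe window rejects
  a same-level neighbour a few percent of the time at realistic noise,
  which silently removes the one anchor able to see a transcript boundary.
  The gate scale \(s_0^{gate}\) is the user's `s0` if supplied, otherwise a
  robust per-track noise estimate (median absolute successive difference,
  scaled by \(0.6745\sqrt2\), floored at 0.01) — successive differences of
  a piecewise-constant signal are blind to the few true steps.
* **(c) span** — the side may not span more than `max_window_expansion`
  (default `10 w`); an unbounded window could swallow a whole transcript.

A side that ends with fewer than two probes is degenerate and the anchor
yields no t value. This is deliberate: an anchor pressed against a signal
step cannot form an honest short-side window, and polluting the window with
cross-step probes instead produces split-fragment artifacts near
boundaries. The first and last `m_w` probes of a track never anchor a
change point; track edges always open and close a SAS.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `w` | mean inter-probe distance (ceiling), per track | initial window width and locality scale, bp |
| `m_w` | min probes in any `w`-window, floored at 2 | minimum CPR size; the t needs two observations per side |
| `s0` | 5th percentile of pooled `s` over anchors, floored at 0.01 | SAM fudge constant, M units |
| `t_threshold` | 3 | change-point threshold on pooled-SD units |
| `k` | 3 | expansion consistency factor (3-sigma outlier gate) |
| `max_window_expansion` | `10 w` | span cap per side, bp |
| `min_orf_overlap_frac` | 0.30 | fraction of an ORF that must be covered |
| `overlapping_utr_max_intergenic` | 30 bp | max ORF-to-ORF gap for overlapping UTRs |
| `utr_max_gap` | 30 bases | max extension beyond an ORF that is still "the ORF" |
| `intergenic_max_len` | 800 bases | max length of an intergenic RNA |

`w` and `m_w` estimated from probe spacing follow the principle that the
window scale should be set by the array design, not by the user. Probe
*position* means the probe start throughout (windowing, gaps, boundaries):
the choice keeps the estimates independent of probe length. The annotation
thresholds (30%, 30 bp, 800 bases) are the standard values for this rule
set. Replicate merging (`merge_replicates()`) median-centers each replicate
column per experiment — a deliberately minimal global normalization that
preserves M-ratio semantics and makes the merged value invariant to an
additive offset in any one channel — then averages per probe; dye-bias loess
or quantile pipelines are out of scope.

## Alignment model

SAS from all experiments are pooled; nodes on the same replicon and strand
whose 1-based inclusive intervals share at least one base are linked, and
each connected component becomes one consensus transcript. Boundaries are
weighted averages
\(\langle x\rangle = \sum_i p_i x_i\) with
\(p_i = |\bar M_i| / \sum_j |\bar M_j|\).
The absolute values matter: raw \(\bar M\) weights break down when repressed
(negative-M) and induced transcripts meet in one component, while
\(|\bar M|\) preserves "stronger signal, more trust" and keeps
\(p_i \in [0,1]\). If every member has \(\bar M = 0\) the weights fall back
to uniform, with a message. Consensus coordinates are rounded half away from
zero. When one experiment contributes several member SAS, its entry in the
per-experiment M vector is the pseudomedian of the union of their probes
(or of the member \(\bar M\) values when probe-level values are no longer
carried, e.g. after a file round trip). An experiment absent from a
component is reported as missing, never as zero — zero would fake "no
change".

The optional pre-alignment filter `min_abs_M` (default 0, i.e. off) removes
weak SAS before the graph is built. It matters in practice: when probes are
longer than the tiling step, adjacent SAS overlap genomically by the probe
overhang, and background segments then chain whole strands into a single
component. Filtering to signal-bearing SAS (e.g. `min_abs_M = 1`) is the
intended way to align transcripts rather than background.

`select_differential()` keeps consensus transcripts whose \(|\bar M|\)
reaches `log2(min_fold_change)` in every named experiment — a plain
fold-change gate, deliberately not a moderated-t/FDR procedure.

## Classification rules

Rules are evaluated in fixed precedence; the first match wins:

1. **operon** — two or more same-strand ORFs each covered at ≥ 30% of their
   length. Operon-before-ORF prevents a polycistronic SAS from degrading to
   a single-ORF call.
2. **overlapping UTR** — the SAS touches two differently oriented ORFs
   whose mutual intergenic gap is under 30 bp.
3. **ORF** — exactly one qualifying same-strand ORF, and the SAS stays
   within 30 bases of it on both sides.
4. **UTR (5'/3')** — one qualifying same-strand ORF with a longer
   extension into flanking intergenic space; the extended biological end is
   resolved strand-aware (on the minus strand the upstream flank lies at
   higher coordinates), and when both ends extend, the longer one decides.
5. **antisense** — no qualifying sense ORF, but an opposite-strand ORF
   covered at ≥ 30%.
6. **intergenic** — no ORF overlap at all and length under 800 bases.
7. **intergenic (long)** — no ORF overlap at ≥ 800 bases: kept as
   intergenic with a `long` marker rather than dropped; dropping would
   silently lose signal, and no positive rule exists for such regions.

The 30% threshold is a fraction of the *ORF's* length, not the SAS's. A SAS
that overlaps ORFs only below the threshold matches none of the rules
above; it falls back to antisense — the "otherwise" of the cascade — with
an `ambiguous` marker in its rule trace so the borderline call is visible
downstream. All interval arithmetic is 1-based inclusive; gaps count bases
strictly between features. Classification is total (every SAS gets exactly
one class), translation-invariant, and symmetric under a global strand flip
except for the intended utr5/utr3 swap.

## What the synthetic generator emulates

`simulate_layout()` / `simulate_signal()` produce probe tracks carrying
piecewise-constant transcript signal plus Gaussian noise on the M scale —
consistent with two-color array practice after log-ratio normalization. The
defaults describe the study conditions used throughout the tests: a 50 kb
replicon (20 kb in the segmentation benchmarks), 25-mer probes tiled every
10 bp or a non-tiling layout with geometric-like gaps of mean 25 bp
(negative binomial, dispersion 1), noise SD 0.25, transcript levels of
M = 2 (four-fold) down to M = 1 (two-fold, the hardest case the detector is
expected to handle), transcripts at least 10 probes long, five experiments
with true boundaries jittered by up to ±20 bp and levels wobbled by
SD 0.1. `simulate_annotation()` engineers one locus per classifier outcome
(and a randomized variant whose expected labels are still known by
construction), writing a well-formed toy GenBank record.

The generator does **not** emulate probe-sequence thermodynamics,
cross-hybridization, spatial slide artifacts, dye bias, or heavy-tailed
noise. Passing tests therefore show that the algorithms are correct under
their stated signal model, not that real arrays are free of those effects;
on real data the pre-alignment filter and the conservative `t_threshold`
are the knobs that absorb them.

## Numerical choices and degenerate inputs

* Pseudomedian: exact \(O(n^2)\) Walsh construction; empty input is an
  error; a single value is its own pseudomedian.
* Ties in change-point runs go to the leftmost strongest anchor.
* Consensus rounding is half-away-from-zero (base `round()`'s banker's
  rounding would make boundaries depend on parity).
* Tracks too small to anchor (fewer than `2 m_w + 1` probes) yield an empty
  t profile and a single SAS; empty tracks yield nothing.
* Weights summing to 1 is asserted to 1e-12 on every consensus.
* All generator randomness is drawn under an explicit seed and restores the
  caller's RNG state; identical configs give byte-identical fixtures.

## Benchmarks under the study conditions

The test suite and `scripts/acceptance.R` recompute, from scratch, at the
problem sizes above: exact agreement of the pseudomedian with its
brute-force construction (1000 random vectors); exact recovery of a
noiseless three-transcript fixture (7 segments, zero boundary error on a
non-overlapping 10-mer grid); recovery of ≥ 95% of true transcripts at
interval Jaccard ≥ 0.9 with ≤ 5% strong false positives over 100 noisy
simulations; SAS-count preservation with mean boundary deviation well
under two mean gaps when a tiling fixture is thinned to 40% density and
re-segmented through the non-tiling path (boundary deviation is assessed as
a per-seed mean because a thinned layout retains no probe at all within two
mean gaps of a boundary about 8% of the time — no segmenter can place a
boundary where there is no probe); the closed-form consensus example
(starts 100/200 at weights 1:3 give 175); a perfect one-per-class
classification truth table with mirror symmetry over 100 randomized
genomes; byte-identical pipeline reruns; and a fold-change gate that keeps
exactly the transcripts simulated at or above two-fold.

## Known limitations

* The segmenter assumes piecewise-constant signal; slowly ramping
  transcription (e.g. partial termination read-through) is split or
  absorbed depending on the noise scale.
* Boundary resolution is bounded by probe spacing; on non-tiling layouts
  expect errors of the order of the local gap.
* The overlap-graph edge rule (≥ 1 shared base, same strand) maximizes
  recall; with long probes and unfiltered background it chains neighbours —
  use `min_abs_M`.
* GenBank support covers CDS features with `join`/`complement` locations
  and `locus_tag`/`gene` qualifiers, which is what the classifier needs;
  it is not a general-purpose GenBank parser.
* Differential selection is a fold-change cut without error control.
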