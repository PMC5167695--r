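# chipsad

Transcript discovery from high-density bacterial transcriptome arrays:
segmentation of probe-level signal into transcript units, alignment of units
across experiments into consensus transcripts, and classification against
the genome annotation — coding *and* non-coding chromosome, in one
framework.

## What it computes

Arrays of this kind report, for every probe on both strands, an **M value**:
the log2 ratio of two hybridization channels (e.g. Δhfq mutant vs wild
type). A transcript shows as a run of probes with a consistently shifted M
level. The package works in three composable stages:

**1. Segmentation.** A pair of sliding/expanding windows (*correlated probe
regions*) is built left and right of each probe anchor and compared with a
SAM-style generalized t-statistic,

    t(x) = (M̄_R − M̄_L) / (s + s0),
    s = sqrt((1/n_L + 1/n_R) (SS_L + SS_R) / (n_L + n_R − 2)),

whose above-threshold extrema are the signal change points. Between change
points lie **signal areas (SAS)** — putative transcripts — each summarized
by the Hodges–Lehmann pseudomedian M̄ of its probes (the median of all
Walsh averages). Uniform (tiling) layouts take the t curve at face value;
irregular (non-tiling) layouts add a merge pass that joins adjacent regions
when |PM(A∪B)| > |PM(A) − PM(B)|.

**2. Alignment.** SAS from several experiments that overlap on the same
strand form components of an interval-overlap graph; each component becomes
one consensus transcript with boundaries `⟨x⟩ = Σ pᵢ xᵢ`, weighted by
`pᵢ = |M̄ᵢ| / Σ|M̄ⱼ|`, plus a per-experiment expression vector (the heat-map
matrix). A fold-change gate (`select_differential()`) then picks
transcripts with |M̄| ≥ log2(fold change) in every experiment of interest.

**3. Classification.** Each (consensus) SAS is compared with the GenBank
ORF annotation and labelled, in fixed precedence: **operon** (≥ 2
co-oriented ORFs each covered ≥ 30%), **overlapping UTR** (bridges two
differently oriented ORFs < 30 bp apart), **ORF**, **5'/3' UTR** (> 30-base
extension beyond the ORF, strand-aware), **antisense**, **intergenic**
(< 800 bases, ORF-free; longer ORF-free regions keep the class with a
`long` marker).

A deterministic synthetic-data module generates probe layouts,
piecewise-constant transcript signal with Gaussian M-noise, and toy GenBank
annotations with known ground truth, so the whole pipeline is testable
without array downloads.

## Worked example

```r
library(chipsad)
library(dplyr)

# two simulated experiments: an induced transcript (M = +2) at 3001-5000
# and a repressed one (M = -1.5) at 9001-9500, noise SD 0.25
cfg <- simulation_config(genome_length = 20000, noise_sd = 0.25, seed = 7,
                         n_experiments = 2)
truth <- tibble::tibble(replicon = "chr", strand = "+",
                        start = c(3001L, 9001L), end = c(5000L, 9500L),
                        level_M = c(2, -1.5))
sim <- simulate_experiments(simulate_layout(cfg), truth, cfg)

# stage 1: segment one experiment
sas <- chipsad(filter(sim$probes, experiment_id == "exp1"))
sas
#> <chipsad_sas> 7 signal areas across 2 track(s)
#> # A tibble: 7 × 8
#>   sas_id       experiment_id replicon strand start   end n_probes pseudomedian_M
#>   <chr>        <chr>         <chr>    <chr>  <int> <int>    <int>          <dbl>
#> 1 exp1:chr+:1… exp1          chr      +          1  3035      302      -0.000970
#> 2 exp1:chr+:3… exp1          chr      +       3021  4985      195       2.02
#> 3 exp1:chr+:4… exp1          chr      +       4971  8975      399      -0.0147
#> ...
```

Both true transcripts come back with the right boundaries (to probe
resolution) and levels (M̄ 2.02 and −1.33); the rest of both strands is
background near M̄ 0.

```r
# stage 2: align the two experiments (filter background first)
pooled <- bind_rows(lapply(split(sim$probes, sim$probes$experiment_id),
                           \(p) tibble::as_tibble(chipsad(p))))
cons <- align_experiments(pooled, min_abs_M = 1)
cons
#> <chipsad_consensus> 2 consensus transcript(s)
#>   consensus_id      replicon strand start   end n_members pseudomedian_M
#> 1 c1:chr+:3011-4995 chr      +       3011  4995         2           1.97
#> 2 c2:chr+:9001-9510 chr      +       9001  9510         2          -1.38

# stage 3: classify against a toy annotation (two ORFs under transcript 1)
orfs <- tibble::tibble(locus_tag = c("NMB0001", "NMB0002"), replicon = "chr",
                       strand = "+", start = c(3101L, 3901L),
                       end = c(3800L, 4800L))
annotate_all(cons, orfs)
#> <chipsad_annotation> 2 classified transcript(s)
#>   transcript_class     n
#> 1 orf                  0
#> 2 operon               1
#> 5 intergenic           1
#> ...
```

The consensus transcript spanning both co-oriented ORFs is called an
**operon**; the ORF-free repressed transcript is an **intergenic** RNA.
`tidy()`/`glance()` give plain tibbles, `autoplot()` draws the segmentation,
t profile, consensus matrix or class summary, and `write_transcripts()`
emits GFF3 / BED6 / TSV.

The same pipeline runs from the shell via the installed script
(`system.file("scripts", "chipsad", package = "chipsad")`) with subcommands
`segment`, `align`, `annotate`, `simulate` and `run-all`, or in one call
from R:

```r
run_all(probe_files, genbank_file, out_dir,
        config = list(alignment = list(min_abs_M = 1)))
```

which writes every intermediate (per-experiment SAS, consensus + M matrix,
classified transcripts + class summary) and a JSON run manifest.

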