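# Synthetic fixtures: probe layouts, piecewise-constant transcript signal and
# toy annotations with known ground truth. All randomness is drawn inside
# with_seed() so a config reproduces its output exactly.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Study conditions for the synthetic fixtures. Defaults describe a small
#' bacterial replicon probed by a two-color array: a 50 kb genome, 25-mer
#' probes tiled every 10 bp (or a non-tiling layout with geometric-like gaps
#' of mean 25 bp), log-ratio noise of SD 0.25, transcripts at M = 2 (a
#' four-fold change) over a zero baseline, five experiments whose true
#' boundaries jitter by up to 20 bp and whose levels wobble by SD 0.1.
#'
#' @param genome_length Genome length in bp.
#' @param layout `"tiling"` or `"nontiling"`.
#' @param step Tiling step in bp.
#' @param probe_length Probe length in bp.
#' @param mean_gap Mean inter-probe gap for the non-tiling layout (bp).
#' @param gap_dispersion Dispersion of the non-tiling gap distribution
#'   (negative-binomial size; 1 = geometric-like).
#' @param noise_sd Gaussian noise SD on the M (log2-ratio) scale.
#' @param baseline_M Background M level.
#' @param level_M Default transcript M level above baseline.
#' @param n_experiments Number of experiments for multi-experiment fixtures.
#' @param boundary_jitter_bp Max per-experiment shift of true boundaries.
#' @param level_jitter_sd Per-experiment SD of the transcript level wobble.
#' @param seed Integer seed; fully determines all randomness.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 50000,
                              layout = c("tiling", "nontiling"),
                              step = 10, probe_length = 25,
                              mean_gap = 25, gap_dispersion = 1,
                              noise_sd = 0.25, baseline_M = 0, level_M = 2,
                              n_experiments = 5, boundary_jitter_bp = 20,
                              level_jitter_sd = 0.1, seed = 1) {
  layout <- match.arg(layout)
  if (genome_length <= 0) abort("genome_length must be positive")
  if (layout == "tiling" && step >= genome_length) {
    abort("tiling step must be smaller than the genome")
  }
  if (layout == "nontiling" && mean_gap >= genome_length) {
    abort("mean_gap must be smaller than the genome")
  }
  structure(list(genome_length = genome_length, layout = layout, step = step,
                 probe_length = probe_length, mean_gap = mean_gap,
                 gap_dispersion = gap_dispersion, noise_sd = noise_sd,
                 baseline_M = baseline_M, level_M = level_M,
                 n_experiments = n_experiments,
                 boundary_jitter_bp = boundary_jitter_bp,
                 level_jitter_sd = level_jitter_sd, seed = seed),
            class = "simulation_config")
}

#' Simulate a probe layout
#'
#' Tiling layouts place a probe every `step` bp; non-tiling layouts draw
#' inter-probe gaps from a negative-binomial (geometric-like for
#' `gap_dispersion = 1`) distribution with the configured mean. Probe
#' coordinates are 1-based inclusive; the same layout serves both strands.
#'
#' @param config [simulation_config()].
#' @return Tibble: `probe_id`, `start`, `end`.
#' @export
simulate_layout <- function(config) {
  starts <- if (config$layout == "tiling") {
    seq.int(1L, config$genome_length - config$probe_length + 1L,
            by = config$step)
  } else {
    with_seed(config$seed, {
      gaps <- pmax(1L, stats::rnbinom(
        n = ceiling(2 * config$genome_length / config$mean_gap),
        mu = config$mean_gap, size = config$gap_dispersion))
      s <- cumsum(c(1L, gaps))
      s[s <= config$genome_length - config$probe_length + 1L]
    })
  }
  tibble::tibble(probe_id = sprintf("p%05d", seq_along(starts)),
                 start = as.integer(starts),
                 end = as.integer(starts + config$probe_length - 1L))
}

#' Simulate probe signal over known transcripts
#'
#' Probes inside a transcript (probe start within the transcript interval, on
#' the transcript's strand) take `baseline_M + level_M`, all others
#' `baseline_M`; Gaussian noise of SD `noise_sd` is added on top. Both
#' strands of the layout are emitted.
#'
#' @param layout Probe layout tibble from [simulate_layout()].
#' @param transcripts Tibble of true transcripts: `replicon`, `strand`,
#'   `start`, `end`, `level_M` (and optionally `label`).
#' @param config [simulation_config()].
#' @param experiment_id Experiment label for the output probes.
#' @param replicon Replicon name.
#' @param seed Seed for the noise draw (defaults to `config$seed`).
#' @return List with `probes` (tidy probe tibble with `M`) and `truth` (the
#'   transcript tibble used).
#' @export
simulate_signal <- function(layout, transcripts, config,
                            experiment_id = "exp1", replicon = "chr",
                            seed = config$seed) {
  probes <- dplyr::bind_rows(
    dplyr::mutate(layout, strand = "+"),
    dplyr::mutate(layout, strand = "-")
  ) |>
    dplyr::mutate(experiment_id = experiment_id, replicon = replicon,
                  M = config$baseline_M)
  for (i in seq_len(nrow(transcripts))) {
    tr <- transcripts[i, ]
    inside <- probes$strand == tr$strand & probes$replicon == tr$replicon &
      probes$start >= tr$start & probes$start <= tr$end
    probes$M[inside] <- probes$M[inside] + tr$level_M
  }
  if (config$noise_sd > 0) {
    probes$M <- probes$M +
      with_seed(seed, stats::rnorm(nrow(probes), 0, config$noise_sd))
  }
  probes <- probes |>
    dplyr::select(dplyr::all_of(c("experiment_id", "replicon", "strand",
                                  "probe_id", "start", "end", "M"))) |>
    dplyr::arrange(.data$strand, .data$start)
  list(probes = tibble::as_tibble(probes), truth = transcripts)
}

#' Simulate a multi-experiment fixture
#'
#' Replays [simulate_signal()] for `n_experiments` experiments; each
#' experiment shifts the true transcript boundaries by an integer drawn
#' uniformly from \[-boundary_jitter_bp, boundary_jitter_bp\] and wobbles the
#' transcript level by `N(0, level_jitter_sd)`, emulating the same loci
#' measured on different arrays.
#'
#' @inheritParams simulate_signal
#' @return List with `probes` (all experiments bound together) and `truth`
#'   (per-experiment true transcripts, with an `experiment_id` column).
#' @export
simulate_experiments <- function(layout, transcripts, config,
                                 replicon = "chr") {
  all_probes <- list(); all_truth <- list()
  for (e in seq_len(config$n_experiments)) {
    eid <- sprintf("exp%d", e)
    seed_e <- config$seed + 1000L * e
    tr <- with_seed(seed_e, {
      j <- config$boundary_jitter_bp
      transcripts |>
        dplyr::mutate(
          start = pmax(1L, .data$start +
                         sample.int(2L * j + 1L, dplyr::n(), replace = TRUE) -
                         j - 1L),
          end = pmin(config$genome_length, .data$end +
                       sample.int(2L * j + 1L, dplyr::n(), replace = TRUE) -
                       j - 1L),
          level_M = .data$level_M +
            stats::rnorm(dplyr::n(), 0, config$level_jitter_sd))
    })
    sim <- simulate_signal(layout, tr, config, experiment_id = eid,
                           replicon = replicon, seed = seed_e + 1L)
    all_probes[[e]] <- sim$probes
    all_truth[[e]] <- dplyr::mutate(tr, experiment_id = eid)
  }
  list(probes = dplyr::bind_rows(all_probes),
       truth = dplyr::bind_rows(all_truth))
}

#' Simulate a toy annotation with known classification ground truth
#'
#' The `one_per_class` scenario engineers one locus for each classifier
#' outcome: an operon pair, a convergent ORF pair bridged across a 20 bp gap,
#' a plain sense ORF, an ORF with a long 5' extension, an antisense ORF, a
#' short ORF-free region and a long (>= 800 bp) ORF-free region. The
#' `random` scenario draws randomized instances of the same constructions
#' (positions, strands and which UTR end is extended vary; the expected label
#' is still known by construction).
#'
#' @param config [simulation_config()] (the seed drives the random scenario).
#' @param scenario `"one_per_class"` or `"random"`.
#' @param replicon Replicon name.
#' @return List: `orfs` (ORF tibble), `sas` (SAS tibble positioned to trigger
#'   each rule; doubles as the true transcript table for signal simulation),
#'   `expected` (tibble `sas_id`, `label`), `genome_length`.
#' @export
simulate_annotation <- function(config = simulation_config(),
                                scenario = c("one_per_class", "random"),
                                replicon = "chr") {
  scenario <- match.arg(scenario)
  if (scenario == "one_per_class") {
    loci <- one_per_class_loci(offset = 0L, strand = "+", utr_end = "utr5",
                               replicon = replicon)
  } else {
    loci <- with_seed(config$seed, {
      offsets <- cumsum(sample.int(2000L, 7L) + 2000L)
      specs <- purrr::pmap(list(seq_len(7), offsets), function(i, off) {
        one_locus(i, offset = off,
                  strand = sample(c("+", "-"), 1),
                  utr_end = sample(c("utr5", "utr3"), 1),
                  replicon = replicon)
      })
      combine_loci(specs)
    })
  }
  genome_length <- max(loci$orfs$end, loci$sas$end) + 2000L
  loci$genome_length <- genome_length
  loci
}

# Locus blueprints. Each returns orfs / sas / expected for one rule, placed
# at `offset`; margins are generous so segmentation-recovered boundaries
# (within ~ one probe step) still classify identically.
one_locus <- function(rule, offset, strand, utr_end, replicon) {
  other <- if (strand == "+") "-" else "+"
  orf <- function(tag, s, e, str) {
    tibble::tibble(locus_tag = tag, replicon = replicon, strand = str,
                   start = as.integer(offset + s), end = as.integer(offset + e))
  }
  sas <- function(s, e, str) {
    tibble::tibble(replicon = replicon, strand = str,
                   start = as.integer(offset + s), end = as.integer(offset + e))
  }
  id <- sprintf("locus%d", rule)
  res <- switch(
    rule,
    # 1: operon — two co-oriented ORFs fully covered
    list(orfs = dplyr::bind_rows(orf(paste0(id, "a"), 100, 700, strand),
                                 orf(paste0(id, "b"), 800, 1400, strand)),
         sas = sas(50, 1450, strand), label = "operon"),
    # 2: overlapping UTR — convergent pair, 20 bp intergenic gap, SAS
    #    bridges the gap with sub-threshold overlap of both ORFs
    list(orfs = dplyr::bind_rows(orf(paste0(id, "a"), 100, 700, strand),
                                 orf(paste0(id, "b"), 721, 1300, other)),
         sas = sas(650, 790, strand), label = "overlapping_utr"),
    # 3: plain ORF — SAS inset within the ORF so boundaries recovered at
    #    probe resolution stay well inside the 30-base UTR gate
    list(orfs = orf(id, 100, 1000, strand),
         sas = sas(120, 980, strand), label = "orf"),
    # 4: UTR — 300-base extension beyond the requested biological end
    {
      ext_low <- (strand == "+") == (utr_end == "utr5")
      list(orfs = orf(id, 400, 1300, strand),
           sas = if (ext_low) sas(100, 1310, strand) else sas(390, 1600, strand),
           label = utr_end)
    },
    # 5: antisense — SAS covers most of an opposite-strand ORF
    list(orfs = orf(id, 100, 1000, other),
         sas = sas(200, 800, strand), label = "antisense"),
    # 6: short intergenic RNA (401 bases, no ORF anywhere near)
    list(orfs = NULL, sas = sas(100, 500, strand), label = "intergenic"),
    # 7: long ORF-free region (901 bases)
    list(orfs = NULL, sas = sas(100, 1000, strand), label = "intergenic_long")
  )
  res
}

one_per_class_loci <- function(offset, strand, utr_end, replicon) {
  specs <- purrr::map(seq_len(7), function(i) {
    one_locus(i, offset = offset + (i - 1L) * 4000L, strand = strand,
              utr_end = utr_end, replicon = replicon)
  })
  combine_loci(specs)
}

combine_loci <- function(specs) {
  orfs <- dplyr::bind_rows(purrr::map(specs, "orfs"))
  sas <- dplyr::bind_rows(purrr::map(specs, "sas")) |>
    dplyr::mutate(level_M = 2, pseudomedian_M = 2,
                  sas_id = sprintf("sim%02d", dplyr::row_number()))
  expected <- tibble::tibble(sas_id = sas$sas_id,
                             label = purrr::map_chr(specs, "label"))
  list(orfs = orfs, sas = sas, expected = expected)
}
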