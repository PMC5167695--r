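# In-code fixtures and independent oracles shared across the test files.

# a single-track probe tibble from starts and M values
make_track <- function(starts, M, strand = "+", probe_len = 25L,
                       experiment_id = "exp1", replicon = "chr") {
  tibble::tibble(
    experiment_id = experiment_id, replicon = replicon, strand = strand,
    probe_id = sprintf("p%04d", seq_along(starts)),
    start = as.integer(starts), end = as.integer(starts + probe_len - 1L),
    M = as.numeric(M)
  )
}

# a minimal SAS row for alignment/annotation tests
make_sas <- function(start, end, M, experiment_id = "exp1", strand = "+",
                     replicon = "chr", probe_M = NULL) {
  tibble::tibble(
    experiment_id = experiment_id, replicon = replicon, strand = strand,
    start = as.integer(start), end = as.integer(end),
    n_probes = if (is.null(probe_M)) 1L else lengths(probe_M),
    pseudomedian_M = as.numeric(M),
    probe_M = probe_M %||% as.list(as.numeric(M))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# brute-force Hodges-Lehmann oracle: explicit double loop over Walsh pairs
walsh_median_oracle <- function(v) {
  n <- length(v)
  walsh <- numeric(n * (n + 1) / 2)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      k <- k + 1L
      walsh[k] <- (v[i] + v[j]) / 2
    }
  }
  stats::median(walsh)
}

# independent pooled-scatter t oracle, written from the formula with var()
sam_t_oracle <- function(left_vals, right_vals, s0) {
  nl <- length(left_vals); nr <- length(right_vals)
  ss_l <- stats::var(left_vals) * (nl - 1)
  ss_r <- stats::var(right_vals) * (nr - 1)
  s <- sqrt((1 / nl + 1 / nr) * (ss_l + ss_r) / (nl + nr - 2))
  (mean(right_vals) - mean(left_vals)) / (s + s0)
}

# per-base interval overlap fraction oracle
overlap_frac_oracle <- function(sas_start, sas_end, orf_start, orf_end) {
  sum(seq(orf_start, orf_end) %in% seq(sas_start, sas_end)) /
    (orf_end - orf_start + 1)
}

# interval Jaccard on 1-based inclusive coordinates
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2) + 1)
  inter / (max(e1, e2) - min(s1, s2) + 1)
}

# the noiseless three-transcript tiling fixture (7 expected segments:
# 3 transcripts + 4 background)
three_transcript_truth <- function() {
  tibble::tibble(replicon = "chr", strand = "+",
                 start = c(3001L, 8001L, 14001L),
                 end = c(4500L, 9800L, 16000L),
                 level_M = 2)
}

simulate_three_transcripts <- function(seed = 1, noise_sd = 0,
                                       genome_length = 20000) {
  cfg <- simulation_config(genome_length = genome_length, noise_sd = noise_sd,
                           seed = seed)
  lay <- simulate_layout(cfg)
  sim <- simulate_signal(lay, three_transcript_truth(), cfg)
  dplyr::filter(sim$probes, strand == "+")
}
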