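test_that("pseudomedian matches hand-derived Walsh medians and the oracle", {
  expect_equal(pseudomedian(7), 7)
  expect_equal(pseudomedian(c(1, 2, 3)), 2)
  expect_equal(pseudomedian(c(0, 0, 10)), 2.5)
  expect_error(pseudomedian(numeric(0)), "empty")

  set.seed(101)
  for (i in 1:200) {
    v <- rnorm(sample(1:50, 1), sd = sample(c(0.1, 1, 10), 1))
    expect_identical(pseudomedian(v), walsh_median_oracle(v))
  }
})

test_that("pseudomedian is translation-equivariant", {
  set.seed(102)
  for (i in 1:50) {
    v <- rnorm(sample(2:30, 1))
    c0 <- runif(1, -100, 100)
    expect_equal(pseudomedian(v + c0), pseudomedian(v) + c0, tolerance = 1e-12)
  }
})

test_that("the generalized t matches hand computations and an oracle", {
  mk_side <- function(vals) {
    n <- length(vals)
    list(idx = seq_len(n), n = n, mean = mean(vals),
         ss = sum((vals - mean(vals))^2),
         sd = stats::sd(vals), degenerate = n < 2)
  }
  # identical sides: zero numerator
  expect_equal(sam_t(mk_side(c(1, 1, 2)), mk_side(c(2, 1, 1)), 0.5), 0)
  # zero-scatter sides: t = difference / s0
  expect_equal(sam_t(mk_side(c(0, 0, 0)), mk_side(c(2, 2, 2)), 0.5), 4)
  # antisymmetry under swapping sides
  set.seed(103)
  for (i in 1:50) {
    l <- rnorm(sample(2:10, 1)); r <- rnorm(sample(2:10, 1))
    expect_equal(sam_t(mk_side(l), mk_side(r), 0.1),
                 -sam_t(mk_side(r), mk_side(l), 0.1), tolerance = 1e-12)
    expect_equal(sam_t(mk_side(l), mk_side(r), 0.1),
                 sam_t_oracle(l, r, 0.1), tolerance = 1e-12)
  }
  # worked example: left {0,2}, right {1,3}
  expect_equal(sam_t(mk_side(c(0, 2)), mk_side(c(1, 3)), 0.1),
               sam_t_oracle(c(0, 2), c(1, 3), 0.1))
  # degenerate side yields no value
  expect_true(is.na(sam_t(list(degenerate = TRUE), mk_side(c(1, 2)), 0.1)))
})

test_that("CPR windows expand over constant signal and stop at steps", {
  params <- segmentation_params(w = 10, m_w = 2, s0 = 0.1,
                                max_window_expansion = 100)
  # constant signal: both sides expand to the span cap with sd 0
  const <- make_track(seq(1, 491, by = 10), rep(1, 50))
  pair <- build_cpr_pair(const, 25, params)
  expect_equal(pair$left$mean, 1); expect_equal(pair$right$mean, 1)
  expect_equal(pair$left$sd, 0)
  expect_equal(pair$left$span, 100); expect_equal(pair$right$span, 100)

  # step signal, anchor at the step: sides stay pure
  step <- make_track(seq(1, 491, by = 10), rep(c(0, 2), each = 25))
  pair <- build_cpr_pair(step, 26, params)
  expect_equal(pair$left$mean, 0)
  expect_equal(pair$right$mean, 2)
  expect_equal(pair$left$sd, 0); expect_equal(pair$right$sd, 0)

  # a 3w probe desert on the left with a tight span cap: degenerate side
  tight <- segmentation_params(w = 10, m_w = 2, s0 = 0.1,
                               max_window_expansion = 20)
  gappy <- make_track(c(1, 11, 21, 51, 61, 71, 81), rep(1, 7))
  pair <- build_cpr_pair(gappy, 4, tight)   # anchor at 51; gap 30 = 3w left
  expect_true(pair$left$degenerate)
  expect_false(pair$right$degenerate)
})

test_that("t profiles are flat on constant tracks and peak at a step", {
  const <- make_track(seq(1, 991, by = 10), rep(1, 100))
  prof <- t_profile(const, segmentation_params(s0 = 0.1))
  expect_true(all(prof$t == 0))

  step_M <- rep(c(0, 2), each = 50)
  step <- make_track(seq(1, 991, by = 10), step_M)
  prof <- t_profile(step, segmentation_params(s0 = 0.1))
  expect_equal(prof$x[which.max(abs(prof$t))], 501)  # first high probe

  # a 3-probe track yields an empty profile
  tiny <- make_track(c(1, 11, 21), c(0, 0, 2))
  expect_equal(nrow(t_profile(tiny, segmentation_params(w = 10, m_w = 2))), 0)
})

test_that("change-point calling collapses runs to their strongest anchor", {
  prof <- tibble::tibble(x = seq(10, 100, by = 10),
                         t = c(0, 1, 4, 5, 3.5, 0.5, -4, -4, 0, 0),
                         anchor_index = 1:10, s = 0.1)
  cps <- detect_change_points(prof, 3)
  expect_equal(cps$x, c(40, 70))        # max |t| per run; leftmost on ties
  expect_equal(cps$t_value, c(5, -4))
  expect_equal(nrow(detect_change_points(prof, 10)), 0)
  expect_equal(nrow(detect_change_points(prof[0, ], 3)), 0)
})

test_that("tiling assembly partitions probes between change points", {
  track <- make_track(seq(1, 191, by = 10), c(rep(0, 10), rep(2, 10)))
  # no change points: a single SAS covering every probe
  one <- segment_tiling(track, tibble::tibble(x = integer(0)))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_probes, 20)
  expect_equal(one$start, 1); expect_equal(one$end, 215)

  # one change point at the step: two SAS partitioning the probes
  two <- segment_tiling(track, tibble::tibble(x = 101L))
  expect_equal(nrow(two), 2)
  expect_equal(two$n_probes, c(10, 10))
  expect_equal(two$pseudomedian_M, c(0, 2))
  expect_equal(two$start, c(1, 101))

  # pathological: every probe its own region
  all_cp <- tibble::tibble(x = track$start[-1])
  shredded <- segment_tiling(track, all_cp)
  expect_equal(nrow(shredded), nrow(all_cp) + 1)
})

test_that("the non-tiling merge joins same-level regions and keeps contrasts", {
  # identical adjacent regions always join (transitively)
  track <- make_track(seq(1, 291, by = 10), rep(2, 30))
  cps <- tibble::tibble(x = c(101L, 201L))
  merged <- segment_nontiling(track, cps)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$pseudomedian_M, 2)

  # PM 0.1 vs -0.1 with union PM ~ 0: |0| > 0.2 is false -> split
  track2 <- make_track(seq(1, 191, by = 10), rep(c(0.1, -0.1), each = 10))
  split <- segment_nontiling(track2, tibble::tibble(x = 101L))
  expect_equal(nrow(split), 2)

  # background vs transcript stays split: |PM(union)| < |0 - 2|
  track3 <- make_track(seq(1, 191, by = 10), rep(c(0, 2), each = 10))
  kept <- segment_nontiling(track3, tibble::tibble(x = 101L))
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pseudomedian_M, c(0, 2))
})

test_that("noiseless segmentation recovers true boundaries at probe resolution", {
  probes <- simulate_three_transcripts(seed = 1, noise_sd = 0)
  truth <- three_transcript_truth()
  sas <- chipsad(probes)
  expect_equal(nrow(sas), 7)
  transcript_sas <- dplyr::filter(tibble::as_tibble(sas), pseudomedian_M > 1)
  expect_equal(nrow(transcript_sas), 3)
  step <- 10
  expect_true(all(abs(transcript_sas$start - truth$start) <= step))
  # SAS end = last probe end; allow the probe-length overhang plus one step
  expect_true(all(abs(transcript_sas$end - truth$end) <= 25 + step))
})

test_that("SAS within a track are probe-disjoint and cover every probe once", {
  for (seed in 1:3) {
    probes <- simulate_three_transcripts(seed = seed, noise_sd = 0.25)
    sas <- chipsad(probes)
    covered <- sort(unlist(lapply(sas$probe_M, length)))
    expect_equal(sum(covered), nrow(probes))
    expect_equal(sum(sas$n_probes), nrow(probes))
    # boundaries are ordered and non-overlapping in probe space
    expect_true(all(diff(sas$start) > 0))
  }
})

test_that("the tiling and non-tiling paths agree on well-separated levels", {
  probes <- simulate_three_transcripts(seed = 5, noise_sd = 0)
  tiling <- chipsad(probes, segmentation_params(layout = "tiling"))
  nontiling <- chipsad(probes, segmentation_params(layout = "nontiling"))
  expect_equal(nrow(nontiling), nrow(tiling))
  expect_equal(nontiling$start, tiling$start)
  expect_equal(nontiling$end, tiling$end)
})

test_that("auto layout detection follows inter-probe gap dispersion", {
  probes <- simulate_three_transcripts(seed = 1, noise_sd = 0)
  sas <- chipsad(probes)
  expect_equal(attr(sas, "tracks")$layout, "tiling")

  set.seed(7)
  thin <- probes[sort(sample.int(nrow(probes), round(0.4 * nrow(probes)))), ]
  sas_thin <- chipsad(thin)
  expect_equal(attr(sas_thin, "tracks")$layout, "nontiling")
})

test_that("an all-noise track yields a single near-baseline SAS", {
  set.seed(42)
  track <- make_track(seq(1, 4991, by = 10), rnorm(500, 0, 0.25))
  sas <- chipsad(track)
  expect_equal(nrow(sas), 1)
  expect_lt(abs(sas$pseudomedian_M), 0.25)
})

test_that("empty and undersized tracks are handled gracefully", {
  expect_equal(nrow(chipsad(make_track(integer(0), numeric(0)))), 0)
  small <- chipsad(make_track(c(1, 11, 21), c(0, 0, 0)),
                   segmentation_params(w = 10, m_w = 2))
  expect_equal(nrow(small), 1)   # no callable anchors -> one SAS
})

test_that("tidy and glance summarize a segmentation result", {
  sas <- chipsad(simulate_three_transcripts(seed = 1, noise_sd = 0))
  td <- tidy(sas)
  expect_s3_class(td, "tbl_df")
  expect_false("probe_M" %in% names(td))
  g <- glance(sas)
  expect_equal(g$n_sas, 7L)
  expect_equal(g$n_change_points, 6L)
})
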