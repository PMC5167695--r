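test_that("the pseudomedian filter keeps strong SAS on both signs", {
  sas <- dplyr::bind_rows(make_sas(100, 200, -1.5),
                          make_sas(300, 400, 0.3),
                          make_sas(500, 600, 1.2))
  expect_equal(nrow(filter_by_pseudomedian(sas, 0)), 3)    # identity at 0
  kept <- filter_by_pseudomedian(sas, 1)
  expect_equal(kept$pseudomedian_M, c(-1.5, 1.2))          # absolute value
})

test_that("overlap edges require shared bases on the same strand and replicon", {
  sas <- dplyr::bind_rows(
    make_sas(100, 200, 1, experiment_id = "a"),
    make_sas(100, 200, 1, experiment_id = "b"),
    make_sas(201, 300, 1, experiment_id = "a"),   # adjacency is not overlap
    make_sas(150, 250, 1, experiment_id = "c", strand = "-"))
  g <- build_overlap_graph(sas)
  expect_equal(g$component[1], g$component[2])
  expect_false(g$component[3] == g$component[1])
  expect_false(g$component[4] == g$component[1])

  # transitive chaining: A overlaps B, B overlaps C, A does not touch C
  chain <- dplyr::bind_rows(
    make_sas(100, 200, 1, experiment_id = "a"),
    make_sas(180, 320, 1, experiment_id = "b"),
    make_sas(300, 400, 1, experiment_id = "c"))
  gc <- build_overlap_graph(chain)
  expect_equal(length(unique(gc$component)), 1)
})

test_that("consensus boundaries follow the M-weighted average formula", {
  members <- dplyr::bind_rows(
    make_sas(100, 500, 1, experiment_id = "a"),
    make_sas(200, 600, 3, experiment_id = "b"))
  cons <- consensus_boundaries(members)
  expect_equal(cons$start, 175L)                 # p = {0.25, 0.75}
  expect_equal(cons$end, 575L)
  expect_equal(sum(cons$weights[[1]]), 1, tolerance = 1e-12)

  # equal weights -> arithmetic mean of boundaries
  eq <- dplyr::bind_rows(make_sas(100, 400, 2, experiment_id = "a"),
                         make_sas(200, 500, 2, experiment_id = "b"),
                         make_sas(300, 600, 2, experiment_id = "c"))
  expect_equal(consensus_boundaries(eq)$start, 200L)

  # all-zero pseudomedians fall back to uniform weights, with a message
  zero <- dplyr::bind_rows(make_sas(100, 400, 0, experiment_id = "a"),
                           make_sas(300, 600, 0, experiment_id = "b"))
  expect_message(cz <- consensus_boundaries(zero), "uniform")
  expect_equal(cz$start, 200L)

  # consensus stays within the convex hull of member boundaries
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:6, 1)
    starts <- sort(sample.int(1000, n))
    members <- make_sas(starts, starts + sample.int(500, n), runif(n, -3, 3),
                        experiment_id = letters[seq_len(n)])
    cc <- consensus_boundaries(members)
    expect_gte(cc$start, min(members$start))
    expect_lte(cc$start, max(members$start))
    expect_gte(cc$end, min(members$end))
    expect_lte(cc$end, max(members$end))
    expect_equal(sum(cc$weights[[1]]), 1, tolerance = 1e-12)
  }
})

test_that("an experiment contributing several SAS is summarized over its probes", {
  members <- dplyr::bind_rows(
    make_sas(100, 300, 1, experiment_id = "a", probe_M = list(c(0.8, 1.0, 1.2))),
    make_sas(250, 500, 2, experiment_id = "a", probe_M = list(c(1.8, 2.0, 2.2))),
    make_sas(120, 480, 1.5, experiment_id = "b", probe_M = list(c(1.4, 1.5, 1.6))))
  cons <- consensus_boundaries(members)
  m <- cons$per_experiment_M[[1]]
  expect_equal(unname(m["a"]),
               pseudomedian(c(0.8, 1.0, 1.2, 1.8, 2.0, 2.2)))
  expect_equal(unname(m["b"]), 1.5)
})

test_that("aligning experiments yields one consensus per overlap component", {
  sas <- dplyr::bind_rows(
    make_sas(100, 500, 2, experiment_id = "a"),
    make_sas(120, 520, 2.2, experiment_id = "b"),
    make_sas(2000, 2400, -1.5, experiment_id = "a"),
    make_sas(2050, 2380, -1.2, experiment_id = "b"))
  cons <- align_experiments(sas)
  expect_equal(nrow(cons), 2)
  expect_equal(cons$n_members, c(2L, 2L))
  # single-experiment input: consensus = its own SAS list
  single <- align_experiments(make_sas(100, 500, 2))
  expect_equal(single$start, 100L)
  expect_equal(single$end, 500L)
  # empty input
  expect_equal(nrow(align_experiments(make_sas(100, 200, 1)[0, ])), 0)
})

test_that("aligning identical experiment copies returns the single-run result", {
  probes <- simulate_three_transcripts(seed = 3, noise_sd = 0)
  sas <- tibble::as_tibble(chipsad(probes))
  strong <- dplyr::filter(sas, abs(pseudomedian_M) >= 1)
  copies <- dplyr::bind_rows(lapply(1:4, function(k) {
    dplyr::mutate(strong, experiment_id = paste0("copy", k))
  }))
  cons <- align_experiments(copies)
  expect_equal(nrow(cons), nrow(strong))
  expect_equal(cons$start, strong$start)
  expect_equal(cons$end, strong$end)
})

test_that("alignment is idempotent and order-invariant", {
  cfg <- simulation_config(genome_length = 20000, noise_sd = 0.25, seed = 9,
                           n_experiments = 5)
  sim <- simulate_experiments(simulate_layout(cfg), three_transcript_truth(),
                              cfg)
  sas <- dplyr::bind_rows(lapply(split(sim$probes, sim$probes$experiment_id),
                                 function(p) tibble::as_tibble(chipsad(p))))
  strong <- dplyr::filter(sas, abs(pseudomedian_M) >= 1)
  cons <- align_experiments(strong)
  # one consensus per simulated locus per strand present
  expect_equal(nrow(cons), 3)
  # idempotence: aligning the consensus with itself changes nothing
  again <- align_experiments(dplyr::mutate(tibble::as_tibble(cons),
                                           experiment_id = "merged",
                                           probe_M = list(NULL)))
  expect_equal(again$start, cons$start)
  expect_equal(again$end, cons$end)
  # permuting experiment order leaves the component partition unchanged
  shuffled <- dplyr::arrange(strong, dplyr::desc(dplyr::row_number()))
  cons2 <- align_experiments(shuffled)
  expect_equal(cons2$start, cons$start)
  expect_equal(cons2$end, cons$end)
})

test_that("the fold-change gate applies log2 thresholds across experiments", {
  cons <- align_experiments(dplyr::bind_rows(
    make_sas(100, 500, 1.2, experiment_id = "a"),
    make_sas(110, 520, -1.4, experiment_id = "b"),
    make_sas(2000, 2400, 1.2, experiment_id = "a"),
    make_sas(2010, 2390, 0.4, experiment_id = "b")))
  kept <- select_differential(cons, c("a", "b"), min_fold_change = 2)
  expect_equal(nrow(kept), 1)            # (1.2, -1.4) passes; (1.2, 0.4) fails
  expect_equal(kept$start, cons$start[1])
  expect_error(select_differential(cons, "nope"), "absent")
  expect_error(select_differential(cons, "a", min_fold_change = 0.5), ">= 1")

  tf <- withr::local_tempfile(fileext = ".tsv")
  kept2 <- select_differential(cons, c("a", "b"), 2, matrix_path = tf)
  mat <- readr::read_tsv(tf, show_col_types = FALSE)
  expect_equal(nrow(mat), 1)
  expect_true(all(c("a", "b") %in% names(mat)))
})

test_that("the consensus matrix reports missing experiments as NA", {
  cons <- align_experiments(dplyr::bind_rows(
    make_sas(100, 500, 2, experiment_id = "a"),
    make_sas(120, 520, 2.1, experiment_id = "b"),
    make_sas(2000, 2300, 1.5, experiment_id = "a")))
  mat <- consensus_matrix(cons)
  expect_equal(nrow(mat), 2)
  expect_true(is.na(mat$b[mat$start == 2000]))
  expect_false(is.na(mat$a[mat$start == 2000]))
})
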