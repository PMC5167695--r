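#' Filter signal areas by absolute pseudomedian M
#'
#' Optional pre-alignment noise filter: keeps SAS with
#' `|pseudomedian_M| >= min_abs_M`. The default threshold 0 keeps everything.
#'
#' @param sas SAS tibble (from [chipsad()] or [read_transcripts()]).
#' @param min_abs_M Minimum absolute pseudomedian M (log2 units).
#' @return Filtered SAS tibble.
#' @export
filter_by_pseudomedian <- function(sas, min_abs_M = 0) {
  if (min_abs_M <= 0) return(sas)
  dplyr::filter(sas, abs(.data$pseudomedian_M) >= min_abs_M)
}

#' Build the cross-experiment SAS overlap graph
#'
#' Nodes are signal areas; an edge links two SAS on the same replicon and
#' strand whose 1-based inclusive intervals share at least one base.
#' Connected components group the SAS that describe the same transcribed
#' locus across experiments.
#'
#' @param sas SAS tibble pooled over experiments.
#' @return The input tibble with a `component` integer column; the igraph
#'   object is attached as attribute `graph`.
#' @export
build_overlap_graph <- function(sas) {
  n <- nrow(sas)
  if (n == 0) {
    out <- dplyr::mutate(sas, component = integer(0))
    return(out)
  }
  edges <- integer(0)
  keys <- split(seq_len(n), paste(sas$replicon, sas$strand, sep = "|"))
  for (ix in keys) {
    if (length(ix) < 2) next
    ord <- ix[order(sas$start[ix])]
    st <- sas$start[ord]; en <- sas$end[ord]
    # sweep: j overlaps i iff start_j <= end_i (sorted by start)
    for (a in seq_along(ord)[-length(ord)]) {
      b <- a + 1L
      while (b <= length(ord) && st[b] <= en[a]) {
        edges <- c(edges, ord[a], ord[b])
        b <- b + 1L
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  out <- dplyr::mutate(sas, component = as.integer(comp))
  attr(out, "graph") <- g
  out
}

#' Consensus boundaries of one overlap-graph component
#'
#' Boundaries of the consensus SAS are the weighted averages of the member
#' boundaries, `<x> = sum(p_i * x_i)` with weights
#' `p_i = |Mbar_i| / sum(|Mbar_j|)` (absolute values keep the weights in
#' \[0, 1\] for negative log-ratios), rounded to the nearest bp. If every
#' member has `Mbar = 0` the weights fall back to uniform. The per-experiment
#' M entry is the pseudomedian of the union of that experiment's member
#' probes (or of the member `Mbar` values when probe-level values are not
#' carried, e.g. for SAS read back from files).
#'
#' @param members SAS tibble: the members of one component (same replicon and
#'   strand).
#' @return One-row tibble: `replicon`, `strand`, `start`, `end`, `n_members`,
#'   `pseudomedian_M` (pseudomedian over all member probes), `member_ids`,
#'   `weights` and `per_experiment_M` (named list column).
#' @export
consensus_boundaries <- function(members) {
  if (nrow(members) == 0) abort("empty component")
  absm <- abs(members$pseudomedian_M)
  if (sum(absm) == 0) {
    inform("component with all-zero pseudomedians: using uniform weights")
    w <- rep(1 / nrow(members), nrow(members))
  } else {
    w <- absm / sum(absm)
  }
  per_exp <- members |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::group_map(function(rows, key) {
      vals <- if ("probe_M" %in% names(rows)) unlist(rows$probe_M) else NULL
      m <- if (length(vals) > 0) pseudomedian(vals) else
        pseudomedian(rows$pseudomedian_M)
      stats::setNames(m, key$experiment_id)
    }) |>
    unlist()
  all_vals <- if ("probe_M" %in% names(members)) unlist(members$probe_M) else NULL
  overall <- if (length(all_vals) > 0) pseudomedian(all_vals) else
    pseudomedian(members$pseudomedian_M)
  tibble::tibble(
    replicon = members$replicon[1],
    strand = members$strand[1],
    start = round_half_away(sum(w * members$start)),
    end = round_half_away(sum(w * members$end)),
    n_members = nrow(members),
    pseudomedian_M = overall,
    member_ids = list(if ("sas_id" %in% names(members)) members$sas_id else
      paste0(members$experiment_id, ":", members$start, "-", members$end)),
    weights = list(w),
    per_experiment_M = list(per_exp)
  )
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Align signal areas across experiments into consensus transcripts
#'
#' The multi-experiment alignment: optionally filters noisy SAS by
#' `min_abs_M`, builds the same-strand interval-overlap graph over the pooled
#' SAS, and collapses each connected component into one consensus SAS with
#' M-weighted boundaries ([consensus_boundaries()]).
#'
#' @param sas SAS tibble pooled over experiments (column `experiment_id`
#'   distinguishes them), e.g. `dplyr::bind_rows()` of per-experiment
#'   [chipsad()] results.
#' @param min_abs_M Optional pre-filter threshold on |pseudomedian M|.
#' @return A `chipsad_consensus` tibble sorted by replicon, strand, start:
#'   one row per consensus SAS with a `consensus_id` and the columns of
#'   [consensus_boundaries()].
#' @export
align_experiments <- function(sas, min_abs_M = 0) {
  kept <- filter_by_pseudomedian(sas, min_abs_M)
  empty <- tibble::tibble(consensus_id = character(0), replicon = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0), n_members = integer(0),
                          pseudomedian_M = numeric(0), member_ids = list(),
                          weights = list(), per_experiment_M = list())
  if (nrow(kept) == 0) {
    return(structure(empty, class = c("chipsad_consensus",
                                      class(tibble::tibble()))))
  }
  with_comp <- build_overlap_graph(kept)
  out <- with_comp |>
    dplyr::group_by(.data$component) |>
    dplyr::group_map(~ consensus_boundaries(.x)) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$replicon, .data$strand, .data$start) |>
    dplyr::mutate(consensus_id = paste0("c", dplyr::row_number(), ":",
                                        .data$replicon, .data$strand, ":",
                                        .data$start, "-", .data$end),
                  .before = 1)
  structure(out, class = c("chipsad_consensus", class(tibble::tibble())),
            min_abs_M = min_abs_M)
}

#' @export
tidy.chipsad_consensus <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::select(-dplyr::any_of(c("member_ids", "weights",
                                   "per_experiment_M")))
}

#' @export
glance.chipsad_consensus <- function(x, ...) {
  n_exp <- length(unique(unlist(lapply(x$per_experiment_M, names))))
  tibble::tibble(
    n_consensus = nrow(x),
    n_experiments = n_exp,
    mean_members = if (nrow(x)) mean(x$n_members) else NA_real_,
    min_abs_M = attr(x, "min_abs_M") %||% 0
  )
}

#' @export
print.chipsad_consensus <- function(x, ...) {
  cat("<chipsad_consensus> ", nrow(x), " consensus transcript(s)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Experiment-by-transcript matrix of pseudomedian M values
#'
#' Pivots a consensus table into the wide matrix behind the usual
#' transcript-expression heat map: one row per consensus transcript, one
#' column of pseudomedian M per experiment. Experiments that contributed no
#' SAS to a component are `NA` (missing, not "no change").
#'
#' @param consensus A `chipsad_consensus` tibble.
#' @return Tibble: `consensus_id`, `replicon`, `strand`, `start`, `end`, then
#'   one `M` column per experiment.
#' @export
consensus_matrix <- function(consensus) {
  base <- tidy(consensus) |>
    dplyr::select(dplyr::all_of(c("consensus_id", "replicon", "strand",
                                  "start", "end")))
  long <- purrr::map2_dfr(consensus$consensus_id, consensus$per_experiment_M,
                          function(id, m) {
                            tibble::tibble(consensus_id = id,
                                           experiment_id = names(m),
                                           M = unname(m))
                          })
  if (nrow(long) == 0) return(base)
  wide <- tidyr::pivot_wider(long, names_from = "experiment_id",
                             values_from = "M")
  dplyr::left_join(base, wide, by = "consensus_id")
}

#' Select differential consensus transcripts by fold change
#'
#' Keeps consensus transcripts whose absolute pseudomedian M is at least
#' `log2(min_fold_change)` in every named experiment (a transcript missing
#' from a named experiment does not pass). `min_fold_change = 2` is the usual
#' two-fold expression-change gate on the log2 scale.
#'
#' @param consensus A `chipsad_consensus` tibble.
#' @param experiments Character vector of experiment ids that must all pass
#'   the gate.
#' @param min_fold_change Minimum fold change (>= 1).
#' @param matrix_path Optional path: writes the experiment-by-transcript M
#'   matrix of the selected transcripts as TSV.
#' @return The selected subset of `consensus`.
#' @export
select_differential <- function(consensus, experiments,
                                min_fold_change = 2, matrix_path = NULL) {
  if (min_fold_change < 1) abort("min_fold_change must be >= 1")
  seen <- unique(unlist(lapply(consensus$per_experiment_M, names)))
  unknown <- setdiff(experiments, seen)
  if (length(unknown) > 0) {
    abort(paste0("experiment(s) absent from all members: ",
                 paste(unknown, collapse = ", ")))
  }
  thr <- log2(min_fold_change)
  pass <- vapply(consensus$per_experiment_M, function(m) {
    all(experiments %in% names(m)) && all(abs(m[experiments]) >= thr)
  }, logical(1))
  out <- consensus[pass, , drop = FALSE]
  class(out) <- class(consensus)
  if (!is.null(matrix_path)) {
    readr::write_tsv(consensus_matrix(out), matrix_path, progress = FALSE)
  }
  out
}
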