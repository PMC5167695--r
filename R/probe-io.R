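#' Read a probe table
#'
#' Reads a tab-separated probe table into a tidy probe tibble. The file must
#' have a header with columns `probe_id`, `replicon`, `strand`, `start`, `end`
#' and one or more signal columns: either a single `M` column (log2 ratio,
#' already replicate-merged) or replicate columns named `M_1`, `M_2`, ... (any
#' column whose name starts with `M` is treated as signal). An optional
#' `experiment_id` column labels the experiment; otherwise the file name
#' (without extension) is used.
#'
#' Probes are sorted by `start` within each (experiment, replicon, strand)
#' track; a duplicated `(start, end)` pair within a track is an error, as is a
#' non-numeric signal value (reported with its line number).
#'
#' @param path Path to a tab-separated probe file.
#' @param experiment_id Experiment label; defaults to the file name.
#' @return A tibble with one row per probe: `experiment_id`, `replicon`,
#'   `strand`, `probe_id`, `start`, `end` and the signal column(s). Coordinates
#'   are 1-based inclusive.
#' @seealso [merge_replicates()] to collapse replicate columns into `M`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("probe_id\treplicon\tstrand\tstart\tend\tM",
#'              "p1\tchr\t+\t1\t25\t0.5",
#'              "p2\tchr\t+\t11\t35\t0.7"), tf)
#' read_probe_table(tf)
read_probe_table <- function(path, experiment_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("probe table not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("probe_id", "replicon", "strand", "start", "end")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("probe table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  m_cols <- grep("^M($|_)", names(raw), value = TRUE)
  if (length(m_cols) == 0) {
    abort("probe table has no signal column (expected `M` or `M_1`, `M_2`, ...)")
  }

  # header is line 1, so data row i lives on file line i + 1
  check_numeric <- function(x, col) {
    bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad) > 0) {
      abort(paste0("non-numeric value in column `", col, "` at line ",
                   bad[1] + 1L, " of ", path))
    }
    as.numeric(x)
  }
  for (col in c("start", "end")) raw[[col]] <- check_numeric(raw[[col]], col)
  for (col in m_cols) raw[[col]] <- check_numeric(raw[[col]], col)

  bad_strand <- which(!raw$strand %in% c("+", "-"))
  if (length(bad_strand) > 0) {
    abort(paste0("invalid strand (must be + or -) at line ", bad_strand[1] + 1L,
                 " of ", path))
  }
  bad_coord <- which(raw$start > raw$end)
  if (length(bad_coord) > 0) {
    abort(paste0("start > end at line ", bad_coord[1] + 1L, " of ", path))
  }

  if (!"experiment_id" %in% names(raw)) {
    raw$experiment_id <- experiment_id %||%
      tools::file_path_sans_ext(basename(path))
  } else if (!is.null(experiment_id)) {
    raw$experiment_id <- experiment_id
  }

  probes <- raw |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    dplyr::select(dplyr::all_of(c("experiment_id", "replicon", "strand",
                                  "probe_id", "start", "end")),
                  dplyr::all_of(m_cols)) |>
    dplyr::arrange(.data$experiment_id, .data$replicon, .data$strand, .data$start,
                   .data$end)

  dup <- probes |>
    dplyr::count(.data$experiment_id, .data$replicon, .data$strand, .data$start,
                 .data$end) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate probe interval (start=", dup$start[1], ", end=",
                 dup$end[1], ") on ", dup$replicon[1], dup$strand[1],
                 " in ", path))
  }
  tibble::as_tibble(probes)
}

#' Write a probe table
#'
#' Inverse of [read_probe_table()]: writes the tidy probe tibble as TSV so the
#' round trip preserves every field.
#'
#' @param probes Probe tibble as returned by [read_probe_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  readr::write_tsv(probes, path, progress = FALSE)
  invisible(path)
}

#' Merge replicate signal columns into a single M value
#'
#' Applies a global normalization to each replicate column (subtracting the
#' column median within each experiment) and then averages the centered
#' replicates per probe, yielding one `M` (log2 ratio) column. Probes whose
#' replicates are all missing are dropped with a warning.
#'
#' Median-centering makes the merged M invariant to an additive offset in any
#' single replicate channel, which is the property the downstream segmentation
#' relies on.
#'
#' @param probes Probe tibble with one or more `M`/`M_*` signal columns.
#' @return Probe tibble with a single `M` column, same ordering.
#' @export
merge_replicates <- function(probes) {
  m_cols <- grep("^M($|_)", names(probes), value = TRUE)
  if (length(m_cols) == 0) abort("no signal column (`M` or `M_*`) to merge")
  if (identical(m_cols, "M")) return(probes)

  centered <- probes |>
    dplyr::group_by(.data$experiment_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(m_cols),
      ~ .x - stats::median(.x, na.rm = TRUE)
    )) |>
    dplyr::ungroup()

  M <- rowMeans(as.matrix(centered[m_cols]), na.rm = TRUE)
  out <- centered |>
    dplyr::select(-dplyr::all_of(m_cols)) |>
    dplyr::mutate(M = M)

  all_missing <- is.nan(out$M) | is.na(out$M)
  if (any(all_missing)) {
    warn(paste0("dropping ", sum(all_missing),
                " probe(s) with all replicate values missing"))
    out <- out[!all_missing, , drop = FALSE]
  }
  out
}

#' Estimate the initial window size w from probe spacing
#'
#' The segmentation window size `w` is the mean distance between consecutive
#' probe starts along a track, rounded up to an integer number of base pairs.
#' With several tracks the gaps are pooled per (experiment, replicon, strand)
#' track and averaged over all consecutive pairs.
#'
#' @param probes Probe tibble (>= 2 probes in at least one track).
#' @return Window size in bp (integer).
#' @export
estimate_window_size <- function(probes) {
  gaps <- probes |>
    dplyr::group_by(.data$experiment_id, .data$replicon, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(gap = list(diff(.data$start)), .groups = "drop") |>
    dplyr::pull(.data$gap) |>
    unlist()
  if (length(gaps) == 0) {
    abort("need at least two probes on one track to estimate the window size")
  }
  as.integer(ceiling(mean(gaps)))
}

#' Estimate m(w), the minimum number of probes per window
#'
#' Slides a window of width `w` across the track, anchored at every probe
#' start, and counts probes whose start falls in `[x, x + w)`. The minimum
#' count over all anchors is returned, floored at 2 (the t-statistic needs at
#' least two observations per side). With several tracks the minimum is taken
#' across tracks.
#'
#' @param probes Probe tibble.
#' @param w Window size in bp.
#' @return Minimum probe count per window (integer, >= 2).
#' @export
estimate_min_probes <- function(probes, w) {
  if (w <= 0) abort("window size w must be positive")
  counts <- probes |>
    dplyr::group_by(.data$experiment_id, .data$replicon, .data$strand) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(min_count = {
      s <- .data$start
      # anchors whose window fits inside the probed span; a truncated
      # window hanging off the track end would fake low density
      anchors <- s[s + w <= max(s) + 1]
      if (length(anchors) == 0) anchors <- s[1]
      # number of starts in [x, x + w) per anchor x, via sorted search
      min(findInterval(anchors + w - 1e-9, s) - findInterval(anchors - 1e-9, s))
    }, .groups = "drop") |>
    dplyr::pull(.data$min_count)
  max(2L, as.integer(min(counts)))
}
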