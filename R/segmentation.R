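#' Segmentation parameters
#'
#' Bundles the tunable parameters of the change-point segmentation. Parameters
#' left `NULL` are estimated from the data by [chipsad()]:
#' `w` as the mean inter-probe distance (ceiling), `m_w` as the minimum probe
#' count in any `w`-window (floored at 2), `s0` as the 5th percentile of the
#' pooled scatter `s` over all anchors (floored at 0.01, the SAM fudge-factor
#' role), and `max_window_expansion` as `10 * w`.
#'
#' @param w Initial window size in bp, or `NULL` to estimate from probe
#'   spacing.
#' @param m_w Minimum probes per window, or `NULL` to estimate; always >= 2.
#' @param s0 Fudge constant added to the pooled scatter in the t denominator
#'   (signal units), or `NULL` for the automatic percentile rule.
#' @param t_threshold Change-point threshold on |t| (dimensionless; default 3,
#'   i.e. three pooled-SD units of log-ratio noise).
#' @param k Window-expansion consistency factor: a probe joins a growing
#'   window only if it lies within `k * max(sd, s0)` of the window mean
#'   (default 3, the loosest standard outlier gate).
#' @param max_window_expansion Maximum span of one window side in bp, or
#'   `NULL` for `10 * w` (an unbounded window could swallow a transcript).
#' @param layout `"tiling"`, `"nontiling"`, or `"auto"` (tiling when the
#'   coefficient of variation of inter-probe gaps is below 0.2).
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(w = NULL, m_w = NULL, s0 = NULL,
                                t_threshold = 3, k = 3,
                                max_window_expansion = NULL,
                                layout = c("auto", "tiling", "nontiling")) {
  layout <- match.arg(layout)
  if (!is.null(w) && w <= 0) abort("w must be positive")
  if (!is.null(m_w) && m_w < 2) abort("m_w must be at least 2")
  if (!is.null(s0) && s0 <= 0) abort("s0 must be positive")
  if (t_threshold <= 0) abort("t_threshold must be positive")
  structure(
    list(w = w, m_w = m_w, s0 = s0, t_threshold = t_threshold, k = k,
         max_window_expansion = max_window_expansion, layout = layout),
    class = "segmentation_params"
  )
}

# Fill the data-estimated fields of `params` for one track.
resolve_params <- function(track, params) {
  p <- unclass(params)
  if (is.null(p$w)) p$w <- estimate_window_size(track)
  if (is.null(p$m_w)) p$m_w <- estimate_min_probes(track, p$w)
  if (is.null(p$max_window_expansion)) p$max_window_expansion <- 10L * p$w
  # scale used by the window-expansion gate before the automatic s0 is
  # known: a robust noise estimate from successive probe differences
  # (median |dM| of a piecewise-constant signal is blind to the few steps)
  p$s0_gate <- p$s0 %||% max(0.01, robust_noise_sd(track$M))
  p
}

# robust sigma of the probe noise: median absolute successive difference,
# scaled for N(0, sigma) (|X| of a normal has median 0.6745 sigma; a
# difference doubles the variance)
robust_noise_sd <- function(M) {
  if (length(M) < 3) return(0)
  stats::median(abs(diff(M))) / (0.6745 * sqrt(2))
}

#' Hodges-Lehmann pseudomedian
#'
#' The median of all Walsh averages `(v[i] + v[j]) / 2` for `i <= j`: a robust
#' location estimate used to summarize the signal of a transcript unit
#' (its pseudomedian M value) and to drive the non-tiling merge rule.
#' The construction is the literal O(n^2) Walsh set, exact at the scales a
#' single transcript unit reaches.
#'
#' @param values Numeric vector of signal values (non-empty).
#' @return The pseudomedian (scalar).
#' @export
#' @examples
#' pseudomedian(c(1, 2, 3))   # 2
#' pseudomedian(c(0, 0, 10))  # 2.5
pseudomedian <- function(values) {
  n <- length(values)
  if (n == 0) abort("pseudomedian of an empty vector is undefined")
  if (anyNA(values)) abort("pseudomedian input contains NA")
  if (n == 1) return(as.numeric(values))
  s <- outer(values, values, "+") / 2
  stats::median(s[upper.tri(s, diag = TRUE)])
}

# One side of a CPR pair: probes grow outward from the anchor coordinate.
# Returns list(idx = integer range, n, mean, ss, sd, degenerate).
# direction = +1 grows right (anchor probe included), -1 grows left.
grow_side <- function(start, M, anchor_index, anchor_x, direction, p) {
  n_probes <- length(start)
  first <- if (direction > 0) anchor_index else anchor_index - 1L
  if (first < 1L || first > n_probes ||
      abs(start[first] - anchor_x) > p$max_window_expansion) {
    # no probe reachable on this side
    return(list(idx = integer(0), n = 0L, degenerate = TRUE))
  }
  # initial window of width w adjacent to the anchor coordinate
  idx <- first
  s1 <- M[first]
  s2 <- M[first]^2
  cur <- first
  repeat {
    nxt <- cur + direction
    if (nxt < 1L || nxt > n_probes) break
    gap <- abs(start[nxt] - start[cur])
    span <- abs(start[nxt] - anchor_x)
    n <- length(idx)
    if (span > p$max_window_expansion) break  # (c) span cap / probe desert
    if (span >= p$w) {
      # outside the initial width-w window: consistency gate (b); the gap
      # rule (a) only once the side holds its m_w minimum, so sparse tracks
      # can still assemble a minimal window across larger gaps
      mu <- s1 / n
      sd_cur <- if (n > 1) sqrt(max(0, (s2 - s1^2 / n) / (n - 1))) else 0
      # sqrt(1 + 1/n): the candidate is compared against a mean that is
      # itself noisy; without this a 1-probe window rejects its own kind
      gate <- p$k * max(sd_cur, p$s0_gate) * sqrt(1 + 1 / n)
      if (abs(M[nxt] - mu) > gate) break                          # (b)
      if (n >= p$m_w && gap > p$w) break                          # (a)
    }
    idx <- c(idx, nxt)
    s1 <- s1 + M[nxt]
    s2 <- s2 + M[nxt]^2
    cur <- nxt
  }
  n <- length(idx)
  mu <- s1 / n
  ss <- max(0, s2 - s1^2 / n)
  list(idx = sort(idx), n = n, mean = mu, ss = ss,
       sd = if (n > 1) sqrt(ss / (n - 1)) else 0,
       span = if (n > 0) abs(start[idx[length(idx)]] - anchor_x) else 0L,
       degenerate = n < 2L)
}

#' Build the pair of correlated probe regions flanking an anchor probe
#'
#' Each side starts as the window of width `w` adjacent to the anchor
#' coordinate (the anchor probe opens the right side) and then expands
#' probe-by-probe outward under three conditions: (a) once the side holds its
#' minimum of `m_w` probes, the gap to the next probe must be at most `w`
#' (below the minimum, gaps are bridged so sparse layouts can still assemble
#' a window); (b) outside the initial window the next M value must lie
#' within `k * max(sd, s0) * sqrt(1 + 1/n)` of the current window mean (the
#' last factor accounts for the window mean itself being noisy at small n);
#' and (c) the side's span may not exceed `max_window_expansion`, which also
#' bounds how far a probe desert can be bridged. Expansion stops at the
#' first violated condition. A side left with fewer than 2 probes is
#' degenerate and the anchor yields no t value, so anchors hard against a
#' signal step on their short side drop out instead of diluting a window
#' with cross-step probes.
#'
#' @param track Probe tibble for a single (experiment, replicon, strand),
#'   sorted by start.
#' @param anchor_index Index of the anchor probe within the track.
#' @param params [segmentation_params()].
#' @return List with elements `left` and `right`, each carrying `idx`, `n`,
#'   `mean`, `sd`, `ss`, `span` and `degenerate`.
#' @export
build_cpr_pair <- function(track, anchor_index, params = segmentation_params()) {
  p <- resolve_params(track, params)
  start <- track$start
  M <- track$M
  x <- start[anchor_index]
  list(
    left = grow_side(start, M, anchor_index, x, -1L, p),
    right = grow_side(start, M, anchor_index, x, +1L, p)
  )
}

#' SAM-style generalized t-statistic between two probe windows
#'
#' The relative-difference form with pooled scatter:
#' `t = (mean_R - mean_L) / (s + s0)` with
#' `s = sqrt((1/n_L + 1/n_R) * (SS_L + SS_R) / (n_L + n_R - 2))`,
#' where SS is the within-side sum of squared deviations. The fudge constant
#' `s0` keeps t finite where the local scatter collapses to zero.
#'
#' @param left,right CPR sides as produced by [build_cpr_pair()].
#' @param s0 Fudge constant (signal units, > 0).
#' @return The t value, or `NA` if either side is degenerate.
#' @export
sam_t <- function(left, right, s0) {
  if (isTRUE(left$degenerate) || isTRUE(right$degenerate)) return(NA_real_)
  s <- pooled_scatter(left, right)
  (right$mean - left$mean) / (s + s0)
}

pooled_scatter <- function(left, right) {
  sqrt((1 / left$n + 1 / right$n) *
         (left$ss + right$ss) / (left$n + right$n - 2))
}

#' Compute the t profile along a track
#'
#' Evaluates the generalized t-statistic at every eligible anchor probe (the
#' first and last `m_w` probes of a track cannot anchor a change point).
#' Anchors whose flanking windows are degenerate are skipped. If `s0` is not
#' supplied in `params` it is resolved here as the 5th percentile of the
#' pooled scatter over all anchors, floored at 0.01, and recorded in the
#' `s0` attribute of the result.
#'
#' @inheritParams build_cpr_pair
#' @return Tibble with one row per evaluated anchor: `x` (probe start),
#'   `t`, `anchor_index`, `s` (pooled scatter); attribute `s0`.
#' @export
t_profile <- function(track, params = segmentation_params()) {
  n <- nrow(track)
  p <- resolve_params(track, params)
  empty <- tibble::tibble(x = integer(0), t = numeric(0),
                          anchor_index = integer(0), s = numeric(0))
  if (n < 2L * p$m_w + 1L) return(structure(empty, s0 = p$s0 %||% 0.01))

  anchors <- seq.int(p$m_w + 1L, n - p$m_w)
  start <- track$start
  M <- track$M
  xs <- integer(0); diffs <- numeric(0); ss <- numeric(0); idxs <- integer(0)
  for (i in anchors) {
    left <- grow_side(start, M, i, start[i], -1L, p)
    right <- grow_side(start, M, i, start[i], +1L, p)
    if (left$degenerate || right$degenerate) next
    xs <- c(xs, start[i])
    diffs <- c(diffs, right$mean - left$mean)
    ss <- c(ss, pooled_scatter(left, right))
    idxs <- c(idxs, i)
  }
  if (length(xs) == 0) return(structure(empty, s0 = p$s0 %||% 0.01))
  s0 <- p$s0 %||% max(0.01, stats::quantile(ss, 0.05, names = FALSE))
  structure(
    tibble::tibble(x = xs, t = diffs / (ss + s0), anchor_index = idxs, s = ss),
    s0 = s0
  )
}

#' Call change points from a t profile
#'
#' A change point is a local extremum of |t| above the threshold. Within any
#' run of consecutive above-threshold anchors only the anchor with the largest
#' |t| is kept (leftmost on ties), so one signal step yields one change point.
#'
#' @param profile Tibble from [t_profile()], ordered by `x`.
#' @param t_threshold Threshold on |t|.
#' @return Tibble of change points: `x`, `t_value`, `anchor_index`.
#' @export
detect_change_points <- function(profile, t_threshold = 3) {
  empty <- tibble::tibble(x = integer(0), t_value = numeric(0),
                          anchor_index = integer(0))
  if (nrow(profile) == 0) return(empty)
  above <- abs(profile$t) >= t_threshold
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- integer(0)
  for (r in which(runs$values)) {
    span <- starts[r]:ends[r]
    keep <- c(keep, span[which.max(abs(profile$t[span]))])
  }
  tibble::tibble(x = profile$x[keep], t_value = profile$t[keep],
                 anchor_index = profile$anchor_index[keep])
}

# Partition track probes into runs delimited by change-point coordinates.
# A probe whose start equals a change-point x opens the right-hand region.
region_membership <- function(track, change_points) {
  if (nrow(change_points) == 0) return(rep(1L, nrow(track)))
  findInterval(track$start, sort(change_points$x)) + 1L
}

sas_from_groups <- function(track, groups) {
  split_idx <- split(seq_len(nrow(track)), groups)
  rows <- lapply(split_idx, function(ix) {
    tibble::tibble(
      experiment_id = track$experiment_id[ix[1]],
      replicon = track$replicon[ix[1]],
      strand = track$strand[ix[1]],
      start = min(track$start[ix]),
      end = max(track$end[ix]),
      n_probes = length(ix),
      pseudomedian_M = pseudomedian(track$M[ix]),
      probe_M = list(track$M[ix])
    )
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$start)
}

#' Assemble signal areas on a tiling layout
#'
#' On a uniform (tiling) probe layout the t curve alone fixes the transcript
#' boundaries: signal areas (SAS) are exactly the probe runs between
#' consecutive change points, plus the track edges. Each SAS takes its start
#' from its first member probe and its end from its last, and its M value is
#' the pseudomedian of the member probe M values.
#'
#' @param track Single-track probe tibble sorted by start.
#' @param change_points Tibble from [detect_change_points()].
#' @return SAS tibble: `experiment_id`, `replicon`, `strand`, `start`, `end`,
#'   `n_probes`, `pseudomedian_M`, `probe_M` (list column of member M values).
#' @export
segment_tiling <- function(track, change_points) {
  if (nrow(track) == 0) return(empty_sas())
  sas_from_groups(track, region_membership(track, change_points))
}

#' Assemble signal areas on a non-tiling layout
#'
#' With non-uniform probe density the t curve alone over-fragments the signal,
#' so the candidate regions between change points are post-processed by a
#' left-to-right merge pass: adjacent regions A and B are joined when the
#' absolute pseudomedian of their union exceeds the absolute difference of
#' their individual pseudomedians, i.e. `|PM(A+B)| > |PM(A) - PM(B)|`. After a
#' join the merged region becomes the left operand for the next comparison;
#' otherwise the boundary between A and B is fixed.
#'
#' @inheritParams segment_tiling
#' @param params [segmentation_params()] (unused by the rule itself; kept so
#'   the tiling and non-tiling paths share a signature).
#' @return SAS tibble as in [segment_tiling()].
#' @export
segment_nontiling <- function(track, change_points, params = segmentation_params()) {
  if (nrow(track) == 0) return(empty_sas())
  groups <- region_membership(track, change_points)
  regions <- unname(split(seq_len(nrow(track)), groups))
  if (length(regions) > 1) {
    merged <- list(regions[[1]])
    for (b in regions[-1]) {
      a <- merged[[length(merged)]]
      pm_a <- pseudomedian(track$M[a])
      pm_b <- pseudomedian(track$M[b])
      pm_ab <- pseudomedian(track$M[c(a, b)])
      if (abs(pm_ab) > abs(pm_a - pm_b)) {
        merged[[length(merged)]] <- c(a, b)
      } else {
        merged <- c(merged, list(b))
      }
    }
    regions <- merged
  }
  groups <- integer(nrow(track))
  for (g in seq_along(regions)) groups[regions[[g]]] <- g
  sas_from_groups(track, groups)
}

empty_sas <- function() {
  tibble::tibble(experiment_id = character(0), replicon = character(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 n_probes = integer(0), pseudomedian_M = numeric(0),
                 probe_M = list())
}

#' Segment probe signal into transcript units
#'
#' The full segmentation: for every (experiment, replicon, strand) track it
#' computes the t profile, calls change points, and assembles signal areas via
#' the tiling or non-tiling path. With `layout = "auto"` the tiling path is
#' used when the coefficient of variation of inter-probe gaps is below 0.2.
#' Window size `w`, minimum probe count `m_w` and the fudge constant `s0` are
#' estimated per track when not supplied (see [segmentation_params()]).
#'
#' @param probes Tidy probe tibble with a single `M` column (run
#'   [merge_replicates()] first if you have replicate columns).
#' @param params [segmentation_params()].
#' @return A `chipsad_sas` object: a tibble of signal areas (one row per SAS,
#'   columns as in [segment_tiling()], plus `sas_id`), with attributes
#'   `params` (resolved per track) and `profiles` (t profiles and change
#'   points per track). Use [tidy()] for the plain table and [glance()] for a
#'   one-row summary.
#' @export
chipsad <- function(probes, params = segmentation_params()) {
  if (!"M" %in% names(probes)) {
    probes <- merge_replicates(probes)
  }
  keys <- probes |>
    dplyr::distinct(.data$experiment_id, .data$replicon, .data$strand)
  sas_list <- list()
  track_meta <- list()
  profiles <- list()
  for (i in seq_len(nrow(keys))) {
    track <- probes |>
      dplyr::semi_join(keys[i, ], by = c("experiment_id", "replicon", "strand")) |>
      dplyr::arrange(.data$start)
    if (nrow(track) == 0) next
    p <- resolve_params(track, params)
    layout <- p$layout
    if (layout == "auto") {
      gaps <- diff(track$start)
      cv <- if (length(gaps) > 1 && mean(gaps) > 0) {
        stats::sd(gaps) / mean(gaps)
      } else 0
      layout <- if (cv < 0.2) "tiling" else "nontiling"
    }
    prof <- t_profile(track, params)
    cps <- detect_change_points(prof, p$t_threshold)
    sas <- if (layout == "tiling") {
      segment_tiling(track, cps)
    } else {
      segment_nontiling(track, cps, params)
    }
    key_lab <- paste(keys$experiment_id[i], keys$replicon[i], keys$strand[i],
                     sep = "|")
    sas_list[[key_lab]] <- sas
    profiles[[key_lab]] <- list(profile = prof, change_points = cps,
                                layout = layout)
    track_meta[[key_lab]] <- tibble::tibble(
      experiment_id = keys$experiment_id[i], replicon = keys$replicon[i],
      strand = keys$strand[i], n_probes = nrow(track), layout = layout,
      w = p$w, m_w = p$m_w, s0 = attr(prof, "s0"),
      t_threshold = p$t_threshold, n_change_points = nrow(cps)
    )
  }
  out <- dplyr::bind_rows(sas_list)
  if (nrow(out) == 0) out <- empty_sas()
  out <- out |>
    dplyr::arrange(.data$experiment_id, .data$replicon, .data$strand,
                   .data$start) |>
    dplyr::mutate(sas_id = paste0(.data$experiment_id, ":", .data$replicon,
                                  .data$strand, ":", .data$start, "-",
                                  .data$end),
                  .before = 1)
  structure(out,
            class = c("chipsad_sas", class(tibble::tibble()))
            , params = params
            , tracks = dplyr::bind_rows(track_meta)
            , profiles = profiles)
}

#' @export
tidy.chipsad_sas <- function(x, ...) {
  tibble::as_tibble(x) |> dplyr::select(-dplyr::any_of("probe_M"))
}

#' @export
glance.chipsad_sas <- function(x, ...) {
  tracks <- attr(x, "tracks")
  tibble::tibble(
    n_sas = nrow(x),
    n_tracks = if (is.null(tracks)) NA_integer_ else nrow(tracks),
    n_change_points = if (is.null(tracks)) NA_integer_ else
      sum(tracks$n_change_points),
    mean_sas_length = if (nrow(x)) mean(x$end - x$start + 1) else NA_real_,
    t_threshold = attr(x, "params")$t_threshold %||% NA_real_
  )
}

#' @export
print.chipsad_sas <- function(x, ...) {
  tracks <- attr(x, "tracks")
  cat("<chipsad_sas> ", nrow(x), " signal areas across ",
      if (is.null(tracks)) 0L else nrow(tracks), " track(s)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}
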