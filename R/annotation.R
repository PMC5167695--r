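#' Annotation classifier parameters
#'
#' Thresholds of the transcript classifier, at their standard values: a SAS
#' must cover at least 30% of an ORF's length to count as overlapping it in
#' the coding sense; a convergent/divergent ORF pair bridged by one SAS is an
#' overlapping UTR only if the intergenic gap between the ORFs is under 30
#' bp; a SAS extending more than 30 bases beyond its ORF is a UTR; and an
#' ORF-free SAS is an intergenic RNA only under 800 bases (longer ones keep
#' the intergenic class with a `long` flag).
#'
#' @param min_orf_overlap_frac Fraction of the ORF length (not the SAS
#'   length) that must be covered (default 0.30).
#' @param overlapping_utr_max_intergenic Maximum ORF-to-ORF gap in bp for the
#'   overlapping-UTR call (default 30).
#' @param utr_max_gap Maximum extension beyond the ORF, in bases, that still
#'   counts as the ORF transcript rather than a UTR (default 30).
#' @param intergenic_max_len Maximum length of an intergenic RNA (default
#'   800).
#' @return List of class `annotation_params`.
#' @export
annotation_params <- function(min_orf_overlap_frac = 0.30,
                              overlapping_utr_max_intergenic = 30,
                              utr_max_gap = 30,
                              intergenic_max_len = 800) {
  structure(list(min_orf_overlap_frac = min_orf_overlap_frac,
                 overlapping_utr_max_intergenic = overlapping_utr_max_intergenic,
                 utr_max_gap = utr_max_gap,
                 intergenic_max_len = intergenic_max_len),
            class = "annotation_params")
}

overlap_bp <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

#' Fraction of an ORF covered by a signal area
#'
#' Overlap in bp between the two 1-based inclusive intervals, divided by the
#' ORF length. Strand is deliberately ignored here: sense vs antisense is the
#' classifier's job.
#'
#' @param sas_start,sas_end SAS interval (1-based inclusive).
#' @param orf_start,orf_end ORF interval (1-based inclusive).
#' @return Fraction in \[0, 1\] (vectorized).
#' @export
orf_overlap_fraction <- function(sas_start, sas_end, orf_start, orf_end) {
  overlap_bp(sas_start, sas_end, orf_start, orf_end) /
    (orf_end - orf_start + 1)
}

transcript_classes <- c("orf", "operon", "antisense", "overlapping_utr",
                        "intergenic", "utr5", "utr3")

#' Classify one signal area against the ORF annotation
#'
#' Applies the rule cascade, first match wins:
#' \describe{
#'   \item{R1 operon}{two or more same-strand ORFs each covered at
#'     `min_orf_overlap_frac` or more.}
#'   \item{R2 overlapping UTR}{the SAS touches two differently oriented ORFs
#'     whose mutual intergenic gap is under
#'     `overlapping_utr_max_intergenic` bp.}
#'   \item{R3 ORF}{exactly one qualifying same-strand ORF and the SAS stays
#'     within `utr_max_gap` bases of it on both sides.}
#'   \item{R4 UTR}{one qualifying same-strand ORF with a longer extension
#'     into flanking intergenic space; `utr5` or `utr3` by which biological
#'     end (strand-aware) is extended, the longer extension deciding when
#'     both are.}
#'   \item{R5 antisense}{no qualifying sense ORF but a qualifying
#'     opposite-strand one.}
#'   \item{R6 intergenic}{no ORF overlap at all and length under
#'     `intergenic_max_len`.}
#'   \item{R7 intergenic (long)}{no ORF overlap, length at or above
#'     `intergenic_max_len`: kept as intergenic with a `long` flag rather
#'     than dropped.}
#' }
#' A SAS that overlaps ORFs only below the coverage threshold matches no rule
#' above; it falls back to antisense (the "otherwise" of the cascade) with an
#' `ambiguous` marker in its rule trace.
#'
#' @param sas One-row SAS tibble (or a row of a consensus table).
#' @param orfs ORF tibble from [read_genbank_orfs()].
#' @param params [annotation_params()].
#' @return One-row tibble: `transcript_class`, `label` (class plus the `long`
#'   marker where it applies), `supporting_orfs` (list of locus tags),
#'   `rule_trace` (list of rules evaluated, with the matched one marked).
#' @export
classify_sas <- function(sas, orfs, params = annotation_params()) {
  stopifnot(nrow(sas) == 1)
  here <- orfs[orfs$replicon == sas$replicon &
                 overlap_bp(sas$start, sas$end, orfs$start, orfs$end) > 0, ,
               drop = FALSE]
  frac <- orf_overlap_fraction(sas$start, sas$end, here$start, here$end)
  sense <- here$strand == sas$strand
  qual <- frac >= params$min_orf_overlap_frac
  qual_sense <- here[sense & qual, , drop = FALSE]
  qual_anti <- here[!sense & qual, , drop = FALSE]
  sas_len <- sas$end - sas$start + 1L

  trace <- character(0)
  done <- function(class, supporting, rule, extra_trace = character(0)) {
    label <- class
    tibble::tibble(transcript_class = class, label = label,
                   supporting_orfs = list(supporting),
                   rule_trace = list(c(trace, extra_trace, paste0(rule, ":match"))))
  }

  # R1 operon
  if (nrow(qual_sense) >= 2) return(done("operon", qual_sense$locus_tag, "R1"))
  trace <- c(trace, "R1:fail")

  # R2 overlapping UTR: two differently oriented touched ORFs, gap < 30 bp
  if (nrow(here) >= 2 && length(unique(here$strand)) == 2) {
    plus <- here[here$strand == "+", , drop = FALSE]
    minus <- here[here$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(plus))) {
      for (j in seq_len(nrow(minus))) {
        gap <- max(plus$start[i], minus$start[j]) -
          min(plus$end[i], minus$end[j]) - 1L
        if (gap < params$overlapping_utr_max_intergenic) {
          return(done("overlapping_utr",
                      c(plus$locus_tag[i], minus$locus_tag[j]), "R2"))
        }
      }
    }
  }
  trace <- c(trace, "R2:fail")

  # R3 / R4: single qualifying sense ORF
  if (nrow(qual_sense) == 1) {
    ext_low <- max(0L, qual_sense$start - sas$start)
    ext_high <- max(0L, sas$end - qual_sense$end)
    if (ext_low <= params$utr_max_gap && ext_high <= params$utr_max_gap) {
      return(done("orf", qual_sense$locus_tag, "R3"))
    }
    trace <- c(trace, "R3:fail")
    # strand-aware: on + the low-coordinate flank is 5'; on - it is 3'
    extended_low <- ext_low > params$utr_max_gap
    extended_high <- ext_high > params$utr_max_gap
    side <- if (extended_low && extended_high) {
      if (ext_low >= ext_high) "low" else "high"
    } else if (extended_low) "low" else "high"
    class <- if (sas$strand == "+") {
      if (side == "low") "utr5" else "utr3"
    } else {
      if (side == "low") "utr3" else "utr5"
    }
    return(done(class, qual_sense$locus_tag, "R4"))
  }
  trace <- c(trace, "R3:fail", "R4:fail")

  # R5 antisense
  if (nrow(qual_sense) == 0 && nrow(qual_anti) >= 1) {
    return(done("antisense", qual_anti$locus_tag, "R5"))
  }
  trace <- c(trace, "R5:fail")

  # R6 / R7: ORF-free
  if (nrow(here) == 0) {
    if (sas_len < params$intergenic_max_len) {
      return(done("intergenic", character(0), "R6"))
    }
    trace <- c(trace, "R6:fail")
    out <- done("intergenic", character(0), "R7")
    out$label <- "intergenic_long"
    return(out)
  }
  trace <- c(trace, "R6:fail", "R7:fail")

  # sub-threshold overlap only: the cascade's "otherwise" -> antisense
  done("antisense", here$locus_tag, "fallback", "ambiguous")
}

#' Classify every signal area and summarize by class
#'
#' Runs [classify_sas()] on each row and attaches the per-class summary.
#'
#' @param sas SAS or consensus tibble.
#' @param orfs ORF tibble from [read_genbank_orfs()].
#' @param params [annotation_params()].
#' @return A `chipsad_annotation` tibble: the input columns plus
#'   `transcript_class`, `label`, `supporting_orfs`, `rule_trace`; the
#'   per-class count table is attribute `summary` (also via
#'   [class_summary()]).
#' @export
annotate_all <- function(sas, orfs, params = annotation_params()) {
  calls <- purrr::map_dfr(seq_len(nrow(sas)),
                          function(i) classify_sas(sas[i, ], orfs, params))
  if (nrow(sas) == 0) {
    calls <- tibble::tibble(transcript_class = character(0),
                            label = character(0), supporting_orfs = list(),
                            rule_trace = list())
  }
  out <- dplyr::bind_cols(tibble::as_tibble(sas), calls)
  summary <- tibble::tibble(transcript_class = transcript_classes) |>
    dplyr::left_join(dplyr::count(out, .data$transcript_class),
                     by = "transcript_class") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  structure(out, class = c("chipsad_annotation", class(tibble::tibble())),
            summary = summary, params = params)
}

#' Per-class transcript counts of an annotation result
#'
#' @param annotation A `chipsad_annotation` tibble.
#' @return Tibble with one row per transcript class and its count.
#' @export
class_summary <- function(annotation) attr(annotation, "summary")

#' @export
tidy.chipsad_annotation <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(supporting_orfs = purrr::map_chr(
      .data$supporting_orfs, paste, collapse = ","),
      rule_trace = purrr::map_chr(.data$rule_trace, paste, collapse = ";")) |>
    dplyr::select(-dplyr::any_of(c("probe_M", "member_ids", "weights",
                                   "per_experiment_M")))
}

#' @export
glance.chipsad_annotation <- function(x, ...) {
  s <- class_summary(x)
  tidyr::pivot_wider(s, names_from = "transcript_class", values_from = "n") |>
    dplyr::mutate(n_transcripts = nrow(x), .before = 1)
}

#' @export
print.chipsad_annotation <- function(x, ...) {
  cat("<chipsad_annotation> ", nrow(x), " classified transcript(s)\n", sep = "")
  print(class_summary(x))
  invisible(x)
}
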