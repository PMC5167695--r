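#' Write signal areas or classified transcripts to disk
#'
#' Supported formats: `"gff3"` (1-based inclusive, `source` column
#' `chipsad`, the transcript class — or `signal_area` — in the type column,
#' pseudomedian M in the `pseudomedian_M` attribute), `"bed"` (BED6, 0-based
#' half-open, score = pseudomedian M x 100 clamped to \[0, 1000\]) and
#' `"tsv"` (mirrors the internal columns; the lossless round-trip format).
#'
#' @param records SAS, consensus or annotation tibble with `replicon`,
#'   `strand`, `start`, `end`, `pseudomedian_M` (and `transcript_class` if
#'   classified).
#' @param path Output path.
#' @param format One of `"gff3"`, `"bed"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(records, path, format = c("tsv", "gff3", "bed")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(paste0(
                       "unknown format: ", format[1],
                       " (use gff3, bed or tsv)")))
  ids <- record_ids(records)
  type <- if ("transcript_class" %in% names(records)) {
    records$transcript_class
  } else {
    rep("signal_area", nrow(records))
  }
  if (format == "tsv") {
    flat <- tibble::as_tibble(records) |>
      dplyr::select(-dplyr::any_of(c("probe_M", "member_ids", "weights",
                                     "per_experiment_M")))
    list_cols <- names(flat)[vapply(flat, is.list, logical(1))]
    for (col in list_cols) {
      flat[[col]] <- purrr::map_chr(flat[[col]], paste, collapse = ";")
    }
    readr::write_tsv(flat, path, progress = FALSE)
  } else if (format == "gff3") {
    lines <- "##gff-version 3"
    if (nrow(records) > 0) {
      attrs <- sprintf("ID=%s;pseudomedian_M=%s", ids,
                       format(records$pseudomedian_M, digits = 15,
                              scientific = FALSE, trim = TRUE))
      if ("experiment_id" %in% names(records)) {
        attrs <- paste0(attrs, ";experiment_id=", records$experiment_id)
      }
      lines <- c(lines, sprintf("%s\tchipsad\t%s\t%d\t%d\t.\t%s\t.\t%s",
                                records$replicon, type,
                                records$start, records$end,
                                records$strand, attrs))
    }
    writeLines(lines, path)
  } else {
    score <- pmin(1000, pmax(0, round(abs(records$pseudomedian_M) * 100)))
    lines <- character(0)
    if (nrow(records) > 0) {
      lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", records$replicon,
                       records$start - 1L, records$end, ids, score,
                       records$strand)
    }
    writeLines(c("#replicon\tstart\tend\tname\tscore\tstrand", lines), path)
  }
  invisible(path)
}

record_ids <- function(records) {
  for (col in c("sas_id", "consensus_id")) {
    if (col %in% names(records)) return(records[[col]])
  }
  if (nrow(records) == 0) return(character(0))
  paste0(records$replicon, records$strand, ":", records$start, "-",
         records$end)
}

#' Read transcripts written by [write_transcripts()]
#'
#' Reads the TSV or GFF3 form back into a tibble with 1-based inclusive
#' coordinates. The TSV round trip is lossless for the scalar columns; GFF3
#' restores coordinates, strand, class and pseudomedian M.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"gff3"` (`"auto"` guesses from the extension and
#'   the `##gff-version` pragma).
#' @return Tibble of transcript records.
#' @export
read_transcripts <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, "##gff-version")) "gff3" else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(tibble::as_tibble(out))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(replicon = character(0), strand = character(0),
                          start = integer(0), end = integer(0),
                          transcript_class = character(0),
                          pseudomedian_M = numeric(0)))
  }
  fields <- stringr::str_split(lines, "\t")
  get_attr <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
    m
  }
  attrs <- vapply(fields, `[`, character(1), 9)
  out <- tibble::tibble(
    replicon = vapply(fields, `[`, character(1), 1),
    type = vapply(fields, `[`, character(1), 3),
    start = as.integer(vapply(fields, `[`, character(1), 4)),
    end = as.integer(vapply(fields, `[`, character(1), 5)),
    strand = vapply(fields, `[`, character(1), 7),
    pseudomedian_M = as.numeric(get_attr(attrs, "pseudomedian_M")),
    experiment_id = get_attr(attrs, "experiment_id")
  )
  out |>
    dplyr::mutate(transcript_class = ifelse(.data$type == "signal_area",
                                            NA_character_, .data$type)) |>
    dplyr::select(-dplyr::all_of("type"))
}
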