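# Minimal GenBank flat-file support: enough to read CDS features (locus_tag,
# strand, outermost coordinates) from one or more LOCUS records, and to write
# a valid toy record for the simulator. No installed R package parses GenBank
# feature tables, so this is done here; locations handled are NUMBER..NUMBER,
# complement(...), join(...), and their nesting, with <| > partial markers.

#' Read ORF features from a GenBank flat file
#'
#' Extracts one feature per `CDS` entry: `locus_tag`, replicon (the LOCUS
#' name), strand, and 1-based inclusive coordinates. `join(...)` and
#' `complement(...)` locations are resolved to the outermost span and overall
#' strand. A CDS without a `/locus_tag` (or `/gene`) qualifier gets a
#' synthetic tag, with a message.
#'
#' @param path GenBank flat file; may contain several LOCUS records
#'   (replicons).
#' @return Tibble of ORFs: `locus_tag`, `replicon`, `strand`, `start`, `end`,
#'   sorted by replicon and start.
#' @export
read_genbank_orfs <- function(path) {
  if (!file.exists(path)) abort(paste0("GenBank file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "LOCUS"))) {
    abort(paste0("not a GenBank flat file (no LOCUS line): ", path))
  }
  records <- split(lines, cumsum(startsWith(lines, "LOCUS")))
  records <- records[names(records) != "0"]
  orfs <- purrr::map_dfr(records, parse_genbank_record)
  if (nrow(orfs) == 0) {
    warn(paste0("no CDS features found in ", path))
    return(tibble::tibble(locus_tag = character(0), replicon = character(0),
                          strand = character(0), start = integer(0),
                          end = integer(0)))
  }
  dplyr::arrange(orfs, .data$replicon, .data$start, .data$end)
}

parse_genbank_record <- function(lines) {
  replicon <- stringr::str_split(stringr::str_squish(lines[1]), " ")[[1]][2]
  feat_start <- which(startsWith(lines, "FEATURES"))
  if (length(feat_start) == 0) return(NULL)
  feat_end <- which(startsWith(lines, "ORIGIN") | startsWith(lines, "//"))
  feat_end <- if (length(feat_end)) min(feat_end[feat_end > feat_start[1]]) else
    length(lines) + 1L
  body <- lines[(feat_start[1] + 1L):(feat_end - 1L)]
  if (length(body) == 0) return(NULL)

  # a new feature starts with a key in columns 6-20; continuations are
  # indented to column 22
  is_key <- grepl("^ {5}\\S", body)
  feat_id <- cumsum(is_key)
  feats <- split(body, feat_id)
  feats <- feats[names(feats) != "0"]

  rows <- list()
  n_anon <- 0L
  for (f in feats) {
    key <- stringr::str_squish(substr(f[1], 1, 21))
    if (key != "CDS") next
    # location may continue over lines until the first qualifier (/xxx)
    qual_start <- which(grepl("^\\s+/", f))
    loc_lines <- if (length(qual_start)) f[1:(qual_start[1] - 1L)] else f
    loc <- paste(stringr::str_squish(
      c(sub("^ {5}\\S+\\s*", "", loc_lines[1]), loc_lines[-1])), collapse = "")
    span <- parse_genbank_location(loc)
    tag <- stringr::str_match(paste(f, collapse = "\n"),
                              '/locus_tag="([^"]+)"')[, 2]
    if (is.na(tag)) {
      tag <- stringr::str_match(paste(f, collapse = "\n"),
                                '/gene="([^"]+)"')[, 2]
    }
    if (is.na(tag)) {
      n_anon <- n_anon + 1L
      tag <- sprintf("%s_CDS%03d", replicon, n_anon)
      inform(paste0("CDS without locus_tag at ", replicon, ":", span$start,
                    "..", span$end, " assigned synthetic tag ", tag))
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      locus_tag = tag, replicon = replicon, strand = span$strand,
      start = span$start, end = span$end)
  }
  dplyr::bind_rows(rows)
}

parse_genbank_location <- function(loc) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.integer(unlist(stringr::str_extract_all(gsub("[<>]", "", loc),
                                                     "[0-9]+")))
  if (length(nums) == 0) abort(paste0("unparseable GenBank location: ", loc))
  list(strand = strand, start = min(nums), end = max(nums))
}

#' Write a toy GenBank flat file
#'
#' Emits a minimal but well-formed GenBank record per replicon: LOCUS header,
#' a source feature, one CDS per ORF (with `complement(..)` for minus-strand
#' features and a `/locus_tag`), an empty ORIGIN and the `//` terminator.
#' [read_genbank_orfs()] round-trips it exactly. Used by the annotation
#' simulator; the sequence itself is not written (the classifier only needs
#' coordinates).
#'
#' @param orfs ORF tibble (`locus_tag`, `replicon`, `strand`, `start`, `end`).
#' @param path Output path.
#' @param genome_length Length recorded in the LOCUS line (named vector per
#'   replicon or single value).
#' @return `path`, invisibly.
#' @export
write_genbank <- function(orfs, path, genome_length = NULL) {
  out <- character(0)
  for (rep_name in unique(orfs$replicon)) {
    sub <- orfs[orfs$replicon == rep_name, , drop = FALSE]
    len <- if (is.null(genome_length)) max(sub$end) + 100L else
      if (!is.null(names(genome_length))) genome_length[[rep_name]] else
        genome_length
    out <- c(out, sprintf(
      "LOCUS       %s %d bp    DNA     circular BCT 01-JAN-2000", rep_name,
      as.integer(len)),
      sprintf("DEFINITION  synthetic record %s.", rep_name),
      "FEATURES             Location/Qualifiers",
      sprintf("     source          1..%d", as.integer(len)))
    for (i in seq_len(nrow(sub))) {
      loc <- sprintf("%d..%d", sub$start[i], sub$end[i])
      if (sub$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      out <- c(out,
               sprintf("     CDS             %s", loc),
               sprintf("                     /locus_tag=\"%s\"",
                       sub$locus_tag[i]))
    }
    out <- c(out, "ORIGIN", "//")
  }
  writeLines(out, path)
  invisible(path)
}
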