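#' Read and validate a pipeline configuration file
#'
#' YAML config with up to four sections: `segmentation` (fields of
#' [segmentation_params()]), `alignment` (`min_abs_M`, `min_fold_change`,
#' `experiments`), `annotation` (fields of [annotation_params()]) and
#' `simulation` (fields of [simulation_config()]). Every key is optional;
#' unknown sections or keys are rejected with an error naming the key.
#'
#' @param path YAML file, or `NULL` for an all-defaults config.
#' @return Nested list of validated config sections.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- list(
    segmentation = c("w", "m_w", "s0", "t_threshold", "k",
                     "max_window_expansion", "layout"),
    alignment = c("min_abs_M", "min_fold_change", "experiments"),
    annotation = names(formals(annotation_params)),
    simulation = names(formals(simulation_config))
  )
  bad_sections <- setdiff(names(cfg), names(allowed))
  if (length(bad_sections) > 0) {
    abort(paste0("unknown config section: ", bad_sections[1]))
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), allowed[[sec]])
    if (length(bad) > 0) {
      abort(paste0("unknown config key: ", sec, ".", bad[1]))
    }
  }
  cfg
}

config_segmentation_params <- function(cfg) {
  do.call(segmentation_params, cfg$segmentation %||% list())
}

#' Run the full pipeline: segment, align, annotate
#'
#' Segments every probe file independently, aligns the pooled signal areas
#' into consensus transcripts, classifies them against the GenBank
#' annotation, and writes every intermediate (per-experiment SAS, consensus,
#' M matrix, classified transcripts, class summary) plus a JSON run manifest
#' recording the parameters and input files. Data outputs are deterministic
#' for identical inputs and config; only the manifest carries a timestamp.
#'
#' @param probe_files Character vector of probe TSV paths (one experiment
#'   each).
#' @param genbank_file GenBank flat file with the ORF annotation.
#' @param out_dir Output directory (created if needed).
#' @param config Config list as from [read_pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the result objects (`sas`, `consensus`,
#'   `differential`, `annotation`) and `files` (paths written).
#' @export
run_all <- function(probe_files, genbank_file, out_dir,
                    config = read_pipeline_config(), quiet = FALSE) {
  if (!all(file.exists(probe_files))) {
    abort(paste0("probe file not found: ",
                 probe_files[!file.exists(probe_files)][1]))
  }
  if (!file.exists(genbank_file)) {
    abort(paste0("GenBank file not found: ", genbank_file))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0(...))
  seg_params <- config_segmentation_params(config)
  files <- list()

  # stage 1: segmentation, one experiment at a time
  sas_all <- list()
  for (pf in probe_files) {
    probes <- merge_replicates(read_probe_table(pf))
    eid <- probes$experiment_id[1]
    say("segment: ", eid, " (", nrow(probes), " probes)")
    sas <- chipsad(probes, seg_params)
    base <- file.path(out_dir, paste0("sas_", eid))
    write_transcripts(sas, paste0(base, ".tsv"), "tsv")
    write_transcripts(sas, paste0(base, ".gff3"), "gff3")
    files[[paste0("sas_", eid)]] <- paste0(base, c(".tsv", ".gff3"))
    sas_all[[eid]] <- sas
  }
  pooled <- dplyr::bind_rows(lapply(sas_all, tibble::as_tibble))

  # stage 2: alignment
  min_abs_M <- config$alignment$min_abs_M %||% 0
  say("align: ", nrow(pooled), " SAS from ", length(sas_all), " experiment(s)")
  consensus <- align_experiments(pooled, min_abs_M = min_abs_M)
  write_transcripts(consensus, file.path(out_dir, "consensus.tsv"), "tsv")
  write_transcripts(consensus, file.path(out_dir, "consensus.gff3"), "gff3")
  readr::write_tsv(consensus_matrix(consensus),
                   file.path(out_dir, "consensus_matrix.tsv"), progress = FALSE)
  files$consensus <- file.path(out_dir, c("consensus.tsv", "consensus.gff3",
                                          "consensus_matrix.tsv"))

  differential <- NULL
  if (!is.null(config$alignment$min_fold_change)) {
    exps <- config$alignment$experiments %||% names(sas_all)
    differential <- select_differential(
      consensus, exps, config$alignment$min_fold_change,
      matrix_path = file.path(out_dir, "differential_matrix.tsv"))
    write_transcripts(differential, file.path(out_dir, "differential.tsv"),
                      "tsv")
    files$differential <- file.path(out_dir, c("differential.tsv",
                                               "differential_matrix.tsv"))
  }

  # stage 3: annotation
  orfs <- read_genbank_orfs(genbank_file)
  say("annotate: ", nrow(consensus), " consensus transcript(s) vs ",
      nrow(orfs), " ORF(s)")
  ann_params <- do.call(annotation_params, config$annotation %||% list())
  annotation <- annotate_all(consensus, orfs, ann_params)
  write_transcripts(annotation, file.path(out_dir, "classified.tsv"), "tsv")
  write_transcripts(annotation, file.path(out_dir, "classified.gff3"), "gff3")
  readr::write_tsv(class_summary(annotation),
                   file.path(out_dir, "class_summary.tsv"), progress = FALSE)
  files$classified <- file.path(out_dir, c("classified.tsv", "classified.gff3",
                                           "class_summary.tsv"))

  manifest <- list(
    package = "chipsad",
    version = as.character(utils::packageVersion("chipsad")),
    timestamp = format(Sys.time(), tz = "UTC"),
    probe_files = probe_files,
    genbank_file = genbank_file,
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files$manifest <- file.path(out_dir, "manifest.json")

  invisible(list(sas = sas_all, consensus = consensus,
                 differential = differential, annotation = annotation,
                 files = files))
}
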