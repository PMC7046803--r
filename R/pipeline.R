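#' Run the occupancy pipeline end to end
#'
#' Orchestrates the analysis stages in order — annotation, regulatory
#' windows, chromatin-state overlay, TF occupancy, motif scanning, family /
#' subtype summaries — and writes deterministic TSV/BED outputs plus a run
#' log (config hash, package version, per-stage record counts; no
#' timestamps, so reruns are byte-identical). Optional inputs degrade
#' gracefully: without histone files the chromatin-state table is omitted,
#' without motif files the motif stage is skipped; both are logged.
#'
#' @param config Named list (or path to a YAML file holding one) with:
#'   * `annotation`: GFF3 path (required)
#'   * `peaks`: character vector of TF peak files (required)
#'   * `peak_dialect`: dialect for [read_peaks()] (default `"bed6"`)
#'   * `fasta`: genome FASTA (needed for the motif stage)
#'   * `histone`: histone peak file(s) (`broadPeak`)
#'   * `motif_pfm`: motif count-matrix file; scanned within peaks whose
#'     label equals the motif name
#'   * `group_config`: YAML with `families` / `subtypes`
#'     (defaults: [default_family_map()], [default_subtype_map()];
#'     the subtype stage is skipped when none of its miRNAs are annotated)
#'   * parameters `promoter_bp` (2000), `enhancer_bp` (10000),
#'     `merge_cell_lines` (TRUE), `require_marked` (FALSE),
#'     `min_score_frac` (0.8)
#' @param out_dir Output directory.
#' @return Invisibly, a list with the stage results (`annotation`,
#'   `regions`, `states`, `occupancy`, `motif_hits`, `summary`) and `paths`
#'   of the written files.
#' @export
run_occupancy_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  if (is.null(cfg$annotation) || is.null(cfg$peaks)) {
    abort("config needs 'annotation' and 'peaks' paths")
  }
  for (p in c(cfg$annotation, cfg$peaks, cfg$fasta, cfg$histone, cfg$motif_pfm,
              cfg$group_config)) {
    if (!file.exists(p)) abort(paste0("config references missing file: ", p))
  }
  prm <- function(name, default) cfg[[name]] %||% default
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("mirreg occupancy pipeline v%s",
                   as.character(utils::packageVersion("mirreg"))),
           sprintf("config_hash: %s", rlang::hash(cfg)))
  paths <- list()

  annotation <- read_gff3(cfg$annotation)
  log <- c(log, sprintf("annotation: %d genes, %d miRNAs",
                        nrow(annotation$genes), nrow(annotation$mirnas)))

  regions <- build_regions(annotation,
                           promoter_bp = prm("promoter_bp", 2000),
                           enhancer_bp = prm("enhancer_bp", 10000))
  log <- c(log, sprintf("regions: %d windows", nrow(regions)))

  peaks <- map(cfg$peaks, read_peaks,
               dialect = prm("peak_dialect", "bed6")) |> list_rbind()
  log <- c(log, sprintf("peaks: %d records, %d TF labels",
                        nrow(peaks), length(unique(peaks$label))))

  states <- NULL
  if (!is.null(cfg$histone)) {
    histone <- map(cfg$histone, read_peaks, dialect = "broadPeak") |> list_rbind()
    states <- classify_regions(regions, histone)
    paths$states <- file.path(out_dir, "chromatin_state.tsv")
    readr::write_tsv(states, paths$states, progress = FALSE)
    log <- c(log, sprintf("chromatin state: %d regions classified (%d unmarked)",
                          nrow(states), sum(states$call == "unmarked")))
    if (isTRUE(prm("require_marked", FALSE))) {
      regions <- regions[states$call != "unmarked", ]
      log <- c(log, sprintf("require_marked: %d regions retained", nrow(regions)))
    }
  } else {
    log <- c(log, "chromatin state: skipped (no histone input)")
    if (isTRUE(prm("require_marked", FALSE))) {
      abort("require_marked needs histone input")
    }
  }

  occupancy <- tabulate_occupancy(regions, peaks,
                                  merge_cell_lines = prm("merge_cell_lines", TRUE))
  paths$occupancy <- file.path(out_dir, "occupancy.tsv")
  write_occupancy_tsv(occupancy, paths$occupancy)
  paths$dedup <- file.path(out_dir, "occupancy_dedup.tsv")
  readr::write_tsv(occupancy$dedup_totals, paths$dedup, progress = FALSE)
  log <- c(log, sprintf("occupancy: %d entries, grand total %d sites",
                        nrow(occupancy$entries), sum(occupancy$entries$n_sites)))

  motif_hits <- NULL
  if (!is.null(cfg$motif_pfm)) {
    if (is.null(cfg$fasta)) abort("motif stage needs a 'fasta' genome path")
    genome <- read_fasta(cfg$fasta)
    motif <- read_motif_pfm(cfg$motif_pfm)
    tf_peaks <- peaks[peaks$label == motif$name, ]
    motif_hits <- scan_peaks(tf_peaks, genome, motif,
                             min_score_frac = prm("min_score_frac", 0.8))
    paths$motif_hits <- file.path(out_dir, "motif_hits.bed")
    write_hits_bed(motif_hits, paths$motif_hits)
    log <- c(log, sprintf("motifs: %d hits of %s in %d peaks",
                          nrow(motif_hits), motif$name, nrow(tf_peaks)))
  } else {
    log <- c(log, "motifs: skipped (no motif input)")
  }

  groups <- if (!is.null(cfg$group_config)) read_group_config(cfg$group_config) else list()
  families <- groups$families %||% default_family_map()
  subtypes <- groups$subtypes %||% default_subtype_map()
  summary <- if (all(unlist(subtypes) %in% annotation$mirnas$mir_id)) {
    subtype_comparison(occupancy, subtypes, families)
  } else {
    log <- c(log, "subtype comparison: skipped (subtype miRNAs not annotated)")
    aggregate_by_family(occupancy, families)
  }
  paths$per_tf <- file.path(out_dir, "per_tf_totals.tsv")
  readr::write_tsv(summary$per_tf_totals, paths$per_tf, progress = FALSE)
  paths$family <- file.path(out_dir, "family_totals.tsv")
  readr::write_tsv(summary$per_family, paths$family, progress = FALSE)
  if (!is.null(summary$per_family_per_subtype)) {
    paths$family_subtype <- file.path(out_dir, "family_subtype.tsv")
    readr::write_tsv(summary$per_family_per_subtype, paths$family_subtype,
                     progress = FALSE)
  }

  paths$log <- file.path(out_dir, "run_log.txt")
  readr::write_lines(log, paths$log)
  invisible(list(annotation = annotation, regions = regions, states = states,
                 occupancy = occupancy, motif_hits = motif_hits,
                 summary = summary, paths = paths))
}

#' Run the qPCR quantification pipeline end to end
#'
#' Hemolysis QC first (exclusions listed with reasons), then comparative-CT
#' relative expression on the passing samples, then — when the CT table
#' carries a `group` column with at least two groups — the group
#' comparison on log-converted values.
#'
#' @param config Named list (or YAML path) with `ct_table` (TSV path),
#'   `target`, `references` (assay names), and optional
#'   `hemolysis_threshold` (7), `log_base` (10), `marker_23a`, `marker_451a`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `qc`, `expression`, `comparison`, `paths`.
#' @export
run_quant_pipeline <- function(config, out_dir) {
  cfg <- load_pipeline_config(config)
  if (is.null(cfg$ct_table) || is.null(cfg$target) || is.null(cfg$references)) {
    abort("config needs 'ct_table', 'target' and 'references'")
  }
  prm <- function(name, default) cfg[[name]] %||% default
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct <- read_ct_table(cfg$ct_table)
  log <- c(sprintf("mirreg quant pipeline v%s",
                   as.character(utils::packageVersion("mirreg"))),
           sprintf("config_hash: %s", rlang::hash(cfg)),
           sprintf("ct records: %d (%d samples)", nrow(ct),
                   length(unique(ct$sample_id))))
  paths <- list()

  qc <- hemolysis_qc(ct,
                     marker_23a = prm("marker_23a", "miR-23a-3p"),
                     marker_451a = prm("marker_451a", "miR-451a"),
                     threshold = prm("hemolysis_threshold", 7))
  qc$reason <- case_when(
    is.na(qc$passed) ~ "hemolysis markers missing",
    !qc$passed ~ "hemolysis dCT above threshold",
    TRUE ~ ""
  )
  paths$qc <- file.path(out_dir, "qc.tsv")
  readr::write_tsv(qc, paths$qc, progress = FALSE)
  keep <- qc$sample_id[!is.na(qc$passed) & qc$passed]
  log <- c(log, sprintf("hemolysis QC: %d/%d samples pass",
                        length(keep), nrow(qc)))
  if (length(keep) == 0) abort("no samples pass QC")

  expr <- relative_expression(ct[ct$sample_id %in% keep, ],
                              target = cfg$target,
                              references = cfg$references,
                              log_base = prm("log_base", 10))
  paths$expression <- file.path(out_dir, "expression.tsv")
  readr::write_tsv(expr, paths$expression, progress = FALSE)
  log <- c(log, sprintf("expression: %d samples quantified", nrow(expr)))

  comparison <- NULL
  if ("group" %in% names(expr) && length(unique(expr$group)) >= 2) {
    comparison <- compare_groups(expr)
    paths$comparison <- file.path(out_dir, "group_comparison.tsv")
    readr::write_tsv(comparison$pairwise, paths$comparison, progress = FALSE)
    paths$descriptives <- file.path(out_dir, "group_descriptives.tsv")
    readr::write_tsv(comparison$descriptives, paths$descriptives, progress = FALSE)
    log <- c(log, sprintf("group comparison: %s design",
                          comparison$meta$design))
  } else {
    log <- c(log, "group comparison: skipped (<2 groups)")
  }

  paths$log <- file.path(out_dir, "run_log.txt")
  readr::write_lines(log, paths$log)
  invisible(list(qc = qc, expression = expr, comparison = comparison,
                 paths = paths))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a named list or a YAML path")
  config
}
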