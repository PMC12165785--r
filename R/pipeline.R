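#' Default pipeline configuration
#'
#' Key-value configuration for [run_pipeline()]. Defaults are the study
#' conditions of the assay: a panel of 9 benign and 14 pathogenic controls
#' plus 54 query variants, at least 7,500 reads per sample, 3 biological
#' replicates, thresholds 25/50, 95% confidence.
#'
#' @param seed Integer seed (mandatory; drives every random draw).
#' @param out_dir Output directory; `NULL` for in-memory results only.
#' @param ... Overrides for any default field.
#' @return Named list of configuration values.
#' @export
default_config <- function(seed, out_dir = NULL, ...) {
  cfg <- list(
    mode = "simulate",            # or "ingest" (requires allele_table_dir)
    seed = as.integer(seed),
    out_dir = out_dir,
    allele_table_dir = NULL,
    n_benign_controls = 9L,
    n_pathogenic_controls = 14L,
    n_query = 54L,
    n_reads = 7500L,
    n_replicates = 3L,
    replicate_cv = 0.1,
    frameshift_day12_retention = 0.2,
    day2_fractions = c(variant = 0.10, wtprime = 0.10,
                       frameshift = 0.20, other = 0.60),
    min_reads = 7500L,
    threshold_deleterious = 25,
    threshold_neutral = 50,
    confidence = 0.95)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> ratio analysis -> calibration ->
#' functional interpretation -> ACMG/AMP classification -> report, and
#' assembles a run manifest (config snapshot, seed, QC summary, frameshift
#' internal-control flags, output checksums). Idempotent given the seed.
#'
#' @param config Configuration list from [default_config()], or the path of
#'   a YAML file with the same keys.
#' @return Invisibly, a list with `panel`, `counts`, `ratios`, `summary`,
#'   `frameshift_report`, `calibration`, `calls`, `classification`,
#'   `report`, `manifest`. When `config$out_dir` is set, tables are written
#'   there as TSV/JSON and their checksums recorded in the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("seed", "mode", "n_reads", "n_replicates", "min_reads")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "))
  }
  cfg <- config
  if (!is.null(cfg$day2_fractions)) {
    cfg$day2_fractions <- unlist(cfg$day2_fractions)
    if (is.null(names(cfg$day2_fractions))) {
      # YAML serializes the vector without names; order is documented
      names(cfg$day2_fractions) <- c("variant", "wtprime", "frameshift",
                                     "other")
    }
  }

  if (cfg$mode == "simulate") {
    panel <- generate_variant_panel(cfg$n_benign_controls,
                                    cfg$n_pathogenic_controls,
                                    cfg$n_query, seed = cfg$seed)
    sim_cfg <- simulation_config(cfg$n_reads, cfg$n_replicates,
                                 cfg$frameshift_day12_retention,
                                 seed = cfg$seed)
    counts <- simulate_panel(panel, sim_cfg,
                             day2_fractions = cfg$day2_fractions,
                             replicate_cv = cfg$replicate_cv)
  } else if (cfg$mode == "ingest") {
    if (is.null(cfg$allele_table_dir)) {
      stop("config error in ingest mode: 'allele_table_dir' is required")
    }
    if (is.null(cfg$panel_file)) {
      stop("config error in ingest mode: 'panel_file' (variant annotation ",
           "table) is required")
    }
    panel <- utils::read.delim(cfg$panel_file, stringsAsFactors = FALSE)
    edit_defs <- make_edit_definitions(panel, seed = cfg$seed)
    counts <- ingest_samples(file.path(cfg$allele_table_dir, "manifest.tsv"),
                             edit_defs, dir = cfg$allele_table_dir)
  } else {
    stop("unknown pipeline mode: ", cfg$mode)
  }

  ratios <- normalized_ratios(counts, "variant", min_reads = cfg$min_reads)
  summary_df <- summarize_ratios(ratios)
  fs_ratios <- normalized_ratios(counts, "frameshift",
                                 min_reads = cfg$min_reads)
  fs_report <- frameshift_selection_report(summarize_ratios(fs_ratios))

  scores <- calibration_scores(summary_df)
  ctrl_roles <- c(control_benign = "benign", control_pathogenic = "pathogenic")
  ctrl <- panel[panel$role %in% names(ctrl_roles), c("variant_id", "role")]
  controls <- merge(ctrl, scores, by = "variant_id")
  controls$truth <- unname(ctrl_roles[controls$role])
  calibration <- calibrate_assay(controls,
                                 threshold_deleterious =
                                   cfg$threshold_deleterious,
                                 threshold_neutral = cfg$threshold_neutral,
                                 confidence = cfg$confidence)

  calls <- functional_calls(summary_df, calibration)
  queries <- calls[calls$variant_id %in%
                     panel$variant_id[panel$role == "query"], , drop = FALSE]
  classification <- classify_panel(queries, panel)

  class_counts <- table(factor(classification$final_class, levels = CLASSES))
  report <- list(
    n_variants = nrow(panel),
    n_query = nrow(classification),
    n_classified = sum(classification$final_class != "uncertain"),
    class_counts = as.list(class_counts),
    sensitivity = calibration$sensitivity,
    specificity = calibration$specificity,
    oddspath_pathogenic = calibration$oddspath_pathogenic,
    oddspath_benign = calibration$oddspath_benign,
    ps3_strength = calibration$ps3_strength,
    bs3_strength = calibration$bs3_strength)

  qc_failed <- attr(ratios, "qc_failures")
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    package_version = as.character(utils::packageVersion("crisprselect")),
    qc = list(n_samples = nrow(counts),
              n_failed_min_reads = nrow(qc_failed),
              failed_samples = if (nrow(qc_failed)) paste(
                qc_failed$variant_id, qc_failed$condition,
                qc_failed$replicate_id, sep = "/") else character()),
    frameshift_depleted_fraction =
      if (nrow(fs_report)) mean(fs_report$depleted) else NA_real_,
    outputs = list())

  result <- list(panel = panel, counts = counts, ratios = ratios,
                 summary = summary_df, frameshift_report = fs_report,
                 calibration = calibration, calls = calls,
                 classification = classification, report = report,
                 manifest = manifest)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      path <- file.path(cfg$out_dir, name)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      path
    }
    paths <- c(wr(panel, "panel.tsv"), wr(summary_df, "ratio_summary.tsv"),
               wr(fs_report, "frameshift_control.tsv"),
               wr(calls, "functional_calls.tsv"),
               wr(classification, "classification.tsv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, file.path(cfg$out_dir, "report.json"))
    result$manifest$outputs <- as.list(tools::md5sum(paths))
    jsonlite::write_json(result$manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}

#' Load the bundled synthetic assay panel
#'
#' A synthetic stand-in table (no measured data): 54 query variants whose
#' per-condition replicate-mean normalized ratios encode the functional
#' categories reported for the assayed VUS panel, with plausible
#' population-frequency and in-silico annotations and asserted splicing
#' codes. It exists so the classification engine can be exercised end to end
#' without the assay's supplementary per-variant tables.
#'
#' @return Data.frame with per-condition `mean_<condition>` columns and
#'   annotation columns.
#' @export
synthetic_pbd_panel <- function() {
  utils::read.delim(system.file("extdata", "synthetic_pbd_panel.tsv",
                                package = "crisprselect", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Classify the bundled synthetic panel
#'
#' Convenience wrapper: converts the bundled panel's per-condition means
#' into functional calls and classifies every variant.
#'
#' @param panel Data.frame as from [synthetic_pbd_panel()].
#' @param thresholds Category thresholds, see [categorize()].
#' @return Classification data.frame from [classify_panel()].
#' @export
classify_mean_panel <- function(panel = synthetic_pbd_panel(),
                                thresholds = c(deleterious = 25,
                                               neutral = 50)) {
  mean_cols <- paste0("mean_", DAY12_CONDITIONS)
  long <- do.call(rbind, lapply(DAY12_CONDITIONS, function(cond) {
    data.frame(variant_id = panel$variant_id, condition = cond,
               mean = panel[[paste0("mean_", cond)]], sd = 0,
               n = 3L, stringsAsFactors = FALSE)
  }))
  calls <- functional_calls(long, thresholds = thresholds)
  classify_panel(calls, panel)
}
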