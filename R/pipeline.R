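#' Assemble a pipeline configuration
#'
#' Collects everything one end-to-end run needs. Defaults mirror the
#' workflow's standard choices: 5 ppm merge tolerance, sample filter at
#' mean replicate correlation 0.7, feature filter at median PID/CV 30%,
#' score weights 30 and 100.
#'
#' @param tables character vector (>= 2) of feature-table paths.
#' @param design path to the replicate-design file.
#' @param output_dir directory for all artifacts (created).
#' @param mz_tolerance_ppm,rt_tolerance_s,t_test_alpha,tie_break see
#'   [merge_config()].
#' @param samp_filt_thresh sample-correlation filter (`NA` disables).
#' @param feat_filt_thresh median-metric feature filter in percent, applied
#'   to the merged table (`NA` disables).
#' @param zero_as_missing missing-value convention for input tables.
#' @param compound_db optional path to a compound database TSV; when given,
#'   the merged features are annotated.
#' @param adducts,annotation_ppm annotation settings.
#' @param w score weights used in the run summary.
#' @param seed integer seed recorded in the log (the pipeline itself is
#'   deterministic; the seed is forwarded to any downstream simulation).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tables, design, output_dir,
                            mz_tolerance_ppm = 5, rt_tolerance_s = 10,
                            t_test_alpha = NA, tie_break = "intensity",
                            samp_filt_thresh = 0.7, feat_filt_thresh = 30,
                            zero_as_missing = TRUE,
                            compound_db = NULL,
                            adducts = c("M+H", "M+H-H2O"),
                            annotation_ppm = 5,
                            w = c(30, 100), seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' Every field of [pipeline_config()] can be given as a flat JSON key;
#' omitted keys take the defaults.
#'
#' @param path path to a JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  # JSON null means "disabled", which the R side spells NA
  raw <- lapply(raw, function(v) if (is.null(v)) NA else v)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Run the end-to-end workflow
#'
#' Stages: read and validate the input tables and design; score sample
#' quality per table and drop biological samples falling below the
#' correlation threshold in any table; merge the (filtered) tables; score
#' sample and feature quality on the merged table; apply the feature
#' filter; optionally annotate the surviving features against a local
#' compound database. All artifacts land in `output_dir`:
#' `merged_features.tsv`, per-stage quality reports, the merge report, the
#' annotation reports, a `run_log.txt` (versions, parameters, seed,
#' timings — the only file with timestamps) and a `manifest.json` with
#' md5 hashes of every primary output.
#'
#' @param config a [pipeline_config()] or path to a JSON config.
#' @return Invisibly, a list with the merged [feature_table()], the merge
#'   report, quality tables, the annotation result (or `NULL`) and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  say("mzmerge pipeline ", as.character(utils::packageVersion("mzmerge")),
      " | R ", getRversion(), " | started ", format(Sys.time(), tz = "UTC"),
      " UTC | seed ", config$seed)

  if (length(config$tables) < 2)
    stop("validation error [input]: need at least two feature tables, got ",
         length(config$tables))
  for (p in c(config$tables, config$design))
    if (!file.exists(p)) stop("file not found [input]: ", p)

  tables <- lapply(config$tables, read_feature_table,
                   zero_as_missing = config$zero_as_missing)
  design <- read_replicate_design(config$design)
  say("inputs: ", length(tables), " tables (",
      paste(vapply(tables, n_features, 0L), collapse = ", "),
      " features), ", nrow(design), " profiles, parameters: ppm=",
      config$mz_tolerance_ppm, " rt_tol=", config$rt_tolerance_s,
      " samp_filt=", config$samp_filt_thresh,
      " feat_filt=", config$feat_filt_thresh)

  # stage: sample quality per input table; drop a sample when it fails in
  # any table so the merged inputs keep identical profile columns
  sample_q <- lapply(seq_along(tables), function(k) {
    q <- evaluate_samples(tables[[k]], design)
    write_quality_reports(q, NULL, out, sprintf("input%d_", k))
    q
  })
  dropped <- character()
  if (!is.na(config$samp_filt_thresh)) {
    for (q in sample_q)
      dropped <- union(dropped, q$sample_id[
        !is.na(q$mean_pairwise_correlation) &
          q$mean_pairwise_correlation < config$samp_filt_thresh])
    if (length(dropped)) {
      keep <- design$profile_id[!design$sample_id %in% dropped]
      if (!length(keep))
        stop("computation error [sample filter]: every sample failed the ",
             "correlation threshold")
      tables <- lapply(tables, subset_profiles, keep = keep)
      design <- structure(
        design[design$profile_id %in% keep, , drop = FALSE],
        class = c("replicate_design", "data.frame"))
      say("sample filter: dropped ", length(dropped), " sample(s): ",
          paste(dropped, collapse = ", "))
    } else say("sample filter: no sample below threshold")
  } else say("sample filter: disabled")

  mcfg <- merge_config(config$mz_tolerance_ppm, config$rt_tolerance_s,
                       config$t_test_alpha, config$tie_break)
  res <- merge_results(tables, design, mcfg)
  write_merge_report(res$report, out)
  say("merge: ", paste(res$report$n_input_features, collapse = " + "),
      " -> ", res$report$n_output, " features (",
      res$report$n_redundant_collapsed, " redundant groups collapsed)")

  merged_q_feat <- evaluate_features(res$table, design)
  merged_q_samp <- evaluate_samples(res$table, design)
  write_quality_reports(merged_q_samp, merged_q_feat, out, "merged_")

  final <- filter_features(res$table, merged_q_feat,
                           config$feat_filt_thresh)
  say("feature filter: ", n_features(res$table), " -> ",
      n_features(final), " features (median metric < ",
      config$feat_filt_thresh, "%)")
  merged_path <- file.path(out, "merged_features.tsv")
  write_feature_table(final, merged_path,
                      zero_as_missing = config$zero_as_missing)

  ann <- NULL
  if (is.character(config$compound_db) && length(config$compound_db) &&
      !is.na(config$compound_db) && nzchar(config$compound_db)) {
    db <- read_compound_db(config$compound_db)
    ann <- batch_annotate(final$mz, db, config$adducts,
                          config$annotation_ppm)
    write_annotation_report(ann, file.path(out, "annotation.tsv"), "text")
    write_annotation_report(ann, file.path(out, "annotation.html"), "html")
    say("annotation: ", nrow(ann$hits), " hits for ",
        length(unique(ann$hits$query_mz)), "/", n_features(final),
        " features against ", nrow(db), " compounds")
  }

  primary <- c("merged_features.tsv", "merged_sample_quality.tsv",
               "merged_feature_quality.tsv", "merge_collapses.tsv",
               "merge_log.txt",
               sprintf("input%d_sample_quality.tsv", seq_along(sample_q)),
               if (!is.null(ann)) c("annotation.tsv", "annotation.html"))
  files <- file.path(out, primary)
  manifest <- list(
    inputs = as.list(config$tables), design = config$design,
    parameters = list(
      mz_tolerance_ppm = config$mz_tolerance_ppm,
      rt_tolerance_s = config$rt_tolerance_s,
      t_test_alpha = config$t_test_alpha,
      samp_filt_thresh = config$samp_filt_thresh,
      feat_filt_thresh = config$feat_filt_thresh,
      zero_as_missing = config$zero_as_missing,
      seed = config$seed),
    dropped_samples = as.list(dropped),
    outputs = lapply(stats::setNames(files, primary), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done ", format(Sys.time(), tz = "UTC"), " UTC")
  writeLines(log, file.path(out, "run_log.txt"))
  invisible(list(table = final, merged_unfiltered = res$table,
                 report = res$report, sample_quality = sample_q,
                 merged_feature_quality = merged_q_feat,
                 merged_sample_quality = merged_q_samp,
                 annotation = ann, manifest = manifest,
                 dropped_samples = dropped))
}
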