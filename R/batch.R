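# Batch orchestration over whole assemblages: per-artifact reports,
# tabular exports, an assemblage summary, and a processing log. Per-file
# failures are logged and skipped so one bad scan never aborts a run.

#' Analyze every mesh in a directory
#'
#' Processes each readable mesh (obj/ply/stl/wrl) through the full pipeline
#' and writes `segments.csv` (one row per edge segment), `artifacts.csv`
#' (one row per artifact), `summary.json` and `processing_log.csv` into
#' `output_dir`. A rotation sidecar `<meshname>.rotation.json` (nine
#' row-major numbers) in the input directory is applied when present.
#'
#' @param input_dir directory of mesh files.
#' @param output_dir output directory (created if needed).
#' @param config a [ceam_config()].
#' @return invisibly, a list with `reports`, `summary`, `log`, and `status`
#'   (`"ok"`, `"partial"`, or `"error"`).
#' @export
run_batch <- function(input_dir, output_dir, config = ceam_config()) {
  files <- list.files(input_dir, pattern = "\\.(obj|ply|stl|wrl|vrml)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no mesh files found in ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(output_dir)) stop("cannot create output directory ", output_dir)

  reports <- list()
  log_rows <- list()
  for (f in files) {
    id <- basename(f)
    t0 <- proc.time()[["elapsed"]]
    rot <- NULL
    sidecar <- file.path(dirname(f),
                         paste0(tools::file_path_sans_ext(basename(f)),
                                ".rotation.json"))
    if (file.exists(sidecar)) {
      nums <- unlist(jsonlite::read_json(sidecar, simplifyVector = TRUE))
      rot <- matrix(as.numeric(nums), 3L, 3L, byrow = TRUE)
    }
    res <- tryCatch(
      suppressMessages(analyze_artifact(f, config, rotation = rot, artifact_id = id)),
      error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      log_rows[[id]] <- data.frame(artifact_id = id, status = "failed",
                                   seconds = elapsed,
                                   message = conditionMessage(res))
    } else {
      reports[[id]] <- res$report
      log_rows[[id]] <- data.frame(artifact_id = id, status = "ok",
                                   seconds = elapsed, message = "")
    }
  }
  log_df <- do.call(rbind, log_rows)
  status <- if (length(reports) == 0L) "error" else
    if (nrow(log_df[log_df$status == "failed", ]) > 0L) "partial" else "ok"

  seg_df <- do.call(rbind, lapply(reports, function(r) {
    cbind(artifact_id = r$artifact_id, r$segments)
  }))
  art_df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(artifact_id = r$artifact_id, n_segments = r$n_segments,
               n_sharp_edges = r$n_sharp_edges,
               percent_sharp = r$percent_sharp_perimeter,
               mean_edge_angle = r$mean_edge_angle,
               refinement = r$refinement, perimeter = r$perimeter,
               threshold_used = r$threshold)
  }))
  summary <- assemblage_summary(reports)
  if (length(reports)) {
    utils::write.csv(seg_df, file.path(output_dir, "segments.csv"), row.names = FALSE)
    utils::write.csv(art_df, file.path(output_dir, "artifacts.csv"), row.names = FALSE)
    jsonlite::write_json(c(summary, list(status = status, config = unclass(config))),
                         file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  utils::write.csv(log_df, file.path(output_dir, "processing_log.csv"), row.names = FALSE)
  invisible(list(reports = reports, summary = summary, log = log_df,
                 status = status))
}

#' Summaries across an assemblage of artifact reports
#'
#' Segment-count proportions, the pooled segment-angle distribution with its
#' sharp/blunt trough (when at least 30 segments are available), the mean and
#' normal-theory 95% confidence interval of percent-sharp perimeter, and
#' concavity-label proportions.
#'
#' @param reports list of `artifact_report` objects.
#' @return named list.
#' @export
assemblage_summary <- function(reports) {
  if (length(reports) == 0L) return(list(n_artifacts = 0L))
  nseg <- vapply(reports, function(r) r$n_segments, 1L)
  seg_counts <- table(nseg)
  seg_prop <- as.numeric(seg_counts) / length(reports)
  names(seg_prop) <- names(seg_counts)
  pooled <- unlist(lapply(reports, function(r) r$segments$mean_angle))
  trough <- if (length(pooled) >= 30L) sharp_threshold(pooled) else NULL
  ps <- vapply(reports, function(r) r$percent_sharp_perimeter, 0)
  ci <- if (length(ps) > 1L) {
    mean(ps) + c(-1, 1) * stats::qt(0.975, length(ps) - 1L) *
      stats::sd(ps) / sqrt(length(ps))
  } else c(NA_real_, NA_real_)
  labels <- unlist(lapply(reports, function(r) r$segments$concavity_label))
  lab_tab <- table(labels)
  lab_prop <- as.numeric(lab_tab) / length(labels)
  names(lab_prop) <- names(lab_tab)
  multi <- mean(vapply(reports, function(r) r$n_sharp_edges > 1L, TRUE))
  blunt_any <- mean(vapply(reports, function(r) {
    r$percent_sharp_perimeter < 100 - 1e-9
  }, TRUE))
  list(n_artifacts = length(reports),
       n_segments_total = sum(nseg),
       segments_per_artifact = mean(nseg),
       n_sharp_segments_total = sum(vapply(reports, function(r) r$n_sharp_edges, 1L)),
       segment_count_proportions = as.list(seg_prop),
       pooled_trough = if (!is.null(trough)) trough$trough else NA_real_,
       pooled_threshold = if (!is.null(trough)) trough$threshold else NA_real_,
       percent_sharp_mean = mean(ps),
       percent_sharp_ci95 = ci,
       prop_multi_edge = multi,
       prop_with_blunt_perimeter = blunt_any,
       concavity_label_proportions = as.list(lab_prop))
}
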