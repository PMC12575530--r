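#' Read / write / validate a case manifest
#'
#' The manifest drives the pipeline: one row per case with columns
#' `case_id, label, pancreas_path, mpd_path, heatmap_path, segment_truth,
#' split`. `split` partitions cases into the threshold-setting set
#' (`"calibration"`) and the evaluation set (`"test"`).
#'
#' @param file CSV path.
#' @return The validated manifest data frame.
#' @export
read_manifest <- function(file) {
  validate_manifest(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, file) {
  utils::write.csv(validate_manifest(manifest), file, row.names = FALSE)
  invisible(file)
}

#' @rdname read_manifest
#' @export
validate_manifest <- function(manifest) {
  needed <- c("case_id", "label", "pancreas_path", "mpd_path",
              "heatmap_path", "split")
  missing_cols <- setdiff(needed, names(manifest))
  if (length(missing_cols))
    stop("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(manifest$case_id))
    stop("duplicate case_id in manifest")
  bad <- setdiff(unique(manifest$split), c("calibration", "test"))
  if (length(bad))
    stop("invalid split values: ", paste(bad, collapse = ", "))
  manifest
}

#' Pipeline configuration
#'
#' Collects every tunable of the detection pipeline with its default:
#' centerline resampling (`step_mm`, 1 mm) and smoothing
#' (`smoothing_window`, 5 stations); cross-section sampling (`extent_mm`
#' 40 mm half-width, `in_plane_spacing_mm` defaulting to the native voxel
#' pitch); D/P summarisation (`percentile_q` 90,
#' `min_parenchyma_area_mm2` 20); jump localization (`jump_smooth_window`
#' 5, `min_jump` 0.005 ratio units); segment breakpoints (head `[0,0.40)`,
#' body `[0.40,0.70)`, tail `[0.70,1]`); head orientation rule
#' (`head_vector`, default `-x`, matching the phantom generator's
#' head-at-low-x convention); calibration targets (80% mass sensitivity,
#' 100% D/P specificity).
#'
#' @param ... overrides for individual entries.
#' @return Named configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    step_mm = 1, smoothing_window = 5L,
    extent_mm = 40, in_plane_spacing_mm = NULL,
    percentile_q = 90, min_parenchyma_area_mm2 = 20,
    jump_smooth_window = 5L, jump_window = 10L, min_jump = 0.005,
    segment_breakpoints = c(head = 0.40, body = 0.70),
    head_rule = head_vector(c(-1, 0, 0)),
    max_localization_distance_mm = 40,
    target_mass_sensitivity = 0.80,
    target_dp_specificity = 1.00,
    roi_restrict = FALSE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Score one case (both channels)
#'
#' Runs the per-case chain: centerline estimation and orientation, D/P
#' profile, 90th-percentile D/P score and jump localization; heatmap
#' maximum with peak projection onto the centerline. Returns the scores
#' and localization inputs that [classify_case] consumes.
#'
#' @param pancreas_mask,mpd_mask,heatmap [image_volume]s on one grid.
#' @param config a [pipeline_config].
#' @param case_id identifier carried through.
#' @return One-row data frame of per-case scores; the D/P profile is
#'   attached as attribute `"profile"`.
#' @export
score_case <- function(pancreas_mask, mpd_mask, heatmap,
                       config = pipeline_config(), case_id = NA_character_) {
  path <- estimate_centerline(pancreas_mask, mpd_mask,
                              step_mm = config$step_mm,
                              smoothing_window = config$smoothing_window)
  path <- orient_path(path, config$head_rule)
  prof <- compute_dp_profile(path, pancreas_mask, mpd_mask,
                             percentile_q = config$percentile_q,
                             min_parenchyma_area_mm2 = config$min_parenchyma_area_mm2,
                             extent_mm = config$extent_mm,
                             in_plane_spacing_mm = config$in_plane_spacing_mm)
  p90 <- dp_score(prof)
  jump <- localize_dp_jump(prof, smooth_window = config$jump_smooth_window,
                           jump_window = config$jump_window,
                           min_jump = config$min_jump)
  hm <- heatmap_score(heatmap,
                      roi_mask = if (config$roi_restrict) pancreas_mask)
  mass_loc <- tryCatch(
    assign_segment(hm$peak_coordinate, path, config$segment_breakpoints,
                   config$max_localization_distance_mm),
    error = function(e) NULL)
  out <- data.frame(
    case_id = case_id,
    heatmap_max = hm$max_value,
    dp_p90 = p90,
    mass_segment = if (is.null(mass_loc)) NA_character_ else mass_loc$segment,
    mass_fraction = if (is.null(mass_loc)) NA_real_ else mass_loc$arclength_fraction,
    dp_segment = if (is.null(jump)) NA_character_ else
      segment_from_fraction(jump$arclength_fraction, config$segment_breakpoints),
    dp_fraction = if (is.null(jump)) NA_real_ else jump$arclength_fraction,
    centerline_length_mm = max(path$arclength_mm),
    stringsAsFactors = FALSE)
  attr(out, "profile") <- prof
  out
}

#' Run the full detection pipeline over a manifest
#'
#' For every case: load the NIfTI triplet, score both channels
#' ([score_case]); then calibrate thresholds on the `calibration` split,
#' classify the `test` split by logical disjunction, and evaluate
#' (confusion metrics with CIs per channel and combined, ROC per channel,
#' decision curves). Per-case failures are logged and reported as
#' unevaluable rather than aborting the cohort. When `output_dir` is
#' given, all intermediates are persisted (scores CSV, per-case profile
#' CSVs, thresholds JSON, classification CSV, metrics JSON) so every
#' reported number can be recomputed from them.
#'
#' @param manifest manifest data frame or CSV path.
#' @param config a [pipeline_config].
#' @param output_dir optional directory for persisted intermediates.
#' @param thresholds optional pre-calibrated `dp_thresholds`; when given,
#'   the calibration split is not required.
#' @return List: `scores`, `thresholds`, `classification` (results +
#'   summary on the test split), `evaluation` (metrics per model, `roc`,
#'   `dca`), `failures`, `log`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         output_dir = NULL, thresholds = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(output_dir, "profiles"), showWarnings = FALSE)
  }
  scores <- NULL
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      vols <- list(pancreas = read_volume(row$pancreas_path, logical = TRUE),
                   mpd = read_volume(row$mpd_path, logical = TRUE),
                   heatmap = read_volume(row$heatmap_path))
      sc <- score_case(vols$pancreas, vols$mpd, vols$heatmap, config,
                       case_id = row$case_id)
      if (!is.null(output_dir))
        write_profile_csv(attr(sc, "profile"),
                          file.path(output_dir, "profiles",
                                    paste0(row$case_id, "_profile.csv")))
      sc
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[row$case_id]] <- conditionMessage(res)
    } else {
      res$label <- row$label
      res$split <- row$split
      scores <- rbind(scores, res)
    }
  }
  if (is.null(scores)) stop("no case could be evaluated; first failure: ",
                            failures[[1L]])
  if (is.null(thresholds)) {
    cal <- scores[scores$split == "calibration", ]
    if (nrow(cal) == 0L)
      stop("no calibration cases evaluated and no thresholds supplied")
    thresholds <- calibrate_thresholds(cal,
                                       config$target_mass_sensitivity,
                                       config$target_dp_specificity)
  }
  test <- scores[scores$split == "test", ]
  classification <- if (nrow(test) > 0L)
    classify_cohort(test, thresholds) else NULL

  evaluation <- NULL
  if (!is.null(classification) && !is.null(classification$summary) &&
      length(unique(test$label)) == 2L) {
    tabs <- classification$summary
    evaluation <- list(
      metrics = lapply(tabs, confusion_metrics),
      roc = list(mass = roc_curve(test$heatmap_max, test$label),
                 dp = roc_curve(test$dp_p90, test$label)),
      dca = decision_curve(tabs))
  }
  log <- list(r_version = R.version.string,
              package_version = as.character(utils::packageVersion("dpdetect")),
              n_cases = nrow(manifest), n_evaluated = nrow(scores),
              n_failed = length(failures),
              config = config[setdiff(names(config), "head_rule")],
              timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(scores = scores, thresholds = thresholds,
              classification = classification, evaluation = evaluation,
              failures = failures, log = log)
  if (!is.null(output_dir)) {
    utils::write.csv(scores, file.path(output_dir, "scores.csv"),
                     row.names = FALSE)
    write_thresholds_json(thresholds, file.path(output_dir, "thresholds.json"))
    if (!is.null(classification))
      utils::write.csv(classification$results,
                       file.path(output_dir, "classification.csv"),
                       row.names = FALSE)
    if (!is.null(evaluation))
      jsonlite::write_json(
        lapply(evaluation$metrics, function(m) as.list(m)),
        file.path(output_dir, "metrics.json"), auto_unbox = TRUE, digits = NA,
        dataframe = "columns")
  }
  out
}

#' Tumor-localization concordance against reference truth
#'
#' Fraction of cancers whose predicted segment matches the reference
#' segment. By default only cancers detected by the software enter the
#' denominator (undetected cancers have no predicted location); set
#' `denominator = "all"` to count them as discordant-by-absence. Head
#' sub-labels (`"head (uncinate process)"`, `"head (the other)"`) match at
#' plain `"head"` granularity.
#'
#' @param results classification results (from [classify_cohort]), with
#'   `case_id`, `verdict`, `segment`.
#' @param truths named character vector or data frame (`case_id`,
#'   `segment_truth`) giving the reference segment per cancer case.
#' @param denominator `"detected"` (default) or `"all"`.
#' @return List: `ratio` (in `[0, 1]`), `percent`, `n_matched`,
#'   `n_discordant`, `n_denominator`.
#' @export
localization_concordance <- function(results, truths,
                                     denominator = c("detected", "all")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(truths))
    truths <- stats::setNames(truths$segment_truth, truths$case_id)
  collapse <- function(x) ifelse(grepl("^head", x), "head", x)
  cancer_ids <- names(truths)[!is.na(truths) & truths != ""]
  if (length(cancer_ids) == 0L) {
    warning("no cancers with reference segments; concordance undefined")
    return(list(ratio = NA_real_, percent = NA_real_, n_matched = 0L,
                n_discordant = 0L, n_denominator = 0L))
  }
  res <- results[match(cancer_ids, results$case_id), ]
  detected <- !is.na(res$verdict) & res$verdict == "positive" &
    !is.na(res$segment)
  match_ok <- detected & collapse(res$segment) == collapse(truths[cancer_ids])
  denom <- if (denominator == "detected") sum(detected) else length(cancer_ids)
  if (denom == 0L) {
    warning("no detected cancers; concordance undefined")
    return(list(ratio = NA_real_, percent = NA_real_, n_matched = 0L,
                n_discordant = 0L, n_denominator = 0L))
  }
  n_matched <- sum(match_ok)
  list(ratio = n_matched / denom, percent = 100 * n_matched / denom,
       n_matched = n_matched, n_discordant = denom - n_matched,
       n_denominator = denom)
}
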