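#' Calibrate the two channel thresholds on a threshold-setting cohort
#'
#' Reproduces the stated threshold-setting rule: the tumor-mass (heatmap)
#' threshold is the largest cutoff `t` such that the fraction of
#' calibration cancers with `heatmap_max > t` is at least
#' `target_mass_sensitivity` (default 80%); the D/P threshold is the
#' smallest cutoff giving at least `target_dp_specificity` (default 100%)
#' on calibration controls under strict `>`, i.e. by default the maximum
#' control D/P score. Cutoffs are realized as midpoints between adjacent
#' distinct observed scores for stability to float jitter.
#'
#' @param calibration_scores data frame with columns `case_id`, `label`
#'   (`"cancer"`/`"control"`), `heatmap_max`, `dp_p90`.
#' @param target_mass_sensitivity required mass-channel sensitivity.
#' @param target_dp_specificity required D/P-channel specificity.
#' @return A `dp_thresholds` list: `heatmap_thr`, `dp_thr`, `provenance`
#'   (set sizes, targets, achieved rates).
#' @export
calibrate_thresholds <- function(calibration_scores,
                                 target_mass_sensitivity = 0.80,
                                 target_dp_specificity = 1.00) {
  sc <- calibration_scores
  if (is.null(sc) || nrow(sc) == 0L) stop("calibration set is empty")
  stopifnot(all(c("label", "heatmap_max", "dp_p90") %in% names(sc)))
  cancers <- sc$heatmap_max[sc$label == "cancer"]
  controls <- sc$dp_p90[sc$label == "control"]
  if (length(cancers) == 0L || length(controls) == 0L)
    stop("calibration set must contain both cancers and controls")

  # mass channel: largest t with sens(t) >= target, midpoint realization
  x <- sort(cancers[is.finite(cancers)], decreasing = TRUE)
  k <- ceiling(target_mass_sensitivity * length(x))
  xk <- x[k]
  below <- x[x < xk]
  heatmap_thr <- if (length(below)) (xk + max(below)) / 2 else xk / 2
  achieved_sens <- mean(cancers > heatmap_thr)
  if (achieved_sens < target_mass_sensitivity || xk <= 0)
    stop(sprintf(paste0("mass-sensitivity target %.0f%% unattainable on the ",
                        "calibration set (achieved %.0f%% at threshold %g)"),
                 100 * target_mass_sensitivity, 100 * achieved_sens,
                 heatmap_thr))

  # D/P channel: smallest t with spec(t) >= target under strict ">"
  y <- sort(controls[is.finite(controls)])
  m <- ceiling(target_dp_specificity * length(y))
  dp_thr <- y[m]
  achieved_spec <- mean(controls <= dp_thr)

  structure(list(
    heatmap_thr = heatmap_thr, dp_thr = dp_thr,
    provenance = list(
      n_cancer = length(cancers), n_control = length(controls),
      target_mass_sensitivity = target_mass_sensitivity,
      target_dp_specificity = target_dp_specificity,
      achieved_mass_sensitivity = achieved_sens,
      achieved_dp_specificity = achieved_spec)),
    class = "dp_thresholds")
}

#' @export
print.dp_thresholds <- function(x, ...) {
  cat(sprintf(paste0("<dp_thresholds> heatmap > %.4g, D/P > %.4g ",
                     "(calibrated on %d cancers / %d controls; achieved ",
                     "sens %.1f%%, spec %.1f%%)\n"),
              x$heatmap_thr, x$dp_thr, x$provenance$n_cancer,
              x$provenance$n_control,
              100 * x$provenance$achieved_mass_sensitivity,
              100 * x$provenance$achieved_dp_specificity))
  invisible(x)
}

#' Classify one case by logical disjunction of the two channels
#'
#' A case is positive if its maximum heatmap value exceeds the heatmap
#' threshold or its D/P 90th-percentile score exceeds the D/P threshold
#' (both strict `>`; boundary equality is negative). Localization follows
#' the reporting rule: the mass channel's segment when the mass channel
#' fired, otherwise the D/P jump segment when the D/P channel fired,
#' otherwise none. A missing score on a channel leaves that channel not
#' fired, with a warning.
#'
#' @param scores one-row data frame or list with `heatmap_max`, `dp_p90`
#'   and optionally `case_id`, `mass_segment`, `mass_fraction`,
#'   `dp_segment`, `dp_fraction`.
#' @param thresholds a `dp_thresholds` (or list with `heatmap_thr`,
#'   `dp_thr`).
#' @return One-row data frame: `case_id, verdict, mass_fired, dp_fired,
#'   fired_channels, segment, arclength_fraction, localization_source`.
#' @export
classify_case <- function(scores, thresholds) {
  get <- function(nm) if (!is.null(scores[[nm]])) scores[[nm]] else NA
  hm <- as.numeric(get("heatmap_max")); dp <- as.numeric(get("dp_p90"))
  if (is.na(hm)) warning("missing heatmap score; mass channel not fired")
  if (is.na(dp)) warning("missing D/P score; D/P channel not fired")
  mass_fired <- isTRUE(hm > thresholds$heatmap_thr)
  dp_fired <- isTRUE(dp > thresholds$dp_thr)
  seg <- NA_character_; frac <- NA_real_; src <- "none"
  if (mass_fired) {
    seg <- as.character(get("mass_segment")); frac <- as.numeric(get("mass_fraction"))
    src <- "mass"
  } else if (dp_fired) {
    seg <- as.character(get("dp_segment")); frac <- as.numeric(get("dp_fraction"))
    src <- "dp"
  }
  fired <- c("mass", "dp")[c(mass_fired, dp_fired)]
  data.frame(case_id = as.character(if (is.null(scores[["case_id"]]))
                                      NA else scores[["case_id"]]),
             verdict = if (mass_fired || dp_fired) "positive" else "negative",
             mass_fired = mass_fired, dp_fired = dp_fired,
             fired_channels = paste(fired, collapse = "+"),
             segment = seg, arclength_fraction = frac,
             localization_source = src, stringsAsFactors = FALSE)
}

#' Classify a cohort and tabulate per-channel performance
#'
#' Row-wise [classify_case] plus, when the scores carry a `label` column,
#' confusion tables for the mass channel, the D/P channel and their
#' disjunction against those labels.
#'
#' @param scores data frame of per-case scores (unique `case_id`).
#' @param thresholds a `dp_thresholds`.
#' @return List with `results` (one row per case) and `summary` (named
#'   list of [confusion_table]s, or `NULL` without labels).
#' @export
classify_cohort <- function(scores, thresholds) {
  stopifnot(is.data.frame(scores), nrow(scores) > 0L)
  if (anyDuplicated(scores$case_id))
    stop("duplicate case_id in scores: ",
         paste(unique(scores$case_id[duplicated(scores$case_id)]),
               collapse = ", "))
  results <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i)
    classify_case(scores[i, , drop = FALSE], thresholds)))
  summary <- NULL
  if ("label" %in% names(scores)) {
    truth <- scores$label == "cancer"
    summary <- list(
      mass = confusion_from_labels(results$mass_fired, truth),
      dp = confusion_from_labels(results$dp_fired, truth),
      combined = confusion_from_labels(results$verdict == "positive", truth))
  }
  list(results = results, summary = summary)
}

#' Persist / load thresholds as JSON
#'
#' @param thresholds a `dp_thresholds`.
#' @param file JSON path.
#' @return `file` (write) or a `dp_thresholds` (read).
#' @export
write_thresholds_json <- function(thresholds, file) {
  jsonlite::write_json(unclass(thresholds), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_thresholds_json
#' @export
read_thresholds_json <- function(file) {
  structure(jsonlite::read_json(file, simplifyVector = TRUE),
            class = "dp_thresholds")
}
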