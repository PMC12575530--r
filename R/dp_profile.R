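as_dp_profile <- function(df, percentile_q = 90, min_parenchyma_area_mm2 = 20) {
  structure(df, class = c("dp_profile", "data.frame"),
            percentile_q = percentile_q,
            min_parenchyma_area_mm2 = min_parenchyma_area_mm2)
}

#' Extract a cross-section of a volume perpendicular to a tangent
#'
#' Samples the volume by nearest-neighbour lookup on a regular 2-D grid
#' spanning the plane through `point` orthogonal to `tangent`. The
#' in-plane basis is chosen deterministically: the tangent is crossed with
#' the coordinate axis it is least aligned with (smallest `|tangent[i]|`,
#' ties toward the lower axis index), then orthonormalized. Samples
#' falling outside the volume are background (0).
#'
#' @param vol an [image_volume] (mask or scalar field).
#' @param point length-3 mm plane origin.
#' @param tangent length-3 plane normal (unit vector).
#' @param extent_mm half-width of the sampled square (default 40 mm,
#'   covering pancreas calibre).
#' @param in_plane_spacing_mm sampling pitch; defaults to the smallest
#'   voxel spacing.
#' @return Numeric matrix of sampled values with attributes `cell_area`
#'   (mm^2 per sample) and `offsets` (the 1-D in-plane mm grid).
#' @export
extract_cross_section <- function(vol, point, tangent, extent_mm = 40,
                                  in_plane_spacing_mm = NULL) {
  stopifnot(is_image_volume(vol))
  tangent <- as.numeric(tangent)
  nrm <- sqrt(sum(tangent^2))
  if (nrm < 1e-12) stop("tangent vector must be non-zero")
  tangent <- tangent / nrm
  if (is.null(in_plane_spacing_mm)) in_plane_spacing_mm <- min(vol$spacing)
  ax <- which.min(abs(tangent))              # least-aligned coordinate axis
  e <- c(0, 0, 0); e[ax] <- 1
  u <- cross3(tangent, e)
  u <- u / sqrt(sum(u^2))
  v <- cross3(tangent, u)

  g <- seq(-extent_mm, extent_mm, by = in_plane_spacing_mm)
  grid <- expand.grid(a = g, b = g)
  pts <- outer(grid$a, u) + outer(grid$b, v)
  pts <- sweep(pts, 2L, as.numeric(point), "+")
  ijk <- world_to_voxel(vol, pts)
  d <- dim(vol$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  vals <- numeric(nrow(ijk))
  if (any(ok)) vals[ok] <- as.numeric(vol$data[ijk[ok, , drop = FALSE]])
  out <- matrix(vals, nrow = length(g))
  attr(out, "cell_area") <- in_plane_spacing_mm^2
  attr(out, "offsets") <- g
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Compute the D/P ratio profile along a centerline
#'
#' For every centerline station, measures the MPD and parenchyma
#' cross-sectional areas on the plane perpendicular to the local tangent
#' and forms the D/P ratio `duct_area / parenchyma_area`. The denominator
#' is the parenchyma mask alone (the duct lumen is already excluded since
#' the masks are disjoint). Stations whose parenchyma area falls below
#' `min_parenchyma_area_mm2` (unstable organ tips where the ratio
#' diverges) are flagged invalid and excluded from all summaries.
#'
#' @param path an oriented `centerline_path`.
#' @param pancreas_mask,mpd_mask disjoint binary [image_volume]s on a
#'   common grid.
#' @param percentile_q percentile used by [dp_score] (default 90).
#' @param min_parenchyma_area_mm2 validity floor (default 20 mm^2).
#' @param extent_mm,in_plane_spacing_mm see [extract_cross_section].
#' @return A `dp_profile` data frame with one row per station:
#'   `arclength_mm, arclength_fraction, duct_area_mm2, parenchyma_area_mm2,
#'   dp_ratio, valid`.
#' @export
compute_dp_profile <- function(path, pancreas_mask, mpd_mask,
                               percentile_q = 90,
                               min_parenchyma_area_mm2 = 20,
                               extent_mm = 40, in_plane_spacing_mm = NULL) {
  stopifnot(inherits(path, "centerline_path"))
  n <- nrow(path$points)
  duct_area <- par_area <- numeric(n)
  for (i in seq_len(n)) {
    sec_p <- extract_cross_section(pancreas_mask, path$points[i, ],
                                   path$tangents[i, ], extent_mm,
                                   in_plane_spacing_mm)
    sec_d <- extract_cross_section(mpd_mask, path$points[i, ],
                                   path$tangents[i, ], extent_mm,
                                   in_plane_spacing_mm)
    par_area[i] <- sum(sec_p > 0) * attr(sec_p, "cell_area")
    duct_area[i] <- sum(sec_d > 0) * attr(sec_d, "cell_area")
  }
  total <- max(path$arclength_mm)
  valid <- par_area >= min_parenchyma_area_mm2
  ratio <- ifelse(par_area > 0, duct_area / par_area, NA_real_)
  if (!any(valid)) stop("no evaluable pancreatic cross-sections ",
                        "(all stations below the parenchyma-area floor)")
  prof <- data.frame(arclength_mm = path$arclength_mm,
                     arclength_fraction = path$arclength_mm / total,
                     duct_area_mm2 = duct_area,
                     parenchyma_area_mm2 = par_area,
                     dp_ratio = ratio, valid = valid)
  as_dp_profile(prof, percentile_q, min_parenchyma_area_mm2)
}

#' Summarise a D/P profile by its upper percentile
#'
#' Returns the `percentile_q`-th percentile (default 90th) of the D/P
#' ratio over valid stations, using the linear-interpolation quantile
#' definition (`stats::quantile` type 7).
#'
#' @param profile a `dp_profile`.
#' @param percentile_q optional override of the profile's percentile.
#' @return Scalar D/P score.
#' @export
dp_score <- function(profile, percentile_q = NULL) {
  if (is.null(percentile_q)) percentile_q <- attr(profile, "percentile_q")
  x <- profile$dp_ratio[profile$valid & is.finite(profile$dp_ratio)]
  if (length(x) == 0L) stop("no valid stations to summarise")
  unname(stats::quantile(x, percentile_q / 100, type = 7))
}

#' Localize the head-to-tail sharp increase of the D/P ratio
#'
#' Formalizes "the location where the D/P ratio increases sharply from the
#' head side to the tail side" as a step detector: after median
#' pre-smoothing, each station is scored by the forward contrast -- the
#' mean ratio over the next `jump_window` stations minus the mean over
#' the previous `jump_window` stations -- and the station maximizing that
#' contrast is reported, provided the contrast reaches `min_jump`. The
#' flanking windows (default 10 stations, i.e. about 1 cm at 1 mm
#' stations) average out voxel-scale noise that a single-station forward
#' difference is defenceless against. Ties go to the most head-ward
#' station.
#'
#' @param profile an oriented (head-to-tail) `dp_profile`.
#' @param smooth_window odd median pre-filter window in stations.
#' @param jump_window flank width of the step contrast, in stations.
#' @param min_jump minimum contrast (ratio units) to report a jump.
#' @return A list `(arclength_mm, arclength_fraction)` or `NULL` when no
#'   contrast reaches `min_jump` (or fewer than 2 valid stations).
#' @export
localize_dp_jump <- function(profile, smooth_window = 5L, jump_window = 10L,
                             min_jump = 0.005) {
  ok <- profile$valid & is.finite(profile$dp_ratio)
  x <- profile$dp_ratio[ok]
  n <- length(x)
  if (n < 2L) return(NULL)
  k <- min(smooth_window, n)
  if (k %% 2L == 0L) k <- k - 1L
  if (k >= 3L) x <- as.numeric(stats::runmed(x, k, endrule = "median"))
  w <- max(1L, jump_window)
  contrast <- vapply(seq_len(n - 1L), function(i)
    mean(x[(i + 1L):min(n, i + w)]) - mean(x[max(1L, i - w + 1L):i]),
    numeric(1L))
  best <- which.max(contrast)                # first index on ties: head-ward
  if (contrast[best] < min_jump) return(NULL)
  idx <- which(ok)[best]
  list(arclength_mm = profile$arclength_mm[idx],
       arclength_fraction = profile$arclength_fraction[idx])
}

#' Export a D/P profile as CSV
#'
#' @param profile a `dp_profile`.
#' @param file output CSV path.
#' @return `file`, invisibly.
#' @export
write_profile_csv <- function(profile, file) {
  utils::write.csv(as.data.frame(profile)[, c(
    "arclength_mm", "arclength_fraction", "duct_area_mm2",
    "parenchyma_area_mm2", "dp_ratio", "valid")], file, row.names = FALSE)
  invisible(file)
}

#' Plot a D/P profile
#'
#' Base-graphics plot of the per-station D/P ratio against arclength
#' fraction, with invalid stations greyed out and an optional threshold
#' line.
#'
#' @param profile a `dp_profile`.
#' @param threshold optional D/P threshold to draw.
#' @param ... passed to [graphics::plot].
#' @return `NULL`, invisibly.
#' @export
plot_dp_profile <- function(profile, threshold = NULL, ...) {
  graphics::plot(profile$arclength_fraction, profile$dp_ratio,
                 type = "l", xlab = "arclength fraction (head to tail)",
                 ylab = "D/P ratio", ...)
  graphics::points(profile$arclength_fraction[!profile$valid],
                   profile$dp_ratio[!profile$valid], col = "grey60", pch = 4)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
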