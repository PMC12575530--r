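#' Summarise a tumor-likelihood heatmap by its maximum
#'
#' The tumor-mass channel of the detector: a voxelwise likelihood volume
#' in `[0, 1]` (produced upstream by a segmentation CNN) is summarised by
#' its maximum value. Optionally the maximum is restricted to an ROI mask,
#' and the supra-threshold connected component containing the peak is
#' sized when a classification threshold is supplied.
#'
#' @param heatmap an [image_volume] with values in `[0, 1]`.
#' @param roi_mask optional binary [image_volume] on the same grid.
#' @param component_threshold optional likelihood cutoff; when given, the
#'   26-connected component of `heatmap > component_threshold` containing
#'   the peak is counted.
#' @return A `heatmap_result` list: `max_value`, `peak_voxel` (1-based
#'   ijk), `peak_coordinate` (mm), `component_voxel_count` (NA when no
#'   threshold given). Ties for the maximum resolve to the smallest
#'   linear voxel index.
#' @export
heatmap_score <- function(heatmap, roi_mask = NULL, component_threshold = NULL) {
  stopifnot(is_image_volume(heatmap))
  vals <- heatmap$data
  rng <- range(vals)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop(sprintf("heatmap values outside [0, 1]: observed range [%g, %g]",
                 rng[1L], rng[2L]))
  search <- vals
  if (!is.null(roi_mask)) {
    stopifnot(is_image_volume(roi_mask),
              all(dim(roi_mask$data) == dim(vals)))
    if (!any(roi_mask$data > 0)) stop("ROI mask is empty")
    search[!(roi_mask$data > 0)] <- -Inf
  }
  peak <- which.max(search)                 # smallest linear index on ties
  ijk <- arrayInd(peak, dim(vals))
  comp_n <- NA_integer_
  if (!is.null(component_threshold)) {
    supra <- vals > component_threshold
    if (supra[peak]) {
      labels <- .cc_label_3d(as.logical(supra), dim(vals), 26L)
      comp_n <- sum(labels == labels[peak])
    } else comp_n <- 0L
  }
  structure(list(max_value = vals[peak],
                 peak_voxel = as.integer(ijk),
                 peak_coordinate = as.vector(voxel_to_world(heatmap, ijk)),
                 component_voxel_count = comp_n),
            class = "heatmap_result")
}

#' Assign an anatomical segment to a location
#'
#' Maps a 3-D location (or an arclength fraction directly) to one of the
#' head / body / tail segments by projecting it onto the nearest
#' centerline station (ties toward the lower station index) and looking
#' the station's arclength fraction up in the breakpoints. The
#' "head (uncinate process)" category is never produced geometrically —
#' arclength cannot distinguish the uncinate — and exists only as a truth
#' label.
#'
#' @param location length-3 mm point, or a single arclength fraction in
#'   `[0, 1]`.
#' @param path oriented `centerline_path` (required for 3-D locations).
#' @param breakpoints named fractions `c(head=, body=)`; head is
#'   `[0, head)`, body `[head, body)`, tail `[body, 1]`.
#' @param max_distance_mm error if a 3-D location is farther than this
#'   from the path.
#' @return List `(segment, arclength_fraction)`.
#' @export
assign_segment <- function(location, path = NULL,
                           breakpoints = c(head = 0.40, body = 0.70),
                           max_distance_mm = 40) {
  if (length(location) == 1L) {
    frac <- as.numeric(location)
    if (frac < 0 || frac > 1) stop("arclength fraction must be in [0, 1]")
  } else {
    stopifnot(inherits(path, "centerline_path"), length(location) == 3L)
    d2 <- rowSums(sweep(path$points, 2L, as.numeric(location), "-")^2)
    i <- which.min(d2)                      # lower index on ties
    if (sqrt(d2[i]) > max_distance_mm)
      stop(sprintf("location off-pancreas: %.1f mm from the centerline ",
                   sqrt(d2[i])), "(limit ", max_distance_mm, " mm)")
    frac <- path$arclength_mm[i] / max(path$arclength_mm)
  }
  list(segment = segment_from_fraction(frac, breakpoints),
       arclength_fraction = frac)
}
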