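#' Specification of a synthetic pancreas phantom
#'
#' Describes one synthetic case: a curved tubular parenchyma with an
#' embedded coaxial main pancreatic duct (MPD), rasterized onto a voxel
#' grid, plus a blob-shaped tumor-likelihood heatmap. Cancer cases carry a
#' focal tumor at arclength fraction `tumor_arclength_fraction`; tail-ward
#' of the tumor the duct radius is multiplied by `dilation_factor`
#' (obstructive duct dilatation) and the parenchyma radius by
#' `atrophy_factor` (parenchymal atrophy), the two indirect indicators the
#' D/P ratio is designed to pick up.
#'
#' Radius profiles are functions of arclength fraction `s` in `[0, 1]`
#' returning mm (constants are promoted). The default geometry is a
#' head-to-tail curve of roughly 105 mm with parenchyma radius tapering
#' 10 to 6.5 mm and a 1.2 mm duct, sized so that a full case fits in a
#' ~0.3-megavoxel grid at 1 mm spacing.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing mm per voxel (scalar or length-3).
#' @param curve_control_points n x 3 matrix of mm points, head first.
#' @param parenchyma_radius_profile function s -> R(s) in mm (or constant).
#' @param duct_radius_profile function s -> r(s) in mm (or constant).
#' @param duct_offset length-3 mm displacement of the duct axis.
#' @param tumor_present logical; cancer case?
#' @param tumor_arclength_fraction tumor position s0 in (0, 1).
#' @param tumor_radius_mm tumor sphere radius (clinical small-PDAC
#'   diameters are 7-20 mm, i.e. radii 3.5-10 mm).
#' @param dilation_factor duct radius multiplier (>= 1) for s > s0.
#' @param atrophy_factor parenchyma radius multiplier (<= 1) for s > s0.
#' @param surface_noise_sd mm-scale boundary perturbation; realized as
#'   independent flips of boundary voxels at rate
#'   `min(0.5, surface_noise_sd / min(voxel_spacing))`.
#' @param heatmap_tumor_amplitude peak tumor-blob likelihood in `[0, 1]`.
#' @param heatmap_noise_sd additive Gaussian noise SD of the heatmap.
#' @param n_distractor_blobs number of non-tumor likelihood blobs.
#' @param distractor_amplitude_range range the distractor amplitudes are
#'   drawn from.
#' @param segment_breakpoints named fractions: head ends at
#'   `breakpoints["head"]`, body at `breakpoints["body"]`, tail at 1.
#' @param seed RNG seed making the case reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(136L, 56L, 40L),
                         voxel_spacing = c(1, 1, 1),
                         curve_control_points = default_control_points(),
                         parenchyma_radius_profile = function(s)
                           (10 - 3.5 * s) * end_taper(s, 0.28, 0.07),
                         duct_radius_profile = function(s)
                           1.2 * end_taper(s, 0.15, 0.15),
                         duct_offset = c(0, 0, 0),
                         tumor_present = FALSE,
                         tumor_arclength_fraction = 0.5,
                         tumor_radius_mm = 8,
                         dilation_factor = 1,
                         atrophy_factor = 1,
                         surface_noise_sd = 0,
                         heatmap_tumor_amplitude = 0.9,
                         heatmap_noise_sd = 0.01,
                         n_distractor_blobs = 2L,
                         distractor_amplitude_range = c(0.05, 0.35),
                         segment_breakpoints = c(head = 0.40, body = 0.70),
                         seed = 1L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing = if (length(voxel_spacing) == 1L)
      rep(as.numeric(voxel_spacing), 3L) else as.numeric(voxel_spacing),
    curve_control_points = as.matrix(curve_control_points),
    parenchyma_radius_profile = as_radius_fun(parenchyma_radius_profile),
    duct_radius_profile = as_radius_fun(duct_radius_profile),
    duct_offset = as.numeric(duct_offset),
    tumor_present = isTRUE(tumor_present),
    tumor_arclength_fraction = tumor_arclength_fraction,
    tumor_radius_mm = tumor_radius_mm,
    dilation_factor = dilation_factor,
    atrophy_factor = atrophy_factor,
    surface_noise_sd = surface_noise_sd,
    heatmap_tumor_amplitude = heatmap_tumor_amplitude,
    heatmap_noise_sd = heatmap_noise_sd,
    n_distractor_blobs = as.integer(n_distractor_blobs),
    distractor_amplitude_range = distractor_amplitude_range,
    segment_breakpoints = segment_breakpoints,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

default_control_points <- function() {
  rbind(c(18, 22, 19), c(48, 36, 21), c(82, 30, 20), c(116, 16, 18))
}

#' End-taper envelope for radius profiles
#'
#' Smoothly shrinks a radius profile toward the organ extremities, the
#' way the pancreatic head beak and tail tip taper: the envelope is 1 in
#' the interior and falls linearly to `floor` over the outer `span` of
#' arclength fraction at each end. Tapered tips keep the rasterized organ
#' from ending in blunt spherical caps, which would not look like a
#' pancreas and would bias centerline termination.
#'
#' @param s arclength fractions in `[0, 1]`.
#' @param floor envelope value at `s = 0` and `s = 1`.
#' @param span arclength fraction over which the taper acts.
#' @return Envelope values in `[floor, 1]`.
#' @export
end_taper <- function(s, floor = 0.28, span = 0.07) {
  pmin(1, floor + (1 - floor) * s / span, floor + (1 - floor) * (1 - s) / span)
}

as_radius_fun <- function(x) {
  if (is.function(x)) return(function(s) rep_len(x(s), length(s)))
  val <- as.numeric(x)
  function(s) rep_len(val, length(s))
}

validate_phantom_spec <- function(spec) {
  stopifnot(length(spec$grid_shape) == 3L, all(spec$grid_shape > 1L),
            all(spec$voxel_spacing > 0), ncol(spec$curve_control_points) == 3L,
            nrow(spec$curve_control_points) >= 2L)
  if (spec$dilation_factor < 1) stop("dilation_factor must be >= 1")
  if (spec$atrophy_factor > 1 || spec$atrophy_factor <= 0)
    stop("atrophy_factor must be in (0, 1]")
  if (spec$tumor_present &&
      (spec$tumor_arclength_fraction <= 0 || spec$tumor_arclength_fraction >= 1))
    stop("tumor_arclength_fraction must lie in (0, 1)")
  # control polygon must be monotone along its principal chord
  cp <- spec$curve_control_points
  chord <- cp[nrow(cp), ] - cp[1L, ]
  proj <- as.vector(cp %*% chord)
  if (any(diff(proj) <= 0))
    stop("curve control polygon is non-monotone along its head-tail chord ",
         "(possible self-intersection)")
  s <- seq(0, 1, length.out = 201L)
  rad <- effective_radii(spec, s)
  off <- sqrt(sum(spec$duct_offset^2))
  if (any(rad$r <= 0) || any(rad$R <= 0)) stop("all radii must be positive")
  if (any(rad$r + off >= rad$R)) {
    bad <- s[which.max(rad$r + off - rad$R)]
    stop(sprintf(paste0("duct does not fit inside parenchyma at s = %.2f ",
                        "(duct %.2f + offset %.2f >= parenchyma %.2f mm)"),
                 bad, rad$r[which.max(rad$r + off - rad$R)], off,
                 rad$R[which.max(rad$r + off - rad$R)]))
  }
  invisible(spec)
}

# duct and parenchyma radii after applying tumor dilation/atrophy tail-ward
effective_radii <- function(spec, s) {
  r <- spec$duct_radius_profile(s)
  R <- spec$parenchyma_radius_profile(s)
  if (spec$tumor_present) {
    tailward <- s > spec$tumor_arclength_fraction
    r[tailward] <- r[tailward] * spec$dilation_factor
    R[tailward] <- R[tailward] * spec$atrophy_factor
  }
  list(r = r, R = R)
}

# densely sample the head-to-tail axis curve at uniform arclength
sample_curve <- function(spec, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- min(spec$voxel_spacing) / 2
  cp <- spec$curve_control_points
  t0 <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  dense_t <- seq(0, t0[length(t0)], length.out = 40L * nrow(cp))
  pts <- sapply(seq_len(3L), function(a)
    stats::spline(t0, cp[, a], xout = dense_t, method = "natural")$y)
  arc <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  total <- arc[length(arc)]
  s_grid <- seq(0, total, by = step_mm)
  if (s_grid[length(s_grid)] < total) s_grid <- c(s_grid, total)
  out <- sapply(seq_len(3L), function(a)
    stats::approx(arc, pts[, a], xout = s_grid)$y)
  list(points = out, arclength = s_grid, fraction = s_grid / total,
       length = total)
}

#' Exact D/P ratio profile of a phantom
#'
#' Computes the per-station duct and parenchyma cross-sectional areas and
#' their ratio directly from the radius profiles (circle areas, no
#' voxelization). Serves as the brute-force oracle for the voxel-based
#' profile computation: the ratio at station `s` is
#' `r(s)^2 / (R(s)^2 - r(s)^2)`, the duct disc over the parenchyma annulus
#' (duct lumen excluded from the denominator, matching disjoint masks).
#'
#' @param spec a [phantom_spec].
#' @param n_stations number of evenly spaced stations on `[0, 1]`.
#' @param min_parenchyma_area_mm2 validity floor applied exactly as in
#'   the voxel-based profile (default 20 mm^2).
#' @return A `dp_profile` data frame (see [compute_dp_profile]).
#' @export
analytic_dp_profile <- function(spec, n_stations = 101L,
                                min_parenchyma_area_mm2 = 20) {
  validate_phantom_spec(spec)
  crv <- sample_curve(spec)
  s <- seq(0, 1, length.out = n_stations)
  rad <- effective_radii(spec, s)
  duct_area <- pi * rad$r^2
  par_area <- pi * rad$R^2 - duct_area
  prof <- data.frame(arclength_mm = s * crv$length, arclength_fraction = s,
                     duct_area_mm2 = duct_area, parenchyma_area_mm2 = par_area,
                     dp_ratio = duct_area / par_area,
                     valid = par_area >= min_parenchyma_area_mm2)
  as_dp_profile(prof, percentile_q = 90, min_parenchyma_area_mm2)
}

# stamp a union of spheres (centers n x 3 mm, radii mm) into a logical array
rasterize_tube <- function(grid_shape, spacing, origin, centers, radii) {
  arr <- array(FALSE, grid_shape)
  ax <- lapply(seq_len(3L), function(a)
    origin[a] + (seq_len(grid_shape[a]) - 1) * spacing[a])
  for (m in seq_len(nrow(centers))) {
    ctr <- centers[m, ]; rad <- radii[m]
    idx <- lapply(seq_len(3L), function(a) {
      lo <- ceiling((ctr[a] - rad - origin[a]) / spacing[a]) + 1
      hi <- floor((ctr[a] + rad - origin[a]) / spacing[a]) + 1
      seq.int(max(1, lo), min(grid_shape[a], hi))
    })
    if (any(lengths(idx) == 0L)) next
    d2 <- outer(outer((ax[[1]][idx[[1]]] - ctr[1])^2,
                      (ax[[2]][idx[[2]]] - ctr[2])^2, "+"),
                (ax[[3]][idx[[3]]] - ctr[3])^2, "+")
    arr[idx[[1]], idx[[2]], idx[[3]]] <-
      arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE] | (d2 <= rad^2)
  }
  arr
}

# flip boundary voxels (erode object rim / dilate background rim) at `rate`
apply_surface_noise <- function(arr, rate) {
  if (rate <= 0) return(arr)
  shifted_or <- function(a) {
    out <- array(FALSE, dim(a))
    d <- dim(a)
    out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
    out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
    out[, , -1] <- out[, , -1] | a[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
    out
  }
  near <- shifted_or(arr)
  inner_rim <- which(arr & shifted_or(!arr))
  outer_rim <- which(!arr & near)
  flips_in <- inner_rim[stats::runif(length(inner_rim)) < rate]
  flips_out <- outer_rim[stats::runif(length(outer_rim)) < rate]
  arr[flips_in] <- FALSE
  arr[flips_out] <- TRUE
  arr
}

# add a Gaussian blob by max-composition within a +/- 3.5 sigma box
add_blob <- function(arr, spacing, origin, center, sigma, amplitude) {
  gs <- dim(arr)
  ax <- lapply(seq_len(3L), function(a)
    origin[a] + (seq_len(gs[a]) - 1) * spacing[a])
  ext <- 3.5 * sigma
  idx <- lapply(seq_len(3L), function(a) {
    lo <- ceiling((center[a] - ext - origin[a]) / spacing[a]) + 1
    hi <- floor((center[a] + ext - origin[a]) / spacing[a]) + 1
    seq.int(max(1, lo), min(gs[a], hi))
  })
  if (any(lengths(idx) == 0L)) return(arr)
  d2 <- outer(outer((ax[[1]][idx[[1]]] - center[1])^2,
                    (ax[[2]][idx[[2]]] - center[2])^2, "+"),
              (ax[[3]][idx[[3]]] - center[3])^2, "+")
  blob <- amplitude * exp(-d2 / (2 * sigma^2))
  arr[idx[[1]], idx[[2]], idx[[3]]] <-
    pmax(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], blob)
  arr
}

#' Generate one synthetic pancreas case
#'
#' Rasterizes the phantom described by `spec` into three co-registered
#' volumes: a binary parenchyma mask (duct voxels removed, so the two
#' masks are disjoint), a binary MPD mask, and a tumor-likelihood heatmap
#' in `[0, 1]`. Cancer cases get a likelihood blob of amplitude
#' `heatmap_tumor_amplitude` at the tumor centre; all cases get
#' `n_distractor_blobs` lower-amplitude distractor blobs and voxelwise
#' noise. Fully deterministic given `spec$seed` (the function seeds the
#' global RNG).
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `pancreas_mask`, `mpd_mask`, `heatmap`
#'   (each an [image_volume]) and `truth` (a `ground_truth` list: label,
#'   tumor position/centre/segment, analytic curve length and analytic
#'   D/P profile).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  set.seed(spec$seed)
  gs <- spec$grid_shape; sp <- spec$voxel_spacing; org <- c(0, 0, 0)
  crv <- sample_curve(spec)
  rad <- effective_radii(spec, crv$fraction)

  # geometry must fit inside the grid
  ext_lo <- crv$points - rad$R - max(sp)
  ext_hi <- crv$points + rad$R + max(sp)
  lim <- (gs - 1) * sp
  if (any(ext_lo < 0) || any(sweep(ext_hi, 2L, lim, ">") )) {
    ax <- which(apply(ext_lo, 2, min) < 0 | apply(ext_hi, 2, max) > lim)[1L]
    stop(sprintf(paste0("phantom overflows the grid on axis %d: extent ",
                        "[%.1f, %.1f] mm vs grid [0, %.1f] mm (radius up to ",
                        "%.1f mm)"), ax, min(ext_lo[, ax]), max(ext_hi[, ax]),
                 lim[ax], max(rad$R)))
  }

  envelope <- rasterize_tube(gs, sp, org, crv$points, rad$R)
  duct_centers <- sweep(crv$points, 2L, spec$duct_offset, "+")
  duct <- rasterize_tube(gs, sp, org, duct_centers, rad$r)
  duct <- duct & envelope            # duct lies inside the parenchyma envelope
  noise_rate <- min(0.5, spec$surface_noise_sd / min(sp))
  envelope <- apply_surface_noise(envelope, noise_rate)
  duct <- apply_surface_noise(duct, noise_rate) & envelope
  pancreas <- envelope & !duct       # masks are disjoint

  # heatmap: noise floor + distractors (+ tumor blob for cancers)
  heat <- array(pmin(pmax(stats::rnorm(prod(gs), 0, spec$heatmap_noise_sd), 0), 1), gs)
  par_idx <- which(envelope)
  if (spec$n_distractor_blobs > 0L && length(par_idx) > 0L) {
    picks <- par_idx[sample.int(length(par_idx), spec$n_distractor_blobs,
                                replace = TRUE)]
    amps <- stats::runif(spec$n_distractor_blobs,
                         spec$distractor_amplitude_range[1L],
                         spec$distractor_amplitude_range[2L])
    sigmas <- stats::runif(spec$n_distractor_blobs, 2, 4)
    for (b in seq_len(spec$n_distractor_blobs)) {
      ctr <- voxel_to_world(image_volume(heat, sp), arrayInd(picks[b], gs))
      heat <- add_blob(heat, sp, org, as.vector(ctr), sigmas[b], amps[b])
    }
  }
  truth <- list(label = if (spec$tumor_present) "cancer" else "control",
                analytic_curve_length_mm = crv$length,
                analytic_dp_profile = analytic_dp_profile(spec),
                head_end_mm = crv$points[1L, ])
  if (spec$tumor_present) {
    s0 <- spec$tumor_arclength_fraction
    ctr <- crv$points[which.min(abs(crv$fraction - s0)), ]
    heat <- add_blob(heat, sp, org, ctr, spec$tumor_radius_mm / 2,
                     spec$heatmap_tumor_amplitude)
    truth$tumor_arclength_fraction <- s0
    truth$tumor_center <- ctr
    truth$tumor_radius_mm <- spec$tumor_radius_mm
    truth$segment_label <- segment_from_fraction(s0, spec$segment_breakpoints)
  }
  heat <- pmin(pmax(heat, 0), 1)
  class(truth) <- "ground_truth"
  list(pancreas_mask = image_volume(pancreas, sp),
       mpd_mask = image_volume(duct, sp),
       heatmap = image_volume(heat, sp),
       truth = truth)
}

segment_from_fraction <- function(fraction, breakpoints = c(head = 0.40, body = 0.70)) {
  ifelse(fraction < breakpoints[["head"]], "head",
         ifelse(fraction < breakpoints[["body"]], "body", "tail"))
}

#' Default cohort-level parameter distributions
#'
#' Ranges the cohort generator draws per-case phantom parameters from.
#' Duct calibre and parenchyma scale vary across cases (inter-patient
#' anatomy); cancers additionally draw tumor diameter (7-20 mm, the
#' clinical small-PDAC range), position, duct dilation, atrophy and
#' heatmap tumor amplitude. Distractor and noise settings apply to every
#' case so control heatmaps have non-trivial maxima.
#'
#' @param ... overrides for individual entries.
#' @return Named list of ranges/values.
#' @export
cohort_parameters <- function(...) {
  defaults <- list(
    duct_radius_range = c(0.9, 1.4),
    parenchyma_scale_range = c(0.9, 1.15),
    control_point_jitter_mm = 2.5,
    dilation_range = c(1.6, 2.4),
    atrophy_range = c(0.80, 0.95),
    tumor_fraction_range = c(0.15, 0.85),
    tumor_diameter_range = c(7, 20),
    tumor_amplitude_range = c(0.25, 0.95),
    surface_noise_sd = 0.3,
    heatmap_noise_sd = 0.01,
    n_distractor_blobs = 2L,
    distractor_amplitude_range = c(0.05, 0.35),
    base_spec = NULL)
  ov <- list(...)
  defaults[names(ov)] <- ov
  defaults
}

# draw one phantom_spec from cohort parameter distributions
draw_phantom_spec <- function(params, cancer, case_seed, base = NULL) {
  if (is.null(base)) base <- phantom_spec()
  runif1 <- function(rng) stats::runif(1L, rng[1L], rng[2L])
  dscale <- runif1(params$duct_radius_range) / 1.2
  pscale <- runif1(params$parenchyma_scale_range)
  cp <- base$curve_control_points
  jit <- params$control_point_jitter_mm
  cp[, 2:3] <- cp[, 2:3] + matrix(stats::runif(2L * nrow(cp), -jit, jit),
                                  ncol = 2L)
  base_R <- base$parenchyma_radius_profile
  base_r <- base$duct_radius_profile
  args <- list(
    grid_shape = base$grid_shape, voxel_spacing = base$voxel_spacing,
    curve_control_points = cp,
    parenchyma_radius_profile = function(s) pscale * base_R(s),
    duct_radius_profile = function(s) dscale * base_r(s),
    surface_noise_sd = params$surface_noise_sd,
    heatmap_noise_sd = params$heatmap_noise_sd,
    n_distractor_blobs = params$n_distractor_blobs,
    distractor_amplitude_range = params$distractor_amplitude_range,
    segment_breakpoints = base$segment_breakpoints,
    seed = case_seed)
  if (cancer) {
    args <- c(args, list(
      tumor_present = TRUE,
      tumor_arclength_fraction = runif1(params$tumor_fraction_range),
      tumor_radius_mm = runif1(params$tumor_diameter_range) / 2,
      dilation_factor = runif1(params$dilation_range),
      atrophy_factor = runif1(params$atrophy_range),
      heatmap_tumor_amplitude = runif1(params$tumor_amplitude_range)))
  }
  do.call(phantom_spec, args)
}

#' Generate a cohort of synthetic cases on disk
#'
#' Draws per-case phantom parameters from `params`, writes one NIfTI
#' triplet (parenchyma mask, MPD mask, heatmap) per case, and returns the
#' case manifest together with the ground truths. Bit-reproducible for a
#' fixed `seed`.
#'
#' @param n_cancer,n_control case counts for the given `split`.
#' @param params a [cohort_parameters] list.
#' @param seed cohort-level RNG seed.
#' @param dir output directory (created if missing).
#' @param split manifest split label, `"test"` or `"calibration"`.
#' @param prefix case-id prefix.
#' @return List with `manifest` (data frame: case_id, label,
#'   pancreas_path, mpd_path, heatmap_path, segment_truth, split),
#'   `truths` (named list of ground truths) and `specs`.
#' @export
generate_cohort <- function(n_cancer, n_control, params = cohort_parameters(),
                            seed = 1L, dir = tempfile("cohort"),
                            split = "test", prefix = split) {
  stopifnot(n_cancer >= 0L, n_control >= 0L)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("output directory not writable: ", dir)
  n <- n_cancer + n_control
  set.seed(seed)
  case_seeds <- sample.int(.Machine$integer.max - 1L, max(n, 1L))
  labels <- rep(c("cancer", "control"), c(n_cancer, n_control))
  manifest <- NULL
  truths <- list()
  specs <- list()
  for (i in seq_len(n)) {
    set.seed(case_seeds[i])
    spec <- draw_phantom_spec(params, labels[i] == "cancer", case_seeds[i],
                              base = params$base_spec)
    case <- generate_phantom(spec)
    cid <- sprintf("%s_%03d", prefix, i)
    paths <- file.path(dir, paste0(cid, c("_pancreas.nii.gz", "_mpd.nii.gz",
                                          "_heatmap.nii.gz")))
    write_volume(case$pancreas_mask, paths[1L])
    write_volume(case$mpd_mask, paths[2L])
    write_volume(case$heatmap, paths[3L])
    manifest <- rbind(manifest, data.frame(
      case_id = cid, label = labels[i],
      pancreas_path = paths[1L], mpd_path = paths[2L], heatmap_path = paths[3L],
      segment_truth = if (labels[i] == "cancer") case$truth$segment_label else "",
      split = split, stringsAsFactors = FALSE))
    truths[[cid]] <- case$truth
    specs[[cid]] <- spec
  }
  if (!is.null(manifest)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    write_truths_json(truths, file.path(dir, "truths.json"))
  }
  list(manifest = manifest, truths = truths, specs = specs, dir = dir)
}

write_truths_json <- function(truths, path) {
  slim <- lapply(truths, function(tr) {
    tr$analytic_dp_profile <- NULL
    unclass(tr)
  })
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
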