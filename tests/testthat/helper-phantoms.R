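# shared geometry helpers and a lazily generated small cohort

# axis-aligned solid cylinder along x: length mm, radius mm, 1 mm voxels
cylinder_volume <- function(length_mm = 100, radius_mm = 10, pad = 10) {
  d <- c(length_mm + 2 * pad, 2 * (radius_mm + pad / 2) + 1,
         2 * (radius_mm + pad / 2) + 1)
  ctr <- (d[2] + 1) / 2
  arr <- array(FALSE, d)
  disc <- outer((seq_len(d[2]) - ctr)^2, (seq_len(d[3]) - ctr)^2, "+") <=
    radius_mm^2
  for (i in seq_len(length_mm) + pad) arr[i, , ] <- disc
  image_volume(arr, c(1, 1, 1))
}

# straight-axis coaxial phantom (no taper, no noise); duct_mm and
# parenchyma_mm may be constants or radius-profile functions
straight_spec <- function(duct_mm = 2, parenchyma_mm = 10, spacing = 1,
                          length_mm = 100, ...) {
  max_R <- if (is.function(parenchyma_mm))
    max(parenchyma_mm(seq(0, 1, 0.01))) else parenchyma_mm
  margin <- max_R + 5
  phantom_spec(
    grid_shape = round(c(length_mm + 2 * margin, 2 * margin, 2 * margin) /
                         spacing),
    voxel_spacing = rep(spacing, 3L),
    curve_control_points = cbind(
      seq(margin, margin + length_mm, length.out = 4L), margin, margin),
    parenchyma_radius_profile = parenchyma_mm,
    duct_radius_profile = duct_mm,
    surface_noise_sd = 0, heatmap_noise_sd = 0, n_distractor_blobs = 0L,
    ...)
}

# centerline taken directly from the generating curve (oracle path)
true_centerline <- function(spec, step_mm = 1) {
  crv <- dpdetect:::sample_curve(spec, step_mm = step_mm)
  centerline_path(crv$points, step_mm = step_mm)
}

# one small calibration + test cohort, generated once per test run
shared_cohort_env <- new.env()
shared_cohort <- function() {
  if (is.null(shared_cohort_env$cohort)) {
    dir <- file.path(tempdir(), "dpdetect-shared-cohort")
    cal <- generate_cohort(6, 6, seed = 101, dir = file.path(dir, "cal"),
                           split = "calibration")
    tst <- generate_cohort(8, 8, seed = 102, dir = file.path(dir, "test"),
                           split = "test")
    shared_cohort_env$cohort <- list(
      manifest = rbind(cal$manifest, tst$manifest),
      truths = c(cal$truths, tst$truths))
  }
  shared_cohort_env$cohort
}

# reconstructed confusion counts behind the published cohort rates
published_tables <- function() {
  list(mass = confusion_table(tp = 77, fp = 25, fn = 23, tn = 79),
       dp = confusion_table(tp = 87, fp = 6, fn = 13, tn = 98),
       combined = confusion_table(tp = 96, fp = 31, fn = 4, tn = 73))
}
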