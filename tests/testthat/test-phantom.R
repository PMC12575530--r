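test_that("analytic D/P profile matches the circle-area formula", {
  spec <- straight_spec(duct_mm = 2, parenchyma_mm = 10)
  prof <- analytic_dp_profile(spec)
  # pi r^2 / (pi R^2 - pi r^2) = 4 / 96 at every station
  expect_equal(prof$dp_ratio, rep(4 / 96, nrow(prof)), tolerance = 1e-12)
  expect_equal(dp_score(prof), 4 / 96, tolerance = 1e-12)

  # no disease: dilation factor 1 leaves the profile at baseline
  base <- analytic_dp_profile(straight_spec())
  nodis <- analytic_dp_profile(straight_spec(tumor_present = TRUE,
                                             dilation_factor = 1,
                                             atrophy_factor = 1))
  expect_equal(nodis$dp_ratio, base$dp_ratio)

  # increasing duct radius => strictly increasing ratio
  inc <- analytic_dp_profile(straight_spec(duct_mm = function(s) 1 + 2 * s))
  expect_true(all(diff(inc$dp_ratio) > 0))
})

test_that("tail-ward dilation raises the analytic ratio beyond s0", {
  spec <- straight_spec(tumor_present = TRUE, tumor_arclength_fraction = 0.5,
                        dilation_factor = 2, atrophy_factor = 0.9)
  prof <- analytic_dp_profile(spec)
  head_side <- prof$dp_ratio[prof$arclength_fraction <= 0.5]
  tail_side <- prof$dp_ratio[prof$arclength_fraction > 0.5]
  expect_true(min(tail_side) > max(head_side))
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(seed = 42L, surface_noise_sd = 0.3)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pancreas_mask$data, b$pancreas_mask$data)
  expect_identical(a$mpd_mask$data, b$mpd_mask$data)
  expect_identical(a$heatmap$data, b$heatmap$data)
  c <- generate_phantom(phantom_spec(seed = 43L, surface_noise_sd = 0.3))
  expect_false(identical(a$heatmap$data, c$heatmap$data))
})

test_that("masks are disjoint, duct is contained, union is connected", {
  spec <- phantom_spec(tumor_present = TRUE, seed = 7L, surface_noise_sd = 0.2)
  ph <- generate_phantom(spec)
  pan <- ph$pancreas_mask$data; duct <- ph$mpd_mask$data
  expect_false(any(pan & duct))
  # duct inside the parenchyma envelope (= union of the disjoint masks)
  expect_true(all(which(duct) %in% which(pan | duct)))
  labels <- dpdetect:::.cc_label_3d(pan | duct, dim(pan), 26L)
  expect_equal(max(labels), 1L)
  expect_true(all(ph$heatmap$data >= 0 & ph$heatmap$data <= 1))
})

test_that("cancer heatmaps carry a blob at the tumor centre", {
  spec <- phantom_spec(tumor_present = TRUE, tumor_arclength_fraction = 0.4,
                       heatmap_tumor_amplitude = 0.9, seed = 5L)
  ph <- generate_phantom(spec)
  res <- heatmap_score(ph$heatmap)
  sigma <- spec$tumor_radius_mm / 2
  dist <- sqrt(sum((res$peak_coordinate - ph$truth$tumor_center)^2))
  expect_lte(dist, sigma)
  expect_gte(res$max_value, 0.85)
})

test_that("invalid phantom specifications are rejected", {
  expect_error(straight_spec(duct_mm = 11, parenchyma_mm = 10),
               "duct does not fit")
  expect_error(straight_spec(tumor_present = TRUE,
                             tumor_arclength_fraction = 1.2),
               "tumor_arclength_fraction")
  expect_error(phantom_spec(dilation_factor = 0.5), "dilation_factor")
  # organ larger than the grid
  expect_error(generate_phantom(phantom_spec(grid_shape = c(80L, 40L, 40L),
                                             parenchyma_radius_profile = 25)),
               "overflows")
  # control polygon doubling back on itself
  expect_error(phantom_spec(curve_control_points =
    rbind(c(10, 20, 20), c(60, 20, 20), c(30, 25, 20), c(80, 20, 20))),
    "non-monotone")
})

test_that("cohort generation books labels, splits and truths correctly", {
  coh <- generate_cohort(0, 3, seed = 1L, dir = tempfile("ctrl"))
  expect_equal(nrow(coh$manifest), 3L)
  expect_true(all(coh$manifest$label == "control"))
  expect_true(all(file.exists(coh$manifest$pancreas_path)))
  expect_true(file.exists(file.path(coh$dir, "manifest.csv")))
  expect_true(file.exists(file.path(coh$dir, "truths.json")))

  one <- generate_cohort(1, 0, cohort_parameters(
    tumor_fraction_range = c(0.8, 0.8)), seed = 2L, dir = tempfile("tail"))
  expect_equal(one$truths[[1L]]$segment_label, "tail")
  expect_equal(one$manifest$segment_truth, "tail")
})

test_that("cohort generation is reproducible for a fixed seed", {
  a <- generate_cohort(1, 1, seed = 9L, dir = tempfile("a"))
  b <- generate_cohort(1, 1, seed = 9L, dir = tempfile("b"))
  expect_identical(a$manifest$label, b$manifest$label)
  for (i in seq_len(2L)) {
    va <- read_volume(a$manifest$heatmap_path[i])
    vb <- read_volume(b$manifest$heatmap_path[i])
    expect_identical(va$data, vb$data)
  }
})

test_that("voxelized areas converge to analytic areas as spacing shrinks", {
  areas <- lapply(c(1, 0.5), function(sp) {
    spec <- straight_spec(duct_mm = 2, parenchyma_mm = 10, spacing = sp,
                          length_mm = 40)
    ph <- generate_phantom(spec)
    path <- true_centerline(spec, step_mm = 2)
    mid <- round(nrow(path$points) / 2)
    sec_d <- extract_cross_section(ph$mpd_mask, path$points[mid, ],
                                   path$tangents[mid, ], extent_mm = 15)
    sec_p <- extract_cross_section(ph$pancreas_mask, path$points[mid, ],
                                   path$tangents[mid, ], extent_mm = 15)
    c(duct = sum(sec_d > 0) * attr(sec_d, "cell_area"),
      par = sum(sec_p > 0) * attr(sec_p, "cell_area"))
  })
  err <- function(a) abs(c(a[["duct"]] - 4 * pi,
                           a[["par"]] - (100 - 4) * pi)) / c(4 * pi, 96 * pi)
  expect_true(all(err(areas[[2L]]) <= err(areas[[1L]]) + 1e-9))
  expect_lt(max(err(areas[[2L]])), 0.05)
})
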