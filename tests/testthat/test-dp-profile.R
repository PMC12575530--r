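test_that("cross-sections measure analytic areas and honour the contract", {
  vol <- cylinder_volume(length_mm = 60, radius_mm = 10)
  mid <- c(40, (dim(vol$data)[2] - 1) / 2, (dim(vol$data)[3] - 1) / 2)
  sec <- extract_cross_section(vol, mid, c(1, 0, 0), extent_mm = 15)
  area <- sum(sec > 0) * attr(sec, "cell_area")
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.03)
  # identical on repeat
  sec2 <- extract_cross_section(vol, mid, c(1, 0, 0), extent_mm = 15)
  expect_identical(sec, sec2)
  # plane entirely outside the volume: all background
  far <- extract_cross_section(vol, c(-500, 0, 0), c(1, 0, 0), extent_mm = 15)
  expect_true(all(far == 0))
  expect_error(extract_cross_section(vol, mid, c(0, 0, 0)), "non-zero")
})

test_that("coaxial phantom D/P profile matches the analytic oracle", {
  spec <- straight_spec(duct_mm = 2, parenchyma_mm = 10)
  ph <- generate_phantom(spec)
  cl <- orient_path(estimate_centerline(ph$pancreas_mask, ph$mpd_mask),
                    head_vector(c(-1, 0, 0)))
  prof <- compute_dp_profile(cl, ph$pancreas_mask, ph$mpd_mask)
  interior <- prof$valid & prof$arclength_fraction > 0.2 &
    prof$arclength_fraction < 0.8
  expect_true(all(abs(prof$dp_ratio[interior] - 4 / 96) / (4 / 96) < 0.10))
  expect_lt(abs(dp_score(prof) - 4 / 96) / (4 / 96), 0.10)

  # empty duct mask: all ratios zero
  empty <- image_volume(array(FALSE, dim(ph$mpd_mask$data)), ph$mpd_mask$spacing)
  prof0 <- compute_dp_profile(cl, ph$pancreas_mask, empty)
  expect_true(all(prof0$dp_ratio[prof0$valid] == 0))
})

test_that("dilated tail raises the measured ratio beyond the tumor", {
  spec <- straight_spec(tumor_present = TRUE, tumor_arclength_fraction = 0.5,
                        dilation_factor = 2, atrophy_factor = 0.9, seed = 8L)
  ph <- generate_phantom(spec)
  cl <- orient_path(estimate_centerline(ph$pancreas_mask, ph$mpd_mask),
                    head_vector(c(-1, 0, 0)))
  prof <- compute_dp_profile(cl, ph$pancreas_mask, ph$mpd_mask)
  ok <- prof$valid
  m_head <- mean(prof$dp_ratio[ok & prof$arclength_fraction < 0.45])
  m_tail <- mean(prof$dp_ratio[ok & prof$arclength_fraction > 0.55])
  expect_gt(m_tail, m_head)
})

test_that("dp_score uses the linear-interpolation quantile", {
  make_prof <- function(ratios, valid = TRUE) {
    n <- length(ratios)
    dpdetect:::as_dp_profile(data.frame(
      arclength_mm = seq_len(n), arclength_fraction = seq_len(n) / n,
      duct_area_mm2 = NA, parenchyma_area_mm2 = 100,
      dp_ratio = ratios, valid = valid))
  }
  expect_equal(dp_score(make_prof(seq(0, 0.10, by = 0.01))), 0.09)
  expect_equal(dp_score(make_prof(rep(0.037, 8))), 0.037)
  expect_equal(dp_score(make_prof(0.03)), 0.03)
  expect_error(dp_score(make_prof(0.5, valid = FALSE)), "no valid stations")
  # percentile is order-free
  set.seed(1)
  r <- runif(31)
  expect_equal(dp_score(make_prof(r)), dp_score(make_prof(sample(r))))
})

test_that("dp_score is non-decreasing in the dilation factor", {
  scores <- vapply(c(1, 1.4, 1.8, 2.2), function(df)
    dp_score(analytic_dp_profile(straight_spec(
      tumor_present = TRUE, tumor_arclength_fraction = 0.5,
      dilation_factor = df, atrophy_factor = 0.9))), numeric(1L))
  expect_true(all(diff(scores) >= 0))
})

test_that("jump localization finds steps and ignores flat profiles", {
  make_prof <- function(ratios) {
    n <- length(ratios)
    dpdetect:::as_dp_profile(data.frame(
      arclength_mm = seq_len(n) - 1, arclength_fraction = (seq_len(n) - 1) / (n - 1),
      duct_area_mm2 = NA, parenchyma_area_mm2 = 100,
      dp_ratio = ratios, valid = TRUE))
  }
  step <- make_prof(c(rep(0.01, 50), rep(0.05, 50)))
  jump <- localize_dp_jump(step)
  expect_false(is.null(jump))
  expect_lt(abs(jump$arclength_fraction - 0.5), 0.02)
  expect_null(localize_dp_jump(make_prof(rep(0.03, 100))))
  expect_null(localize_dp_jump(make_prof(0.03)))
})
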