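test_that("stack projection takes the per-pixel maximum", {
  m <- matrix(1:6, 2, 3)
  expect_equal(project_stack(list(m)), m)
  expect_equal(project_stack(list(m, m, m)), m)
  a <- matrix(0, 4, 4); a[1, 1] <- 9
  b <- matrix(0, 4, 4); b[4, 4] <- 7
  p <- project_stack(list(a, b))
  expect_equal(p[1, 1], 9)
  expect_equal(p[4, 4], 7)
  expect_error(project_stack(list(m, matrix(0, 3, 3))), "differ")
})

test_that("component labeling is 8-connected with top-left label order", {
  m <- matrix(0, 5, 5)
  m[2, 2] <- 1; m[3, 3] <- 1   # diagonal neighbors: one component
  expect_equal(max(label_components(m)), 1L)
  m2 <- matrix(0, 7, 7)
  m2[2, 2] <- 1; m2[6, 6] <- 1; m2[2, 6] <- 1
  lab <- label_components(m2)
  expect_equal(max(lab), 3L)
  expect_equal(lab[2, 2], 1L)  # (row 2, col 2) before (row 2, col 6)
  expect_equal(lab[2, 6], 2L)
  expect_equal(lab[6, 6], 3L)
})

test_that("segmentation counts disks and drops specks below min_area", {
  img <- matrix(0, 64, 64)
  img[disk_mask(64, 12, 12, 6)] <- 1000
  img[disk_mask(64, 12, 45, 6)] <- 1000
  img[disk_mask(64, 45, 30, 6)] <- 1000
  expect_equal(max(segment(img)), 3L)
  expect_equal(max(segment(matrix(0, 32, 32))), 0L)

  img2 <- matrix(0, 64, 64)
  img2[disk_mask(64, 30, 30, 8)] <- 1000
  img2[2, 2:4] <- 1000  # 3-pixel speck
  expect_equal(max(segment(img2, min_area = 10)), 1L)
  expect_equal(max(segment(img2, threshold = 500, min_area = 1)), 2L)
})

test_that("shape features: area count, chain-code perimeter, roundness", {
  sq <- matrix(1, 21, 21)
  sf <- shape_features(sq)
  expect_equal(sf$area, 441)
  expect_equal(sf$perimeter, 80)
  expect_equal(sf$roundness, 4 * pi * 441 / 6400, tolerance = 1e-12)

  d <- disk_mask(61, 31, 31, 20)
  sfd <- shape_features(d)
  # frozen from the boundary-tracing oracle on this rasterization: the
  # chain-code estimator overshoots a smooth circle's perimeter by ~5%,
  # giving roundness 0.908 rather than 1
  expect_equal(sfd$roundness, 0.908, tolerance = 0.02)
  expect_lte(sfd$roughness, 0.05)

  # rotation invariance (90 degrees) within discretization tolerance
  blob <- disk_mask(61, 31, 31, 15) | prostmark:::raster_ray_rect(61, 31, 31, 0.4, 10, 25, 5)
  r0 <- shape_features(blob)$roundness
  r90 <- shape_features(t(blob)[, rev(seq_len(61))])$roundness
  expect_lt(abs(r0 - r90), 0.03)

  # translation conserves area exactly
  shifted <- matrix(FALSE, 61, 61)
  shifted[16:61, 16:61] <- disk_mask(61, 31, 31, 15)[1:46, 1:46]
  expect_equal(shape_features(shifted)$area,
               shape_features(disk_mask(61, 31, 31, 15))$area)
  expect_error(shape_features(matrix(0, 4, 4)), "empty")
})

test_that("protrusion features count spikes surviving the opening", {
  d <- disk_mask(61, 31, 31, 15)
  pf0 <- protrusion_features(d, opening_radius = 4)
  expect_equal(pf0$app_count, 0L)
  expect_equal(pf0$app_index, 0)

  m <- d
  for (a in (0:4) * 2 * pi / 5)
    m <- m | prostmark:::raster_ray_rect(61, 31, 31, a, 13, 28, 3)
  pf <- protrusion_features(m, opening_radius = 4)
  expect_equal(pf$app_count, 5L)
  expect_gt(pf$app_index, 0)
  expect_lt(pf$app_index, 1)

  tiny <- disk_mask(21, 11, 11, 2)
  pfd <- protrusion_features(tiny, opening_radius = 8)
  expect_true(pfd$degenerate)
  expect_equal(pfd$app_count, 0L)
})

test_that("intensity features and cell number follow their definitions", {
  mask <- disk_mask(31, 16, 16, 8)
  live <- matrix(0, 31, 31); live[mask] <- 7
  dead0 <- matrix(0, 31, 31)
  f <- intensity_features(live, dead0, mask)
  expect_equal(f$density, 7)
  expect_equal(f$ethd_total, 0)

  dead <- dead0
  px <- which(mask)
  dead[px[seq_len(length(px) / 2)]] <- 10
  f2 <- intensity_features(live, dead, mask)
  expect_equal(f2$ethd_mean, 5, tolerance = 0.05)

  expect_equal(cell_number(matrix(TRUE, 25, 40), typical_cell_area = 100), 10L)
  nuc <- matrix(0, 31, 31)
  centers <- cbind(c(10, 10, 16, 16, 22, 22, 16), c(10, 22, 10, 22, 10, 22, 16))
  for (i in seq_len(nrow(centers))) nuc[centers[i, 1], centers[i, 2]] <- 1
  expect_equal(cell_number(mask | TRUE, nuclei_image = nuc), 7L)
  expect_equal(cell_number(matrix(FALSE, 5, 5), typical_cell_area = 10), 0L)
  expect_error(cell_number(mask), "nuclei image or")
})

test_that("morphometry round-trips the generated ground truth exactly", {
  cfg <- sim_config(seed = 4, n_organoids = 3L,
                    protrusion_count = c(5L, 3L, 0L))
  img <- gen_organoid_image(cfg)
  rec <- morphometric_record(img, opening_radius = 5)
  expect_equal(nrow(rec), nrow(img$truth))
  expect_equal(sort(rec$area), sort(img$truth$area))
  expect_equal(sort(rec$app_count), sort(img$truth$protrusions))
  # organoids without protrusions are round; with protrusions, rough
  expect_gt(min(rec$roundness[rec$app_count == 0]), 0.85)
  expect_lt(max(rec$roundness[rec$app_count == 5]),
            min(rec$roundness[rec$app_count == 0]))
})

test_that("condition summary is 100% at control and tracks signal changes", {
  rec <- function(cond, ethd) {
    data.frame(condition = cond, area = 100, apoptosis_mean = 2,
               apoptosis_total = 200, ethd_mean = ethd,
               ethd_total = ethd * 100)
  }
  records <- rbind(rec("untreated", 3), rec("untreated", 3),
                   rec("kd", 6), rec("kd", 6))
  cs <- condition_summary(records, "untreated")
  ctrl <- cs[cs$condition == "untreated", -1]
  expect_true(all(ctrl == 100))
  expect_equal(cs$ethd_total[cs$condition == "kd"], 200)
  expect_equal(cs$ethd_mean[cs$condition == "kd"], 200)
  expect_error(condition_summary(records, "mock"), "missing")
})
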