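region_from_mask <- function(mask, level = 0) {
  perigranule:::new_region(which(mask, arr.ind = TRUE), level)
}

test_that("disk metrics: area within 10% of pi r^2, circularity near 1", {
  psz <- 0.05
  disk <- raster_disk(40, 40, 20.5, 20.5, 0.4 / psz)
  img <- calibrated_image(disk * 120, psz)
  m <- measure_granule(region_from_mask(disk), img)
  expect_equal(m$area, pi * 0.4^2, tolerance = 0.1)
  expect_gte(m$circularity, 0.9)
  expect_lte(m$circularity, 1)
  expect_equal(m$mean_intensity, 120)
})

test_that("a thin line scores low circularity", {
  img <- calibrated_image(matrix(1, 10, 25), 0.05)
  line <- perigranule:::new_region(cbind(5L, 1L:20L), 0)
  expect_lt(measure_granule(line, img)$circularity, 0.35)
})

test_that("circularity of rasterised disks is non-decreasing in radius", {
  psz <- 0.05
  circ <- vapply(c(0.2, 0.4, 0.8, 1.6), function(r) {
    n <- ceiling(2 * r / psz) + 10
    disk <- raster_disk(n, n, (n + 1) / 2, (n + 1) / 2, r / psz)
    measure_granule(region_from_mask(disk),
                    calibrated_image(disk * 1, psz))$circularity
  }, numeric(1))
  expect_true(all(diff(circ) >= -1e-6))
  expect_gte(circ[length(circ)], 0.95)
})

test_that("area is gain-invariant and mean intensity scales linearly", {
  psz <- 0.05
  disk <- raster_disk(30, 30, 15, 15, 6)
  rg <- region_from_mask(disk)
  m1 <- measure_granule(rg, calibrated_image(disk * 50, psz))
  m2 <- measure_granule(rg, calibrated_image(disk * 50 * 3.7, psz))
  expect_equal(m1$area, m2$area)
  expect_equal(m2$mean_intensity, 3.7 * m1$mean_intensity)
  expect_error(measure_granule(perigranule:::new_region(
    matrix(integer(), 0, 2), 0), calibrated_image(disk * 1, psz)), "empty")
})

test_that("planted and measured areas agree on synthetic germlines", {
  meas <- NULL; planted <- NULL
  for (s in c(42, 7, 101)) {
    sim <- simulate_germline_image(image_sim_spec(noise_sd = 0, seed = s))
    regs <- segment_granules(sim$granules)
    tab <- regions_to_table(regs)
    mt <- match_regions(as.matrix(sim$truth[, c("row", "col")]),
                        as.matrix(tab[, c("centroid_row", "centroid_col")]))
    meas <- c(meas, tab$area_px[mt$pairs[, 2]] * 0.05^2)
    planted <- c(planted, sim$truth$planted_area_um2[mt$pairs[, 1]])
  }
  slope <- unname(coef(lm(meas ~ 0 + planted)))
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
})

test_that("nucleus boundary distances follow the signed convention", {
  psz <- 0.05
  lab <- matrix(0L, 100, 100)
  lab[raster_disk(100, 100, 50, 50, 40)] <- 1L
  nm <- structure(list(labels = lab, pixel_size = psz),
                  class = "nucleus_mask")
  # centroid 10 px outside the boundary -> +0.5 um (+- 1 px discretisation)
  outside <- perigranule:::new_region(cbind(50L, 100L), 0)
  expect_equal(nucleus_boundary_distance(outside, nm), 0.5,
               tolerance = psz / 0.5)
  # centroid on the boundary -> ~0
  on_b <- perigranule:::new_region(cbind(50L, 90L), 0)
  expect_lt(abs(nucleus_boundary_distance(on_b, nm)), psz + 1e-9)
  # centroid at the centre of a radius-2 um nucleus -> -2.0 um (+- 1 px)
  centre <- perigranule:::new_region(cbind(50L, 50L), 0)
  expect_equal(nucleus_boundary_distance(centre, nm), -2, tolerance = psz / 2)
  # no nuclei -> error
  empty <- structure(list(labels = matrix(0L, 10, 10), pixel_size = psz),
                     class = "nucleus_mask")
  expect_error(nucleus_boundary_distance(outside, empty), "no nucleus")
})

test_that("germline summaries are per-metric means over one germline", {
  rec <- data.frame(germline_id = "g1", genotype = "wt", experiment_id = "e1",
                    mean_intensity = c(10, 20), area_um2 = c(0.1, 0.3),
                    circularity = c(0.8, 1), nucleus_distance_um = c(0, 0.2))
  s <- summarize_germline(rec)
  expect_equal(s$mean_intensity, 15)
  expect_equal(s$area_um2, 0.2)
  expect_equal(s$n_granules, 2L)
  # single record: summary equals the record
  s1 <- summarize_germline(rec[1, ])
  expect_equal(s1$mean_intensity, 10)
  expect_equal(s1$n_granules, 1L)
  # mixed germlines rejected
  rec2 <- rec; rec2$germline_id <- c("g1", "g2")
  expect_error(summarize_germline(rec2), "multiple germline_ids")
  expect_error(summarize_germline(rec[0, ]), "no granule records")
})

test_that("nucleus segmentation labels filled disks and ignores blanks", {
  psz <- 0.05
  px <- matrix(5, 120, 120)
  for (c_ in list(c(30, 30), c(30, 90), c(90, 60)))
    px[raster_disk(120, 120, c_[1], c_[2], 20)] <- 100
  nm <- segment_nuclei(calibrated_image(px, psz))
  expect_equal(max(nm$labels), 3L)
  blank <- segment_nuclei(calibrated_image(matrix(5, 50, 50), psz))
  expect_equal(max(blank$labels), 0L)
  # touching disks are not split (no watershed)
  px2 <- matrix(5, 80, 80)
  px2[raster_disk(80, 80, 40, 28, 15)] <- 100
  px2[raster_disk(80, 80, 40, 52, 15)] <- 100
  nm2 <- segment_nuclei(calibrated_image(px2, psz))
  expect_equal(max(nm2$labels), 1L)
})
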