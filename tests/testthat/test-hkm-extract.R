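single_level <- function(t) {
  structure(list(levels = t, Ka = length(t), separable = TRUE),
            class = "hkm_levels")
}

test_that("a single disk above one level is extracted with the right area", {
  psz <- 0.05
  disk <- raster_disk(40, 40, 20.5, 20.5, 0.3 / psz)
  img <- calibrated_image(disk * 100, psz)
  regs <- extract_objects(img, single_level(50), hkm_params())
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$area_px * psz^2, pi * 0.3^2, tolerance = 0.1)
})

test_that("an oversized dim disk defers so its bright core is extracted higher up", {
  psz <- 0.05
  dim_disk <- raster_disk(64, 64, 32, 32, 1.0 / psz)
  core <- raster_disk(64, 64, 32, 32, 0.3 / psz)
  img <- calibrated_image(dim_disk * 50 + core * 150, psz)
  regs <- extract_objects(img, single_level(c(25, 100)), hkm_params())
  expect_length(regs, 1L)
  expect_equal(regs[[1]]$extraction_level, 100)
  expect_equal(regs[[1]]$area_px, sum(core))
})

test_that("an all-zero image yields no regions", {
  img <- calibrated_image(matrix(0, 16, 16), 0.05)
  regs <- extract_objects(img, single_level(0.5), hkm_params())
  expect_length(regs, 0L)
  expect_length(attr(regs, "fragments"), 0L)
})

test_that("single-level extraction equals thresholding + size filtering", {
  # brute-force oracle: connected components (igraph) of pixels > t,
  # size-filtered with the same bounds
  skip_if_not_installed("igraph")
  set.seed(31)
  params <- hkm_params(radius_min = 0.1, radius_max = 0.4)
  psz <- 0.05
  bounds <- area_bounds_px(params, psz)
  for (rep in 1:5) {
    px <- matrix(rbinom(48 * 48, 1, 0.25) * 100, 48, 48)
    img <- calibrated_image(px, psz)
    t <- 50
    regs <- extract_objects(img, single_level(t), params)
    lab <- label_oracle(px > t)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= bounds["min"] & sizes <= bounds["max"])
    # same number of regions and identical pixel sets
    expect_length(regs, length(keep))
    got <- vapply(regs, function(r)
      paste(sort(r$pixel_set[, 1] + 1000L * r$pixel_set[, 2]),
            collapse = ","), character(1))
    want <- vapply(keep, function(k) {
      ij <- which(lab == k, arr.ind = TRUE)
      paste(sort(ij[, 1] + 1000L * ij[, 2]), collapse = ",")
    }, character(1))
    expect_setequal(got, want)
  }
})

test_that("no pixel is assigned to two regions across levels", {
  sim <- simulate_germline_image(image_sim_spec(noise_sd = 0, seed = 3))
  regs <- segment_granules(sim$granules)
  all_px <- do.call(rbind, lapply(regs, function(r) r$pixel_set))
  expect_equal(nrow(all_px), nrow(unique(all_px)))
})

test_that("the 8-connected labeller matches the igraph oracle as a partition", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:5) {
    mask <- matrix(rbinom(900, 1, 0.3) == 1, 30, 30)
    a <- label_components(mask)
    b <- label_oracle(mask)
    expect_equal(max(a), max(b))
    # identical partitions: label co-occurrence is a bijection
    expect_equal(length(unique(paste(a[mask], b[mask]))), max(a))
  }
})

test_that("the Otsu gate drops low-intensity regions and keeps bright ones", {
  psz <- 0.05
  px <- matrix(0, 50, 50)
  px[5:14, 5:14] <- 10     # dim square
  px[30:39, 30:39] <- 200  # bright square
  px[5:14, 30:39] <- 200   # more bright pixels so Otsu sits between classes
  img <- calibrated_image(px, psz)
  thr <- otsu_threshold(build_histogram(img))
  expect_gt(thr, 10); expect_lt(thr, 200)
  regs <- list(
    perigranule:::new_region(which(px == 10, arr.ind = TRUE), 1),
    perigranule:::new_region(which(px == 200, arr.ind = TRUE)[1:100, ], 1)
  )
  kept <- intensity_gate(regs, img, "otsu")
  expect_length(kept, 1L)
  expect_equal(mean(img$pixels[kept[[1]]$pixel_set]), 200)
  # all-above-threshold: identity; empty list: empty; unknown method: error
  expect_length(intensity_gate(regs[2], img, "otsu"), 1L)
  expect_length(intensity_gate(list(), img, "otsu"), 0L)
  expect_error(intensity_gate(regs, img, "nope"), "unknown intensity filter")
})

test_that("package Otsu agrees with EBImage's Otsu on an 8-bit image", {
  set.seed(5)
  px <- matrix(round(c(rnorm(600, 60, 10), rnorm(424, 180, 12))), 32, 32)
  px[px < 0] <- 0; px[px > 255] <- 255
  img <- calibrated_image(px, 0.1)
  ours <- otsu_threshold(build_histogram(img))
  ref <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1),
                       levels = 256) * 255
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("fragment reclustering merges neighbours within the size cap", {
  psz <- 0.05
  params <- hkm_params()  # min area pi*0.1^2 = 0.0314 um^2 ~ 12.6 px
  f1 <- perigranule:::new_region(cbind(10L, 1:8), 50)   # 8 px = 0.02 um^2
  f2 <- perigranule:::new_region(cbind(11L, 1:8), 50)
  merged <- recluster_fragments(list(f1, f2), params, psz)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$area_px, 16L)
  expect_equal(merged[[1]]$area_px * psz^2, 0.04, tolerance = 1e-9)

  # isolated sub-minimum fragment: discarded
  expect_length(recluster_fragments(list(f1), params, psz), 0L)

  # union exceeding the maximum area: left unmerged, both discarded if small,
  # or kept individually if already in range
  big1 <- perigranule:::new_region(
    which(raster_disk(40, 40, 12, 12, 8), arr.ind = TRUE), 50)  # ~201 px
  big2 <- perigranule:::new_region(
    which(raster_disk(40, 40, 30, 30, 9), arr.ind = TRUE), 50)  # ~254 px
  out <- recluster_fragments(list(big1, big2),
                             hkm_params(radius_min = 0.5, radius_max = 0.6),
                             psz)  # max 452 px < 455 combined
  expect_length(out, 0L)  # each below min (282 px), union over max: no merge
})
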