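#' 8-connected component labelling
#'
#' Labels connected foreground components under 8-connectivity (single
#' confocal slices are analysed in 2-D). A fast 4-connected pass
#' (`EBImage::bwlabel`) is followed by a union-find merge of label pairs that
#' touch diagonally.
#'
#' @param mask Logical (or 0/1) matrix; `TRUE`/1 is foreground.
#' @return Integer matrix of the same shape; 0 = background, components
#'   labelled 1..n in raster order of first pixel.
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)

  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs
  a <- lab[-nr, -nc]; b <- lab[-1, -1]    # down-right
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]   # up-right (shifted view)
  pairs <- rbind(
    cbind(as.vector(a), as.vector(b)),
    cbind(as.vector(c_), as.vector(d))
  )
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    parent <- seq_len(nl)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(nl), find, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  # relabel consecutively
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) > 0L) lab[lab > 0L] <- match(lab[lab > 0L], ids)
  lab
}

new_region <- function(pixels, extraction_level) {
  structure(
    list(pixel_set = pixels,                 # n x 2 integer matrix (row, col)
         extraction_level = extraction_level,
         area_px = nrow(pixels)),
    class = "segmented_region"
  )
}

#' @export
print.segmented_region <- function(x, ...) {
  ctr <- colMeans(x$pixel_set)
  cat(sprintf(
    "segmented_region: %d px at (%.1f, %.1f), extraction level %.4g\n",
    x$area_px, ctr[1], ctr[2], x$extraction_level))
  invisible(x)
}

region_centroid <- function(region) colMeans(region$pixel_set)

#' Area bounds in pixels implied by the radius range
#'
#' The size range is interpreted as an equivalent-circle radius, so the area
#' bounds are `pi * r^2` converted to pixels via the pixel size.
#'
#' @param params An [hkm_params()].
#' @param pixel_size um per pixel.
#' @return Named numeric vector `c(min = , max = )` in pixels.
#' @export
area_bounds_px <- function(params, pixel_size) {
  c(min = pi * params$radius_min^2 / pixel_size^2,
    max = pi * params$radius_max^2 / pixel_size^2)
}

#' Ascending multi-level object extraction
#'
#' Applies the computed threshold levels in ascending order. At each level,
#' unclaimed pixels strictly above the level are labelled (8-connected);
#' components with area inside the size range are accepted and their pixels
#' claimed; components below the minimum are recorded as fragments (claimed at
#' the lowest level where they appear) for [recluster_fragments()]; oversized
#' components are left unclaimed and deferred to the next ascending level,
#' where they may split into acceptable objects.
#'
#' @param image A [calibrated_image()].
#' @param levels An [hkm_levels()] result (or a list with a numeric `levels`
#'   element).
#' @param params An [hkm_params()].
#' @param mask Optional logical analysis mask.
#' @return List of `segmented_region` objects (accepted, in extraction
#'   order), with sub-minimum fragments attached as `attr(, "fragments")`.
#' @export
extract_objects <- function(image, levels, params = hkm_params(), mask = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  lv <- sort(unique(levels$levels))
  if (length(lv) == 0L) stop("no threshold levels supplied")
  if (isFALSE(levels$separable)) {
    # no separable intensity classes (unimodal histogram): nothing to extract
    out <- list()
    attr(out, "fragments") <- list()
    return(out)
  }
  px <- image$pixels
  bounds <- area_bounds_px(params, image$pixel_size)
  claimed <- matrix(FALSE, nrow(px), ncol(px))
  analysed <- if (is.null(mask)) matrix(TRUE, nrow(px), ncol(px)) else mask

  regions <- list()
  fragments <- list()
  for (t in lv) {
    fg <- (px > t) & !claimed & analysed
    if (!any(fg)) next
    lab <- label_components(fg)
    nl <- max(lab)
    if (nl == 0L) next
    idx <- which(lab > 0L)
    comp <- split(idx, lab[idx])
    for (ii in comp) {
      a <- length(ii)
      coords <- cbind(row = (ii - 1L) %% nrow(px) + 1L,
                      col = (ii - 1L) %/% nrow(px) + 1L)
      if (a >= bounds["min"] && a <= bounds["max"]) {
        regions[[length(regions) + 1L]] <- new_region(coords, t)
        claimed[ii] <- TRUE
      } else if (a < bounds["min"]) {
        fragments[[length(fragments) + 1L]] <- new_region(coords, t)
        claimed[ii] <- TRUE
      }
      # oversized: leave unclaimed, defer to the next ascending level
    }
  }
  attr(regions, "fragments") <- fragments
  regions
}

# --- registered global-threshold methods for the low-intensity gate --------

#' Otsu threshold of an intensity histogram
#'
#' Maximises between-class variance over the histogram bins; the returned
#' threshold is the bin centre at the optimum (objects with mean intensity
#' below it are considered background-like).
#'
#' @param hist An [build_histogram()] result.
#' @return A single threshold intensity.
#' @export
otsu_threshold <- function(hist) {
  v <- hist$bin_centers
  w <- as.numeric(hist$counts)
  if (length(v) < 2L) return(v[1])
  W <- sum(w)
  p <- w / W
  omega <- cumsum(p)
  mu <- cumsum(p * v)
  mu_t <- mu[length(mu)]
  # between-class variance for threshold after bin i
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, length(v))
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  i <- which.max(sigma_b)
  # midpoint between the last background bin and the first foreground bin
  if (i < length(v)) (v[i] + v[i + 1L]) / 2 else v[i]
}

gate_methods <- list(otsu = otsu_threshold)

#' Low-intensity gate on extracted regions
#'
#' Filters out objects of low intensity: a global threshold (default Otsu) is
#' computed once over all analysed pixels, and regions whose mean intensity
#' falls below it are removed. Region order is preserved.
#'
#' @param regions List of `segmented_region`.
#' @param image The [calibrated_image()] they were extracted from.
#' @param method Registered method name; currently `"otsu"`.
#' @param mask Optional analysis mask (the same one used for extraction).
#' @return Filtered region list.
#' @export
intensity_gate <- function(regions, image, method = "otsu", mask = NULL) {
  if (!method %in% names(gate_methods))
    stop(sprintf("unknown intensity filter '%s'", method))
  if (length(regions) == 0L) return(regions)
  thr <- gate_methods[[method]](build_histogram(image, mask))
  keep <- vapply(regions, function(rg) {
    mean(image$pixels[rg$pixel_set]) >= thr
  }, logical(1))
  out <- regions[keep]
  attr(out, "threshold") <- thr
  out
}

#' Recluster sub-minimum fragments
#'
#' Agglomeratively merges the sub-minimum fragments produced by
#' [extract_objects()] to reconstruct objects that remain within the size
#' range: at each step the closest centroid pair (within one maximum diameter,
#' `2 * radius_max`) whose combined area does not exceed the maximum is
#' merged. Merged fragments are re-reported as single regions; fragments still
#' below the minimum area when no merge applies are discarded.
#'
#' @param fragments List of `segmented_region` fragments.
#' @param params An [hkm_params()].
#' @param pixel_size um per pixel (needed to convert the radius range).
#' @return List of reconstructed `segmented_region`s with area at or above
#'   the minimum.
#' @export
recluster_fragments <- function(fragments, params = hkm_params(), pixel_size) {
  if (length(fragments) == 0L) return(list())
  bounds <- area_bounds_px(params, pixel_size)
  max_dist_px <- 2 * params$radius_max / pixel_size
  frs <- fragments
  repeat {
    n <- length(frs)
    if (n < 2L) break
    ctr <- t(vapply(frs, region_centroid, numeric(2)))
    areas <- vapply(frs, function(f) f$area_px, numeric(1))
    d <- as.matrix(stats::dist(ctr))
    diag(d) <- Inf
    comb <- outer(areas, areas, "+")
    d[comb > bounds["max"]] <- Inf
    d[d > max_dist_px] <- Inf
    if (!any(is.finite(d))) break
    ij <- arrayInd(which.min(d), dim(d))
    i <- min(ij); j <- max(ij)
    merged <- new_region(rbind(frs[[i]]$pixel_set, frs[[j]]$pixel_set),
                         min(frs[[i]]$extraction_level,
                             frs[[j]]$extraction_level))
    frs[[j]] <- NULL
    frs[[i]] <- merged
  }
  Filter(function(f) f$area_px >= bounds["min"], frs)
}

#' Segment perinuclear granules with the HKM pipeline
#'
#' Deterministic composition of the full granule pipeline:
#' [build_histogram()] -> [hkm_levels()] -> [extract_objects()] ->
#' [intensity_gate()] -> [recluster_fragments()]. Defaults are the condensate
#' quantification settings (`K0 = 16`, radii 0.1-0.6 um, Otsu gate).
#'
#' @param image A [calibrated_image()].
#' @param params An [hkm_params()].
#' @param mask Optional logical analysis mask (e.g. a curated germline
#'   region).
#' @return List of `segmented_region`s; attributes `levels` (the
#'   [hkm_levels()] result) and `gate_threshold`.
#' @examples
#' sim <- simulate_germline_image(image_sim_spec(n_nuclei = 2,
#'                                               granules_per_nucleus = 3,
#'                                               seed = 1))
#' length(segment_granules(sim$granules))
#' @export
segment_granules <- function(image, params = hkm_params(), mask = NULL) {
  hist <- build_histogram(image, mask)
  lv <- hkm_levels(hist, params)
  regions <- extract_objects(image, lv, params, mask)
  fragments <- attr(regions, "fragments")
  gated <- intensity_gate(regions, image, params$intensity_filter, mask)
  thr <- attr(gated, "threshold")
  # gate fragments before reclustering: reclustering reconstructs bright
  # objects split across levels, not background speckle
  fragments <- intensity_gate(fragments, image, params$intensity_filter, mask)
  rec <- recluster_fragments(fragments, params, image$pixel_size)
  out <- c(gated, rec)
  attr(out, "levels") <- lv
  attr(out, "gate_threshold") <- thr
  out
}

#' Convert regions to a labelled mask and a summary table
#'
#' @param regions List of `segmented_region`.
#' @param dim Image dimensions `c(nrow, ncol)`.
#' @return Integer label matrix (0 background, region i labelled i).
#' @export
regions_to_mask <- function(regions, dim) {
  lab <- matrix(0L, dim[1], dim[2])
  for (i in seq_along(regions))
    lab[regions[[i]]$pixel_set] <- i
  lab
}

#' @rdname regions_to_mask
#' @param pixel_size um per pixel, used for centroid conversion only when
#'   reporting; centroids are reported in pixel coordinates.
#' @return For `regions_to_table`: data.frame with one row per region
#'   (id, centroid_row, centroid_col, extraction_level, area_px).
#' @export
regions_to_table <- function(regions, pixel_size = NULL) {
  if (length(regions) == 0L)
    return(data.frame(id = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), extraction_level = numeric(),
                      area_px = integer()))
  ctr <- t(vapply(regions, region_centroid, numeric(2)))
  data.frame(
    id = seq_along(regions),
    centroid_row = ctr[, 1],
    centroid_col = ctr[, 2],
    extraction_level = vapply(regions, function(r) r$extraction_level,
                              numeric(1)),
    area_px = vapply(regions, function(r) r$area_px, integer(1))
  )
}
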