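#' Parameters for hierarchical K-means segmentation
#'
#' Bundles the tunable parameters of the HKM granule pipeline. Defaults are
#' the settings used for perinuclear condensate quantification: a starting K
#' of 16, an equivalent-circle radius range of 0.1-0.6 um, and an Otsu
#' low-intensity gate.
#'
#' @param K0 Initial (maximum) number of intensity levels; integer >= 2.
#' @param radius_min,radius_max Equivalent-circle radius bounds in
#'   micrometres; objects outside `pi * r^2` area bounds are rejected.
#' @param intensity_filter Name of the registered global-threshold method for
#'   the low-intensity gate (see [intensity_gate()]); default `"otsu"`.
#' @param convergence_tol Maximum level movement (in intensity units) below
#'   which, together with a stable assignment, clustering is declared
#'   converged. `NULL` (default) means `1e-6 * r` where `r` is the intensity
#'   range of the histogram being clustered.
#' @return An object of class `hkm_params`.
#' @examples
#' hkm_params()                # the condensate-pipeline defaults
#' hkm_params(K0 = 32)
#' @export
hkm_params <- function(K0 = 16L, radius_min = 0.1, radius_max = 0.6,
                       intensity_filter = "otsu", convergence_tol = NULL) {
  K0 <- as.integer(K0)
  if (is.na(K0) || K0 < 2L) stop("'K0' must be an integer >= 2")
  if (!(radius_min > 0 && radius_max > radius_min))
    stop("need 0 < radius_min < radius_max")
  if (!is.null(convergence_tol) && convergence_tol < 0)
    stop("'convergence_tol' must be >= 0")
  structure(
    list(K0 = K0, radius_min = radius_min, radius_max = radius_max,
         intensity_filter = intensity_filter,
         convergence_tol = convergence_tol),
    class = "hkm_params"
  )
}

#' Hierarchical K-means threshold levels from an intensity histogram
#'
#' Agglomerative, frequency-weighted K-means on the image histogram. An
#' initial set of `K0` levels is placed evenly through the intensity range
#' `r = i_max - i_min` regardless of bin frequency. Each sweep (a) assigns
#' every populated bin to its nearest level (a bin equidistant between two
#' levels goes to the lower one), (b) moves each level to the count-weighted
#' mean of its assigned bins, dropping levels with no bins, and (c) merges
#' adjacent level pairs closer than the merging distance `m = r / K_a`,
#' lowest pair first, into their mass-weighted mean, recomputing `m` from the
#' new `K_a` after every merge. Clustering continues until assignments stop
#' changing and no level moves more than `convergence_tol`, with
#' `2 <= K_a <= K0` throughout. Because `m` grows as levels merge, runs
#' started at different sufficiently large `K0` converge to the same final
#' `K_a` and levels.
#'
#' @param hist An [build_histogram()] result (or any list with strictly
#'   increasing `bin_centers` and positive `counts`).
#' @param params An [hkm_params()] object.
#' @return Object of class `hkm_levels`: list with `levels` (strictly
#'   increasing thresholds), `Ka`, `iterations`, `m_final = r / Ka`, the
#'   intensity range `i_min`, `i_max`, and `separable` (`FALSE` when merging
#'   stopped only because of the `Ka = 2` floor, i.e. the histogram is
#'   effectively single-class and supports no object extraction).
#' @examples
#' h <- structure(list(bin_centers = c(10, 200), counts = c(500L, 500L),
#'                     n_pixels = 1000L), class = "intensity_histogram")
#' hkm_levels(h, hkm_params())   # converges to Ka = 2, levels 10 and 200
#' @export
hkm_levels <- function(hist, params = hkm_params()) {
  v <- hist$bin_centers
  w <- as.numeric(hist$counts)
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  if (length(v) < 2L) stop("degenerate intensity range")
  imin <- min(v); imax <- max(v)
  r <- imax - imin
  if (r <= 0) stop("degenerate intensity range")
  tol <- if (is.null(params$convergence_tol)) 1e-6 * r else params$convergence_tol

  levels <- seq(imin, imax, length.out = params$K0)
  assign_prev <- rep(NA_integer_, length(v))
  iterations <- 0L
  max_iter <- 200L

  repeat {
    iterations <- iterations + 1L
    # nearest level; exact ties resolved to the lower level.
    d <- abs(outer(v, levels, "-"))
    assign <- max.col(-d, ties.method = "first")
    # drop empty levels
    used <- sort(unique(assign))
    levels_new <- vapply(used, function(k) {
      sel <- assign == k
      sum(v[sel] * w[sel]) / sum(w[sel])
    }, numeric(1))
    mass <- vapply(used, function(k) sum(w[assign == k]), numeric(1))
    assign <- match(assign, used)

    # merge adjacent pairs closer than m = r / Ka, lowest pair first;
    # m is recomputed from the new Ka after every merge.
    Ka <- length(levels_new)
    repeat {
      if (Ka <= 2L) break
      m <- r / Ka
      gaps <- diff(levels_new)
      hit <- which(gaps < m)
      if (length(hit) == 0L) break
      i <- hit[1L]
      wsum <- mass[i] + mass[i + 1L]
      merged <- (levels_new[i] * mass[i] + levels_new[i + 1L] * mass[i + 1L]) / wsum
      levels_new <- c(levels_new[seq_len(i - 1L)], merged,
                      levels_new[-seq_len(i + 1L)])
      mass <- c(mass[seq_len(i - 1L)], wsum, mass[-seq_len(i + 1L)])
      assign[assign > i] <- assign[assign > i] - 1L
      Ka <- Ka - 1L
    }

    moved <- if (length(levels_new) == length(levels))
      max(abs(levels_new - levels)) else Inf
    same_assign <- length(assign) == length(assign_prev) &&
      all(assign == assign_prev, na.rm = FALSE) && !anyNA(assign_prev)
    levels <- levels_new
    assign_prev <- assign
    if ((same_assign && moved < tol) || iterations >= max_iter) break
  }

  Ka <- length(levels)
  # Merging stops at the Ka = 2 floor; if the two remaining levels are still
  # closer than the merging distance the histogram is effectively one class
  # (e.g. granule-free noise) and carries no separable intensity structure.
  separable <- Ka > 2L || diff(levels) >= r / Ka
  structure(
    list(levels = levels, Ka = Ka, iterations = iterations,
         m_final = r / Ka, i_min = imin, i_max = imax,
         separable = separable),
    class = "hkm_levels"
  )
}

#' @export
print.hkm_levels <- function(x, ...) {
  cat(sprintf("hkm_levels: Ka = %d (%d iterations), m_final = %.4g\n",
              x$Ka, x$iterations, x$m_final))
  cat("  levels:", paste(signif(x$levels, 5), collapse = ", "), "\n")
  invisible(x)
}
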