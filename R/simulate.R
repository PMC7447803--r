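# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic germline image
#'
#' Describes a single-slice two-channel germline field: disk nuclei with
#' perinuclear granules rendered as 2-D Gaussian spots (sigma = radius / 2,
#' clipped at 2 sigma, i.e. at the nominal radius, so the rendered footprint
#' equals the nominal granule area pi * r^2 — a compromise between a hard
#' disk and a diffraction-limited spot). Granules sit on the nucleus
#' perimeter at
#' angularly uniform positions with 1 px radial jitter. All randomness is
#' fixed by `seed`.
#'
#' @param size_px Image edge length in pixels (square field).
#' @param pixel_size um per pixel.
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radius_um Nucleus radius, um.
#' @param granules_per_nucleus Granule count per nucleus.
#' @param granule_radius_range_um Granule radius range, um (the analysis
#'   range 0.1-0.6 um; in vivo clusters are ~0.25 um across).
#' @param granule_peak Peak granule intensity above background, a.u.
#' @param background Background intensity, a.u.
#' @param noise_sd Additive Gaussian noise sd, a.u. (0 = noise-free).
#' @param seed Integer seed fixing all randomness.
#' @return Object of class `image_sim_spec`.
#' @export
image_sim_spec <- function(size_px = 260L, pixel_size = 0.05,
                           n_nuclei = 3L, nucleus_radius_um = 1.5,
                           granules_per_nucleus = 8L,
                           granule_radius_range_um = c(0.15, 0.5),
                           granule_peak = 150, background = 10,
                           noise_sd = 2, seed = 1L) {
  stopifnot(size_px >= 32L, pixel_size > 0, n_nuclei >= 0,
            nucleus_radius_um > 0,
            all(granule_radius_range_um > 0),
            granule_radius_range_um[1] <= granule_radius_range_um[2],
            granule_peak > 0, background >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "image_sim_spec")
}

#' Simulate a two-channel germline image with known ground truth
#'
#' Generates a granule channel and a nuclear (DAPI-like) channel plus a truth
#' table listing every planted granule. Identical seeds give bit-identical
#' output.
#'
#' @param spec An [image_sim_spec()].
#' @return List: `granules` and `dapi` ([calibrated_image()]s), `truth`
#'   (data.frame: granule_id, nucleus_id, row, col, radius_um, peak,
#'   planted_area_um2), `nuclei_truth` (data.frame of nucleus centres/radii).
#' @examples
#' sim <- simulate_germline_image(image_sim_spec(n_nuclei = 2,
#'                                               granules_per_nucleus = 4,
#'                                               seed = 7))
#' nrow(sim$truth)  # 8
#' @export
simulate_germline_image <- function(spec) {
  stopifnot(inherits(spec, "image_sim_spec"))
  with_local_seed(spec$seed, {
    n <- spec$size_px
    psz <- spec$pixel_size
    nuc_r_px <- spec$nucleus_radius_um / psz
    # clearance: granules sit on the perimeter and extend r_max beyond it
    clear_px <- nuc_r_px + spec$granule_radius_range_um[2] / psz + 2

    # jittered-grid placement: guarantees non-overlap up to the packing limit
    ncell <- max(1L, ceiling(sqrt(spec$n_nuclei)))
    cell <- n / ncell
    if (spec$n_nuclei > 0L && cell < 2 * clear_px)
      stop("could not place nuclei without overlap: packing limit exceeded")
    jit_max <- max(0, cell / 2 - clear_px)
    grid <- expand.grid(gy = seq_len(ncell), gx = seq_len(ncell))
    grid <- grid[seq_len(spec$n_nuclei), , drop = FALSE]
    centers <- cbind(
      (grid$gy - 0.5) * cell +
        stats::runif(nrow(grid), -jit_max / 2, jit_max / 2),
      (grid$gx - 0.5) * cell +
        stats::runif(nrow(grid), -jit_max / 2, jit_max / 2))

    gr <- matrix(spec$background, n, n)
    dapi <- matrix(5, n, n)
    rowidx <- matrix(seq_len(n), n, n)
    colidx <- matrix(seq_len(n), n, n, byrow = TRUE)

    truth <- NULL
    gid <- 0L
    for (k in seq_len(nrow(centers))) {
      cy <- centers[k, 1]; cx <- centers[k, 2]
      dapi <- dapi + 100 * ((rowidx - cy)^2 + (colidx - cx)^2 <= nuc_r_px^2)
      if (spec$granules_per_nucleus == 0L) next
      base_ang <- stats::runif(1, 0, 2 * pi)
      angs <- base_ang + 2 * pi * (seq_len(spec$granules_per_nucleus) - 1) /
        spec$granules_per_nucleus +
        stats::runif(spec$granules_per_nucleus, -0.15, 0.15)
      for (a in angs) {
        gid <- gid + 1L
        r_um <- stats::runif(1, spec$granule_radius_range_um[1],
                             spec$granule_radius_range_um[2])
        rad_jit <- stats::runif(1, -1, 1)  # 1 px radial jitter
        gy <- cy + (nuc_r_px + rad_jit) * sin(a)
        gx <- cx + (nuc_r_px + rad_jit) * cos(a)
        sig_px <- (r_um / 2) / psz
        d2 <- (rowidx - gy)^2 + (colidx - gx)^2
        spot <- spec$granule_peak * exp(-d2 / (2 * sig_px^2))
        spot[d2 > (2 * sig_px)^2] <- 0  # clip at 2 sigma = nominal radius
        gr <- gr + spot
        truth <- rbind(truth, data.frame(
          granule_id = gid, nucleus_id = k, row = gy, col = gx,
          radius_um = r_um, peak = spec$granule_peak,
          planted_area_um2 = pi * r_um^2))
      }
    }
    if (is.null(truth))
      truth <- data.frame(granule_id = integer(), nucleus_id = integer(),
                          row = numeric(), col = numeric(),
                          radius_um = numeric(), peak = numeric(),
                          planted_area_um2 = numeric())
    if (spec$noise_sd > 0) {
      gr <- gr + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
      dapi <- dapi + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    }
    gr[gr < 0] <- 0
    dapi[dapi < 0] <- 0
    list(
      granules = calibrated_image(gr, psz, "granule"),
      dapi = calibrated_image(dapi, psz, "dapi"),
      truth = truth,
      nuclei_truth = if (nrow(centers) > 0L)
        data.frame(nucleus_id = seq_len(nrow(centers)),
                   row = centers[, 1], col = centers[, 2],
                   radius_um = spec$nucleus_radius_um)
      else data.frame(nucleus_id = integer(), row = numeric(),
                      col = numeric(), radius_um = numeric())
    )
  })
}

#' Specification for a synthetic small RNA count matrix
#'
#' Negative-binomial gene x sample counts with genotype-specific
#' multiplicative effects on designated gene sets, emulating 22G abundance
#' changes between wild-type and mutant libraries (3 biologically
#' independent replicates per genotype by default).
#'
#' @param n_genes Number of genes.
#' @param replicates Replicates per genotype.
#' @param genotypes Genotype labels (first is the reference).
#' @param library_size Mean per-sample uniquely-mapped total.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean rpm.
#' @param effect_sets Named list: each element `list(genes =, fc =)` applies
#'   fold change `fc` to those genes in every non-reference genotype.
#' @param dispersion Negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param seed Integer seed.
#' @return Object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 2000L, replicates = 3L,
                           genotypes = c("wild-type", "mutant"),
                           library_size = 2e6,
                           baseline_meanlog = log(60),
                           baseline_sdlog = 1.2,
                           effect_sets = list(),
                           dispersion = 10,
                           seed = 1L) {
  stopifnot(n_genes >= 1L, replicates >= 1L, length(genotypes) >= 1L,
            library_size > 0, dispersion > 0)
  structure(as.list(environment()), class = "count_sim_spec")
}

#' Simulate a small RNA count table with planted effects
#'
#' @param spec A [count_sim_spec()].
#' @return List: `table` (a [small_rna_table()]), `truth` (list: per-set gene
#'   ids and fold changes, plus the per-gene baseline mean rpm).
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  with_local_seed(spec$seed, {
    genes <- sprintf("gene%05d", seq_len(spec$n_genes))
    base_rpm <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog,
                              spec$baseline_sdlog)
    names(base_rpm) <- genes

    samples <- expand.grid(rep = seq_len(spec$replicates),
                           genotype = spec$genotypes,
                           stringsAsFactors = FALSE)
    samples$sample <- sprintf("%s_r%d", samples$genotype, samples$rep)
    totals <- round(stats::rlnorm(nrow(samples), log(spec$library_size), 0.1))

    counts <- matrix(0L, spec$n_genes, nrow(samples),
                     dimnames = list(genes, samples$sample))
    ref <- spec$genotypes[1]
    for (j in seq_len(nrow(samples))) {
      mu_rpm <- base_rpm
      if (samples$genotype[j] != ref) {
        for (es in spec$effect_sets)
          mu_rpm[es$genes] <- mu_rpm[es$genes] * es$fc
      }
      mu <- mu_rpm * totals[j] / 1e6
      counts[, j] <- stats::rnbinom(spec$n_genes, mu = mu,
                                    size = spec$dispersion)
    }
    tab <- small_rna_table(
      counts,
      data.frame(sample = samples$sample, genotype = samples$genotype,
                 unique_mapped_total = totals))
    list(table = tab,
         truth = list(effect_sets = spec$effect_sets,
                      baseline_rpm = base_rpm))
  })
}

#' Simulate an MST-style titration from the quadratic isotherm
#'
#' Signal = baseline + amplitude * FB(T; Kd, L) + Gaussian noise, over a
#' serial dilution of the titrant, emulating a thermophoresis binding
#' experiment with a fixed labelled-species concentration (10 nM by
#' default).
#'
#' @param Kd_nM Ground-truth dissociation constant, nM.
#' @param labeled_nM Labelled-species concentration, nM.
#' @param top_nM Top titrant concentration, nM.
#' @param factor Serial dilution factor.
#' @param n_points Number of titration points.
#' @param baseline,amplitude Signal offset and span, a.u.
#' @param noise_sd Gaussian noise sd in signal units (the conventional design
#'   uses 2% of the amplitude).
#' @param seed Integer seed.
#' @return List: `curve` (a [binding_curve()]), `truth` (generating
#'   parameters).
#' @examples
#' simulate_titration(855, seed = 3)$curve
#' @export
simulate_titration <- function(Kd_nM, labeled_nM = 10, top_nM = 20000,
                               factor = 2, n_points = 16L,
                               baseline = 0.2, amplitude = 1,
                               noise_sd = 0.02, seed = 1L) {
  conc <- serial_dilution(top_nM, factor, n_points)
  with_local_seed(seed, {
    fb <- fraction_bound(conc, labeled_nM, Kd_nM)
    sig <- baseline + amplitude * fb +
      stats::rnorm(n_points, 0, noise_sd)
    list(curve = binding_curve(conc, sig, labeled_nM),
         truth = list(Kd_nM = Kd_nM, labeled_nM = labeled_nM,
                      baseline = baseline, amplitude = amplitude,
                      noise_sd = noise_sd))
  })
}

#' Simulate a two-group iBAQ matrix with spiked-in enriched proteins
#'
#' Log-normal protein abundances; the spike set is multiplied by `effect` in
#' the bait-IP group only.
#'
#' @param n_proteins Number of proteins.
#' @param n_bait,n_control Samples per group.
#' @param spike_set Indices or protein ids forming the enriched set.
#' @param effect Multiplicative bait-group enrichment (> 0; 1 = null).
#' @param sigma Log10-scale replicate noise sd.
#' @param seed Integer seed.
#' @return List: `mat` (proteins x samples iBAQ matrix), `groups` (column
#'   labels), `truth` (spiked protein ids).
#' @export
simulate_ibaq <- function(n_proteins = 500L, n_bait = 4L, n_control = 3L,
                          spike_set = 1:5, effect = 10, sigma = 0.1,
                          seed = 1L) {
  stopifnot(effect > 0, n_proteins >= 1L)
  with_local_seed(seed, {
    prot <- sprintf("prot%04d", seq_len(n_proteins))
    base <- stats::rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1.5)
    if (is.character(spike_set)) spike_set <- match(spike_set, prot)
    groups <- c(rep("bait_IP", n_bait), rep("control", n_control))
    mat <- sapply(seq_along(groups), function(j) {
      mu <- base
      if (groups[j] == "bait_IP") mu[spike_set] <- mu[spike_set] * effect
      mu * 10^stats::rnorm(n_proteins, 0, sigma)
    })
    idx <- as.integer(stats::ave(seq_along(groups), groups, FUN = seq_along))
    dimnames(mat) <- list(prot, sprintf("%s_%d", groups, idx))
    list(mat = mat, groups = groups, truth = list(spiked = prot[spike_set]))
  })
}
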