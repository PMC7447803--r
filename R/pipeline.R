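#' Load / save a run configuration
#'
#' Run configurations are plain YAML mappings; [load_run_config()] and
#' [save_run_config()] round-trip a configuration unchanged. Recognised
#' fields are documented under [run_condensate_report()] and
#' [run_srna_report()]; unrecognised fields are preserved.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config A `run_config` (or plain named list).
#' @export
save_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Condensate comparison report
#'
#' End-to-end orchestration of the imaging arm: segment granules in every
#' germline image (HKM pipeline), measure them, summarise per germline, then
#' compare each metric between the test and control genotypes with the
#' normality-gated scheme and compute within-experiment intensity fold
#' changes. Output is a comparison-table-shaped report (metric, test used,
#' p, significance code, direction).
#'
#' @param images data.frame with one row per germline image: columns
#'   `granule_path` (TIFF) or `image` (a [calibrated_image()] in a list
#'   column), `germline_id`, `genotype`, `experiment_id`, and optionally
#'   `nuclei_path` / `nuclei` (label mask).
#' @param control_genotype,test_genotype Genotype labels to compare.
#' @param params [hkm_params()] used for every image.
#' @param pixel_size um per pixel (used when reading TIFFs).
#' @param alpha_sw Shapiro-Wilk gate level.
#' @param output_dir Optional directory; when given, `comparison.tsv`,
#'   `fold_changes.tsv`, `germline_summaries.tsv` and `report.json` are
#'   written there.
#' @return List: `comparison` (one row per metric), `fold_changes`,
#'   `summaries`, `records`.
#' @export
run_condensate_report <- function(images, control_genotype, test_genotype,
                                  params = hkm_params(), pixel_size = 0.05,
                                  alpha_sw = 0.05, output_dir = NULL) {
  if (!control_genotype %in% images$genotype)
    stop(sprintf("control genotype '%s' absent from image table",
                 control_genotype))
  records <- NULL
  for (i in seq_len(nrow(images))) {
    img <- if ("image" %in% names(images)) images$image[[i]] else
      read_calibrated_tiff(images$granule_path[i], pixel_size)
    nuclei <- NULL
    if ("nuclei" %in% names(images)) nuclei <- images$nuclei[[i]]
    regions <- segment_granules(img, params)
    records <- rbind(records, measure_granules(
      regions, img, nuclei,
      germline_id = images$germline_id[i],
      genotype = images$genotype[i],
      experiment_id = images$experiment_id[i]))
  }
  summaries <- summarize_germlines(records)
  metrics <- c(Intensity = "mean_intensity", Area = "area_um2",
               Circularity = "circularity")
  comparison <- do.call(rbind, lapply(names(metrics), function(mn) {
    col <- metrics[[mn]]
    compare_groups(
      summaries[[col]][summaries$genotype == control_genotype],
      summaries[[col]][summaries$genotype == test_genotype],
      alpha_sw = alpha_sw, metric = mn)
  }))
  fcs <- fold_changes(summaries, control_genotype)
  out <- list(comparison = comparison, fold_changes = fcs,
              summaries = summaries, records = records)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(comparison, file.path(output_dir, "comparison.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(fcs, file.path(output_dir, "fold_changes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summaries,
                       file.path(output_dir, "germline_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(comparison = comparison,
           n_germlines = nrow(summaries), n_granules = nrow(records)),
      file.path(output_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Small RNA abundance / fold-change / enrichment report
#'
#' Orchestrates the small-RNA arm: rpm-normalise the count table, build the
#' expressed universe (mean rpm strictly over `threshold_rpm`), compute
#' per-gene genotype fold changes, form the twofold-reduced set, and test
#' every supplied gene set for enrichment (or depletion) against it with the
#' exact hypergeometric tail. Direct-entry tests on printed `(N, K, n, k)`
#' counts are also supported, for re-checking published overlaps without the
#' underlying table.
#'
#' @param table A [small_rna_table()], or `NULL` when only `direct_tests`
#'   are requested.
#' @param wild_type_label,mutant_label Genotype labels.
#' @param gene_sets Named list of character vectors (published target
#'   lists).
#' @param set_tails Named character vector giving `"upper"`/`"lower"` per
#'   gene set (default upper for all).
#' @param threshold_rpm Expression cutoff (strict, mean across all samples).
#' @param direct_tests Optional data.frame with columns `name, N, K, n, k,
#'   tail` evaluated as-is.
#' @param output_dir Optional directory for `abundance.tsv`,
#'   `fold_changes.tsv`, `enrichment.tsv`.
#' @return List: `universe`, `fold_changes`, `reduced_set`, `enrichment`
#'   (data.frame: set, N, K, n, k, tail, log10_p).
#' @export
run_srna_report <- function(table = NULL, wild_type_label = "wild-type",
                            mutant_label = "mutant", gene_sets = list(),
                            set_tails = NULL, threshold_rpm = 50,
                            direct_tests = NULL, output_dir = NULL) {
  enr <- NULL
  universe <- character()
  fcs <- NULL
  reduced <- character()
  ab <- NULL
  if (!is.null(table)) {
    ab <- rpm_normalize(table)
    universe <- filter_expressed(ab, threshold_rpm)
    fcs <- genotype_fold_change(ab, wild_type_label, mutant_label)
    fcs <- fcs[fcs$gene %in% universe & fcs$defined, , drop = FALSE]
    universe <- fcs$gene          # undefined-FC genes leave the universe too
    reduced <- twofold_reduced(fcs)
    for (nm in names(gene_sets)) {
      tl <- if (!is.null(set_tails) && nm %in% names(set_tails))
        set_tails[[nm]] else "upper"
      set_in <- intersect(gene_sets[[nm]], universe)
      if (length(set_in) == 0L) {
        warning(sprintf("gene set '%s' is disjoint from the universe", nm))
        enr <- rbind(enr, data.frame(set = nm, N = length(universe), K = 0L,
                                     n = length(reduced), k = 0L, tail = tl,
                                     log10_p = 0))
        next
      }
      r <- set_enrichment(universe, reduced, set_in, tl)
      enr <- rbind(enr, data.frame(set = nm, N = r$N, K = r$K, n = r$n,
                                   k = r$k, tail = r$tail,
                                   log10_p = r$log10_p))
    }
  }
  if (!is.null(direct_tests)) {
    for (i in seq_len(nrow(direct_tests))) {
      d <- direct_tests[i, ]
      r <- hypergeometric_tail(d$N, d$K, d$n, d$k, d$tail)
      enr <- rbind(enr, data.frame(set = d$name, N = r$N, K = r$K, n = r$n,
                                   k = r$k, tail = r$tail,
                                   log10_p = r$log10_p))
    }
  }
  if (!is.null(enr) && nrow(enr) > 0L)
    enr <- enr[order(enr$log10_p), , drop = FALSE]
  out <- list(universe = universe, fold_changes = fcs,
              reduced_set = reduced, enrichment = enr)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(ab)) {
      abt <- data.frame(gene = rownames(ab$rpm), ab$rpm, check.names = FALSE)
      utils::write.table(abt, file.path(output_dir, "abundance.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    if (!is.null(fcs))
      utils::write.table(fcs, file.path(output_dir, "fold_changes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(enr))
      utils::write.table(enr, file.path(output_dir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Read a counts TSV + samples TSV pair as a small_rna_table
#'
#' `counts_path`: first column gene id, remaining columns one per sample.
#' `samples_path`: columns `sample`, `genotype`, `unique_mapped_total`
#' (optionally `h2b_total`).
#'
#' @param counts_path,samples_path TSV file paths.
#' @return A [small_rna_table()].
#' @export
read_small_rna_tsv <- function(counts_path, samples_path) {
  cts <- utils::read.delim(counts_path, check.names = FALSE)
  genes <- cts[[1]]
  m <- as.matrix(cts[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  smp <- utils::read.delim(samples_path)
  small_rna_table(m, smp)
}

#' Read gene sets from plain-text files
#'
#' Accepts one-id-per-line files or GMT lines (`name<TAB>desc<TAB>id...`).
#'
#' @param paths Named character vector of file paths (names become set
#'   names; unnamed paths use the file name).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- tools::file_path_sans_ext(basename(paths))
  out <- list()
  for (nm in names(paths)) {
    lines <- readLines(paths[[nm]])
    lines <- lines[nzchar(lines)]
    if (any(grepl("\t", lines))) {  # GMT: possibly several sets per file
      for (ln in lines) {
        f <- strsplit(ln, "\t")[[1]]
        out[[f[1]]] <- unique(f[-(1:2)])
      }
    } else {
      out[[nm]] <- unique(lines)
    }
  }
  out
}
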