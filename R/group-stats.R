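#' Significance coding for condensate comparison tables
#'
#' Maps a p value to the comparison-table code: `"+++"` for p < 0.001,
#' `"++"` for 0.001 <= p < 0.01, `"+"` for 0.01 <= p < 0.05, `"-"` for
#' p >= 0.05. The four bands partition [0, 1].
#'
#' @param p Numeric vector of p values in [0, 1].
#' @return Character vector of codes.
#' @examples
#' significance_code(c(0.0005, 0.005, 0.03, 0.2))
#' @export
significance_code <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "+++",
         ifelse(p < 0.01, "++",
                ifelse(p < 0.05, "+", "-")))
}

#' Normality-gated two-group comparison of germline means
#'
#' The comparison scheme used for condensate metrics: Shapiro-Wilk normality
#' is tested on both groups at `alpha_sw`; if both pass, a two-sided
#' equal-variance Student's t-test is used, otherwise a two-sample two-sided
#' Kolmogorov-Smirnov test. Direction is the sign of
#' `mean(test) - mean(control)` (reported as `"none"` when not significant).
#'
#' @param control,test Numeric vectors of germline means (>= 3 values each).
#' @param alpha_sw Shapiro-Wilk significance level for the gate
#'   (default 0.05).
#' @param metric Metric name carried into the result.
#' @return A one-row data.frame (`comparison_result`): `metric`,
#'   `test_used` ("t" or "KS"), `p_value`, `direction`, `significance_code`.
#' @examples
#' compare_groups(c(1.0, 1.1, 0.9, 1.05), c(1.5, 1.6, 1.4, 1.55))
#' @export
compare_groups <- function(control, test, alpha_sw = 0.05,
                           metric = "intensity") {
  if (length(control) < 3L || length(test) < 3L)
    stop("insufficient germlines: need >= 3 per group")
  normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)  # SW undefined for constant data
    stats::shapiro.test(x)$p.value >= alpha_sw
  }
  use_t <- normal(control) && normal(test)
  p <- if (use_t) {
    stats::t.test(test, control, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::ks.test(test, control)$p.value)
  }
  dir <- if (p >= 0.05) "none" else if (mean(test) > mean(control)) "up" else "down"
  data.frame(metric = metric,
             test_used = if (use_t) "t" else "KS",
             p_value = p,
             direction = dir,
             significance_code = significance_code(p))
}

#' Within-experiment fold changes of germline intensity
#'
#' For each experiment, the average intensity over that experiment's control
#' germlines is computed and used as the denominator for every germline of
#' the same experiment, so control germlines have mean fold change 1 by
#' construction and imaging-session gain differences cancel.
#'
#' @param summaries Germline summary data.frame (see
#'   [summarize_germlines()]), with columns `germline_id`, `genotype`,
#'   `experiment_id`, `mean_intensity`.
#' @param control_genotype Genotype label of the control strain.
#' @param metric Column to normalise (default `"mean_intensity"`).
#' @return data.frame: `germline_id`, `genotype`, `experiment_id`,
#'   `fold_change`.
#' @export
fold_changes <- function(summaries, control_genotype,
                         metric = "mean_intensity") {
  stopifnot(metric %in% names(summaries))
  out <- lapply(split(summaries, summaries$experiment_id), function(ex) {
    ctrl <- ex[[metric]][ex$genotype == control_genotype]
    if (length(ctrl) == 0L)
      stop(sprintf("experiment '%s' has no control germlines",
                   ex$experiment_id[1]))
    data.frame(germline_id = ex$germline_id,
               genotype = ex$genotype,
               experiment_id = ex$experiment_id,
               fold_change = ex[[metric]] / mean(ctrl))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
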