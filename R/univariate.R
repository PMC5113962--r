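# Per-metabolite two-group statistics and fold changes, computed on the
# sum-normalized (unlogged) scale so fold changes are ratios of relative
# abundances.

#' Two-group contrast statistics per metabolite
#'
#' Two-sided pooled-variance (Student) t-test on present values and fold
#' change = mean(case) / mean(reference), per metabolite. Groups may be
#' unions, e.g. `case_group = c("MS","NMOSD","ITM")` for the pooled-disease
#' contrast. Metabolites with fewer than two present values on either side
#' are flagged untestable (`NA` p-value) and never enter the significant set.
#'
#' @param m normalized `metab_matrix` (missing values allowed).
#' @param samples a `sample_annotation`.
#' @param reference_group,case_group group label or vector of labels, or a
#'   status label (`REMISSION`/`RELAPSE`) for status contrasts.
#' @param by `"group"` or `"status"`: which annotation column defines sides.
#' @param alpha significance level (default 0.05, uncorrected, mirroring the
#'   reference analysis).
#' @param welch use the Welch (unequal-variance) test instead of Student.
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (`"none"` by default).
#' @return data.frame of class `contrast_result`: `metabolite`, `p_value`,
#'   `fold_change`, `direction` (`up`/`down`), `significant`, `testable`,
#'   with the contrast name, alpha and adjustment recorded as attributes.
#' @export
contrast_stats <- function(m, samples, reference_group, case_group,
                           by = c("group", "status"), alpha = 0.05,
                           welch = FALSE, p_adjust = "none") {
  by <- match.arg(by)
  samples <- samples[match(rownames(m), samples$sample_id), ]
  lab <- samples[[by]]
  ref_idx <- lab %in% reference_group
  case_idx <- lab %in% case_group
  if (!any(ref_idx) || !any(case_idx))
    stop("empty side in contrast ", paste(reference_group, collapse = "+"),
         " vs ", paste(case_group, collapse = "+"))
  p <- fc <- rep(NA_real_, ncol(m))
  for (j in seq_len(ncol(m))) {
    x <- m[ref_idx, j]; x <- x[!is.na(x)]
    y <- m[case_idx, j]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    fc[j] <- mean(y) / mean(x)
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # degenerate: both sides constant; the t statistic is 0/0 or infinite
      p[j] <- if (mean(x) == mean(y)) 1 else .Machine$double.xmin
      next
    }
    p[j] <- stats::t.test(y, x, var.equal = !welch)$p.value
  }
  p_adj <- p
  ok <- !is.na(p)
  p_adj[ok] <- stats::p.adjust(p[ok], method = p_adjust)
  out <- data.frame(
    metabolite = colnames(m),
    p_value = p_adj,
    fold_change = fc,
    direction = ifelse(is.na(fc), NA_character_, ifelse(fc > 1, "up", "down")),
    significant = !is.na(p_adj) & p_adj < alpha,
    testable = ok,
    stringsAsFactors = FALSE)
  attr(out, "contrast") <- paste0(paste(reference_group, collapse = "+"),
                                  "_vs_", paste(case_group, collapse = "+"))
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Significant metabolites of a contrast, sorted by p-value
#'
#' @param result a `contrast_result`.
#' @param alpha significance level (defaults to the level stored on the
#'   result).
#' @return character vector of metabolite ids with p < alpha, ascending p.
#' @export
significant_set <- function(result, alpha = attr(result, "alpha")) {
  hit <- result[result$testable & !is.na(result$p_value) &
                  result$p_value < alpha, ]
  hit$metabolite[order(hit$p_value)]
}
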