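# Normalization, occurrence filtering, imputation and scaling.
#
# Presence means a non-missing cell: a peak height of zero is a reported
# measurement, a missing cell is a censored non-detect.

#' Sum-intensity normalization
#'
#' Divides each sample's present values by the sample total and multiplies
#' by the cohort-median total, preserving the original magnitude. Missing
#' cells stay missing. Idempotent.
#'
#' @param m a `metab_matrix`.
#' @return normalized `metab_matrix`.
#' @export
sum_normalize <- function(m) {
  totals <- rowSums(m, na.rm = TRUE)
  empty <- rowSums(!is.na(m)) == 0
  if (any(empty))
    stop("sample(s) with no present value: ",
         paste(rownames(m)[empty], collapse = ", "))
  med <- stats::median(totals)
  out <- m * (med / totals)
  metabolite_matrix(unclass(out))
}

#' Group-wise occurrence filter
#'
#' Keeps a metabolite iff its presence fraction reaches `min_frac` in at
#' least one study-design group.
#'
#' @param m a `metab_matrix`.
#' @param samples a `sample_annotation` covering the rows of `m`.
#' @param min_frac minimum within-group presence fraction (default 0.5).
#' @return filtered `metab_matrix`.
#' @export
occurrence_filter <- function(m, samples, min_frac = 0.5) {
  samples <- samples[match(rownames(m), samples$sample_id), ]
  keep <- rep(FALSE, ncol(m))
  for (g in unique(samples$group)) {
    sub <- m[samples$group == g, , drop = FALSE]
    keep <- keep | (colMeans(!is.na(sub)) >= min_frac)
  }
  m[, keep, drop = FALSE]
}

#' Impute missing abundances
#'
#' `half_min` replaces each missing cell by half the metabolite's minimum
#' present value (a limit-of-detection surrogate); `none` leaves missing
#' values in place (tolerated by the univariate stage only).
#'
#' @param m a `metab_matrix`.
#' @param strategy `"half_min"` or `"none"`.
#' @return imputed `metab_matrix`.
#' @export
impute_missing <- function(m, strategy = c("half_min", "none")) {
  strategy <- match.arg(strategy)
  if (strategy == "none") return(m)
  allmiss <- colSums(!is.na(m)) == 0
  if (any(allmiss))
    stop("all-missing metabolite(s), cannot impute: ",
         paste(colnames(m)[allmiss], collapse = ", "))
  for (j in which(colSums(is.na(m)) > 0)) {
    fill <- min(m[, j], na.rm = TRUE) / 2
    m[is.na(m[, j]), j] <- fill
  }
  m
}

#' Log-transform and autoscale a complete matrix
#'
#' Optionally natural-log transforms, then centers each metabolite to mean 0
#' and scales to unit standard deviation (UV scaling, the chemometric
#' default); Pareto scaling (centering and division by the square root of
#' the standard deviation) is available. The returned scaling state can be
#' applied to held-out samples with [apply_scaling()].
#'
#' @param m complete `metab_matrix` (no missing values).
#' @param transform `"log"` or `"none"`.
#' @param scaling `"uv"`, `"pareto"` or `"none"` (centering only).
#' @return list `matrix` (scaled plain matrix) and `state` (a
#'   `scaling_state`: per-metabolite center, dispersion, flags).
#' @export
autoscale <- function(m, transform = c("log", "none"),
                      scaling = c("uv", "pareto", "none")) {
  transform <- match.arg(transform)
  scaling <- match.arg(scaling)
  if (anyNA(m)) stop("autoscale requires a complete matrix; impute first")
  x <- unclass(as.matrix(m))
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires strictly positive values")
    x <- log(x)
  }
  center <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero <- s == 0
  if (any(zero))
    stop("zero-variance metabolite(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  divisor <- switch(scaling, uv = s, pareto = sqrt(s),
                    none = rep(1, length(s)))
  scaled <- sweep(sweep(x, 2, center), 2, divisor, "/")
  state <- list(center = center, dispersion = s, divisor = divisor,
                transform = transform, scaling = scaling)
  class(state) <- "scaling_state"
  list(matrix = scaled, state = state)
}

#' Apply a stored scaling state to (held-out) samples
#'
#' @param m `metab_matrix` or matrix with the metabolites of the state.
#' @param state a `scaling_state` from [autoscale()].
#' @return scaled plain matrix.
#' @export
apply_scaling <- function(m, state) {
  stopifnot(inherits(state, "scaling_state"))
  x <- unclass(m)[, names(state$center), drop = FALSE]
  if (state$transform == "log") x <- log(x)
  sweep(sweep(x, 2, state$center), 2, state$divisor, "/")
}

#' Invert a scaling state
#'
#' @param x scaled matrix.
#' @param state the `scaling_state` that produced it.
#' @return matrix on the original abundance scale.
#' @export
unscale <- function(x, state) {
  out <- sweep(sweep(x, 2, state$divisor, "*"), 2, state$center, "+")
  if (state$transform == "log") out <- exp(out)
  out
}
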