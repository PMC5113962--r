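# Shared-and-unique-structures (SUS) analysis of the remission/relapse
# transition: two OPLS-DA models sharing the control class (control vs
# remission, control vs relapse), each metabolite placed by its p(corr)
# coordinate in the two models, regions classified against configurable
# thresholds, confirmed by K-means profile clustering.

SUS_REGIONS <- c("shared_up_gradual", "shared_up", "shared_down",
                 "relapse_specific", "remission_specific", "null")

subset_scaled <- function(m, idx, transform, scaling) {
  sc <- autoscale(m[idx, , drop = FALSE], transform = transform,
                  scaling = scaling)
  sc$matrix
}

#' SUS-plot coordinates from paired OPLS-DA models
#'
#' Fits two single-predictive-component OPLS-DA models sharing the control
#' class — control vs remission and control vs relapse — on pre-treatment
#' samples of the chosen disease (or of all diseases pooled), orients each
#' predictive score so the disease class has the higher mean, and returns
#' the p(corr) of every metabolite in both models.
#'
#' @param m normalized, imputed (complete) `metab_matrix`.
#' @param samples a `sample_annotation`; a `pre_treatment` column, when
#'   present, restricts patient samples to pre-treatment ones (a warning is
#'   issued when the column is absent).
#' @param disease `"MS"`, `"NMOSD"`, `"ITM"` or `"ALL"` (pooled).
#' @param a_orth orthogonal components per model (default 1).
#' @param transform,scaling per-model scaling, see [autoscale()].
#' @return data.frame of class `sus_coordinates`: `metabolite`,
#'   `pcorr_remission`, `pcorr_relapse`, `region` (all `"null"` until
#'   [classify_regions()] is applied).
#' @export
sus_coordinates <- function(m, samples, disease = "ALL", a_orth = 1,
                            transform = "log", scaling = "uv") {
  samples <- samples[match(rownames(m), samples$sample_id), ]
  if (!disease %in% c(DISEASES, "ALL")) stop("unknown disease: ", disease)
  in_disease <- if (disease == "ALL") samples$group %in% DISEASES
                else samples$group == disease
  pre <- samples$pre_treatment
  if (is.null(pre)) {
    warning("no pre_treatment flag in the annotation; using all samples")
    pre <- rep(1, nrow(samples))
  }
  pre[is.na(pre)] <- 1
  is_ctrl <- samples$group == "CTRL"
  use_rem <- is_ctrl | (in_disease & samples$status == "REMISSION" & pre == 1)
  use_rel <- is_ctrl | (in_disease & samples$status == "RELAPSE" & pre == 1)
  if (!any(use_rem & !is_ctrl) || !any(use_rel & !is_ctrl))
    stop("disease ", disease, " lacks remission or relapse samples")

  one_side <- function(use) {
    Xs <- subset_scaled(m, use, transform, scaling)
    lab <- ifelse(is_ctrl[use], "CTRL", "CASE")
    model <- fit_opls(Xs, lab, a_pred = 1, a_orth = a_orth)
    t1 <- model$T[, 1]
    flip <- mean(t1[lab == "CASE"]) < mean(t1[lab == "CTRL"])
    pc <- pcorr(model, Xs)
    if (flip) pc <- -pc
    pc
  }
  out <- data.frame(metabolite = colnames(m),
                    pcorr_remission = one_side(use_rem),
                    pcorr_relapse = one_side(use_rel),
                    region = "null",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "disease") <- disease
  class(out) <- c("sus_coordinates", "data.frame")
  out
}

#' Classify SUS-plot regions
#'
#' Deterministic region assignment from the two p(corr) coordinates
#' (x = control vs remission, y = control vs relapse):
#' `relapse_specific` iff |x| < c_axis and y >= c_contrib (and symmetrically
#' `remission_specific`); `shared_up_gradual` iff x > c_axis and
#' y > x + c_diag (above the diagonal: control < remission < relapse);
#' `shared_up` iff both >= c_contrib and |y - x| <= c_diag; `shared_down`
#' iff both <= -c_contrib; otherwise `null`. Thresholds are configuration
#' values recorded as attributes.
#'
#' @param coords a `sus_coordinates`.
#' @param c_contrib minimum |p(corr)| for a substantive contribution.
#' @param c_axis half-width of the axis bands.
#' @param c_diag half-width of the diagonal band.
#' @return the coordinates with `region` filled in.
#' @export
classify_regions <- function(coords, c_contrib = 0.3, c_axis = 0.1,
                             c_diag = 0.1) {
  x <- coords$pcorr_remission; y <- coords$pcorr_relapse
  region <- rep("null", length(x))
  region[abs(x) < c_axis & y >= c_contrib] <- "relapse_specific"
  region[abs(y) < c_axis & x >= c_contrib] <- "remission_specific"
  region[x > c_axis & y > x + c_diag] <- "shared_up_gradual"
  region[x >= c_contrib & y >= c_contrib & abs(y - x) <= c_diag] <- "shared_up"
  region[x <= -c_contrib & y <= -c_contrib] <- "shared_down"
  coords$region <- region
  attr(coords, "thresholds") <- c(c_contrib = c_contrib, c_axis = c_axis,
                                  c_diag = c_diag)
  coords
}

#' K-means confirmation of status expression patterns
#'
#' Clusters candidate metabolites on their per-metabolite standardized
#' profiles (pattern, not magnitude) with seeded multi-restart K-means, and
#' reports, per cluster, the mean abundance by status and whether the
#' monotone pattern control < remission < relapse holds.
#'
#' @param m complete `metab_matrix` (all samples).
#' @param samples a `sample_annotation`.
#' @param metabolites candidate metabolite ids (rows of the clustering).
#' @param k number of clusters (default: number of distinct SUS regions
#'   present is a sensible choice; must be >= 2 and <= #metabolites).
#' @param seed integer seed.
#' @param restarts K-means restarts (best within-cluster SS kept).
#' @return list: `cluster` (named assignment), `profiles` (cluster x status
#'   mean matrix over CTRL/REMISSION/RELAPSE), `monotone` (logical per
#'   cluster), `tot_withinss`.
#' @export
kmeans_confirm <- function(m, samples, metabolites, k = 2, seed = 1,
                           restarts = 20) {
  if (k < 2) stop("k must be >= 2")
  if (k > length(metabolites)) stop("k exceeds the number of metabolites")
  samples <- samples[match(rownames(m), samples$sample_id), ]
  prof <- t(unclass(m)[, metabolites, drop = FALSE])
  if (all(prof > 0)) prof <- log(prof)
  prof <- t(scale(t(prof)))  # per-metabolite z-scored profile
  if (anyNA(prof)) stop("constant metabolite profile(s) cannot be clustered")
  set.seed(seed)
  km <- stats::kmeans(prof, centers = k, nstart = restarts)
  st <- ifelse(samples$group == "CTRL", "CTRL", samples$status)
  lev <- c("CTRL", "REMISSION", "RELAPSE")
  profiles <- matrix(NA_real_, k, length(lev), dimnames = list(NULL, lev))
  for (ci in seq_len(k)) {
    rows <- prof[km$cluster == ci, , drop = FALSE]
    for (s in lev)
      profiles[ci, s] <- mean(rows[, st == s, drop = FALSE])
  }
  monotone <- profiles[, "CTRL"] < profiles[, "REMISSION"] &
    profiles[, "REMISSION"] < profiles[, "RELAPSE"]
  list(cluster = km$cluster, profiles = profiles, monotone = monotone,
       tot_withinss = km$tot.withinss)
}

#' Merged gradual-relapse metabolite screen
#'
#' Pools remission/relapse statuses across all diseases, classifies the SUS
#' regions and returns the `shared_up_gradual` metabolites that additionally
#' pass the univariate relapse-vs-remission confirmation (p < alpha and
#' fold change > 1 on pre-treatment patient samples).
#'
#' @param m normalized, imputed `metab_matrix`.
#' @param samples a `sample_annotation`.
#' @param alpha significance level of the univariate confirmation.
#' @param c_contrib,c_axis,c_diag region thresholds, see
#'   [classify_regions()].
#' @param a_orth orthogonal components of the SUS models.
#' @return character vector of metabolite ids; the classified coordinates
#'   are attached as attribute `"coordinates"`.
#' @export
merged_gradual_screen <- function(m, samples, alpha = 0.05, c_contrib = 0.3,
                                  c_axis = 0.1, c_diag = 0.1, a_orth = 1) {
  coords <- sus_coordinates(m, samples, disease = "ALL", a_orth = a_orth)
  coords <- classify_regions(coords, c_contrib, c_axis, c_diag)
  gradual <- coords$metabolite[coords$region == "shared_up_gradual"]
  samples2 <- samples[match(rownames(m), samples$sample_id), ]
  pre <- samples2$pre_treatment
  if (is.null(pre)) pre <- rep(1, nrow(samples2))
  pre[is.na(pre)] <- 1
  use <- samples2$group %in% DISEASES & pre == 1 &
    samples2$status %in% c("REMISSION", "RELAPSE")
  cs <- contrast_stats(m[use, , drop = FALSE], samples2[use, ],
                       reference_group = "REMISSION",
                       case_group = "RELAPSE", by = "status", alpha = alpha)
  confirmed <- cs$metabolite[cs$significant & !is.na(cs$fold_change) &
                               cs$fold_change > 1]
  out <- intersect(gradual, confirmed)
  attr(out, "coordinates") <- coords
  out
}

#' Hierarchical leaf ordering for heatmap display
#'
#' Agglomerative clustering of metabolite profiles with distance
#' 1 - Spearman rank correlation and average linkage. Metabolites with a
#' constant profile (undefined correlation) are flagged and placed last.
#'
#' @param m complete `metab_matrix`.
#' @param metabolites metabolite ids to order (>= 2).
#' @return character vector: dendrogram leaf order, constant metabolites
#'   appended; the `hclust` object is attached as attribute `"hclust"`.
#' @export
hcluster_order <- function(m, metabolites = colnames(m)) {
  if (length(metabolites) < 2) stop("need at least 2 metabolites")
  prof <- t(unclass(m)[, metabolites, drop = FALSE])
  const <- apply(prof, 1, function(r) stats::sd(r) == 0)
  if (all(const)) return(metabolites)
  ok <- rownames(prof)[!const]
  if (length(ok) == 1) {
    out <- c(ok, rownames(prof)[const])
    return(out)
  }
  rho <- stats::cor(t(prof[ok, , drop = FALSE]), method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  out <- c(ok[hc$order], rownames(prof)[const])
  attr(out, "hclust") <- hc
  if (any(const))
    attr(out, "constant") <- rownames(prof)[const]
  out
}
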