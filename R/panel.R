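# VIP-driven biomarker panels scored by a single latent component (T1) and
# evaluated by one-vs-rest ROC with bootstrap confidence intervals.

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(tie), computed from midranks.
#' Orientation is not flipped: the positive class is expected to score high.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` = positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve with AUC
#'
#' @param scores,labels as in [auc_rank()].
#' @return object of class `roc_curve`: data.frame `points` (`threshold`,
#'   `fpr`, `tpr`) running from (0,0) to (1,1), `auc`, `n_pos`, `n_neg`,
#'   and `ci_low`/`ci_high` (`NA` until bootstrapped).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  out <- list(points = pts, auc = auc_rank(scores, labels),
              n_pos = n_pos, n_neg = n_neg,
              ci_low = NA_real_, ci_high = NA_real_)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (95%% CI %.3f-%.3f)", x$ci_low, x$ci_high)
  cat(sprintf("ROC: AUC = %.3f%s, %d positive / %d negative\n",
              x$auc, ci, x$n_pos, x$n_neg))
  invisible(x)
}

#' Single-component panel score
#'
#' Coordinately transforms the abundances of the panel features into one
#' latent component: a one-predictive-component two-class PLS-DA is fitted
#' on the panel columns and its score T1 is returned, oriented so the
#' positive class has the higher mean.
#'
#' @param X_panel scaled matrix restricted to the panel features.
#' @param labels logical vector, `TRUE` = positive class.
#' @return numeric score vector (T1).
#' @export
panel_score <- function(X_panel, labels) {
  X_panel <- as.matrix(X_panel)
  labels <- as.logical(labels)
  sds <- apply(X_panel, 2, stats::sd)
  if (any(sds == 0))
    stop("constant panel column(s): ",
         paste(colnames(X_panel)[sds == 0], collapse = ", "))
  model <- fit_plsda(X_panel, ifelse(labels, "pos", "rest"), a_pred = 1)
  t1 <- model$T[, 1]
  if (mean(t1[labels]) < mean(t1[!labels])) t1 <- -t1
  t1
}

#' Percentile bootstrap confidence interval for an AUC
#'
#' Class-stratified resampling: positives and negatives are resampled with
#' replacement independently; the interval is the percentile interval of the
#' resampled AUCs. Deterministic given `seed`.
#'
#' @param scores,labels as in [auc_rank()] (both classes >= 3).
#' @param n_boot bootstrap replicates (default 500).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return named vector `c(ci_low, ci_high)`.
#' @export
bootstrap_ci <- function(scores, labels, n_boot = 500, level = 0.95, seed = 1) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) < 3 || length(neg) < 3)
    stop("both classes need >= 3 observations to bootstrap")
  set.seed(seed)
  aucs <- vapply(seq_len(n_boot), function(b) {
    ps <- pos[sample.int(length(pos), replace = TRUE)]
    ns <- neg[sample.int(length(neg), replace = TRUE)]
    auc_rank(c(ps, ns), c(rep(TRUE, length(ps)), rep(FALSE, length(ns))))
  }, 0)
  a <- (1 - level) / 2
  ci <- unname(quantile(aucs, c(a, 1 - a), type = 7))
  c(ci_low = ci[1], ci_high = ci[2])
}

contrast_names <- function(levels) paste0(levels, "_vs_rest")

# out-of-fold single-component panel score: the two-class PLS-DA is
# re-fitted without each held-out fold and the fold is scored by the
# training model, removing the optimistic bias of in-sample scores
panel_score_cv <- function(X_panel, labels, folds = 7, seed = 1) {
  X_panel <- as.matrix(X_panel)
  labels <- as.logical(labels)
  if (is.null(rownames(X_panel)))
    rownames(X_panel) <- sprintf("row%05d", seq_len(nrow(X_panel)))
  folds <- min(folds, nrow(X_panel))
  fold <- fold_assignment(rownames(X_panel),
                          ifelse(labels, "pos", "rest"), folds, seed)
  out <- numeric(nrow(X_panel))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    model <- fit_plsda(X_panel[tr, , drop = FALSE],
                       ifelse(labels[tr], "pos", "rest"), a_pred = 1)
    flip <- mean(model$T[labels[tr], 1]) < mean(model$T[!labels[tr], 1])
    sc <- drop(latent_scores(model, X_panel[!tr, , drop = FALSE]))
    out[!tr] <- if (flip) -sc else sc
  }
  out
}

#' Build a biomarker panel model over the four one-vs-rest contrasts
#'
#' For every class, the panel features are transformed to a single
#' PLS-DA component (class vs rest) and the component is scored by ROC;
#' optionally each AUC gets a bootstrap confidence interval.
#'
#' @param X scaled feature matrix (metabolites, possibly plus covariates).
#' @param labels class vector (e.g. CTRL/MS/NMOSD/ITM).
#' @param features ordered character vector of panel feature names.
#' @param n_boot bootstrap replicates for the CI (0 = none).
#' @param seed seed for the bootstrap.
#' @return object of class `panel_model`: `features`, `roc` (named list of
#'   `roc_curve` per contrast), `scores` (matrix of T1 per contrast).
#' @export
build_panel <- function(X, labels, features, n_boot = 0, seed = 1) {
  X <- as.matrix(X)
  missing_feat <- setdiff(features, colnames(X))
  if (length(missing_feat))
    stop("panel feature(s) not in the matrix: ",
         paste(missing_feat, collapse = ", "))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  Xp <- X[, features, drop = FALSE]
  roc <- list(); scores <- matrix(NA_real_, nrow(X), length(classes),
                                  dimnames = list(rownames(X), contrast_names(classes)))
  for (i in seq_along(classes)) {
    pos <- labels == classes[i]
    t1 <- panel_score(Xp, pos)
    rc <- roc_curve(t1, pos)
    if (n_boot > 0) {
      ci <- bootstrap_ci(t1, pos, n_boot = n_boot, seed = seed + i)
      rc$ci_low <- ci[["ci_low"]]; rc$ci_high <- ci[["ci_high"]]
    }
    roc[[contrast_names(classes)[i]]] <- rc
    scores[, i] <- t1
  }
  out <- list(features = features, roc = roc, scores = scores,
              classes = classes)
  class(out) <- "panel_model"
  out
}

#' @export
print.panel_model <- function(x, ...) {
  cat("biomarker panel:", paste(x$features, collapse = ", "), "\n")
  for (nm in names(x$roc))
    cat(sprintf("  %-18s AUC = %.3f\n", nm, x$roc[[nm]]$auc))
  invisible(x)
}

#' Mean one-vs-rest AUC of a panel model
#' @param panel a `panel_model`.
#' @return mean of the per-contrast AUCs.
#' @export
mean_auc <- function(panel) mean(vapply(panel$roc, `[[`, 0, "auc"))

#' Panel-size sweep over the VIP ranking
#'
#' For each k the top-k VIP features form the panel and each one-vs-rest
#' contrast is scored by a single PLS-DA component and [auc_rank()].
#' Scores are computed out-of-fold (cross-validated) by default: in-sample
#' T1 scores grow more optimistic with every added feature, which would hide
#' the true optimum panel size. Reports the k maximizing the mean AUC and
#' the plateau (all k within `plateau_tol` of the maximum).
#'
#' @param X scaled feature matrix.
#' @param labels class vector.
#' @param vip_order feature names in decreasing VIP order (from a 4-class
#'   model; ties broken by ascending name upstream).
#' @param k_min,k_max panel sizes tried.
#' @param plateau_tol mean-AUC tolerance defining the plateau (default 0.005).
#' @param cv_folds folds for the out-of-fold scores (0 = in-sample).
#' @param seed seed for the fold shuffle.
#' @param n_rep number of cross-validation repetitions (distinct fold
#'   shuffles) averaged per k; repetitions damp fold-assignment noise, which
#'   otherwise dwarfs the `plateau_tol` band on a flat curve.
#' @param rank_in_cv re-rank features by VIP inside every training fold
#'   (default). Ranking on the full cohort lets chance-correlated features
#'   earn both their rank and their apparent discrimination from the same
#'   samples, so the curve keeps creeping upward past the true optimum;
#'   fold-internal ranking removes that selection bias.
#' @return list: `table` (data.frame `k`, one AUC column per contrast,
#'   `mean_auc`), `k_best`, `plateau` (integer vector).
#' @export
sweep_panel_size <- function(X, labels, vip_order, k_min = 2, k_max = 20,
                             plateau_tol = 0.005, cv_folds = 7, seed = 1,
                             n_rep = 1, rank_in_cv = TRUE) {
  if (k_max > length(vip_order))
    stop("k_max exceeds the number of available features")
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%05d", seq_len(nrow(X)))
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  ks <- seq.int(k_min, k_max)
  if (cv_folds > 0 && rank_in_cv) {
    # selection inside cross-validation: per repetition and fold, rank by
    # VIP on the training samples, fit the per-contrast panel models on the
    # training samples, score the held-out fold; pool scores per (k, class)
    auc_rep <- array(0, c(length(ks), length(classes), n_rep))
    for (r in seq_len(max(1, n_rep))) {
      fold <- fold_assignment(rownames(X), labels, cv_folds,
                              seed + (r - 1) * 1000L)
      scores <- array(NA_real_, c(nrow(X), length(ks), length(classes)))
      for (f in sort(unique(fold))) {
        tr <- fold != f
        vo_f <- vip_ranking(X[tr, , drop = FALSE], labels[tr])
        for (ki in seq_along(ks)) {
          feats <- vo_f[seq_len(ks[ki])]
          for (ci in seq_along(classes)) {
            pos_tr <- labels[tr] == classes[ci]
            model <- fit_plsda(X[tr, feats, drop = FALSE],
                               ifelse(pos_tr, "pos", "rest"), a_pred = 1)
            flip <- mean(model$T[pos_tr, 1]) < mean(model$T[!pos_tr, 1])
            sc <- drop(latent_scores(model, X[!tr, feats, drop = FALSE]))
            scores[!tr, ki, ci] <- if (flip) -sc else sc
          }
        }
      }
      for (ki in seq_along(ks)) for (ci in seq_along(classes))
        auc_rep[ki, ci, r] <- auc_rank(scores[, ki, ci], labels == classes[ci])
    }
    aucm <- apply(auc_rep, c(1, 2), mean)
    rows <- lapply(seq_along(ks), function(ki) {
      aucs <- aucm[ki, ]
      names(aucs) <- contrast_names(classes)
      c(k = ks[ki], aucs, mean_auc = mean(aucs))
    })
    tab <- as.data.frame(do.call(rbind, rows))
    best <- max(tab$mean_auc)
    return(list(table = tab,
                k_best = tab$k[which.max(tab$mean_auc)],
                plateau = tab$k[tab$mean_auc >= best - plateau_tol]))
  }
  rows <- lapply(ks, function(k) {
    Xp <- X[, vip_order[seq_len(k)], drop = FALSE]
    aucs <- rowMeans(vapply(seq_len(max(1, n_rep)), function(r)
      vapply(classes, function(cl) {
        pos <- labels == cl
        sc <- if (cv_folds > 0) panel_score_cv(Xp, pos, cv_folds,
                                               seed + (r - 1) * 1000L)
              else panel_score(Xp, pos)
        auc_rank(sc, pos)
      }, 0), numeric(length(classes))))
    names(aucs) <- contrast_names(classes)
    c(k = k, aucs, mean_auc = mean(aucs))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  best <- max(tab$mean_auc)
  list(table = tab,
       k_best = tab$k[which.max(tab$mean_auc)],
       plateau = tab$k[tab$mean_auc >= best - plateau_tol])
}

#' VIP ranking of features from a multi-class PLS-DA
#'
#' @param X scaled feature matrix.
#' @param labels class vector.
#' @param a_pred predictive components for the ranking model; defaults to
#'   the discriminant dimensionality, number of classes - 1.
#' @return character vector of feature names in decreasing VIP order, ties
#'   broken by ascending name.
#' @export
vip_ranking <- function(X, labels, a_pred = NULL) {
  if (is.null(a_pred)) a_pred <- max(1L, length(unique(labels)) - 1L)
  model <- fit_plsda(as.matrix(X), labels, a_pred = a_pred)
  v <- vip(model)
  names(v)[order(-v, names(v))]
}

#' Scale clinical covariates for joint modelling
#'
#' Numeric covariates are autoscaled like metabolites; the binary OCB is
#' centered but not variance-scaled (unit-variance scaling of a rare binary
#' would inflate its leverage).
#'
#' @param samples a `sample_annotation`.
#' @param clinical covariate names among `edss`, `ocb`, `protein`, `wbc`,
#'   `igg_index`.
#' @return list `matrix` (samples x covariates, `NA` where missing) built
#'   from the scaled covariates.
#' @keywords internal
scale_clinical <- function(samples, clinical) {
  bad <- setdiff(clinical, CLINICAL_VARS)
  if (length(bad)) stop("unknown clinical covariate(s): ",
                        paste(bad, collapse = ", "))
  out <- matrix(NA_real_, nrow(samples), length(clinical),
                dimnames = list(samples$sample_id, clinical))
  for (v in clinical) {
    x <- samples[[v]]
    if (all(is.na(x))) stop("covariate entirely missing: ", v)
    if (v == "ocb") out[, v] <- x - mean(x, na.rm = TRUE)
    else {
      s <- stats::sd(x, na.rm = TRUE)
      if (is.na(s) || s == 0) stop("covariate has no variance: ", v)
      out[, v] <- (x - mean(x, na.rm = TRUE)) / s
    }
  }
  out
}

#' Joint metabolite + clinical biomarker panel
#'
#' Appends scaled clinical covariates to the metabolite matrix, recomputes
#' the VIP ranking on the augmented multi-class model, takes the top
#' `n_features` features and evaluates them over the four one-vs-rest
#' contrasts. Samples missing a selected covariate are excluded (their count
#' is reported via `message`).
#'
#' @param X scaled metabolite matrix.
#' @param samples a `sample_annotation` aligned with the rows of `X`.
#' @param labels class vector aligned with the rows of `X`.
#' @param clinical covariate names (empty vector reduces to the
#'   metabolite-only pipeline).
#' @param n_features panel size (default 10, the reference joint panel size).
#' @param features optional explicit feature set overriding the VIP
#'   selection (e.g. [panel_joint_reference()]).
#' @param a_pred components of the VIP ranking model.
#' @param n_boot,seed bootstrap settings passed to [build_panel()].
#' @return a `panel_model` with the VIP ranking attached as attribute
#'   `"vip_order"`.
#' @export
joint_panel <- function(X, samples, labels, clinical = c("edss", "ocb", "protein"),
                        n_features = 10, features = NULL, a_pred = NULL,
                        n_boot = 0, seed = 1) {
  X <- as.matrix(X)
  if (length(clinical)) {
    samples <- samples[match(rownames(X), samples$sample_id), ]
    cm <- scale_clinical(samples, clinical)
    keep <- rowSums(is.na(cm)) == 0
    if (any(!keep))
      message(sum(!keep), " sample(s) dropped for missing clinical covariates")
    X <- cbind(X[keep, , drop = FALSE], cm[keep, , drop = FALSE])
    labels <- labels[keep]
    # re-center the covariates on the retained samples
    X[, clinical] <- sweep(X[, clinical, drop = FALSE], 2,
                           colMeans(X[, clinical, drop = FALSE]))
  }
  vip_order <- vip_ranking(X, labels, a_pred = a_pred)
  if (is.null(features)) features <- vip_order[seq_len(min(n_features, ncol(X)))]
  pm <- build_panel(X, labels, features, n_boot = n_boot, seed = seed)
  attr(pm, "vip_order") <- vip_order
  pm
}
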