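# NIPALS partial least squares machinery: PLS-DA, OPLS(-DA),
# cross-validated Q2, VIP and p(corr).
#
# All fitting functions expect a scaled predictor matrix (see autoscale());
# responses are centered internally. Class responses are one-hot dummy
# matrices, one centered column per class, prediction by largest predicted
# dummy.

class_dummies <- function(labels, levels = NULL) {
  f <- factor(labels, levels = if (is.null(levels)) sort(unique(labels)) else levels)
  if (anyNA(f)) stop("labels contain values outside the class levels")
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  rownames(Y) <- names(labels)
  Y
}

center_cols <- function(Y, scale = FALSE) {
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  scl <- rep(1, ncol(Y))
  if (scale) {
    scl <- apply(Yc, 2, stats::sd)
    if (any(scl == 0)) stop("constant response column")
    Yc <- sweep(Yc, 2, scl, "/")
  }
  list(Y = Yc, center = ctr, scale = scl)
}

# one NIPALS PLS round on (X, Y): returns normalized weight w, score t,
# loading p and y-loading c for the current residual matrices
nipals_round <- function(X, Y, max_iter = 2000, tol = 1e-10, comp = 1) {
  u <- Y[, which.max(apply(Y, 2, stats::var)), drop = TRUE]
  t_old <- rep(Inf, nrow(X))
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(X, u)) / sum(u^2)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) stop("rank of X exhausted at component ", comp)
    w <- w / nw
    tt <- drop(X %*% w)
    cc <- drop(crossprod(Y, tt)) / sum(tt^2)
    u <- drop(Y %*% cc) / sum(cc^2)
    if (sqrt(sum((tt - t_old)^2)) < tol * max(1, sqrt(sum(tt^2)))) break
    t_old <- tt
    if (it == max_iter)
      stop("NIPALS did not converge at component ", comp)
  }
  # sign convention: the largest-|weight| variable gets a positive weight
  j <- which.max(abs(w))
  if (w[j] < 0) { w <- -w; tt <- -tt; cc <- -cc }
  p <- drop(crossprod(X, tt)) / sum(tt^2)
  list(w = w, t = tt, c = cc, p = p)
}

nipals_pls <- function(X, Y, ncomp, max_iter = 2000) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ssy_tot <- sum(Y^2)
  W <- P <- matrix(0, p, ncomp, dimnames = list(colnames(X), NULL))
  Tm <- matrix(0, n, ncomp, dimnames = list(rownames(X), NULL))
  C <- matrix(0, m, ncomp, dimnames = list(colnames(Y), NULL))
  ssy_explained <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    r <- nipals_round(X, Y, max_iter = max_iter, comp = a)
    W[, a] <- r$w; Tm[, a] <- r$t; C[, a] <- r$c; P[, a] <- r$p
    ssy_before <- sum(Y^2)
    X <- X - tcrossprod(r$t, r$p)
    Y <- Y - tcrossprod(r$t, r$c)
    ssy_explained[a] <- ssy_before - sum(Y^2)
  }
  list(W = W, P = P, T = Tm, C = C, ssy_explained = ssy_explained,
       r2y = 1 - sum(Y^2) / ssy_tot)
}

finish_model <- function(fit, orth, y_center, kind, class_levels = NULL,
                         y_name = NULL, y_scale = NULL) {
  # regression coefficients of the predictive part: B = W (P'W)^-1 C'
  Wstar <- fit$W %*% solve(crossprod(fit$P, fit$W))
  B <- tcrossprod(Wstar, fit$C)
  if (is.null(y_scale)) y_scale <- rep(1, length(y_center))
  model <- list(W = fit$W, P = fit$P, T = fit$T, C = fit$C,
                W_o = orth$W_o, P_o = orth$P_o, T_o = orth$T_o,
                B = B, y_center = y_center, y_scale = y_scale,
                ssy_explained = fit$ssy_explained, R2Y_cum = fit$r2y,
                a_pred = ncol(fit$W),
                a_orth = if (is.null(orth$W_o)) 0L else ncol(orth$W_o),
                kind = kind, class_levels = class_levels, y_name = y_name)
  class(model) <- "latent_model"
  model
}

#' @export
print.latent_model <- function(x, ...) {
  cat(sprintf("latent_model (%s): %d predictive + %d orthogonal component(s), R2Y = %.3f\n",
              x$kind, x$a_pred, x$a_orth, x$R2Y_cum))
  invisible(x)
}

#' Fit a PLS-DA model by NIPALS
#'
#' PLS2 discriminant analysis: the class vector is expanded to one-hot
#' dummies, centered and unit-variance scaled (the chemometric default;
#' scaling the dummy block keeps small classes from being drowned out by
#' large ones), and latent components are extracted by the NIPALS iteration
#' with deflation of both blocks. Component signs are fixed so the
#' largest-|weight| variable is positive.
#'
#' @param X scaled predictor matrix (samples x metabolites).
#' @param labels class vector (>= 2 classes).
#' @param a_pred number of predictive components.
#' @return a `latent_model` with weights `W`, loadings `P`, scores `T`,
#'   Y-loadings `C`, per-component explained Y-variance and cumulative
#'   `R2Y_cum`.
#' @export
fit_plsda <- function(X, labels, a_pred = 2) {
  X <- as.matrix(X)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (a_pred > min(dim(X))) stop("a_pred exceeds the rank bound of X")
  Yc <- center_cols(class_dummies(labels), scale = TRUE)
  fit <- nipals_pls(X, Yc$Y, a_pred)
  finish_model(fit, list(), Yc$center, "plsda",
               class_levels = sort(unique(as.character(labels))),
               y_scale = Yc$scale)
}

#' Fit an OPLS(-DA) model
#'
#' Orthogonal projections to latent structures: for each orthogonal
#' component the current PLS loading is stripped of its response-predictive
#' part (projection onto the column space of X'Y), yielding a weight whose
#' score is exactly uncorrelated with every response column; X is deflated
#' by these orthogonal components before the predictive component(s) are
#' fitted. With `a_orth = 0` the model coincides with [fit_plsda()].
#'
#' @param X scaled predictor matrix.
#' @param y class vector (discriminant) or numeric response (regression).
#' @param a_pred predictive components (1 is the standard choice).
#' @param a_orth orthogonal components (>= 0).
#' @return a `latent_model` with additional `W_o`, `P_o`, `T_o`.
#' @export
fit_opls <- function(X, y, a_pred = 1, a_orth = 1) {
  X <- as.matrix(X)
  if (a_orth < 0) stop("a_orth must be >= 0")
  discriminant <- is.character(y) || is.factor(y)
  if (discriminant) {
    Yc <- center_cols(class_dummies(y), scale = TRUE)
    class_levels <- sort(unique(as.character(y)))
    y_name <- NULL
  } else {
    ym <- matrix(as.numeric(y), ncol = 1,
                 dimnames = list(rownames(X), "y"))
    Yc <- center_cols(ym)
    class_levels <- NULL
    y_name <- "y"
  }
  Y <- Yc$Y
  # orthonormal basis of the predictive weight space; X'Y is invariant under
  # orthogonal deflation, so one basis serves every orthogonal round
  Wy <- qr.Q(qr(crossprod(X, Y)))
  W_o <- P_o <- matrix(0, ncol(X), a_orth, dimnames = list(colnames(X), NULL))
  T_o <- matrix(0, nrow(X), a_orth, dimnames = list(rownames(X), NULL))
  if (a_orth > 0) {
    for (k in seq_len(a_orth)) {
      r <- nipals_round(X, Y, comp = k)
      w_o <- r$p - drop(Wy %*% crossprod(Wy, r$p))
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-10)
        stop("residual X rank exhausted: a_orth = ", a_orth, " is too large")
      w_o <- w_o / nw
      j <- which.max(abs(w_o))
      if (w_o[j] < 0) w_o <- -w_o
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
      W_o[, k] <- w_o; P_o[, k] <- p_o; T_o[, k] <- t_o
    }
  }
  fit <- nipals_pls(X, Y, a_pred)
  orth <- if (a_orth > 0) list(W_o = W_o, P_o = P_o, T_o = T_o) else list()
  finish_model(fit, orth, Yc$center,
               if (discriminant) "oplsda" else "opls",
               class_levels = class_levels, y_name = y_name,
               y_scale = Yc$scale)
}

# strip a new (scaled) matrix of the model's orthogonal components
remove_orthogonal <- function(model, X) {
  if (model$a_orth == 0) return(X)
  for (k in seq_len(model$a_orth)) {
    t_o <- drop(X %*% model$W_o[, k])
    X <- X - tcrossprod(t_o, model$P_o[, k])
  }
  X
}

#' Predict from a fitted latent model
#'
#' @param object a `latent_model`.
#' @param newdata scaled matrix with the model's predictor columns.
#' @param type `"response"` (numeric predictions of the response block) or
#'   `"class"` (discriminant models: largest predicted dummy).
#' @param ... unused.
#' @return matrix of predicted responses, or a character vector of classes.
#' @export
predict.latent_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- remove_orthogonal(object, as.matrix(newdata))
  Yhat <- sweep(sweep(X %*% object$B, 2, object$y_scale, "*"),
                2, object$y_center, "+")
  if (type == "response") return(Yhat)
  if (is.null(object$class_levels)) stop("not a discriminant model")
  colnames(Yhat)[max.col(Yhat, ties.method = "first")]
}

#' Latent scores of new samples
#'
#' @param model a `latent_model`.
#' @param newdata scaled matrix.
#' @return samples x a_pred matrix of predictive scores.
#' @export
latent_scores <- function(model, newdata) {
  X <- remove_orthogonal(model, as.matrix(newdata))
  Wstar <- model$W %*% solve(crossprod(model$P, model$W))
  X %*% Wstar
}

# deterministic stratified fold assignment: samples are taken in sorted-id
# order, permuted with the given seed within stratum, then dealt cyclically
fold_assignment <- function(ids, strata, folds, seed) {
  fold <- integer(length(ids))
  names(fold) <- ids
  ord <- order(ids)
  for (s in unique(strata)) {
    idx <- ord[strata[ord] == s]
    set.seed(seed + sum(utf8ToInt(paste(as.character(s), collapse = ""))))
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold[ids]
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS/SSY with the prediction residual sum of squares
#' accumulated over held-out folds. Folds are stratified by class for
#' discriminant responses; centering and scaling of X are re-estimated
#' inside each training fold and applied to the held-out samples.
#'
#' @param X unscaled (but complete) predictor matrix.
#' @param y class vector or numeric response.
#' @param a_pred,a_orth component counts; `a_orth > 0` fits OPLS models.
#' @param folds number of folds (>= 2; `nrow(X)` gives leave-one-out).
#' @param seed seed for the deterministic fold shuffle.
#' @param transform,scaling per-fold preprocessing, see [autoscale()].
#' @return scalar Q2 (<= 1).
#' @export
q2_cv <- function(X, y, a_pred = 1, a_orth = 0, folds = 7, seed = 1,
                  transform = "none", scaling = "uv") {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("row%05d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("var%05d", seq_len(ncol(X)))
  if (folds < 2) stop("folds must be >= 2")
  folds <- min(folds, nrow(X))
  discriminant <- is.character(y) || is.factor(y)
  strata <- if (discriminant) as.character(y) else rep("all", nrow(X))
  fold <- fold_assignment(rownames(X), strata, folds, seed)
  levels_all <- if (discriminant) sort(unique(as.character(y))) else NULL
  press <- ssy <- 0
  for (k in seq_len(folds)) {
    tr <- fold != k; te <- !tr
    if (discriminant && length(unique(strata[tr])) < length(levels_all))
      stop("fold ", k, " lost an entire class; reduce folds")
    sc <- autoscale(X[tr, , drop = FALSE],
                    transform = transform, scaling = scaling)
    Xtr <- sc$matrix
    Xte <- apply_scaling(X[te, , drop = FALSE], sc$state)
    if (discriminant) {
      Ytr <- class_dummies(strata[tr], levels_all)
      Yte <- class_dummies(strata[te], levels_all)
    } else {
      Ytr <- matrix(as.numeric(y)[tr], ncol = 1)
      Yte <- matrix(as.numeric(y)[te], ncol = 1)
    }
    ctr <- colMeans(Ytr)
    model <- if (a_orth > 0) fit_opls(Xtr, if (discriminant) strata[tr] else drop(Ytr),
                                      a_pred, a_orth)
             else if (discriminant) fit_plsda(Xtr, strata[tr], a_pred)
             else fit_opls(Xtr, drop(Ytr), a_pred, 0)
    Yhat <- predict(model, Xte)
    Yte_c <- sweep(Yte, 2, ctr)
    Yhat_c <- sweep(Yhat, 2, ctr)  # back to the centered scale of the fold
    press <- press + sum((Yte_c - Yhat_c)^2)
    ssy <- ssy + sum(Yte_c^2)
  }
  1 - press / ssy
}

#' Select the number of predictive components by cross-validation
#'
#' Components are added while cross-validated Q2 improves by more than
#' `delta` (the conventional chemometric rule).
#'
#' @inheritParams q2_cv
#' @param a_max maximum components considered.
#' @param delta minimum Q2 improvement to accept a component.
#' @return list `a_pred` (selected count) and `q2` (Q2 per count tried).
#' @export
choose_ncomp <- function(X, y, a_max = 5, a_orth = 0, folds = 7, seed = 1,
                         delta = 0.01, transform = "none", scaling = "uv") {
  q2 <- numeric(0)
  best <- -Inf; a_sel <- 1
  for (a in seq_len(a_max)) {
    q2[a] <- q2_cv(X, y, a_pred = a, a_orth = a_orth, folds = folds,
                   seed = seed, transform = transform, scaling = scaling)
    if (q2[a] > best + delta) { best <- q2[a]; a_sel <- a } else break
  }
  list(a_pred = a_sel, q2 = q2)
}

#' Variable importance in the projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a ) over the
#' predictive components; the mean of squared VIP scores is exactly 1.
#'
#' @param model a fitted `latent_model`.
#' @return named numeric vector of VIP scores (>= 0).
#' @export
vip <- function(model) {
  W <- model$W
  ssy <- model$ssy_explained
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  v <- sqrt(nrow(W) * drop(wn^2 %*% ssy) / sum(ssy))
  names(v) <- rownames(W)
  v
}

#' p(corr): correlation of each variable with the predictive score
#'
#' The loading coordinate used by S- and SUS-plots: Pearson correlation
#' between the single predictive score T1 and each (scaled) predictor
#' column.
#'
#' @param model a `latent_model` with exactly one predictive component.
#' @param X the scaled matrix the model was fitted on.
#' @return named vector of correlations in \[-1, 1\].
#' @export
pcorr <- function(model, X) {
  if (model$a_pred != 1) stop("p(corr) requires exactly 1 predictive component")
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  drop(cor(model$T[, 1], X))
}

#' Response-related variable profile for a numeric response
#'
#' Fits a single-predictive-component OPLS regression of the response
#' (typically the EDSS disability score) on all metabolites and returns the
#' predictive weight of each metabolite together with its p(corr), ordered
#' by a structural-class grouping when one is supplied.
#'
#' @param X scaled metabolite matrix.
#' @param response numeric response, no missing values.
#' @param a_orth orthogonal components (default 1).
#' @param class_order optional character vector (e.g. chemical classes in
#'   display order) named by metabolite, used to re-organize the profile.
#' @return list: `profile` data.frame (`metabolite`, `weight`, `pcorr`,
#'   `class`), `model` the fitted `latent_model`.
#' @export
y_related_profile <- function(X, response, a_orth = 1, class_order = NULL) {
  if (anyNA(response)) stop("response contains missing values")
  if (length(unique(response)) < 2) stop("response is constant")
  model <- fit_opls(as.matrix(X), as.numeric(response), a_pred = 1,
                    a_orth = a_orth)
  # orient the component so it points along increasing response
  if (cor(model$T[, 1], response) < 0) {
    model$W <- -model$W; model$T <- -model$T
    model$C <- -model$C; model$P <- -model$P
  }
  pc <- pcorr(model, X)
  prof <- data.frame(metabolite = colnames(X),
                     weight = model$W[, 1],
                     pcorr = pc,
                     stringsAsFactors = FALSE)
  if (!is.null(class_order)) {
    prof$class <- class_order[prof$metabolite]
    prof <- prof[order(match(prof$class, unique(class_order)), prof$metabolite), ]
  }
  rownames(prof) <- NULL
  list(profile = prof, model = model)
}

#' Principal-component scores
#'
#' @param X complete (scaled) matrix.
#' @param n_comp number of components.
#' @return samples x n_comp score matrix with the fraction of variance
#'   explained attached as attribute `"explained"`.
#' @export
pca_scores <- function(X, n_comp = 2) {
  X <- as.matrix(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_comp <- min(n_comp, ncol(pc$x))
  out <- pc$x[, seq_len(n_comp), drop = FALSE]
  attr(out, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_comp)]
  out
}
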