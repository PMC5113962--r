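# independent oracle: PLS weights via eigen-decomposition of X'YY'X,
# component by component with the same deflation as NIPALS
eigen_pls_oracle <- function(X, Y, ncomp) {
  W <- T_ <- NULL
  for (a in seq_len(ncomp)) {
    M <- crossprod(X, Y)
    ev <- eigen(tcrossprod(M), symmetric = TRUE)
    w <- ev$vectors[, 1]
    tt <- drop(X %*% w)
    p <- drop(crossprod(X, tt)) / sum(tt^2)
    cc <- drop(crossprod(Y, tt)) / sum(tt^2)
    X <- X - tcrossprod(tt, p)
    Y <- Y - tcrossprod(tt, cc)
    W <- cbind(W, w); T_ <- cbind(T_, tt)
  }
  list(W = W, T = T_)
}

dummy_scaled <- function(labels) {
  Y <- stats::model.matrix(~ factor(labels) - 1)
  colnames(Y) <- levels(factor(labels))
  scale(Y)
}

test_that("two separable classes are split by the first score with no overlap", {
  set.seed(1)
  X <- rbind(matrix(rnorm(40, -3, 0.5), 20, 2), matrix(rnorm(40, 3, 0.5), 20, 2))
  dimnames(X) <- list(sprintf("s%02d", 1:40), c("v1", "v2"))
  lab <- rep(c("A", "B"), each = 20)
  m <- fit_plsda(scale(X), lab, a_pred = 1)
  expect_lt(max(m$T[lab == "A", 1]) * min(m$T[lab == "B", 1]), 0)  # opposite sides
  expect_true(max(m$T[lab == "A", 1]) < min(m$T[lab == "B", 1]) ||
                min(m$T[lab == "A", 1]) > max(m$T[lab == "B", 1]))
  expect_identical(unname(predict(m, scale(X), type = "class")), lab)
})

test_that("single-response PLS weight is proportional to X'y", {
  set.seed(2)
  X <- scale(matrix(rnorm(30 * 6), 30, 6,
                    dimnames = list(sprintf("s%02d", 1:30), sprintf("v%d", 1:6))))
  y <- rnorm(30)
  m <- fit_opls(X, y, a_pred = 1, a_orth = 0)
  w_closed <- drop(crossprod(X, y - mean(y)))
  w_closed <- w_closed / sqrt(sum(w_closed^2))
  expect_equal(abs(m$W[, 1]), abs(w_closed), tolerance = 1e-10)
})

test_that("NIPALS matches the eigen-decomposition oracle up to sign", {
  set.seed(3)
  X <- scale(matrix(rnorm(6 * 4), 6, 4,
                    dimnames = list(sprintf("s%d", 1:6), sprintf("v%d", 1:4))))
  lab <- c("A", "A", "B", "B", "C", "C")
  m <- fit_plsda(X, lab, a_pred = 2)
  orc <- eigen_pls_oracle(X, dummy_scaled(lab), 2)
  for (a in 1:2) {
    expect_equal(unname(abs(m$W[, a])), unname(abs(orc$W[, a])), tolerance = 1e-8)
    expect_equal(unname(abs(m$T[, a])), unname(abs(orc$T[, a])), tolerance = 1e-8)
  }
})

test_that("scores from successive components are mutually orthogonal", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(25 * 10), 25, 10,
                      dimnames = list(sprintf("s%02d", 1:25), sprintf("v%02d", 1:10))))
    lab <- sample(c("A", "B", "C"), 25, replace = TRUE)
    m <- fit_plsda(X, lab, a_pred = 3)
    G <- crossprod(m$T)
    expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  }
})

test_that("orthogonal components have zero correlation with every response column", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(30 * 12), 30, 12,
                      dimnames = list(sprintf("s%02d", 1:30), sprintf("v%02d", 1:12))))
    lab <- sample(c("A", "B", "C"), 30, replace = TRUE)
    m <- fit_opls(X, lab, a_pred = 1, a_orth = 2)
    Y <- dummy_scaled(lab)
    expect_lt(max(abs(cor(m$T_o, Y))), 1e-8)
  }
})

test_that("injected response-orthogonal structure is captured by the orthogonal part", {
  set.seed(6)
  n <- 40; p <- 10
  y <- rnorm(n); y <- y - mean(y)
  t_o <- residuals(lm(rnorm(n) ~ y))     # structured variation orthogonal to y
  c_p <- rnorm(p); p_o <- rnorm(p)
  X <- tcrossprod(y, c_p) + 3 * tcrossprod(t_o, p_o) +
    matrix(rnorm(n * p, 0, 0.01), n, p)
  dimnames(X) <- list(sprintf("s%02d", 1:n), sprintf("v%02d", 1:p))
  m <- fit_opls(X, y, a_pred = 1, a_orth = 1)
  expect_lt(abs(cor(m$T_o[, 1], y)), 1e-8)
  expect_gt(abs(cor(m$T_o[, 1], t_o)), 0.99)
})

test_that("zero orthogonal components reduce OPLS to plain PLS exactly", {
  tc <- random_two_class(seed = 7)
  m0 <- fit_opls(tc$X, tc$labels, a_pred = 2, a_orth = 0)
  mp <- fit_plsda(tc$X, tc$labels, a_pred = 2)
  expect_equal(m0$T, mp$T, tolerance = 1e-12)
  expect_equal(m0$W, mp$W, tolerance = 1e-12)
})

test_that("rank exhaustion is reported", {
  tc <- random_two_class(n = 10, p = 3, seed = 8)
  expect_error(fit_opls(tc$X, tc$labels, a_pred = 1, a_orth = 5), "rank")
})

test_that("Q2 is near one for a noiseless linear response and low for permuted", {
  set.seed(9)
  X <- matrix(rnorm(120 * 5), 120, 5)
  y <- drop(X %*% c(1, -2, 0.5, 1, 0))
  expect_gte(q2_cv(X, y, a_pred = 3, folds = 7, seed = 1), 0.99)
  q2p <- vapply(1:20, function(i) q2_cv(X, sample(y), a_pred = 2,
                                        folds = 7, seed = i), 0)
  expect_lte(mean(q2p), 0.1)
})

test_that("leave-one-out Q2 runs and is finite; losing a class errors", {
  tc <- random_two_class(n = 14, p = 4, seed = 10)
  q <- q2_cv(tc$X, tc$labels, a_pred = 1, folds = nrow(tc$X), seed = 1)
  expect_true(is.finite(q))
  lab_rare <- c("A", rep("B", 13))
  expect_error(q2_cv(tc$X, lab_rare, a_pred = 1, folds = 7, seed = 1), "class")
})

test_that("Q2 is invariant to sample order under the deterministic fold scheme", {
  tc <- random_two_class(n = 24, p = 6, seed = 11)
  q1 <- q2_cv(tc$X, tc$labels, a_pred = 2, folds = 6, seed = 5)
  perm <- sample(nrow(tc$X))
  q2 <- q2_cv(tc$X[perm, ], tc$labels[perm], a_pred = 2, folds = 6, seed = 5)
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("the VIP mean-square identity holds and duplicate columns share scores", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- scale(matrix(rnorm(30 * 9), 30, 9,
                      dimnames = list(sprintf("s%02d", 1:30), sprintf("v%02d", 1:9))))
    lab <- sample(c("A", "B", "C"), 30, replace = TRUE)
    v <- vip(fit_plsda(X, lab, a_pred = 2))
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
    expect_true(all(v >= 0))
  }
  # two identical columns receive identical VIP
  set.seed(20)
  X <- matrix(rnorm(40 * 3), 40, 3)
  X <- cbind(X, X[, 3])
  X <- scale(X)
  dimnames(X) <- list(sprintf("s%02d", 1:40), c("a", "b", "c", "c2"))
  v <- vip(fit_plsda(X, rep(c("A", "B"), 20), a_pred = 1))
  expect_equal(unname(v["c"]), unname(v["c2"]), tolerance = 1e-10)
})

test_that("p(corr) equals direct correlation with the predictive score", {
  set.seed(12)
  X <- scale(matrix(rnorm(10 * 5), 10, 5,
                    dimnames = list(sprintf("s%02d", 1:10), sprintf("v%d", 1:5))))
  lab <- rep(c("A", "B"), 5)
  m <- fit_opls(X, lab, a_pred = 1, a_orth = 1)
  expect_equal(pcorr(m, X), drop(cor(m$T[, 1], X)), tolerance = 1e-12)
  # a column proportional to T1 has p(corr) = 1
  X2 <- cbind(X, t1col = m$T[, 1] / sd(m$T[, 1]))
  expect_equal(unname(drop(cor(m$T[, 1], X2[, "t1col"]))), 1, tolerance = 1e-12)
  # multi-component models are refused
  m2 <- fit_plsda(X, lab, a_pred = 2)
  expect_error(pcorr(m2, X), "1 predictive")
  # zero-variance columns are refused
  X3 <- X; X3[, 2] <- 0
  expect_error(pcorr(m, X3), "zero-variance")
})

test_that("PCA scores match prcomp behaviour on degenerate inputs", {
  line <- outer(seq(1, 5), c(1, 2, 0.5))
  dimnames(line) <- list(sprintf("s%d", 1:5), sprintf("v%d", 1:3))
  sc <- pca_scores(line, 2)
  expect_equal(attr(sc, "explained")[1], 1, tolerance = 1e-12)
  dup <- rbind(line, line[3, , drop = FALSE])
  rownames(dup)[6] <- "s3dup"
  sc2 <- pca_scores(dup, 2)
  expect_equal(unname(sc2["s3", ]), unname(sc2["s3dup", ]), tolerance = 1e-12)
})

test_that("PCA scores agree with a NIPALS-PCA oracle up to sign", {
  set.seed(13)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("s%02d", 1:20), sprintf("v%d", 1:6)))
  got <- pca_scores(X, 2)
  # NIPALS PCA oracle: power iteration with deflation on the centered matrix
  Xc <- scale(X, scale = FALSE)
  orc <- NULL
  for (a in 1:2) {
    tt <- Xc[, 1]
    for (i in 1:500) {
      p <- drop(crossprod(Xc, tt)) / sum(tt^2)
      p <- p / sqrt(sum(p^2))
      t_new <- drop(Xc %*% p)
      if (sqrt(sum((t_new - tt)^2)) < 1e-12) break
      tt <- t_new
    }
    Xc <- Xc - tcrossprod(t_new, p)
    orc <- cbind(orc, t_new)
  }
  for (a in 1:2)
    expect_equal(abs(unname(got[, a])), abs(unname(orc[, a])), tolerance = 1e-6)
})

test_that("component selection follows the Q2 improvement rule", {
  set.seed(14)
  X <- matrix(rnorm(80 * 6), 80, 6)
  y <- drop(X[, 1:2] %*% c(2, -1)) + rnorm(80, 0, 0.1)
  sel <- choose_ncomp(X, y, a_max = 4, folds = 7, seed = 1)
  expect_gte(sel$a_pred, 1)
  expect_lte(sel$a_pred, 4)
  expect_true(all(diff(sel$q2[seq_len(sel$a_pred)]) > 0.01 | sel$a_pred == 1))
})

test_that("the response profile recovers designed EDSS couplings (seed-averaged)", {
  wsum <- NULL
  for (s in 1:5) {
    pp <- preprocessed_cohort(seed = s)
    sam <- pp$cohort$samples
    pat <- sam$group != "CTRL"
    yr <- y_related_profile(pp$scaled[sam$sample_id[pat], ], sam$edss[pat])
    w <- setNames(yr$profile$weight, yr$profile$metabolite)
    wsum <- if (is.null(wsum)) w else wsum + w[names(wsum)]
  }
  wavg <- sort(wsum / 5, decreasing = TRUE)
  expect_setequal(names(wavg)[1:2], c("1-monostearin", "1-monopalmitin"))
  negs <- names(sort(wsum))
  expect_identical(negs[1], "ethanolamine")
  expect_true(all(c("threose", "1,5-anhydroglucitol") %in% negs[1:4]))
})

test_that("a pure-noise response yields no profile coefficient beyond the permutation null", {
  pp <- preprocessed_cohort(seed = 6)
  sam <- pp$cohort$samples
  pat <- sam$group != "CTRL"
  X <- pp$scaled[sam$sample_id[pat], ]
  set.seed(77)
  fake <- sample(seq(0, 10, 0.5), sum(pat), replace = TRUE)
  obs <- max(abs(y_related_profile(X, fake)$profile$weight))
  null_max <- vapply(1:30, function(i) {
    max(abs(y_related_profile(X, sample(fake))$profile$weight))
  }, 0)
  expect_lte(obs, quantile(null_max, 0.95) * 1.05)
})
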