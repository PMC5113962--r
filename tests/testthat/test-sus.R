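coords_df <- function(x, y) {
  data.frame(metabolite = sprintf("m%d", seq_along(x)),
             pcorr_remission = x, pcorr_relapse = y, region = "null",
             stringsAsFactors = FALSE)
}

test_that("region classification follows the threshold geometry", {
  co <- classify_regions(coords_df(
    x = c(0.0, 0.4, 0.35, -0.4, 0.05, 0.4, 0.02, -0.02),
    y = c(0.8, 0.7, 0.42, -0.5, 0.02, 0.05, 0.29, -0.8)))
  expect_identical(co$region,
                   c("relapse_specific", "shared_up_gradual", "shared_up",
                     "shared_down", "null", "remission_specific", "null",
                     "null"))
})

test_that("every point gets exactly one region and swapping axes swaps specifics", {
  set.seed(41)
  x <- runif(200, -1, 1); y <- runif(200, -1, 1)
  co <- classify_regions(coords_df(x, y))
  expect_true(all(co$region %in% c("shared_up_gradual", "shared_up",
                                   "shared_down", "relapse_specific",
                                   "remission_specific", "null")))
  swapped <- classify_regions(coords_df(y, x))
  expect_identical(swapped$region == "relapse_specific",
                   co$region == "remission_specific")
  expect_identical(swapped$region == "remission_specific",
                   co$region == "relapse_specific")
})

test_that("SUS coordinates place designed structure where the plot expects it", {
  # small bespoke cohort: one metabolite equally elevated in both statuses,
  # one relapse-only, one null
  cat3 <- data.frame(metabolite_id = c("shared", "relonly", "null1", "null2"),
                     name = c("shared", "relonly", "null1", "null2"),
                     chem_class = "misc", stringsAsFactors = FALSE)
  d <- synthetic_design(
    group_sizes = c(CTRL = 15, MS = 60, NMOSD = 2, ITM = 2),
    status_split = data.frame(group = c("MS", "NMOSD", "ITM"),
                              n_remission = c(30, 1, 1),
                              n_relapse = c(30, 1, 1)),
    n_pre_treatment = c(remission = 32, relapse = 32),
    catalogue = cat3,
    gradient = data.frame(metabolite = c("shared", "relonly"),
                          remission_mult = c(2.5, 1.0),
                          relapse_mult = c(2.5, 2.5)),
    noise_sigma = 0.3, base_abundance = numeric(0),
    loading_sigma = 0, missing_rate = 0, seed = 5)
  out <- generate_cohort(d)
  # no loading factor designed in, so the raw matrix is already comparable
  # across samples; normalizing a 4-metabolite table would mostly impose
  # compositional closure
  imp <- impute_missing(out$matrix)
  co <- sus_coordinates(imp, out$samples, disease = "MS")
  shared <- co[co$metabolite == "shared", ]
  relonly <- co[co$metabolite == "relonly", ]
  # equal elevation: on the diagonal; relapse-only: near the y-axis
  expect_lt(abs(shared$pcorr_remission - shared$pcorr_relapse), 0.15)
  expect_gt(shared$pcorr_remission, 0.5)
  expect_lt(abs(relonly$pcorr_remission), 0.2)
  expect_gt(relonly$pcorr_relapse, 0.5)
})

test_that("SUS uses pre-treatment samples only and errors without statuses", {
  pp <- preprocessed_cohort(seed = 1)
  sam <- pp$cohort$samples
  co <- sus_coordinates(pp$imputed, sam, "ALL")
  expect_equal(nrow(co), ncol(pp$imputed))
  sam2 <- sam
  sam2$pre_treatment <- NULL
  expect_warning(sus_coordinates(pp$imputed, sam2, "MS"), "pre_treatment")
  sam3 <- sam
  sam3$status[sam3$group == "ITM"] <- "REMISSION"
  expect_error(sus_coordinates(pp$imputed, sam3, "ITM"), "relapse")
  expect_error(sus_coordinates(pp$imputed, sam, "ALS"), "unknown disease")
})

test_that("K-means separates two designed profile groups and keeps duplicates together", {
  set.seed(42)
  n <- 30
  up <- matrix(rep(c(rep(0, 10), rep(1, 10), rep(2, 10)), 5), ncol = n,
               byrow = TRUE) + matrix(rnorm(5 * n, 0, 0.05), 5)
  down <- -up + 2
  prof <- exp(rbind(up, down))
  vals <- t(prof)
  dimnames(vals) <- list(sprintf("s%02d", 1:n), sprintf("met%02d", 1:10))
  m <- metabolite_matrix(vals)
  sam <- sample_annotation(data.frame(
    sample_id = rownames(vals),
    group = rep(c("CTRL", "MS", "MS"), each = 10),
    status = rep(c("NONE", "REMISSION", "RELAPSE"), each = 10)))
  km <- kmeans_confirm(m, sam, colnames(vals), k = 2, seed = 1)
  expect_equal(length(unique(km$cluster[1:5])), 1)
  expect_equal(length(unique(km$cluster[6:10])), 1)
  expect_false(km$cluster[1] == km$cluster[6])
  # the rising cluster is flagged monotone, the falling one is not
  expect_identical(sort(unname(km$monotone)), c(FALSE, TRUE))
  # duplicate metabolite rows always co-cluster
  vals2 <- cbind(vals, dup = vals[, 1])
  m2 <- metabolite_matrix(vals2)
  km2 <- kmeans_confirm(m2, sam, colnames(vals2), k = 2, seed = 1)
  expect_equal(unname(km2$cluster["met01"]), unname(km2$cluster["dup"]))
  expect_error(kmeans_confirm(m, sam, colnames(vals), k = 20), "exceeds")
})

test_that("multi-restart K-means never does worse than a single run", {
  set.seed(43)
  for (i in 1:10) {
    prof <- matrix(rnorm(12 * 20), 12)
    vals <- exp(t(prof))
    dimnames(vals) <- list(sprintf("s%02d", 1:20), sprintf("m%02d", 1:12))
    m <- metabolite_matrix(vals)
    sam <- sample_annotation(data.frame(
      sample_id = rownames(vals), group = rep(c("CTRL", "MS"), each = 10),
      status = rep(c("NONE", "RELAPSE"), each = 10)))
    multi <- kmeans_confirm(m, sam, colnames(vals), k = 3, seed = i, restarts = 20)
    single <- kmeans_confirm(m, sam, colnames(vals), k = 3, seed = i, restarts = 1)
    expect_lte(multi$tot_withinss, single$tot_withinss + 1e-9)
  }
})

test_that("the merged screen returns gradual-region members confirmed univariately", {
  pp <- preprocessed_cohort(seed = 1)
  hits <- merged_gradual_screen(pp$imputed, pp$cohort$samples)
  coords <- attr(hits, "coordinates")
  gradual <- coords$metabolite[coords$region == "shared_up_gradual"]
  expect_true(all(hits %in% gradual))
  expect_gt(length(hits), 0)
  # most designed gradient metabolites are recovered on a typical cohort
  expect_gte(length(intersect(hits, gradient_metabolites_reference())), 12)
})

test_that("hierarchical ordering matches a naive average-linkage oracle", {
  set.seed(44)
  vals <- exp(matrix(rnorm(8 * 6), 8, 6,
                     dimnames = list(sprintf("s%d", 1:8), sprintf("m%d", 1:6))))
  m <- metabolite_matrix(vals)
  ord <- hcluster_order(m)
  hc <- attr(ord, "hclust")
  # naive O(n^3) average linkage on 1 - spearman
  d0 <- 1 - cor(vals, method = "spearman")
  clusters <- as.list(colnames(vals))
  heights <- c()
  repeat {
    k <- length(clusters)
    if (k == 1) break
    best <- c(Inf, 0, 0)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- mean(d0[clusters[[i]], clusters[[j]]])
      if (dd < best[1]) best <- c(dd, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(sort(hc$height), sort(heights), tolerance = 1e-10)
})

test_that("perfect rank correlation merges first and constant rows go last", {
  vals <- cbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
                c = c(5, 3, 4, 1, 2), k = rep(2, 5))
  rownames(vals) <- sprintf("s%d", 1:5)
  m <- metabolite_matrix(vals)
  ord <- hcluster_order(m)
  expect_identical(attr(ord, "constant"), "k")
  expect_identical(ord[4], "k")
  hc <- attr(ord, "hclust")
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  # a and b (perfectly rank-correlated) merge first, at distance 0
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))
  # determinism
  expect_identical(as.character(ord), as.character(hcluster_order(m)))
})
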