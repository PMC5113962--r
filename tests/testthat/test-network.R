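rand_fp <- function(n, bits = 24, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) paste(rbinom(bits, 1, 0.4), collapse = ""), "")
}

fp_annotation <- function(fps, ids = sprintf("m%02d", seq_along(fps))) {
  metabolite_annotation(data.frame(
    metabolite_id = ids, name = ids, chem_class = "misc",
    fingerprint = fps, stringsAsFactors = FALSE))
}

test_that("tanimoto similarity obeys its closed form and edge cases", {
  expect_equal(tanimoto(c(1, 1, 0, 1), c(1, 1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)  # 2 shared of 4
  expect_true(is.na(tanimoto(c(0, 0), c(0, 0))))
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
  set.seed(2)
  a <- rbinom(16, 1, 0.5); b <- rbinom(16, 1, 0.5)
  expect_identical(tanimoto(a, b), tanimoto(b, a))
})

test_that("a cutoff of 1 with distinct fingerprints yields an edgeless network", {
  ann <- fp_annotation(c("1100", "0110", "0011"))
  net <- build_network(ann, cutoff = 1.0, rpairs = NULL)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 3)
})

test_that("the edge set equals a brute-force all-pairs computation", {
  ann <- fp_annotation(rand_fp(30, seed = 7))
  net <- build_network(ann, cutoff = 0.5, rpairs = NULL)
  fp <- fingerprint_matrix(ann)
  want <- data.frame()
  for (i in 1:29) for (j in (i + 1):30) {
    s <- tanimoto(fp[i, ], fp[j, ])
    if (!is.na(s) && s >= 0.5)
      want <- rbind(want, data.frame(source = rownames(fp)[i],
                                     target = rownames(fp)[j], weight = s))
  }
  expect_equal(nrow(net$edges), nrow(want))
  got <- net$edges[order(net$edges$source, net$edges$target), ]
  want <- want[order(want$source, want$target), ]
  expect_identical(got$source, want$source)
  expect_identical(got$target, want$target)
  expect_equal(got$weight, want$weight, tolerance = 1e-12)
  expect_true(all(got$source != got$target))
  expect_false(any(duplicated(got[, c("source", "target")])))
})

test_that("the edge set is monotone decreasing in the cutoff", {
  ann <- fp_annotation(rand_fp(20, seed = 8))
  e1 <- build_network(ann, cutoff = 0.4, rpairs = NULL)$edges
  e2 <- build_network(ann, cutoff = 0.7, rpairs = NULL)$edges
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(e2) %in% key(e1)))
  expect_lte(nrow(e2), nrow(e1))
})

test_that("reaction pairs overlay as rpair or both, unknown partners are skipped", {
  ann <- fp_annotation(c("1110", "1110", "0001"), c("a", "b", "c"))
  rp <- data.frame(a = c("a", "a", "x"), b = c("b", "c", "c"))
  expect_warning(net <- build_network(ann, cutoff = 0.7, rpairs = rp), "skip")
  typed <- setNames(net$edges$type, paste(net$edges$source, net$edges$target))
  expect_identical(unname(typed["a b"]), "both")   # similarity 1 + rpair
  expect_identical(unname(typed["a c"]), "rpair")  # below cutoff, rpair only
})

test_that("class-structured fingerprints connect within classes more than between", {
  cohort <- generate_cohort(reference_design(seed = 3))
  net <- build_network(cohort$metabolites, cutoff = 0.7, rpairs = NULL)
  cls <- setNames(cohort$metabolites$chem_class, cohort$metabolites$metabolite_id)
  same <- cls[net$edges$source] == cls[net$edges$target]
  n_per_class <- table(cls)
  within_possible <- sum(n_per_class * (n_per_class - 1) / 2)
  total_possible <- length(cls) * (length(cls) - 1) / 2
  dens_within <- sum(same) / within_possible
  dens_between <- sum(!same) / (total_possible - within_possible)
  expect_gt(dens_within, dens_between)
  expect_gt(dens_within, 0.5)
})

test_that("node annotation colours significant directions and sizes by log2 fc", {
  ann <- fp_annotation(c("1100", "0110", "0011", "1001"),
                       c("up1", "down1", "flat", "ns1"))
  net <- build_network(ann, cutoff = 2, rpairs = NULL)  # no edges needed
  contrast <- data.frame(metabolite = c("up1", "down1", "flat", "ns1"),
                         p_value = c(0.001, 0.02, 0.001, 0.5),
                         fold_change = c(1.72, 0.4, 1.0, 3.0),
                         direction = c("up", "down", "down", "up"),
                         significant = c(TRUE, TRUE, TRUE, FALSE),
                         testable = TRUE)
  out <- annotate_nodes(net, contrast)
  n <- out$nodes
  expect_identical(n$direction[n$metabolite_id == "up1"], "up")
  expect_equal(n$size[n$metabolite_id == "up1"], log2(1.72))
  expect_identical(n$direction[n$metabolite_id == "down1"], "down")
  # p = 0.5 is ns regardless of fold change; fc exactly 1 is ns too
  expect_identical(n$direction[n$metabolite_id == "ns1"], "ns")
  expect_identical(n$direction[n$metabolite_id == "flat"], "ns")
})

test_that("SIF export round-trips the edge set deterministically", {
  dir <- withr::local_tempdir()
  ann <- fp_annotation(rand_fp(12, seed = 9))
  net <- build_network(ann, cutoff = 0.45, rpairs = NULL)
  paths <- export_sif(net, file.path(dir, "net.sif"))
  back <- read_sif(paths[["sif"]])
  expect_equal(nrow(back), nrow(net$edges))
  expect_setequal(paste(back$source, back$target),
                  paste(net$edges$source, net$edges$target))
  expect_identical(readLines(paths[["sif"]]),
                   readLines(export_sif(net, file.path(dir, "net2.sif"))[["sif"]]))
  attrs <- read.delim(paths[["nodes"]])
  expect_equal(nrow(attrs), 12)
  # empty network: empty sif, header-only attributes
  empty <- build_network(fp_annotation(c("10", "01")), cutoff = 1, rpairs = NULL)
  p2 <- export_sif(empty, file.path(dir, "empty.sif"))
  expect_length(readLines(p2[["sif"]]), 0)
  expect_equal(nrow(read.delim(p2[["nodes"]])), 2)
  expect_equal(nrow(read_sif(p2[["sif"]])), 0)
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # closed-form cases
  u <- sprintf("m%02d", 1:10)
  expect_equal(hypergeom_enrich(u[c(1, 2, 5)], u[1:4], u), 1 / 3)  # k=2: 40/120
  expect_equal(hypergeom_enrich(character(0), u[1:4], u), 1)
  expect_equal(hypergeom_enrich(u[1:3], u, u), 1)  # pathway = universe
  expect_error(hypergeom_enrich(u[1:3], c(u[1], "zz"), u), "outside")
  # enumeration oracle over all universes up to N = 12
  set.seed(51)
  for (N in 2:12) {
    uni <- sprintf("x%02d", 1:N)
    for (rep in 1:3) {
      K <- sample(1:N, 1); n <- sample(1:N, 1)
      pw <- sample(uni, K); hits <- sample(uni, n)
      k_obs <- length(intersect(hits, pw))
      draws <- combn(N, n)
      inpw <- matrix(uni[draws] %in% pw, nrow = n)
      p_enum <- mean(colSums(inpw) >= k_obs)
      expect_equal(hypergeom_enrich(hits, pw, uni), p_enum, tolerance = 1e-12)
    }
  }
})

test_that("relative betweenness matches path counting on canonical graphs", {
  path3 <- data.frame(source = c("A", "B"), target = c("B", "C"))
  b <- betweenness_centrality(path3, c("A", "B", "C"))
  expect_equal(unname(b[c("A", "B", "C")]), c(0, 1, 0))
  star <- data.frame(source = "hub", target = c("a", "b", "c", "d"))
  bs <- betweenness_centrality(star, c("hub", "a", "b", "c", "d"))
  expect_equal(unname(bs["hub"]), 1)
  expect_true(all(bs[c("a", "b", "c", "d")] == 0))
  # fewer than three nodes: all zeros
  expect_equal(unname(betweenness_centrality(path3[1, ], c("A", "B"))), c(0, 0))
})

test_that("betweenness equals an exhaustive shortest-path oracle on small graphs", {
  brute_betweenness <- function(edges, nodes) {
    n <- length(nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
    for (r in seq_len(nrow(edges))) {
      adj[edges$source[r], edges$target[r]] <- TRUE
      adj[edges$target[r], edges$source[r]] <- TRUE
    }
    # enumerate all simple paths between every pair, keep the shortest
    paths_between <- function(a, b) {
      found <- list(); best <- Inf
      walk <- function(cur, visited) {
        if (length(visited) - 1 > best) return()
        if (cur == b) {
          if (length(visited) - 1 < best) { best <<- length(visited) - 1; found <<- list() }
          if (length(visited) - 1 == best) found[[length(found) + 1]] <<- visited
          return()
        }
        for (nx in nodes[adj[cur, ]])
          if (!nx %in% visited) walk(nx, c(visited, nx))
      }
      walk(a, a)
      found
    }
    score <- setNames(rep(0, n), nodes)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sp <- paths_between(nodes[i], nodes[j])
      if (!length(sp)) next
      for (pth in sp) {
        inner <- setdiff(pth, c(nodes[i], nodes[j]))
        for (v in inner) score[v] <- score[v] + 1 / length(sp)
      }
    }
    score / ((n - 1) * (n - 2) / 2)
  }
  set.seed(52)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    nodes <- sprintf("n%d", 1:n)
    pairs <- t(combn(nodes, 2))
    take <- runif(nrow(pairs)) < 0.45
    if (!any(take)) take[1] <- TRUE
    edges <- data.frame(source = pairs[take, 1], target = pairs[take, 2])
    expect_equal(betweenness_centrality(edges, nodes)[nodes],
                 brute_betweenness(edges, nodes)[nodes], tolerance = 1e-10)
  }
})

test_that("pathway impact covers its boundary cases and is monotone in hits", {
  path3 <- data.frame(source = c("A", "B"), target = c("B", "C"))
  nodes <- c("A", "B", "C")
  expect_equal(pathway_impact(character(0), path3, nodes), 0)
  expect_equal(pathway_impact(nodes, path3, nodes), 1)
  expect_equal(pathway_impact("B", path3, nodes), 1)  # B carries all centrality
  expect_error(pathway_impact("Z", path3, nodes), "outside")
  set.seed(53)
  nodes6 <- sprintf("n%d", 1:6)
  pairs <- t(combn(nodes6, 2))
  take <- runif(nrow(pairs)) < 0.5
  edges <- data.frame(source = pairs[take, 1], target = pairs[take, 2])
  # monotone under set inclusion
  small <- sample(nodes6, 2); big <- union(small, sample(nodes6, 2))
  expect_lte(pathway_impact(small, edges, nodes6),
             pathway_impact(big, edges, nodes6) + 1e-12)
})

test_that("pathway_enrich reports consistent counts on the synthetic catalogue", {
  cohort <- generate_cohort(reference_design(seed = 2))
  hits <- gradient_metabolites_reference()
  enr <- pathway_enrich(hits, cohort$metabolites)
  expect_true(all(enr$n_hits_pathway <= enr$n_pathway))
  expect_true(all(enr$p_hyper > 0 & enr$p_hyper <= 1))
  expect_true(all(enr$impact >= 0 & enr$impact <= 1))
  # the fatty-acid pathway is the strongest enrichment for the gradient set
  expect_identical(enr$pathway[1], "fatty acid metabolism")
  expect_lt(enr$p_hyper[1], 1e-6)
})
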