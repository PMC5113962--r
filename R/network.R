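# Chemical-similarity metabolic network with reaction-pair overlay, SIF
# export, hypergeometric pathway over-representation and betweenness-based
# pathway impact.

#' Tanimoto similarity of two binary fingerprints
#'
#' |intersection| / |union| over set bits. Undefined (returns `NA`) when
#' neither fingerprint has a set bit.
#'
#' @param fp_a,fp_b equal-length binary (0/1) vectors.
#' @return similarity in \[0, 1\], or `NA` for two empty fingerprints.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprints differ in length")
  a <- fp_a != 0; b <- fp_b != 0
  union <- sum(a | b)
  if (union == 0) return(NA_real_)
  sum(a & b) / union
}

#' Build the metabolic network
#'
#' Nodes are the annotated metabolites; edges connect pairs whose Tanimoto
#' fingerprint similarity reaches `cutoff`, overlaid with reaction-pair
#' (substrate-product) edges added regardless of similarity. A pair
#' satisfying both criteria carries type `both`. Reaction pairs referencing
#' unknown metabolites are skipped with a warning.
#'
#' @param metabolites a `metabolite_annotation`.
#' @param cutoff Tanimoto connectivity cutoff (default 0.7).
#' @param rpairs data.frame `a`, `b` of reaction pairs; defaults to the
#'   pairs encoded in the annotation's `rpairs` column.
#' @return object of class `metab_network`: `nodes` (data.frame
#'   `metabolite_id`, `fold_change`, `direction`, `significant`), `edges`
#'   (data.frame `source`, `target`, `type`, `weight`), `cutoff`.
#' @export
build_network <- function(metabolites, cutoff = 0.7, rpairs = rpair_table(metabolites)) {
  ids <- metabolites$metabolite_id
  fp <- fingerprint_matrix(metabolites)
  edges <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(fp) >= 2) {
    # all-pairs |A.B| / |A|+|B|-|A.B| on the 0/1 matrix
    inter <- tcrossprod(fp)
    sz <- rowSums(fp)
    uni <- outer(sz, sz, "+") - inter
    sim <- ifelse(uni > 0, inter / uni, NA)
    idx <- which(upper.tri(sim) & !is.na(sim) & sim >= cutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      pa <- rownames(fp)[idx[, 1]]; pb <- rownames(fp)[idx[, 2]]
      swap <- pa > pb
      edges <- data.frame(source = ifelse(swap, pb, pa),
                          target = ifelse(swap, pa, pb),
                          weight = sim[idx], stringsAsFactors = FALSE)
    }
  }
  edges$type <- if (nrow(edges)) "tanimoto" else character(0)
  if (!is.null(rpairs) && nrow(rpairs)) {
    known <- rpairs$a %in% ids & rpairs$b %in% ids
    if (any(!known)) {
      warning(sum(!known), " reaction pair(s) reference unknown metabolites; skipped")
      rpairs <- rpairs[known, , drop = FALSE]
    }
    for (i in seq_len(nrow(rpairs))) {
      a <- min(rpairs$a[i], rpairs$b[i]); b <- max(rpairs$a[i], rpairs$b[i])
      if (a == b) next
      hit <- which(edges$source == a & edges$target == b)
      if (length(hit)) edges$type[hit] <- "both"
      else edges <- rbind(edges, data.frame(source = a, target = b,
                                            weight = NA_real_, type = "rpair",
                                            stringsAsFactors = FALSE))
    }
  }
  edges <- edges[order(edges$source, edges$target), c("source", "target", "type", "weight")]
  rownames(edges) <- NULL
  nodes <- data.frame(metabolite_id = ids, fold_change = NA_real_,
                      direction = "ns", significant = FALSE,
                      stringsAsFactors = FALSE)
  out <- list(nodes = nodes, edges = edges, cutoff = cutoff)
  class(out) <- "metab_network"
  out
}

#' @export
print.metab_network <- function(x, ...) {
  cat(sprintf("metab_network: %d nodes, %d edges (%d tanimoto, %d rpair, %d both)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$type == "tanimoto"),
              sum(x$edges$type == "rpair"), sum(x$edges$type == "both")))
  invisible(x)
}

#' Annotate network nodes with contrast statistics
#'
#' Significant nodes receive their direction (`up`/`down`) and a size
#' attribute |log2 fold change|; non-significant nodes are marked `ns` but
#' retained in the data model (display filtering is the consumer's choice).
#'
#' @param net a `metab_network`.
#' @param contrast a `contrast_result` covering the network metabolites.
#' @param alpha significance level.
#' @return the network with annotated nodes (plus a `size` column).
#' @export
annotate_nodes <- function(net, contrast, alpha = 0.05) {
  i <- match(net$nodes$metabolite_id, contrast$metabolite)
  fc <- contrast$fold_change[i]
  p <- contrast$p_value[i]
  sig <- !is.na(p) & p < alpha & !is.na(fc) & fc != 1
  net$nodes$fold_change <- fc
  net$nodes$significant <- sig
  net$nodes$direction <- ifelse(sig, ifelse(fc > 1, "up", "down"), "ns")
  net$nodes$size <- ifelse(sig, abs(log2(fc)), 0)
  net
}

#' Export a network as SIF plus node attributes
#'
#' Writes one line per edge (`source <type> target`, tab-separated) in
#' deterministic lexicographic order, and a sidecar node-attribute TSV
#' (`node`, `fold_change`, `direction`, `significant`).
#'
#' @param net a `metab_network`.
#' @param path output SIF path; the attribute table goes to
#'   `<path base>.nodes.tsv`.
#' @return invisibly, the two paths.
#' @export
export_sif <- function(net, path) {
  edges <- net$edges[order(net$edges$source, net$edges$type, net$edges$target), ]
  lines <- sprintf("%s\t%s\t%s", edges$source, edges$type, edges$target)
  writeLines(lines, path)
  attr_path <- paste0(sub("\\.sif$", "", path), ".nodes.tsv")
  nodes <- net$nodes[order(net$nodes$metabolite_id),
                     intersect(c("metabolite_id", "fold_change", "direction",
                                 "significant"), names(net$nodes))]
  names(nodes)[1] <- "node"
  utils::write.table(nodes, attr_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(sif = path, nodes = attr_path))
}

#' Read a SIF file back into an edge table
#'
#' @param path SIF path.
#' @return data.frame `source`, `type`, `target`.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(source = character(0), type = character(0),
                      target = character(0)))
  parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(source = parts[, 1], type = parts[, 2], target = parts[, 3],
             stringsAsFactors = FALSE)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability P(X >= k) of drawing at least the observed number
#' of pathway members in `|hits|` draws from the universe.
#'
#' @param hits significant metabolite set.
#' @param pathway pathway member set (subset of the universe).
#' @param universe all analyzed metabolites.
#' @return p-value in (0, 1\].
#' @export
hypergeom_enrich <- function(hits, pathway, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(pathway, universe)))
    stop("pathway members outside the universe")
  if (length(setdiff(hits, universe)))
    stop("hits outside the universe")
  N <- length(unique(universe))
  K <- length(unique(pathway))
  n <- length(unique(hits))
  k <- length(intersect(unique(hits), unique(pathway)))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

edges_to_igraph <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(edges[, c("source", "target"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g
}

#' Relative betweenness centrality
#'
#' Fraction of shortest paths between node pairs passing through each node,
#' normalized by (n-1)(n-2)/2 (undirected). Graphs with fewer than three
#' nodes get all zeros.
#'
#' @param edges data.frame `source`, `target` (undirected).
#' @param nodes node names (isolated nodes allowed).
#' @return named numeric vector in \[0, 1\].
#' @export
betweenness_centrality <- function(edges, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) < 3)
    return(stats::setNames(rep(0, length(nodes)), nodes))
  g <- edges_to_igraph(edges, nodes)
  b <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  b[nodes]
}

#' Pathway impact from hit centralities
#'
#' Sum of the relative betweenness centralities of the hit metabolites over
#' the centrality total of all pathway metabolites; 0 when the pathway
#' carries no centrality.
#'
#' @param hits hit metabolite ids (subset of the pathway nodes).
#' @param pathway_edges data.frame `source`, `target` of the pathway graph.
#' @param pathway_nodes all pathway metabolite ids.
#' @return impact in \[0, 1\].
#' @export
pathway_impact <- function(hits, pathway_edges, pathway_nodes) {
  if (length(setdiff(hits, pathway_nodes)))
    stop("hits outside the pathway")
  b <- betweenness_centrality(pathway_edges, pathway_nodes)
  tot <- sum(b)
  if (tot == 0) return(0)
  sum(b[unique(hits)]) / tot
}

#' Pathway over-representation and impact analysis
#'
#' For every pathway in the annotation: hypergeometric enrichment of the
#' hit set and betweenness-based impact on the pathway graph (reaction-pair
#' edges restricted to pathway members).
#'
#' @param hits significant metabolite ids.
#' @param metabolites a `metabolite_annotation` (defines pathways, the
#'   universe and the reaction pairs).
#' @param p_adjust multiple-testing method (default `"none"`, mirroring the
#'   reference analysis; `"BH"` available).
#' @return data.frame of class `pathway_enrichment`: `pathway`,
#'   `n_pathway`, `n_hits_pathway`, `p_hyper`, `impact`.
#' @export
pathway_enrich <- function(hits, metabolites, p_adjust = "none") {
  universe <- metabolites$metabolite_id
  hits <- intersect(hits, universe)
  sets <- pathway_sets(metabolites)
  rp <- rpair_table(metabolites)
  rows <- lapply(names(sets), function(pw) {
    members <- sets[[pw]]
    inpw <- rp[rp$a %in% members & rp$b %in% members, , drop = FALSE]
    names(inpw) <- c("source", "target")
    hit_in <- intersect(hits, members)
    data.frame(pathway = pw,
               n_pathway = length(members),
               n_hits_pathway = length(hit_in),
               p_hyper = hypergeom_enrich(hits, members, universe),
               impact = pathway_impact(hit_in, inpw, members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_hyper <- stats::p.adjust(out$p_hyper, method = p_adjust)
  out <- out[order(out$p_hyper, out$pathway), ]
  rownames(out) <- NULL
  attr(out, "n_universe") <- length(universe)
  attr(out, "n_hits_universe") <- length(hits)
  class(out) <- c("pathway_enrichment", "data.frame")
  out
}
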