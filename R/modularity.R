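#' Average clustering coefficient
#'
#' Node-averaged ratio of triangles impingent on a node to the connected
#' triples through it, on a simplified (undirected, unweighted, no parallel
#' edges or self-loops) view of the graph. Nodes of degree below 2
#' contribute 0. Not meaningful for strictly bipartite graphs.
#'
#' @param graph an `igraph` graph; directions, weights and multi-edges are
#'   dropped internally.
#' @return the global average in `[0, 1]`.
#' @export
clustering_coefficient <- function(graph) {
  if (igraph::gorder(graph) == 0L) stop("empty graph")
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

membership_vector <- function(graph, part) {
  if (inherits(part, "communities")) part <- igraph::membership(part)
  m <- as.integer(part)
  if (length(m) != igraph::gorder(graph))
    stop("partition must assign every node")
  as.integer(factor(m))                         # contiguous ids from 1
}

edge_weights <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) rep(1, igraph::ecount(graph)) else w
}

#' Newman-Girvan modularity of a partition
#'
#' Weighted modularity `Q = 1/(2m) sum_ij (A_ij - k_i k_j / (2m)) d(c_i, c_j)`
#' with `m` the total edge weight, `k` the weighted degrees and `d` the
#' same-community indicator. Positive values indicate assortative mixing
#' across the modules of the partition, negative disassortative.
#'
#' @param graph undirected weighted `igraph` graph with at least one edge.
#' @param part membership vector (or `communities` object) over the nodes.
#' @return Q in `[-1, 1]`.
#' @export
ng_modularity <- function(graph, part) {
  g <- igraph::as_undirected(graph, mode = "each")
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  memb <- membership_vector(g, part)
  w <- edge_weights(g)
  m <- sum(w)
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::strength(g, weights = w)
  within <- memb[el[, 1L]] == memb[el[, 2L]]
  kc <- tapply(k, memb, sum)
  e_c <- stats::setNames(numeric(length(kc)), names(kc))
  if (any(within)) {
    e_in <- tapply(w[within], memb[el[within, 1L]], sum)
    e_c[names(e_in)] <- e_in
  }
  sum(2 * e_c / (2 * m) - (kc / (2 * m))^2)
}

#' VOS-style community detection by seeded local moving
#'
#' Resolution-parameterized quality maximization through iterative local
#' moving and agglomeration (multi-level Louvain), the same family of
#' procedures as Pajek's visualization-of-similarity clustering, with link
#' weights read as similarities. Deterministic for a fixed seed.
#'
#' @param graph `igraph` graph (made undirected internally; weights used as
#'   similarities).
#' @param resolution resolution parameter of the quality function
#'   (default 1).
#' @param seed RNG seed making the local moving deterministic.
#' @return integer membership vector, community ids contiguous from 1.
#' @export
vos_cluster <- function(graph, resolution = 1, seed = 1L) {
  g <- igraph::as_undirected(graph, mode = "collapse",
                             edge.attr.comb = list(weight = "sum", "ignore"))
  if (igraph::ecount(g) == 0L)
    return(stats::setNames(seq_len(igraph::gorder(g)),
                           igraph::V(g)$name))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- as.integer(factor(igraph::membership(cl)))
  stats::setNames(memb, igraph::V(g)$name)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' VOS quality index of a layout partition
#'
#' Implements the published formula literally:
#' `VQ = sum_{i<j} (e_ij - a_i^2)` over ordered community pairs, where
#' `e_ij` is the fraction of adjacency-matrix weight between communities i
#' and j (both orientations, i.e. `w_between / m`) and `a_i = k_i / (2m)`
#' is community i's fraction of weighted degree. Note this differs from
#' standard modularity and is not confined to `[0, 1]` (two disjoint
#' triangles under the component partition give -1/4); [ng_modularity()] is
#' reported alongside for comparison.
#'
#' @inheritParams ng_modularity
#' @return the literal VQ value; 0 for a single community (empty sum).
#' @export
vq_index <- function(graph, part) {
  g <- igraph::as_undirected(graph, mode = "each")
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  memb <- membership_vector(g, part)
  nc <- max(memb)
  if (nc < 2L) return(0)
  w <- edge_weights(g)
  m <- sum(w)
  el <- igraph::as_edgelist(g, names = FALSE)
  k <- igraph::strength(g, weights = w)
  a <- as.numeric(tapply(k, factor(memb, levels = 1:nc), sum,
                         default = 0)) / (2 * m)
  between <- matrix(0, nc, nc)
  for (r in seq_len(nrow(el))) {
    ci <- memb[el[r, 1L]]; cj <- memb[el[r, 2L]]
    if (ci != cj) {
      between[ci, cj] <- between[ci, cj] + w[r]
      between[cj, ci] <- between[cj, ci] + w[r]
    }
  }
  vq <- 0
  for (i in 1:(nc - 1L)) for (j in (i + 1L):nc)
    vq <- vq + between[i, j] / m - a[i]^2
  vq
}

#' Fast-greedy community detection
#'
#' Agglomerative hierarchical modularity maximization; returns the best-Q
#' cut of the merge dendrogram. If the best achievable Q is not positive the
#' graph is treated as a single community (Q = 0).
#'
#' @param graph `igraph` graph with at least one edge; collapsed to a simple
#'   undirected weighted graph internally.
#' @return list with `membership` (named integer) and `q`.
#' @export
fgc <- function(graph) {
  g <- igraph::as_undirected(graph, mode = "collapse",
                             edge.attr.comb = list(weight = "sum", "ignore"))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "sum", "ignore"))
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  cl <- igraph::cluster_fast_greedy(g)
  memb <- as.integer(igraph::membership(cl))
  q <- ng_modularity(g, memb)
  if (q <= 0) {
    memb <- rep(1L, igraph::gorder(g))
    q <- 0
  }
  list(membership = stats::setNames(as.integer(factor(memb)),
                                    igraph::V(g)$name),
       q = q)
}

#' Equal-width age-bin partition
#'
#' Ten equal-width bins over nd in `[0, 1]` (right-closed last bin), the
#' age color-coding used throughout the network renderings; serves as the
#' age-defined input partition of the Newman-Girvan index.
#'
#' @param nd numeric ages in `[0, 1]`.
#' @param n_bins number of bins (default 10).
#' @return integer bin ids in `1..n_bins`.
#' @export
age_partition <- function(nd, n_bins = 10L) {
  if (any(nd < 0 | nd > 1, na.rm = TRUE)) stop("ages must lie in [0, 1]")
  pmin(floor(nd * n_bins) + 1L, n_bins)
}

#' Modularity heatmap bundle
#'
#' Builds the modularity matrix `B_ij = A_ij - k_i k_j / (2m)` (whose rows
#' sum to zero), scales it by a sign-preserving log10 transform of the
#' network-wide modularity index at the event,
#' `s = sign(Q) * log10(1 + |Q| * scale)`, computes squared Euclidean
#' distances between the scaled rows, and clusters them with Ward's minimum
#' variance linkage. When ages are supplied, leaves are age-sorted within
#' clusters.
#'
#' @param graph undirected weighted `igraph` graph with at least one edge.
#' @param global_q the network modularity index at the event (any of the six
#'   indices; the published heatmaps use the age-partition Newman-Girvan).
#' @param ages optional named nd vector for leaf ordering.
#' @param scale multiplier inside the log transform (default 10, chosen so
#'   the toy two-clique case stays order-preserving).
#' @return list with `matrix` (scaled B), `raw` (B), `distances` (squared
#'   Euclidean matrix), `dendrogram` (`hclust`), `order` (leaf order).
#' @export
heatmap_bundle <- function(graph, global_q, ages = NULL, scale = 10) {
  g <- igraph::as_undirected(graph, mode = "each")
  if (igraph::ecount(g) == 0L) stop("graph has no edges")
  w <- edge_weights(g)
  attr_name <- if (!is.null(igraph::E(g)$weight)) "weight" else NULL
  A <- as.matrix(igraph::as_adjacency_matrix(g, attr = attr_name, sparse = TRUE))
  k <- rowSums(A)
  m <- sum(w)
  B <- A - outer(k, k) / (2 * m)
  s <- sign(global_q) * log10(1 + abs(global_q) * scale)
  M <- B * s
  d2 <- as.matrix(stats::dist(M))^2
  hc <- stats::hclust(stats::as.dist(d2), method = "ward.D")
  ord <- hc$order
  if (!is.null(ages)) {
    dd <- stats::reorder(stats::as.dendrogram(hc),
                         as.numeric(ages[rownames(A)]), agglo.FUN = mean)
    ord <- stats::order.dendrogram(dd)
  }
  list(matrix = M, raw = B, distances = d2, dendrogram = hc, order = ord)
}

#' Six modularity indices per time event
#'
#' For each requested event of an evolving network, computes on the
#' cumulative undirected weighted snapshot: the literal VOS quality index
#' (VQ) at the VOS partition, the clustering ratio (communities per
#' connected node), the average clustering coefficient C (on the simplified
#' graph), the fast-greedy community index FGC, and the Newman-Girvan index
#' under the age partition (NG_age) and the VOS partition (NG_vos). Events
#' whose snapshot has no edges are recorded as `NA` gaps.
#'
#' @param net an `evolving_network`.
#' @param events event ordinals (default all).
#' @param resolution,seed passed to [vos_cluster()].
#' @return data frame with one row per event: `event`, `nd`, `vq`,
#'   `c_ratio`, `c_avg`, `fgc_q`, `ng_age`, `ng_vos`, `n_communities`.
#' @export
modularity_report <- function(net, events = seq_len(net$timeline$n_events),
                              resolution = 1, seed = 1L) {
  stopifnot(inherits(net, "evolving_network"))
  rows <- vector("list", length(events))
  for (k in seq_along(events)) {
    e <- events[k]
    g <- snapshot_undirected(net, e)
    gap <- data.frame(event = e, nd = net$timeline$events[e], vq = NA_real_,
                      c_ratio = NA_real_, c_avg = NA_real_, fgc_q = NA_real_,
                      ng_age = NA_real_, ng_vos = NA_real_,
                      n_communities = NA_integer_)
    if (igraph::ecount(g) == 0L) { rows[[k]] <- gap; next }
    memb <- vos_cluster(g, resolution = resolution, seed = seed)
    deg <- igraph::degree(g)
    connected <- deg > 0
    nc <- length(unique(memb[connected]))
    rows[[k]] <- data.frame(
      event = e, nd = net$timeline$events[e],
      vq = vq_index(g, memb),
      c_ratio = nc / sum(connected),
      c_avg = clustering_coefficient(g),
      fgc_q = fgc(g)$q,
      ng_age = ng_modularity(g, age_partition(igraph::V(g)$nd)),
      ng_vos = ng_modularity(g, memb),
      n_communities = nc)
  }
  out <- do.call(rbind, rows)
  attr(out, "criterion") <- net$criterion
  out
}

#' Export a heatmap bundle as plain text
#'
#' Writes the squared-Euclidean distance matrix as TSV and the Ward merge
#' tree as Newick.
#'
#' @param bundle from [heatmap_bundle()].
#' @param dist_path,newick_path output paths (either may be `NULL`).
#' @export
write_heatmap_bundle <- function(bundle, dist_path = NULL, newick_path = NULL) {
  if (!is.null(dist_path))
    utils::write.table(bundle$distances, dist_path, sep = "\t", quote = FALSE)
  if (!is.null(newick_path))
    ape::write.tree(ape::as.phylo(bundle$dendrogram), file = newick_path)
  invisible(NULL)
}
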