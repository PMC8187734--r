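two_triangles <- function() {
  igraph::make_graph(c(1, 2, 2, 3, 3, 1, 4, 5, 5, 6, 6, 4), directed = FALSE)
}

test_that("clustering coefficient is the node-averaged triangle ratio", {
  expect_equal(clustering_coefficient(
    igraph::make_full_graph(3)), 1)
  path <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  expect_equal(clustering_coefficient(path), 0)
  k4e <- igraph::make_graph(c(1, 2, 1, 3, 1, 4, 2, 3, 2, 4), directed = FALSE)
  expect_equal(clustering_coefficient(k4e), 5 / 6)
  expect_error(clustering_coefficient(igraph::make_empty_graph(0)), "empty")
})

test_that("ng_modularity evaluates the printed formula", {
  g <- two_triangles()
  expect_equal(ng_modularity(g, c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_equal(ng_modularity(g, rep(1, 6)), 0)
  k3 <- igraph::make_full_graph(3)
  expect_equal(ng_modularity(k3, 1:3), -1 / 3)
  expect_error(ng_modularity(igraph::make_empty_graph(3), rep(1, 3)),
               "no edges")
})

test_that("ng_modularity agrees with the double-loop oracle and igraph", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(5:30, 1)
    g <- igraph::sample_gnp(n, 0.25)
    if (igraph::ecount(g) == 0) next
    igraph::E(g)$weight <- sample(1:4, igraph::ecount(g), replace = TRUE)
    memb <- sample(1:3, n, replace = TRUE)
    q <- ng_modularity(g, memb)
    expect_equal(q, oracle_ng(g, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("vq_index implements the published formula literally", {
  g <- two_triangles()
  expect_equal(vq_index(g, c(1, 1, 1, 2, 2, 2)), -1 / 4)
  expect_equal(vq_index(g, rep(1, 6)), 0)   # empty sum
  gb <- igraph::add_edges(g, c(3, 4))       # bridge, m = 7
  expect_equal(vq_index(gb, c(1, 1, 1, 2, 2, 2)), 1 / 7 - 1 / 4)
})

test_that("vos_cluster finds planted module structure deterministically", {
  g <- two_triangles()
  memb <- vos_cluster(g, seed = 4)
  expect_equal(length(unique(memb)), 2L)
  expect_equal(length(unique(memb[1:3])), 1L)
  expect_equal(length(unique(memb[4:6])), 1L)

  # ring of 4 cliques joined by single bridges
  ring <- igraph::make_full_graph(4)
  for (i in 1:3) ring <- igraph::disjoint_union(ring, igraph::make_full_graph(4))
  ring <- igraph::add_edges(ring, c(4, 5, 8, 9, 12, 13, 16, 1))
  m1 <- vos_cluster(ring, resolution = 1, seed = 1)
  expect_equal(length(unique(m1)), 4L)
  expect_equal(m1, vos_cluster(ring, resolution = 1, seed = 99))
})

test_that("fast-greedy returns the best modularity cut", {
  r <- fgc(two_triangles())
  expect_equal(r$q, 0.5)
  expect_equal(length(unique(r$membership)), 2L)

  # star: no positive cut exists, collapses to one community
  star <- igraph::make_star(6, mode = "undirected")
  rs <- fgc(star)
  expect_equal(rs$q, 0)
  expect_equal(length(unique(rs$membership)), 1L)
  expect_error(fgc(igraph::make_empty_graph(4)), "no edges")

  # never exceeds the exhaustive maximum on small graphs
  set.seed(33)
  for (i in 1:4) {
    g <- igraph::sample_gnp(7, 0.45)
    if (igraph::ecount(g) == 0) next
    parts <- expand.grid(rep(list(1:3), 7))
    qmax <- max(apply(parts, 1, function(p) ng_modularity(g, p)))
    expect_lte(fgc(g)$q, qmax + 1e-12)
  }
})

test_that("age partition bins nd into 10 equal widths", {
  expect_equal(age_partition(0), 1L)
  expect_equal(age_partition(1), 10L)
  expect_equal(age_partition(0.65), 7L)
  expect_equal(age_partition(c(0.099, 0.1)), c(1L, 2L))
  expect_error(age_partition(1.5), "\\[0, 1\\]")
})

test_that("heatmap bundle: zero row sums, Ward tree separates modules", {
  g <- two_triangles()
  igraph::V(g)$name <- letters[1:6]
  hb <- heatmap_bundle(g, global_q = 0.5)
  expect_true(all(abs(rowSums(hb$raw)) < 1e-12))
  expect_true(isSymmetric(hb$matrix))
  expect_true(all(diag(hb$distances) == 0))
  expect_true(all(diff(hb$dendrogram$height) >= -1e-12))
  top <- stats::cutree(hb$dendrogram, k = 2)
  expect_equal(length(unique(top[1:3])), 1L)
  expect_equal(length(unique(top[4:6])), 1L)
  # sign-preserving scaling keeps order
  expect_equal(sign(hb$matrix), sign(hb$raw))
  expect_error(heatmap_bundle(igraph::make_empty_graph(3), 0.5), "no edges")

  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".nwk")
  write_heatmap_bundle(hb, p1, p2)
  expect_equal(dim(as.matrix(read.delim(p1))), c(6L, 6L))
  expect_equal(sort(ape::read.tree(p2)$tip.label), letters[1:6])
})

test_that("modularity_report walks events with all six indices", {
  net <- toy_networks()$PX
  rep_df <- modularity_report(net)
  expect_equal(nrow(rep_df), net$timeline$n_events)
  expect_true(is.na(rep_df$ng_vos[1]))    # no edges at the first event
  last <- rep_df[nrow(rep_df), ]
  expect_false(is.na(last$c_avg))
  expect_true(last$c_ratio > 0 && last$c_ratio <= 1)
  expect_true(abs(last$ng_age) <= 1 && abs(last$ng_vos) <= 1)

  syn <- gen_entity_set(synth_config(n_domains = 50, n_multidomains = 200,
                                     n_events = 30, seed = 2))
  net2 <- build_network("SPX", syn$set, syn$ages)
  r2 <- modularity_report(net2, events = net2$timeline$n_events)
  expect_false(anyNA(r2[, c("vq", "c_ratio", "c_avg", "fgc_q",
                            "ng_age", "ng_vos")]))
  expect_equal(r2$c_ratio, r2$n_communities /
                 sum(igraph::degree(snapshot_undirected(
                   net2, net2$timeline$n_events)) > 0))
})
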