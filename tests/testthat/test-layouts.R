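test_that("radial toy model follows the orbital arithmetic", {
  r10 <- radial_toy(10)
  expect_equal(r10$nodes, 55)
  expect_equal(r10$links, 45)
  expect_equal(radial_toy(1)$nodes, 1)
  expect_equal(radial_toy(1)$links, 0)
  expect_equal(radial_toy(3)$nodes, 6)
  expect_equal(radial_toy(3)$links, 3)
  expect_error(radial_toy(0), ">= 1")

  # o = t-r-1, i = r, o+i = t-1 for every orbital at every t
  for (t in 1:50) {
    rt <- radial_toy(t)
    expect_equal(rt$orbitals$outward, t - rt$orbitals$r - 1L)
    expect_equal(rt$orbitals$inward, rt$orbitals$r)
    expect_true(all(rt$orbitals$outward + rt$orbitals$inward == t - 1L))
    expect_equal(sum(rt$orbitals$n_nodes), rt$nodes)
    expect_equal(rt$links, t * (t - 1L) / 2)
  }
})

test_that("waterfall layout stacks strictly by age", {
  net <- toy_networks()$CX
  g <- snapshot(net, net$timeline$n_events)
  co <- waterfall_coords(g)
  expect_true(all(diff(co$y[order(co$nd)]) <= 0))
  old <- co[co$label == "1", ]; young <- co[co$label == "4|3|2", ]
  expect_gt(old$y, young$y)

  # equal-age nodes share a row
  es <- classify_entities(c("a", "b", "a|b"), strict = FALSE)
  net2 <- build_network("CX", es, c(a = 0, b = 0, `a|b` = 0.5))
  co2 <- waterfall_coords(snapshot(net2, 2))
  expect_equal(co2$y[co2$label == "a"], co2$y[co2$label == "b"])

  # communities occupy disjoint x-bands
  spx <- toy_networks()$SPX
  gs <- snapshot(spx, spx$timeline$n_events)
  memb <- vos_cluster(gs, seed = 1)
  co3 <- waterfall_coords(gs, memb)
  rngs <- lapply(split(co3$x, memb), range)
  if (length(rngs) > 1)
    for (i in seq_len(length(rngs) - 1))
      expect_lt(rngs[[i]][2], rngs[[i + 1]][1])
})

test_that("radial layout puts each node on its event orbital", {
  net <- toy_networks()$CX
  g <- snapshot(net, net$timeline$n_events)
  co <- radial_coords(g, net$timeline)
  expect_equal(co$radius, event_index(net$timeline, co$nd))
  expect_equal(nrow(unique(co[, "radius", drop = FALSE])), 7L)
  expect_true(all(diff(co$radius[order(co$nd)]) >= 0))
  # single-event graph: all on orbital 1
  es <- classify_entities(c("a", "b", "a|b"), strict = FALSE)
  net1 <- build_network("CX", es, c(a = 0, b = 0, `a|b` = 0))
  co1 <- radial_coords(snapshot(net1, 1), net1$timeline)
  expect_true(all(co1$radius == 1))
})

test_that("reduce_network keeps the top connectivity percentile", {
  net <- toy_networks()$SPX
  g <- snapshot(net, net$timeline$n_events)
  expect_equal(igraph::gorder(reduce_network(g, pct = 0)),
               igraph::gorder(g))
  # star: only the hub survives a high percentile
  star <- igraph::graph_from_data_frame(
    data.frame(source = "h", target = paste0("l", 1:9), weight = 1))
  top <- reduce_network(star, pct = 99)
  expect_equal(igraph::V(top)$name, "h")
  # uniform degrees: ties keep everyone
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- letters[1:6]
  igraph::E(ring)$weight <- 1
  expect_equal(igraph::gorder(reduce_network(ring, pct = 99)), 6L)
})

test_that("symbol sizes and arc offsets follow the published presets", {
  net <- toy_networks()$CX
  g <- snapshot(net, net$timeline$n_events)
  s3 <- symbol_sizes(g, "scale")
  s2 <- symbol_sizes(g, "shift")
  wout <- igraph::strength(g, mode = "out", weights = igraph::E(g)$weight)
  expect_equal(s3$width, unname(wout * 2 + 2))
  expect_equal(s2$width, unname(wout + 10))
  off <- arc_offsets(net$arcs)
  expect_true(all(off %% 2 == 0))
  expect_equal(max(table(paste(net$arcs$source, off))), 1L)
})

test_that("Pajek NET writer/reader round-trips nodes, arcs and weights", {
  nets <- toy_networks()
  for (nm in names(nets)) {
    p <- withr::local_tempfile(fileext = ".net")
    write_pajek_net(nets[[nm]], p)
    back <- read_pajek_net(p)
    expect_equal(back$nodes$label, names(nets[[nm]]$nodes))
    expect_equal(back$nodes$nd, unname(round(nets[[nm]]$nodes, 7)))
    expect_equal(back$arcs$source, nets[[nm]]$arcs$source)
    expect_equal(back$arcs$target, nets[[nm]]$arcs$target)
    expect_equal(back$arcs$weight, as.numeric(nets[[nm]]$arcs$weight))
  }
  # snapshot writing honours the event cutoff
  p2 <- withr::local_tempfile(fileext = ".net")
  write_pajek_net(nets$CX, p2, event = 3)
  expect_equal(nrow(read_pajek_net(p2)$arcs), 0L)
})

test_that("partition, edge-list and SVG writers emit valid text", {
  net <- toy_networks()$CX
  clu <- withr::local_tempfile(fileext = ".clu")
  write_pajek_clu(rep(1:2, length.out = 7), clu)
  expect_equal(length(readLines(clu)), 8L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(net, tsv)
  df <- read.delim(tsv)
  expect_equal(names(df), c("source", "target", "weight", "age",
                            "contemporary"))
  expect_equal(nrow(df), 11L)

  svg <- withr::local_tempfile(fileext = ".svg")
  g <- snapshot(net, net$timeline$n_events)
  write_layout_svg(waterfall_coords(g), net$arcs, svg)
  txt <- readLines(svg)
  expect_match(txt[1], "^<svg ")
  expect_equal(sum(grepl("<circle", txt)), 7L)
})
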