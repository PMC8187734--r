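test_that("CX on the toy census yields exactly the 11 containment arcs", {
  net <- toy_networks()$CX
  want <- c("1>1|2", "2>1|2", "3>3|2", "2>3|2", "1>1|2|3", "2>1|2|3",
            "3>1|2|3", "1|2>1|2|3", "2>4|3|2", "3>4|3|2", "3|2>4|3|2")
  got <- paste(net$arcs$source, net$arcs$target, sep = ">")
  expect_setequal(got, want)
  expect_true(all(net$arcs$weight == 1))
  expect_length(net$nodes, 7L)
})

test_that("pairwise networks on the toy census match hand enumeration", {
  nets <- toy_networks()
  px <- nets$PX$arcs
  expect_setequal(pair_key(px$source, px$target),
                  c("1~2", "1~3", "2~3", "1|2~3"))
  expect_equal(px$weight[pair_key(px$source, px$target) == "2~3"], 2L)
  expect_setequal(names(nets$PX$nodes), c("1", "2", "3", "1|2", "3|2"))

  pax <- nets$PAX$arcs
  expect_setequal(pair_key(pax$source, pax$target),
                  c("1~2", "2~3", "1|2~3"))
  expect_equal(pax$weight[pair_key(pax$source, pax$target) == "2~3"], 2L)

  spx <- nets$SPX$arcs
  expect_setequal(pair_key(spx$source, spx$target),
                  c("1~2", "1~3", "2~3", "3~4", "2~4"))
  expect_equal(spx$weight[pair_key(spx$source, spx$target) == "2~3"], 2L)
  expect_setequal(names(nets$SPX$nodes), c("1", "2", "3", "4"))

  spax <- nets$SPAX$arcs
  expect_setequal(pair_key(spax$source, spax$target),
                  c("1~2", "2~3", "3~4"))
})

test_that("CX weights count multiple occurrences of a repeated component", {
  es <- classify_entities(c("a", "b", "a|b|a"), strict = FALSE)
  ages <- c(a = 0, b = 0.1, `a|b|a` = 0.5)
  net <- build_network("CX", es, ages)
  wa <- net$arcs$weight[net$arcs$source == "a"]
  expect_equal(wa, 2L)
})

test_that("spliced token ages are first appearances", {
  ta <- token_ages(toy_set(), toy_ages())
  expect_equal(unname(ta[c("1", "2", "3", "4")]), c(0, 0.1, 0.2, 0.6))
  # SPX timeline can be shorter than the entity timeline
  nets <- toy_networks()
  expect_equal(nets$SPX$timeline$n_events, 4L)
  expect_equal(nets$CX$timeline$n_events, 7L)
})

test_that("arc direction embeds age and missing ages are named", {
  for (nm in names(toy_networks())) {
    net <- toy_networks()[[nm]]
    nd_s <- net$nodes[net$arcs$source]
    nd_t <- net$nodes[net$arcs$target]
    expect_true(all(nd_s[!net$arcs$contemporary] <
                    nd_t[!net$arcs$contemporary]))
    expect_equal(unname(net$arcs$age), unname(pmax(nd_s, nd_t)))
  }
  ages <- toy_ages()[-3]
  expect_error(build_network("CX", toy_set(), ages), "3")
})

test_that("snapshots are cumulative and monotone", {
  net <- toy_networks()$CX
  expect_error(snapshot(net, 0), "out of range")
  expect_error(snapshot(net, 99), "out of range")

  g1 <- snapshot(net, 1)
  expect_equal(igraph::ecount(g1), 0L)      # no younger partner yet

  sizes <- vapply(seq_len(net$timeline$n_events), function(e)
    c(igraph::gorder(snapshot(net, e)), igraph::ecount(snapshot(net, e))),
    numeric(2))
  expect_true(all(diff(sizes[1, ]) >= 0))
  expect_true(all(diff(sizes[2, ]) >= 0))

  # before 1|2 appears, no container is present: 0 arcs
  e_before <- event_index(net$timeline, 0.2)
  expect_equal(igraph::ecount(snapshot(net, e_before)), 0L)
  # final snapshot is the full network
  gN <- snapshot(net, net$timeline$n_events)
  expect_equal(igraph::ecount(gN), nrow(net$arcs))
})

test_that("degree series records donors and acceptors per event", {
  # star with an old center donating to three younger leaves
  es <- classify_entities(c("h", "x", "h|x", "h|x|x", "x|h"), strict = FALSE)
  ages <- c(h = 0, x = 0.05, `h|x` = 0.2, `h|x|x` = 0.4, `x|h` = 0.6)
  net <- build_network("CX", es, ages)
  d <- degree_series(net, net$timeline$n_events)
  expect_equal(d$outdegree[d$label == "h"], 3L)
  expect_true(all(d$w_indegree[d$label %in% c("h|x", "x|h")] >= 1))
  expect_true(all(d$w_outdegree >= d$outdegree))

  # toy SPX: node 3 has partners 1, 2 (w=2), 4 -> weighted total degree 4
  spx <- toy_networks()$SPX
  ds <- degree_series(spx, spx$timeline$n_events)
  expect_equal(ds$w_outdegree[ds$label == "3"] +
               ds$w_indegree[ds$label == "3"], 4)
})

test_that("CX arc weights at a container conserve its occurrence count", {
  # arcs are age-directed, so the containment weight of M is the summed
  # weight of arcs joining M to entities with fewer blocks (its components),
  # whichever way age pointed them
  for (seed in 1:6) {
    fz <- fuzz_entity_set(seed = seed)
    net <- build_network("CX", fz$set, fz$ages)
    nblocks <- lengths(lapply(fz$set$entities, `[[`, "tokens"))
    for (lab in fz$set$labels) {
      if (nblocks[[lab]] < 2) next
      occ <- component_occurrences(fz$set$entities[[lab]], fz$set)
      a <- net$arcs
      other <- ifelse(a$source == lab, a$target,
                      ifelse(a$target == lab, a$source, NA))
      win <- sum(a$weight[!is.na(other) & nblocks[other] < nblocks[[lab]]])
      expect_equal(win, nrow(occ))
    }
  }
})

test_that("adjacency restricts pairwise criteria edgewise on fuzzed sets", {
  for (seed in 1:8) {
    fz <- fuzz_entity_set(n_dom = 7, n_multi = 14, seed = seed)
    px <- build_network("PX", fz$set, fz$ages)$arcs
    pax <- build_network("PAX", fz$set, fz$ages)$arcs
    spx <- build_network("SPX", fz$set, fz$ages)$arcs
    spax <- build_network("SPAX", fz$set, fz$ages)$arcs
    expect_true(all(pair_key(pax$source, pax$target) %in%
                    pair_key(px$source, px$target)))
    expect_true(all(pair_key(spax$source, spax$target) %in%
                    pair_key(spx$source, spx$target)))
    # weights dominate edgewise
    i <- match(pair_key(pax$source, pax$target),
               pair_key(px$source, px$target))
    expect_true(all(px$weight[i] >= pax$weight))
    j <- match(pair_key(spax$source, spax$target),
               pair_key(spx$source, spx$target))
    expect_true(all(spx$weight[j] >= spax$weight))
  }
})

test_that("first_events returns the oldest arc with lexicographic ties", {
  net <- toy_networks()$CX
  fe <- first_events(net)
  expect_equal(fe$source, "1")
  expect_equal(fe$target, "1|2")
  expect_equal(fe$age, 0.3)

  # all-contemporary network errors
  es <- classify_entities(c("a", "b", "a|b"), strict = FALSE)
  net0 <- build_network("CX", es, c(a = 0, b = 0, `a|b` = 0))
  expect_error(first_events(net0), "non-contemporary")
})

test_that("contemporary arcs are kept, flagged and excludable", {
  es <- classify_entities(c("a", "b", "a|b"), strict = FALSE)
  net <- build_network("CX", es, c(a = 0, b = 0, `a|b` = 0))
  expect_true(all(net$arcs$contemporary))
  g <- snapshot(net, 1)
  expect_equal(igraph::ecount(g), 2L)
  expect_equal(igraph::ecount(snapshot(net, 1, contemporary = FALSE)), 0L)
})
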