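# The seven-entity toy census used throughout: 3 domains, 2 supradomains,
# 2 multidomains, with all-distinct ages ordered 1,2,3 < 1|2 < 3|2 <
# 1|2|3 < 4|3|2.

toy_labels <- c("1", "2", "3", "1|2", "3|2", "1|2|3", "4|3|2")

toy_set <- function() classify_entities(toy_labels, strict = FALSE)

toy_ages <- function() {
  c("1" = 0, "2" = 0.1, "3" = 0.2, "1|2" = 0.3, "3|2" = 0.4,
    "1|2|3" = 0.5, "4|3|2" = 0.6)
}

toy_networks <- function() {
  set <- toy_set(); ages <- toy_ages()
  lapply(stats::setNames(nm = c("CX", "PX", "PAX", "SPX", "SPAX")),
         build_network, set = set, ages = ages)
}

# unordered-pair edge key for comparing edge sets
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

# brute-force occurrence oracle: test every (start,end) window of the
# container against every entity label
oracle_occurrences <- function(container, set) {
  tk <- container$tokens
  b <- length(tk)
  rows <- list()
  for (s in 1:b) for (e in s:b) {
    w <- paste(tk[s:e], collapse = "|")
    if (w == container$label) next
    for (lab in set$labels) {
      if (identical(w, lab))
        rows[[length(rows) + 1L]] <- data.frame(
          label = lab, start = s - 1L, end = e, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(label = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$label), , drop = FALSE]
}

# brute-force double-loop Newman-Girvan modularity over the full adjacency
# matrix, straight from the printed formula
oracle_ng <- function(graph, memb) {
  g <- igraph::as_undirected(graph, mode = "each")
  w <- igraph::E(g)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(g))
  A <- matrix(0, igraph::gorder(g), igraph::gorder(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    A[el[r, 1], el[r, 2]] <- A[el[r, 1], el[r, 2]] + w[r]
    A[el[r, 2], el[r, 1]] <- A[el[r, 2], el[r, 1]] + w[r]
  }
  m <- sum(w)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (memb[i] == memb[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  q / (2 * m)
}

# random small entity set for fuzzing: a few domains plus random
# concatenations (may coincide, duplicates dropped)
fuzz_entity_set <- function(n_dom = 6, n_multi = 10, max_blocks = 4,
                            seed = 1) {
  set.seed(seed)
  doms <- as.character(seq_len(n_dom))
  multi <- replicate(n_multi, paste(
    sample(doms, sample(2:max_blocks, 1), replace = TRUE), collapse = "|"))
  labels <- unique(c(doms, multi))
  set <- classify_entities(labels, strict = FALSE)
  ages <- stats::setNames(round(stats::runif(length(labels)), 2), labels)
  list(set = set, ages = ages)
}
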