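#' Build one of the five evolving networks of domain organization
#'
#' The five operative criteria define nodes and links from an entity set and
#' its age map:
#'
#' * **CX** (composition): nodes are all entities; one arc per (component,
#'   container) pair where the component entity is a contiguous proper
#'   token-subsequence of a multi-block container (supradomain-to-multidomain
#'   and multidomain-to-multidomain containment included); weight = number of
#'   distinct containment-inducing occurrences.
#' * **PX** (pairwise): nodes are domains and supradomains; every multidomain
#'   entity is decomposed into unordered pairs of entity-set components with
#'   disjoint (non-overlapping) occurrences; weight = number of distinct
#'   inducing multidomains.
#' * **PAX**: as PX, restricted to pairs whose occurrences are adjacent (one
#'   occurrence ends where the other starts).
#' * **SPX** (spliced pairwise): nodes are the domain tokens spliced from the
#'   architectures ([spliced_domains()]); every multidomain induces links
#'   between all unordered pairs of distinct tokens it contains.
#' * **SPAX**: as SPX, restricted to adjacent token positions.
#'
#' Self-pairs (the same token or entity twice in a container) are dropped.
#' Arcs are directed old-to-new: the source is the older endpoint and the arc
#' age is the nd of the younger endpoint. Equal-age (contemporary) arcs are
#' kept for statistics and flagged.
#'
#' Node ages: entities take their nd from `ages`; spliced tokens (SPX/SPAX)
#' take the minimum nd over all entities in which they occur, their time of
#' first appearance.
#'
#' @param criterion one of `"CX"`, `"PX"`, `"PAX"`, `"SPX"`, `"SPAX"`.
#' @param set a `ccs_entity_set` from [classify_entities()].
#' @param ages named numeric vector of nd covering every entity label.
#' @return object of class `evolving_network`: list with `criterion`,
#'   `nodes` (named numeric nd), `arcs` (data frame `source`, `target`,
#'   `weight`, `age`, `contemporary`) and `timeline` (an `nd_timeline` over
#'   the node ages).
#' @export
build_network <- function(criterion = c("CX", "PX", "PAX", "SPX", "SPAX"),
                          set, ages) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(set, "ccs_entity_set"))
  ages <- round(ages[!is.na(ages)], 7L)
  miss <- setdiff(set$labels, names(ages))
  if (length(miss))
    stop("missing age for entity: ", paste(utils::head(miss, 5L), collapse = ", "))
  tokens <- lapply(set$entities, `[[`, "tokens")
  multiblock <- set$labels[lengths(tokens) >= 2L]
  multidomain <- set$labels[set$kind == "multidomain"]

  if (criterion == "CX") {
    nodes <- stats::setNames(as.numeric(ages[set$labels]), set$labels)
    from <- character(0); to <- character(0); w <- integer(0)
    for (m in multiblock) {
      occ <- component_occurrences(set$entities[[m]], set)
      if (!nrow(occ)) next
      cnt <- table(occ$label)
      from <- c(from, names(cnt)); to <- c(to, rep(m, length(cnt)))
      w <- c(w, as.integer(cnt))
    }
    arcs <- data.frame(a = from, b = to, weight = w, stringsAsFactors = FALSE)
  } else if (criterion %in% c("PX", "PAX")) {
    keep <- set$labels[set$kind != "multidomain"]
    nodes <- stats::setNames(as.numeric(ages[keep]), keep)
    adjacent_only <- criterion == "PAX"
    pair_a <- character(0); pair_b <- character(0)
    for (m in multidomain) {
      occ <- component_occurrences(set$entities[[m]], set)
      n <- nrow(occ)
      if (n < 2L) next
      pa <- character(0); pb <- character(0)
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        if (occ$label[i] == occ$label[j]) next
        disjoint <- occ$end[i] <= occ$start[j] || occ$end[j] <= occ$start[i]
        if (!disjoint) next
        if (adjacent_only &&
            !(occ$end[i] == occ$start[j] || occ$end[j] == occ$start[i])) next
        p <- sort(c(occ$label[i], occ$label[j]))
        pa <- c(pa, p[1L]); pb <- c(pb, p[2L])
      }
      if (length(pa)) {
        dup <- duplicated(paste(pa, pb, sep = "\r"))
        pair_a <- c(pair_a, pa[!dup]); pair_b <- c(pair_b, pb[!dup])
      }
    }
    arcs <- aggregate_pairs(pair_a, pair_b)
  } else {                                      # SPX / SPAX
    tok <- spliced_domains(set)
    tok_age <- token_ages(set, ages)
    nodes <- tok_age[tok]
    adjacent_only <- criterion == "SPAX"
    pair_a <- character(0); pair_b <- character(0)
    for (m in multidomain) {
      tk <- tokens[[m]]
      b <- length(tk)
      pa <- character(0); pb <- character(0)
      if (adjacent_only) {
        for (i in 1:(b - 1L)) {
          if (tk[i] == tk[i + 1L]) next
          p <- sort(c(tk[i], tk[i + 1L]))
          pa <- c(pa, p[1L]); pb <- c(pb, p[2L])
        }
      } else {
        ut <- unique(tk)
        if (length(ut) >= 2L) {
          cmb <- utils::combn(sort(ut), 2L)
          pa <- cmb[1L, ]; pb <- cmb[2L, ]
        }
      }
      if (length(pa)) {
        dup <- duplicated(paste(pa, pb, sep = "\r"))
        pair_a <- c(pair_a, pa[!dup]); pair_b <- c(pair_b, pb[!dup])
      }
    }
    arcs <- aggregate_pairs(pair_a, pair_b)
  }

  ## orient old -> new by nd; contemporary arcs keep construction order
  nd_a <- as.numeric(nodes[arcs$a]); nd_b <- as.numeric(nodes[arcs$b])
  swap <- nd_a > nd_b
  src <- ifelse(swap, arcs$b, arcs$a)
  tgt <- ifelse(swap, arcs$a, arcs$b)
  arcs <- data.frame(
    source = src, target = tgt, weight = arcs$weight,
    age = pmax(nd_a, nd_b), contemporary = nd_a == nd_b,
    stringsAsFactors = FALSE)
  arcs <- arcs[order(arcs$age, arcs$source, arcs$target), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(
    list(criterion = criterion, nodes = nodes, arcs = arcs,
         timeline = make_timeline(nodes)),
    class = "evolving_network")
}

aggregate_pairs <- function(a, b) {
  if (!length(a))
    return(data.frame(a = character(0), b = character(0), weight = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(a, b, sep = "\r")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  data.frame(a = vapply(parts, `[[`, character(1), 1L),
             b = vapply(parts, `[[`, character(1), 2L),
             weight = as.integer(cnt), stringsAsFactors = FALSE)
}

#' First appearance (nd) of each spliced token
#'
#' @param set a `ccs_entity_set`.
#' @param ages named numeric nd per entity label.
#' @return named numeric vector over [spliced_domains()] tokens: minimum nd
#'   over the entities containing each token.
#' @export
token_ages <- function(set, ages) {
  stopifnot(inherits(set, "ccs_entity_set"))
  tok <- lapply(set$entities, `[[`, "tokens")
  lab <- rep(names(tok), lengths(tok))
  tk <- unlist(tok, use.names = FALSE)
  age <- round(as.numeric(ages[lab]), 7L)
  out <- tapply(age, tk, min)
  stats::setNames(as.numeric(out), names(out))
}

#' @export
print.evolving_network <- function(x, ...) {
  cat("<evolving network> ", x$criterion, ": ", length(x$nodes), " nodes, ",
      nrow(x$arcs), " arcs (", sum(x$arcs$contemporary), " contemporary), ",
      x$timeline$n_events, " time events\n", sep = "")
  invisible(x)
}

#' Cumulative snapshot of an evolving network at a time event
#'
#' The snapshot at event `e` contains exactly the nodes with nd at most the
#' event's nd and the arcs whose age is at most the event's nd; snapshots are
#' monotone in `e`.
#'
#' @param net an `evolving_network`.
#' @param event 1-based event ordinal on the network's timeline.
#' @param contemporary include equal-age arcs (default TRUE; renderings
#'   conventionally exclude them, statistics keep them).
#' @return a directed weighted `igraph` graph with vertex attribute `nd`.
#' @export
snapshot <- function(net, event, contemporary = TRUE) {
  stopifnot(inherits(net, "evolving_network"))
  if (!(is.numeric(event) && length(event) == 1L &&
        event >= 1L && event <= net$timeline$n_events))
    stop("event out of range 1..", net$timeline$n_events)
  nd_e <- net$timeline$events[as.integer(event)]
  keep_n <- net$nodes <= nd_e
  a <- net$arcs[net$arcs$age <= nd_e, , drop = FALSE]
  if (!contemporary) a <- a[!a$contemporary, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    a[, c("source", "target", "weight", "age", "contemporary")],
    directed = TRUE,
    vertices = data.frame(name = names(net$nodes)[keep_n],
                          nd = as.numeric(net$nodes[keep_n]),
                          stringsAsFactors = FALSE))
  g
}

#' Undirected (optionally simplified) view of a snapshot
#'
#' Modularity indices need cumulative undirected weighted input; the average
#' clustering coefficient needs a simplified (unweighted, no multi-edges)
#' graph.
#'
#' @inheritParams snapshot
#' @param simplify drop weights and collapse parallel edges.
#' @export
snapshot_undirected <- function(net, event, simplify = FALSE,
                                contemporary = TRUE) {
  g <- igraph::as_undirected(snapshot(net, event, contemporary = contemporary),
                             mode = "each")
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "sum", "ignore"))
  if (simplify) g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Per-event cumulative degree records
#'
#' For each time event and each node present at that event, the unweighted
#' and multiplicity-weighted in/out-degrees of the cumulative network.
#' Outdegree counts donor (source) roles, indegree acceptor (sink) roles.
#'
#' @param net an `evolving_network`.
#' @param events integer vector of event ordinals (default: all).
#' @return data frame with columns `event`, `nd_event`, `label`, `nd`,
#'   `outdegree`, `indegree`, `w_outdegree`, `w_indegree`.
#' @export
degree_series <- function(net, events = seq_len(net$timeline$n_events)) {
  stopifnot(inherits(net, "evolving_network"))
  labs <- names(net$nodes)
  out <- vector("list", length(events))
  for (k in seq_along(events)) {
    e <- events[k]
    nd_e <- net$timeline$events[e]
    present <- labs[net$nodes <= nd_e]
    a <- net$arcs[net$arcs$age <= nd_e, , drop = FALSE]
    fs <- factor(a$source, levels = present)
    ft <- factor(a$target, levels = present)
    out[[k]] <- data.frame(
      event = e, nd_event = nd_e, label = present,
      nd = as.numeric(net$nodes[present]),
      outdegree = as.integer(tabulate(fs, length(present))),
      indegree = as.integer(tabulate(ft, length(present))),
      w_outdegree = as.numeric(rowsum_by(a$weight, fs, length(present))),
      w_indegree = as.numeric(rowsum_by(a$weight, ft, length(present))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

rowsum_by <- function(x, f, nlev) {
  out <- numeric(nlev)
  if (length(x)) {
    s <- rowsum(x, f)
    out[match(rownames(s), levels(f))] <- s[, 1L]
  }
  out
}

#' First non-contemporary arc of an evolving network
#'
#' The earliest donor/acceptor event: the arc with minimal age among arcs
#' whose endpoints differ in nd; ties are broken lexicographically by
#' (source, target).
#'
#' @param net an `evolving_network`.
#' @return one-row data frame `source`, `target`, `weight`, `age`.
#' @export
first_events <- function(net) {
  stopifnot(inherits(net, "evolving_network"))
  a <- net$arcs[!net$arcs$contemporary, , drop = FALSE]
  if (!nrow(a)) stop("network has no non-contemporary arcs")
  a <- a[a$age == min(a$age), , drop = FALSE]
  a <- a[order(a$source, a$target), , drop = FALSE]
  rownames(a) <- NULL
  a[1L, c("source", "target", "weight", "age")]
}

#' Write arcs as a TSV edge list (`source target weight age contemporary`)
#' @param net an `evolving_network`.
#' @param path output path.
#' @export
write_edge_tsv <- function(net, path) {
  utils::write.table(net$arcs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
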