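#' The radial toy model of orbital network growth
#'
#' An idealized network growing in concentric orbitals, one per time event:
#' at time `t` orbital `r` (0-based) holds `r + 1` nodes, and exactly one
#' node per orbital links to single nodes in every other orbital, so an
#' orbital's outward links are `o = t - r - 1`, its inward links `i = r`
#' (hence `o + i = t - 1`), and the network totals `t(t+1)/2` nodes and
#' `t(t-1)/2` links. At `t = 10` the model reaches 55 nodes.
#'
#' @param t current time event, `t >= 1`.
#' @return list with `nodes`, `links`, and a per-orbital data frame
#'   `orbitals` (`r`, `n_nodes`, `outward`, `inward`).
#' @export
radial_toy <- function(t) {
  if (!(is.numeric(t) && length(t) == 1L && t >= 1))
    stop("t must be a single value >= 1")
  t <- as.integer(t)
  r <- 0:(t - 1L)
  list(nodes = t * (t + 1L) / 2,
       links = t * (t - 1L) / 2,
       orbitals = data.frame(r = r, n_nodes = r + 1L,
                             outward = t - r - 1L, inward = r))
}

#' Waterfall layout coordinates
#'
#' Time flows top-down: y is the negated event rank of each node's nd, so
#' strictly older nodes sit strictly higher and contemporaries share a row.
#' x spreads community groups into disjoint horizontal bands (communities
#' from `partition`, default a single band), with nodes ordered by label
#' within a band. Deterministic.
#'
#' @param graph a snapshot `igraph` graph with vertex attribute `nd`.
#' @param partition optional membership vector over the vertices.
#' @return data frame `label`, `nd`, `x`, `y`.
#' @export
waterfall_coords <- function(graph, partition = NULL) {
  nd <- igraph::V(graph)$nd
  if (is.null(nd)) stop("graph lacks the nd vertex attribute")
  lab <- igraph::V(graph)$name
  memb <- if (is.null(partition)) rep(1L, length(lab))
          else membership_vector(graph, partition)
  y <- -match(nd, sort(unique(nd)))
  x <- numeric(length(lab))
  off <- 0
  for (cm in sort(unique(memb))) {
    idx <- which(memb == cm)
    idx <- idx[order(lab[idx])]
    x[idx] <- off + seq_along(idx)
    off <- off + length(idx) + 1         # one-column gap between bands
  }
  data.frame(label = lab, nd = nd, x = x, y = y, stringsAsFactors = FALSE)
}

#' Radial layout coordinates
#'
#' Nodes accumulate in concentric orbitals, one per time event: the radius
#' is the event ordinal of the node's nd on the timeline and nodes are
#' spread at even angles within their orbital (by label order).
#'
#' @param graph a snapshot `igraph` graph with vertex attribute `nd`.
#' @param timeline an `nd_timeline` covering the node ages.
#' @return data frame `label`, `nd`, `radius`, `angle`, `x`, `y`.
#' @export
radial_coords <- function(graph, timeline) {
  nd <- igraph::V(graph)$nd
  if (is.null(nd)) stop("graph lacks the nd vertex attribute")
  lab <- igraph::V(graph)$name
  r <- event_index(timeline, nd)
  theta <- numeric(length(lab))
  for (orb in unique(r)) {
    idx <- which(r == orb)
    idx <- idx[order(lab[idx])]
    theta[idx] <- 2 * pi * (seq_along(idx) - 1L) / length(idx)
  }
  data.frame(label = lab, nd = nd, radius = r, angle = theta,
             x = r * cos(theta), y = r * sin(theta),
             stringsAsFactors = FALSE)
}

#' Reduce a snapshot to its most connected nodes
#'
#' Keeps the nodes whose combined (out + in) weighted degree reaches the
#' `pct` percentile of all nodes' combined degrees, with the arcs among
#' them — the "100th-percentile connectivity" view of the published
#' waterfall figure. `pct = 0` keeps everything; ties at the threshold are
#' retained.
#'
#' @param graph a directed weighted snapshot `igraph` graph.
#' @param pct percentile in `[0, 100]` (default 99).
#' @return induced `igraph` subgraph (possibly empty).
#' @export
reduce_network <- function(graph, pct = 99) {
  w <- igraph::E(graph)$weight
  combined <- igraph::strength(graph, mode = "all", weights = w)
  thr <- as.numeric(stats::quantile(combined, pct / 100, type = 7))
  igraph::induced_subgraph(graph, which(combined >= thr))
}

#' Node symbol sizes from weighted degrees
#'
#' Width encodes the donor role (weighted outdegree), height the acceptor
#' role (weighted indegree). Two presets keep 0-degree nodes visible:
#' `"scale"` maps degree to x2+2 (the reduced-waterfall convention) and
#' `"shift"` to +10 (the radial-snapshot convention).
#'
#' @param graph a directed weighted snapshot graph.
#' @param preset `"scale"` (x2+2) or `"shift"` (+10).
#' @return data frame `label`, `width`, `height`.
#' @export
symbol_sizes <- function(graph, preset = c("scale", "shift")) {
  preset <- match.arg(preset)
  w <- igraph::E(graph)$weight
  wout <- igraph::strength(graph, mode = "out", weights = w)
  win <- igraph::strength(graph, mode = "in", weights = w)
  f <- if (preset == "scale") function(d) d * 2 + 2 else function(d) d + 10
  data.frame(label = igraph::V(graph)$name, width = f(wout), height = f(win),
             stringsAsFactors = FALSE)
}

#' Angular offsets for multiple arcs from a node
#'
#' Arcs sharing a source are fanned out in 2-degree increments to avoid
#' overlap in renderings.
#'
#' @param arcs data frame with a `source` column (e.g. an
#'   `evolving_network`'s `arcs`).
#' @param step increment in degrees (default 2).
#' @return numeric vector of offsets (degrees), one per arc.
#' @export
arc_offsets <- function(arcs, step = 2) {
  off <- stats::ave(seq_len(nrow(arcs)), arcs$source, FUN = seq_along)
  (off - 1) * step
}

#' Write a layout as a minimal SVG drawing
#'
#' Nodes as circles, arcs as straight lines; a plain-text rendering hook,
#' not a Pajek reproduction.
#'
#' @param coords data frame from [waterfall_coords()] or [radial_coords()].
#' @param arcs optional arcs data frame (`source`, `target`).
#' @param path output path.
#' @param scale pixels per layout unit.
#' @export
write_layout_svg <- function(coords, arcs = NULL, path, scale = 40) {
  x <- coords$x * scale; y <- -coords$y * scale
  pad <- 2 * scale
  xr <- range(x); yr <- range(y)
  tx <- function(v) v - xr[1L] + pad
  ty <- function(v) v - yr[1L] + pad
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
    diff(xr) + 2 * pad, diff(yr) + 2 * pad))
  if (!is.null(arcs) && nrow(arcs)) {
    i <- match(arcs$source, coords$label)
    j <- match(arcs$target, coords$label)
    ok <- !is.na(i) & !is.na(j)
    out <- c(out, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#888" stroke-width="0.5"/>',
      tx(x[i[ok]]), ty(y[i[ok]]), tx(x[j[ok]]), ty(y[j[ok]])))
  }
  out <- c(out,
           sprintf('<circle cx="%.1f" cy="%.1f" r="%.1f" fill="#1f77b4"/>',
                   tx(x), ty(y), scale / 8),
           sprintf('<text x="%.1f" y="%.1f" font-size="%.1f">%s</text>',
                   tx(x) + scale / 6, ty(y), scale / 5, coords$label),
           "</svg>")
  writeLines(out, path)
  invisible(path)
}
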