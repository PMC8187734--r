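#' Write a network snapshot in Pajek NET format
#'
#' `*Vertices` lines carry the node label (quoted) followed by the node's nd
#' as a trailing comment field; `*Arcs` lines carry 1-based source/target
#' ids and the arc weight. The reader below round-trips this dialect
#' exactly.
#'
#' @param net an `evolving_network`, or an `igraph` graph with vertex
#'   attribute `nd` and edge attribute `weight`.
#' @param path output path.
#' @param event optional event ordinal; for an `evolving_network`, write the
#'   cumulative snapshot at that event (default: final event).
#' @export
write_pajek_net <- function(net, path, event = NULL) {
  if (inherits(net, "evolving_network")) {
    labels <- names(net$nodes)
    nd <- as.numeric(net$nodes)
    arcs <- net$arcs
    if (!is.null(event)) {
      nd_e <- net$timeline$events[event]
      keep <- net$nodes <= nd_e
      labels <- labels[keep]; nd <- nd[keep]
      arcs <- arcs[arcs$age <= nd_e, , drop = FALSE]
    }
  } else {
    labels <- igraph::V(net)$name
    nd <- igraph::V(net)$nd %||% rep(0, length(labels))
    el <- igraph::as_edgelist(net)
    arcs <- data.frame(source = el[, 1L], target = el[, 2L],
                       weight = igraph::E(net)$weight %||%
                         rep(1, nrow(el)),
                       stringsAsFactors = FALSE)
  }
  id <- stats::setNames(seq_along(labels), labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", length(labels)), con)
  writeLines(sprintf('%d "%s" %.7f', id, labels, nd), con)
  writeLines("*Arcs", con)
  if (nrow(arcs))
    writeLines(sprintf("%d %d %g", id[arcs$source], id[arcs$target],
                       arcs$weight), con)
  invisible(path)
}

#' Read a Pajek NET file written by [write_pajek_net()]
#'
#' @param path input path.
#' @return list with `nodes` (data frame `id`, `label`, `nd`) and `arcs`
#'   (data frame `source`, `target`, `weight`, with labels resolved).
#' @export
read_pajek_net <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  hv <- grep("^\\*Vertices", ln, ignore.case = TRUE)
  ha <- grep("^\\*(Arcs|Edges)", ln, ignore.case = TRUE)
  if (length(hv) != 1L || length(ha) != 1L)
    stop("not a Pajek NET file: ", path)
  vlines <- ln[(hv + 1L):(ha - 1L)]
  m <- regmatches(vlines,
                  regexec('^(\\d+)\\s+"([^"]*)"(\\s+(-?[0-9.eE+]+))?', vlines))
  nodes <- data.frame(
    id = as.integer(vapply(m, `[[`, character(1), 2L)),
    label = vapply(m, `[[`, character(1), 3L),
    nd = as.numeric(vapply(m, function(p)
      if (length(p) >= 5L && nzchar(p[5L])) p[5L] else "NA", character(1))),
    stringsAsFactors = FALSE)
  arcs <- data.frame(source = character(0), target = character(0),
                     weight = numeric(0), stringsAsFactors = FALSE)
  if (ha < length(ln)) {
    alines <- ln[(ha + 1L):length(ln)]
    fields <- strsplit(alines, "\\s+")
    arcs <- data.frame(
      source = nodes$label[as.integer(vapply(fields, `[[`, character(1), 1L))],
      target = nodes$label[as.integer(vapply(fields, `[[`, character(1), 2L))],
      weight = vapply(fields, function(f)
        if (length(f) >= 3L) as.numeric(f[3L]) else 1, numeric(1)),
      stringsAsFactors = FALSE)
  }
  list(nodes = nodes, arcs = arcs)
}

#' Write a Pajek CLU partition file
#'
#' @param membership integer community ids, in vertex order.
#' @param path output path.
#' @export
write_pajek_clu <- function(membership, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("*Vertices %d", length(membership)), con)
  writeLines(as.character(as.integer(membership)), con)
  invisible(path)
}
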