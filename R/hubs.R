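#' Donor/acceptor hub table across the five networks
#'
#' Ranks nodes by combined weighted degree — the sum of per-network weighted
#' outdegree (donors) or indegree (acceptors) over the supplied evolving
#' networks at the latest event with nd not exceeding `event_nd`. The hub
#' threshold is the `pct`-percentile of the combined degrees over all nodes
#' (linear interpolation, so fractional thresholds arise). A node's
#' `networks` field lists the criteria in which its own per-network degree
#' also meets the threshold.
#'
#' @param nets named list of `evolving_network`s built from the same entity
#'   set (typically all five criteria).
#' @param event_nd age cutoff of the snapshot (default 1, the extant
#'   networks).
#' @param direction `"out"` for donors, `"in"` for acceptors.
#' @param pct percentile threshold (default 99.9).
#' @param flags optional named character vector of fusional/fissional flags
#'   per label (ingested, never inferred); unknown labels get `NA`.
#' @return object of class `hub_table`: data frame with `label`, `age_rank`,
#'   `nd`, `combined`, `networks`, one `deg_<criterion>` column per network,
#'   sorted by combined degree descending; the threshold is attached as
#'   attribute `threshold`.
#' @export
hub_table <- function(nets, event_nd = 1, direction = c("out", "in"),
                      pct = 99.9, flags = NULL) {
  direction <- match.arg(direction)
  if (!length(nets)) stop("empty network list")
  stopifnot(all(vapply(nets, inherits, logical(1), "evolving_network")))
  if (is.null(names(nets)))
    names(nets) <- vapply(nets, `[[`, character(1), "criterion")
  col <- if (direction == "out") "w_outdegree" else "w_indegree"

  per_net <- lapply(nets, function(net) {
    ev <- which(net$timeline$events <= event_nd + 1e-9)
    if (!length(ev)) stop("no event at or before nd = ", event_nd)
    d <- degree_series(net, max(ev))
    stats::setNames(d[[col]], d$label)
  })
  labels <- unique(unlist(lapply(per_net, names), use.names = FALSE))
  degs <- vapply(per_net, function(v) {
    out <- v[labels]; out[is.na(out)] <- 0; as.numeric(out)
  }, numeric(length(labels)))
  if (is.null(dim(degs))) degs <- matrix(degs, nrow = length(labels))
  colnames(degs) <- names(nets)
  combined <- rowSums(degs)
  thr <- as.numeric(stats::quantile(combined, pct / 100, type = 7))

  nd_all <- rep(NA_real_, length(labels))
  for (net in nets) {
    hit <- match(names(net$nodes), labels)
    nd_all[hit] <- as.numeric(net$nodes)
  }
  ord_age <- order(nd_all, labels)
  age_rank <- integer(length(labels))
  age_rank[ord_age] <- seq_along(labels)

  keep <- combined >= thr
  nets_hit <- apply(degs >= thr, 1L, function(r)
    paste(colnames(degs)[r], collapse = ", "))
  out <- data.frame(label = labels, age_rank = age_rank, nd = nd_all,
                    combined = combined, networks = nets_hit,
                    fusional_fissional = if (is.null(flags)) NA_character_
                                         else unname(flags[labels]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, stats::setNames(as.data.frame(degs),
                                    paste0("deg_", colnames(degs))))
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out$combined, out$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "direction") <- direction
  class(out) <- c("hub_table", class(out))
  out
}

#' @export
print.hub_table <- function(x, ...) {
  cat("<hub table> ", nrow(x), " ", attr(x, "direction"), "-degree hubs at threshold ",
      format(attr(x, "threshold")), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 20L), ...)
  invisible(x)
}

#' Annotate hub records with SCOP descriptions and GO names
#'
#' Left-joins single-domain labels on the FSF sccs identifier. Composites
#' (labels containing `|`), repeat-marked labels and labels missing from the
#' annotation files get `"N/A"`, mirroring the published tables. The GO
#' table dialect is a TSV `sccs<TAB>go_id<TAB>go_name` (`#` comments
#' ignored); when several annotations exist, the first is used.
#'
#' @param records a `hub_table` (or data frame with a `label` column).
#' @param scop_des_path optional dir.des.scop.txt-style file
#'   ([read_scop_des()]).
#' @param go_path optional GO TSV.
#' @return `records` with `description` and `go_name` columns filled.
#' @export
annotate_hubs <- function(records, scop_des_path = NULL, go_path = NULL) {
  lab <- records$label
  single <- !grepl("|", lab, fixed = TRUE) & !endsWith(lab, "&")
  description <- rep("N/A", length(lab))
  go_name <- rep("N/A", length(lab))
  if (!is.null(scop_des_path)) {
    des <- read_scop_des(scop_des_path)
    hit <- match(lab, des$sccs)
    ok <- single & !is.na(hit)
    description[ok] <- des$description[hit[ok]]
  }
  if (!is.null(go_path)) {
    ln <- readLines(go_path)
    ln <- ln[!grepl("^\\s*(#|$)", ln)]
    if (length(ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)
      parts <- parts[lengths(parts) >= 3L]
      sccs <- vapply(parts, `[[`, character(1), 1L)
      name <- vapply(parts, `[[`, character(1), 3L)
      hit <- match(lab, sccs)
      ok <- single & !is.na(hit)
      go_name[ok] <- name[hit[ok]]
    }
  }
  records$description <- description
  records$go_name <- go_name
  records
}

#' Write a hub table as TSV
#' @param records a `hub_table`.
#' @param path output path.
#' @export
write_hub_tsv <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
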