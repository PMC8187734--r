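#' Parse a SCOP concise classification string (ccs)
#'
#' A ccs label describes the domain organization of a protein as an ordered,
#' N-to-C list of fold superfamily (FSF) identifiers joined by `|`. A trailing
#' `&` on a token marks a collapsed tandem repeat; such tokens are network
#' nodes in their own right, distinct from their unmarked form (`"c.43.1&"`
#' never matches `"c.43.1"`).
#'
#' @param label a single non-empty ccs string, e.g.
#'   `"c.43.1&|e.23.1|a.28.1|c.43.1&"`.
#' @param strict if `TRUE` (default) every token must match the SCOP sccs
#'   pattern `[a-l].<fold>.<superfamily>` (plus optional `&`). With
#'   `strict = FALSE` any token free of `|`, whitespace and quotes is
#'   accepted, which is convenient for toy and synthetic entity sets.
#' @return an object of class `ccs_architecture`: a list with `label`, the
#'   token vector `tokens` (repeat markers kept), `fsf_id` (markers stripped)
#'   and the logical `repeat_flag` per block.
#' @examples
#' a <- parse_ccs("c.43.1&|e.23.1|a.28.1|c.43.1&")
#' a$repeat_flag    # TRUE FALSE FALSE TRUE
#' @export
parse_ccs <- function(label, strict = TRUE) {
  if (length(label) != 1L || is.na(label) || !nzchar(label))
    stop("ccs label must be a single non-empty string")
  tokens <- strsplit(label, "|", fixed = TRUE)[[1L]]
  if (length(tokens) == 0L || any(!nzchar(tokens)))
    stop("malformed ccs label (empty token): ", sQuote(label))
  pat <- if (strict) "^[a-l]\\.[0-9]+\\.[0-9]+&?$" else "^[^|[:space:]\"']+$"
  bad <- tokens[!grepl(pat, tokens)]
  if (length(bad))
    stop("malformed ccs token ", sQuote(bad[1L]), " in ", sQuote(label))
  rep_flag <- endsWith(tokens, "&")
  structure(
    list(label = label,
         tokens = tokens,
         fsf_id = sub("&$", "", tokens),
         repeat_flag = rep_flag),
    class = "ccs_architecture")
}

#' @export
format.ccs_architecture <- function(x, ...) {
  paste0("<architecture> ", x$label, " (", length(x$tokens), " block",
         if (length(x$tokens) > 1L) "s", ")")
}

#' @export
print.ccs_architecture <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Re-serialize an architecture to its ccs label
#'
#' Joining the block tokens with `|` round-trips the original label.
#' @param x a `ccs_architecture`.
#' @return the ccs label string.
#' @export
ccs_label <- function(x) paste(x$tokens, collapse = "|")

as_architectures <- function(x, strict = TRUE) {
  if (inherits(x, "ccs_architecture")) return(list(x))
  if (is.character(x)) return(lapply(x, parse_ccs, strict = strict))
  if (is.list(x)) {
    return(unlist(lapply(x, function(e) {
      if (inherits(e, "ccs_architecture")) list(e)
      else as_architectures(e, strict = strict)
    }), recursive = FALSE))
  }
  stop("cannot interpret input as architectures")
}

## every contiguous window of >= 2 tokens of every entity, as '|'-joined
## strings; used for supradomain detection
all_windows <- function(arch_tokens) {
  out <- vector("list", length(arch_tokens))
  for (i in seq_along(arch_tokens)) {
    tk <- arch_tokens[[i]]
    b <- length(tk)
    if (b < 2L) next
    w <- character(0)
    for (len in 2:b) {
      if (len == b) next            # the full window is the entity itself
      for (s in 1:(b - len + 1L))
        w <- c(w, paste(tk[s:(s + len - 1L)], collapse = "|"))
    }
    out[[i]] <- w
  }
  out
}

#' Classify an entity set into domains, supradomains and multidomains
#'
#' Single-block entities are *domains*. A multi-block entity that occurs as a
#' contiguous proper token-subsequence of at least one other entity is a
#' *supradomain* (a reused sub-combination); the remaining multi-block
#' entities are *multidomains*. An entity can simultaneously be a real
#' protein architecture and a supradomain; classification picks supradomain
#' whenever the containment condition holds.
#'
#' @param entities a character vector of ccs labels, or a list of
#'   `ccs_architecture` objects. Labels must be unique.
#' @param strict passed to [parse_ccs()] when `entities` is character.
#' @return an object of class `ccs_entity_set`: list with `entities` (named
#'   list of architectures), `kind` (named character:
#'   domain/supradomain/multidomain) and `labels`.
#' @examples
#' es <- classify_entities(c("1", "2", "3", "1|2", "3|2", "1|2|3", "4|3|2"),
#'                         strict = FALSE)
#' split(names(es$kind), es$kind)
#' @export
classify_entities <- function(entities, strict = TRUE) {
  arch <- as_architectures(entities, strict = strict)
  labels <- vapply(arch, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("duplicate entity labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  names(arch) <- labels
  tokens <- lapply(arch, `[[`, "tokens")
  nblocks <- lengths(tokens)
  windows <- unique(unlist(all_windows(tokens)))
  kind <- ifelse(nblocks == 1L, "domain",
                 ifelse(labels %in% windows, "supradomain", "multidomain"))
  names(kind) <- labels
  structure(list(entities = arch, kind = kind, labels = labels),
            class = "ccs_entity_set")
}

#' @export
print.ccs_entity_set <- function(x, ...) {
  tab <- table(factor(x$kind, levels = c("domain", "supradomain", "multidomain")))
  cat("<entity set> ", length(x$labels), " architectures (",
      tab[["domain"]], " domains, ", tab[["supradomain"]], " supradomains, ",
      tab[["multidomain"]], " multidomains)\n", sep = "")
  invisible(x)
}

#' Occurrences of entity-set members inside a container architecture
#'
#' Enumerates every occurrence of every *other* entity-set member as a
#' contiguous token-subsequence of the container, in N-to-C order. Matching
#' is exact token-wise (repeat-marked tokens only match themselves) and
#' order-sensitive: `3|2` does not match inside `1|2|3`. Overlapping
#' occurrences are all reported; downstream network criteria decide
#' disjointness.
#'
#' @param container a `ccs_architecture` (or label present in `set`) with at
#'   least 2 blocks.
#' @param set a `ccs_entity_set`.
#' @return data frame with columns `label`, `start`, `end` (0-based,
#'   half-open block positions), ordered by `start` then `end`.
#' @export
component_occurrences <- function(container, set) {
  stopifnot(inherits(set, "ccs_entity_set"))
  if (is.character(container)) {
    container <- set$entities[[container]]
    if (is.null(container)) stop("container label not in entity set")
  }
  tk <- container$tokens
  b <- length(tk)
  if (b < 2L) stop("container must have at least 2 blocks")
  lab <- character(0); st <- integer(0); en <- integer(0)
  for (s in 1:b) {
    for (e in s:b) {
      w <- paste(tk[s:e], collapse = "|")
      if (w == container$label) next
      if (!is.na(match(w, set$labels))) {
        lab <- c(lab, w); st <- c(st, s - 1L); en <- c(en, e)
      }
    }
  }
  o <- order(st, en, lab)
  data.frame(label = lab[o], start = st[o], end = en[o],
             stringsAsFactors = FALSE)
}

#' Domain tokens spliced from a set of architectures
#'
#' The union of all block tokens over all architectures, including tokens
#' that never occur as standalone entities. Repeat-marked tokens (`"x&"`)
#' are kept distinct from their unmarked form. These tokens are the node set
#' of the SPX and SPAX networks.
#'
#' @param entities character labels, a list of `ccs_architecture`s, or a
#'   `ccs_entity_set`.
#' @param strict passed to [parse_ccs()] for character input.
#' @return character vector of unique tokens, in order of first appearance.
#' @export
spliced_domains <- function(entities, strict = TRUE) {
  if (inherits(entities, "ccs_entity_set")) arch <- entities$entities
  else arch <- as_architectures(entities, strict = strict)
  unique(unlist(lapply(arch, `[[`, "tokens"), use.names = FALSE))
}

#' Read an entity list with ages from a two-column TSV
#'
#' Expected dialect: `label<TAB>nd`, optional header line, `#` comments
#' ignored.
#'
#' @param path file path.
#' @param strict passed to [parse_ccs()].
#' @return list with `set` (a `ccs_entity_set`) and `ages` (named numeric of
#'   nd per label).
#' @export
read_entity_tsv <- function(path, strict = TRUE) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  if (!length(ln)) stop("no entity rows in ", path)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("expected two tab-separated columns")
  lab <- vapply(parts, `[[`, character(1), 1L)
  ndc <- vapply(parts, `[[`, character(1), 2L)
  if (is.na(suppressWarnings(as.numeric(ndc[1L])))) {  # header
    lab <- lab[-1L]; ndc <- ndc[-1L]
  }
  nd <- as.numeric(ndc)
  if (anyNA(nd)) stop("non-numeric nd value in ", path)
  set <- classify_entities(lab, strict = strict)
  list(set = set, ages = stats::setNames(nd, lab))
}

#' Read FSF descriptions from a SCOP dir.des file
#'
#' Parses the `dir.des.scop.txt` v1.75 dialect (tab-separated columns:
#' sunid, entry type, sccs, sid, description) and keeps superfamily (`sf`)
#' rows, whose sccs strings are FSF identifiers like `c.37.1`.
#'
#' @param path path to a dir.des.scop.txt-style file.
#' @return data frame with columns `sunid`, `sccs`, `description`.
#' @export
read_scop_des <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 5L && p[2L] == "sf", logical(1))
  parts <- parts[keep]
  data.frame(
    sunid = vapply(parts, `[[`, character(1), 1L),
    sccs = vapply(parts, `[[`, character(1), 3L),
    description = vapply(parts, `[[`, character(1), 5L),
    stringsAsFactors = FALSE)
}
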