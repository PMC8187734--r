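#' Relative ages (nd) from a rooted phylogenomic tree
#'
#' For each leaf the path count `c` is the number of internal nodes on the
#' root-to-leaf path, root included. Ages are min-max normalized,
#' `nd = (c - c_min) / (c_max - c_min)`, so the earliest-appearing leaf gets
#' nd exactly 0 and the latest 1. Branch lengths are ignored: on highly
#' imbalanced phylogenomic trees, only topology (node counts) carries the
#' chronology. If all path counts are equal (a perfectly balanced tree) every
#' nd is 0.
#'
#' nd values are rounded to 7 decimals, the precision at which time events
#' are distinguished, to avoid float noise splitting time slivers.
#'
#' @param tree an `ape::phylo` object, or a path to / text of a Newick tree.
#'   Must be rooted with at least 2 uniquely-labeled leaves.
#' @return named numeric vector of nd in `[0, 1]` per leaf label.
#' @examples
#' compute_nd(ape::read.tree(text = "(A,(B,(C,D)));"))
#' # A = 0, B = 0.5, C = D = 1
#' @export
compute_nd <- function(tree) {
  if (is.character(tree)) {
    tree <- if (length(tree) == 1L && file.exists(tree)) ape::read.tree(tree)
            else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick input")
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  depth <- integer(nnode)
  depth[root] <- 1L                            # root counts as internal node
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    depth[ch] <- depth[p] + (ch > ntip)        # tips inherit parent depth
  }
  cc <- depth[seq_len(ntip)]
  rng <- range(cc)
  nd <- if (rng[1L] == rng[2L]) rep(0, ntip) else (cc - rng[1L]) / diff(rng)
  stats::setNames(round(nd, 7L), tree$tip.label)
}

#' Discrete evolutionary timeline from an age map
#'
#' The distinct nd values, ascending, define the time events at which the
#' evolving networks are snapshotted. Values are compared after rounding to
#' 7 decimals.
#'
#' @param ages named numeric vector of nd values.
#' @return object of class `nd_timeline`: list with `events` (ascending
#'   distinct nd) and `n_events`.
#' @export
make_timeline <- function(ages) {
  if (!length(ages)) stop("empty age map")
  ev <- sort(unique(round(as.numeric(ages), 7L)))
  structure(list(events = ev, n_events = length(ev)), class = "nd_timeline")
}

#' @export
print.nd_timeline <- function(x, ...) {
  cat("<timeline> ", x$n_events, " time events, nd ",
      format(x$events[1L]), " .. ", format(x$events[x$n_events]), "\n", sep = "")
  invisible(x)
}

#' Event ordinal (1-based) of nd values on a timeline
#' @param timeline an `nd_timeline`.
#' @param nd numeric vector of ages.
#' @return integer vector of event ordinals.
#' @export
event_index <- function(timeline, nd) {
  idx <- match(round(nd, 7L), timeline$events)
  if (anyNA(idx)) stop("nd value not on the timeline")
  idx
}

#' Molecular clock parameters for FSF structures
#'
#' The published clock maps relative age to geological time as
#' `t = slope * nd + intercept` with t in billions of years ago (Gya). The
#' default slope -3.831 Gy per nd unit and intercept 3.628 Gya place the
#' origin of the chronology ~3.63 Gya. Note that the clock extrapolates past
#' the present for nd close to 1 (nd = 1 gives -0.203 Gya); such values are
#' flagged, not clamped.
#'
#' @param slope Gy per nd unit, must be negative.
#' @param intercept Gya at nd = 0.
#' @export
clock_params <- function(slope = -3.831, intercept = 3.628) {
  if (!(slope < 0)) stop("clock slope must be negative")
  structure(list(slope = slope, intercept = intercept), class = "fsf_clock")
}

#' Geological age in Gya for relative ages
#'
#' Affine transform of the clock: differences obey
#' `clock_age(a) - clock_age(b) = slope * (a - b)` exactly.
#'
#' @param nd numeric vector of relative ages in `[0, 1]`.
#' @param params a [clock_params()] object.
#' @return numeric vector of ages in Gya; a warning flags post-present
#'   (negative) values, an artifact of the published calibration.
#' @export
clock_age <- function(nd, params = clock_params()) {
  nd <- as.numeric(nd)
  if (any(is.na(nd) | nd < 0 | nd > 1))
    stop("nd must lie in [0, 1]")
  t <- params$slope * nd + params$intercept
  if (any(t < 0))
    warning("clock maps ", sum(t < 0), " age(s) past the present (t < 0); ",
            "values flagged, not clamped")
  t
}

#' Write an age map as TSV (`label<TAB>nd<TAB>gya`)
#' @param ages named numeric vector of nd.
#' @param path output path.
#' @param params clock used for the gya column.
#' @export
write_agemap_tsv <- function(ages, path, params = clock_params()) {
  gya <- suppressWarnings(clock_age(ages, params))
  utils::write.table(
    data.frame(label = names(ages), nd = as.numeric(ages), gya = gya),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
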