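#' Configuration of the synthetic entity-set generator
#'
#' The generator emulates the statistical shape of a genomic census of
#' domain organization: a pool of single domains born along a discrete
#' timeline, plus multidomains concatenating 2..`max_blocks` domain tokens
#' drawn with "rich-get-richer" preference for already-reused and older
#' domains, with occasional collapsed tandem-repeat (`&`) markers. Defaults
#' describe a census about one fifth the size of the published one (300
#' domains, 3000 multidomains, a ~150-event timeline versus 1643 domains,
#' 6162 entities, 169 events), keeping the full test suite inside seconds
#' while preserving the heavy-tailed reuse that the analysis assumes.
#'
#' @param n_domains number of single domains (>= 2).
#' @param n_multidomains number of multidomain architectures to draw.
#' @param max_blocks maximum blocks per multidomain (>= 2).
#' @param pref_strength preferential-reuse exponent; 0 = uniform reuse,
#'   1 = linear rich-get-richer (default).
#' @param repeat_prob per-block probability of the `&` repeat marker.
#' @param n_events target number of distinct time events on the age grid
#'   (>= 2).
#' @param seed RNG seed; generation is deterministic per seed.
#' @export
synth_config <- function(n_domains = 300L, n_multidomains = 3000L,
                         max_blocks = 6L, pref_strength = 1,
                         repeat_prob = 0.05, n_events = 150L, seed = 1L) {
  stopifnot(n_domains >= 2, n_multidomains >= 1, max_blocks >= 2,
            pref_strength >= 0, repeat_prob >= 0, repeat_prob < 1,
            n_events >= 2)
  structure(list(n_domains = as.integer(n_domains),
                 n_multidomains = as.integer(n_multidomains),
                 max_blocks = as.integer(max_blocks),
                 pref_strength = pref_strength,
                 repeat_prob = repeat_prob,
                 n_events = as.integer(n_events),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic entity set with ages
#'
#' Domains receive ages on a uniform nd grid of `n_events` values (biased
#' toward early birth, matching the early burst of domain innovation; at
#' least one domain sits at nd = 0, and none on the final grid step).
#' Each multidomain samples distinct domains with probability proportional
#' to `(reuse + 1)^pref_strength * (2 - nd)`, marks blocks as collapsed
#' repeats with probability `repeat_prob`, and is dated one grid step after
#' its youngest component — so every multidomain is strictly younger than
#' all of its components and old-to-new arcs are guaranteed (real
#' tree-derived data does not guarantee this; the contemporary flag absorbs
#' violations there).
#'
#' @param cfg a [synth_config()].
#' @return list with `set` (a `ccs_entity_set`) and `ages` (named nd
#'   vector over all entity labels).
#' @export
gen_entity_set <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(cfg$seed)

  grid <- seq(0, 1, length.out = cfg$n_events)
  if (cfg$n_events > length(grid))
    stop("infeasible: n_events exceeds the distinct achievable ages")
  ## domain birth events on grid positions 1..n_events-1 (never the last
  ## step, so component max age + one step stays on the grid)
  n_free <- cfg$n_events - 1L
  cls <- letters[1:12]
  dom_labels <- sprintf("%s.%d.1", cls[(seq_len(cfg$n_domains) - 1L) %% 12L + 1L],
                        (seq_len(cfg$n_domains) - 1L) %/% 12L + 1L)
  birth_idx <- sample.int(n_free, cfg$n_domains, replace = TRUE,
                          prob = exp(-3 * grid[seq_len(n_free)]))
  birth_idx[1L] <- 1L                       # anchor the origin at nd = 0
  dom_nd <- grid[birth_idx]

  reuse <- numeric(cfg$n_domains)
  md_labels <- character(cfg$n_multidomains)
  md_idx <- integer(cfg$n_multidomains)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (d in dom_labels) assign(d, TRUE, envir = seen)
  kept <- 0L
  for (j in seq_len(cfg$n_multidomains)) {
    for (try in 1:25) {
      b <- sample(2:cfg$max_blocks, 1L)
      w <- (reuse + 1)^cfg$pref_strength * (2 - dom_nd)
      pick <- sample.int(cfg$n_domains, min(b, cfg$n_domains), prob = w)
      tokens <- dom_labels[pick]
      amp <- stats::runif(length(tokens)) < cfg$repeat_prob
      tokens[amp] <- paste0(tokens[amp], "&")
      lab <- paste(tokens, collapse = "|")
      if (!exists(lab, envir = seen, inherits = FALSE)) {
        assign(lab, TRUE, envir = seen)
        kept <- kept + 1L
        md_labels[kept] <- lab
        md_idx[kept] <- max(birth_idx[pick]) + 1L
        reuse[pick] <- reuse[pick] + 1
        break
      }
    }
  }
  md_labels <- md_labels[seq_len(kept)]
  md_nd <- grid[md_idx[seq_len(kept)]]

  labels <- c(dom_labels, md_labels)
  ages <- stats::setNames(round(c(dom_nd, md_nd), 7L), labels)
  list(set = classify_entities(labels), ages = ages)
}

#' Generate a rooted tree with tunable imbalance
#'
#' Recursive splitting of the leaf set: with probability `imbalance` a split
#' peels a single leaf off (caterpillar-like), otherwise it divides the
#' leaves as evenly as possible. `imbalance = 1` yields a pure caterpillar
#' (`n - 1` distinct nd values under [compute_nd()]); `imbalance = 0` a
#' maximally balanced tree (all nd equal when `n` is a power of 2).
#'
#' @param n_leaves number of leaves (>= 2).
#' @param imbalance splitting bias in `[0, 1]`.
#' @param seed RNG seed.
#' @param labels optional leaf labels (default `t1..tn`).
#' @return a rooted `ape::phylo` tree.
#' @export
gen_tree <- function(n_leaves, imbalance = 1, seed = 1L, labels = NULL) {
  stopifnot(n_leaves >= 2, imbalance >= 0, imbalance <= 1)
  if (is.null(labels)) labels <- paste0("t", seq_len(n_leaves))
  stopifnot(length(labels) == n_leaves, !anyDuplicated(labels))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  build <- function(lv) {
    n <- length(lv)
    if (n == 1L) return(lv)
    if (n == 2L) return(paste0("(", lv[1L], ",", lv[2L], ")"))
    k <- if (stats::runif(1) < imbalance) 1L else n %/% 2L
    paste0("(", build(lv[seq_len(k)]), ",", build(lv[-seq_len(k)]), ")")
  }
  ape::read.tree(text = paste0(build(labels), ";"))
}

#' Write a synthetic entity set as the pipeline's entity TSV
#' @param synth list from [gen_entity_set()].
#' @param path output path.
#' @export
write_entity_tsv <- function(synth, path) {
  utils::write.table(
    data.frame(label = names(synth$ages), nd = as.numeric(synth$ages)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
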