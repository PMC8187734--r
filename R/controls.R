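#' Specification of a null-model control network
#'
#' Three null models are matched in size to the evolving-network events:
#' preferential attachment (`barabasi`, probability of attachment to node i
#' proportional to `k_i^alpha_pa`), age-extended preferential attachment
#' (`barabasi_age`, proportional to `k_i^alpha_pa * l_i^beta_age` with the
#' node age `l_i` counted in events since addition and bucketed into
#' `aging_bins`; positive `beta_age` favors older nodes), and the
#' Erdos-Renyi random graph (`erdos_renyi`, `m_edges` uniform edges).
#'
#' @param model one of `"barabasi"`, `"barabasi_age"`, `"erdos_renyi"`.
#' @param n number of nodes (>= 1).
#' @param m_edges edges per step (PA models, default 1) or total edge count
#'   (Erdos-Renyi, required).
#' @param alpha_pa preferential-attachment exponent (1 = linear PA).
#' @param beta_age aging exponent (PA-age only).
#' @param aging_bins number of age buckets (default `n`, i.e. one per step).
#' @param seed RNG seed; identical specs generate identical graphs.
#' @export
control_spec <- function(model = c("barabasi", "barabasi_age", "erdos_renyi"),
                         n, m_edges = NULL, alpha_pa = 1, beta_age = 0,
                         aging_bins = NULL, seed = 1L) {
  model <- match.arg(model)
  if (!(is.numeric(n) && n >= 1)) stop("n must be >= 1")
  if (model == "erdos_renyi") {
    if (is.null(m_edges)) stop("erdos_renyi needs m_edges")
    if (m_edges > n * (n - 1) / 2)
      stop("infeasible: m_edges exceeds n(n-1)/2")
  }
  structure(list(model = model, n = as.integer(n),
                 m_edges = m_edges %||% 1L, alpha_pa = alpha_pa,
                 beta_age = beta_age,
                 aging_bins = as.integer(aging_bins %||% max(n, 1L)),
                 seed = as.integer(seed)),
            class = "control_spec")
}

#' Generate a control network from a specification
#'
#' Seeded and deterministic: the same spec always yields the same edge list.
#'
#' @param spec a [control_spec()].
#' @return an `igraph` graph (directed for the PA models, following their
#'   growth process; undirected for Erdos-Renyi).
#' @export
generate_control <- function(spec) {
  stopifnot(inherits(spec, "control_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  switch(spec$model,
    barabasi = igraph::sample_pa(spec$n, power = spec$alpha_pa,
                                 m = spec$m_edges, directed = TRUE),
    barabasi_age = igraph::sample_pa_age(spec$n, pa.exp = spec$alpha_pa,
                                         aging.exp = spec$beta_age,
                                         m = spec$m_edges,
                                         aging.bin = spec$aging_bins,
                                         directed = TRUE),
    erdos_renyi = igraph::sample_gnm(spec$n, spec$m_edges, directed = FALSE))
}

#' Size-matched control series along an evolving network's timeline
#'
#' One control graph per time event with the same node count as the
#' cumulative network at that event (and, for Erdos-Renyi, the same
#' unweighted arc count). Per-event seeds are derived from `seed` so the
#' series is reproducible.
#'
#' @param net an `evolving_network`.
#' @param model control model, see [control_spec()].
#' @param alpha_pa,beta_age,aging_bins PA parameters.
#' @param seed base seed.
#' @return list of `igraph` graphs, one per event.
#' @export
match_series <- function(net, model = c("barabasi", "barabasi_age",
                                        "erdos_renyi"),
                         alpha_pa = 1, beta_age = 0, aging_bins = NULL,
                         seed = 1L) {
  stopifnot(inherits(net, "evolving_network"))
  model <- match.arg(model)
  ev <- net$timeline$events
  lapply(seq_along(ev), function(e) {
    n <- sum(net$nodes <= ev[e])
    m <- sum(net$arcs$age <= ev[e])
    if (n <= 1L) return(igraph::make_empty_graph(n, directed = model != "erdos_renyi"))
    spec <- switch(model,
      erdos_renyi = control_spec("erdos_renyi", n,
                                 m_edges = min(m, n * (n - 1) / 2),
                                 seed = seed + e),
      barabasi = control_spec("barabasi", n,
                              m_edges = max(1L, round(m / n)),
                              alpha_pa = alpha_pa, seed = seed + e),
      barabasi_age = control_spec("barabasi_age", n,
                                  m_edges = max(1L, round(m / n)),
                                  alpha_pa = alpha_pa, beta_age = beta_age,
                                  aging_bins = aging_bins %||% n,
                                  seed = seed + e))
    generate_control(spec)
  })
}
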