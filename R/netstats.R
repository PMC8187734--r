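#' Log-linear regression estimate of the power-law slope
#'
#' Least-squares fit of `log10 P(k)` on `log10 k` over the observed degrees
#' with nonzero frequency, where `P(k)` is the raw (unbinned) frequency of
#' degree `k` normalized by the number of nodes. `gamma` is the absolute
#' slope; a large gamma together with a large R-squared indicates strong
#' scale-free behavior.
#'
#' @param degrees multiset (numeric vector) of positive degrees; zeros and
#'   non-positive values are dropped before fitting.
#' @return list with `gamma`, `r2` and `defined`. Fewer than 3 distinct
#'   positive degree values make the fit undefined (`defined = FALSE`,
#'   gamma/r2 `NA`): the statistic series records a gap, not an error.
#' @examples
#' fit_regression(rep(c(1, 2, 4), c(16, 4, 1)))  # gamma = 2, r2 = 1
#' @export
fit_regression <- function(degrees) {
  degrees <- degrees[!is.na(degrees)]
  n <- length(degrees)
  k <- degrees[degrees > 0]
  tab <- table(k)
  if (length(tab) < 3L)
    return(list(gamma = NA_real_, r2 = NA_real_, defined = FALSE))
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab) / n)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(gamma = abs(unname(slope)),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       defined = TRUE)
}

#' Discrete power-law fit by maximum likelihood
#'
#' Fits `P(X = x) ~ x^-alpha` above a lower cutoff `xmin` chosen by
#' Kolmogorov-Smirnov distance minimization (the standard plfit procedure,
#' via [igraph::fit_power_law()]), and reports the KS distance against the
#' fitted distribution, the plfit significance approximation of its p-value
#' (null hypothesis: the data above xmin were drawn from the fitted power
#' law) and the maximized log-likelihood.
#'
#' @param degrees numeric vector with at least 2 values >= 1; degenerate
#'   (all-equal) input is an error.
#' @param xmin force a lower cutoff instead of KS selection (`NULL` scans).
#' @return object of class `power_law_fit`: list with `alpha`, `xmin`,
#'   `ks_fit`, `ks_p`, `loglik`, `n_tail`.
#' @export
fit_mle <- function(degrees, xmin = NULL) {
  x <- degrees[!is.na(degrees) & degrees >= 1]
  x <- as.integer(round(x))
  if (length(x) < 2L) stop("need at least 2 degree values >= 1")
  if (length(unique(x)) < 2L) stop("degenerate degree data (all values equal)")
  f <- igraph::fit_power_law(x, xmin = xmin, implementation = "plfit",
                             p.value = TRUE)
  structure(list(alpha = f$alpha, xmin = f$xmin, ks_fit = f$KS.stat,
                 ks_p = f$KS.p, loglik = f$logLik,
                 n_tail = sum(x >= f$xmin)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power-law fit> alpha = %.3f (xmin = %g, tail n = %d), KS D = %.4f, KS p = %.4f\n",
              x$alpha, x$xmin, x$n_tail, x$ks_fit, x$ks_p))
  invisible(x)
}

#' Rank version of von Neumann's ratio test for randomness (Bartels)
#'
#' With ranks `R_i` (midranks for ties) of the series, the statistic is
#' `RVN = sum (R_i - R_{i+1})^2 / sum (R_i - (n+1)/2)^2`. Under the
#' randomness null its expectation is 2; values near 0 indicate trend, near
#' 4 oscillation. The two-sided p-value uses the beta approximation on
#' `[0, 4]` whose variance matches
#' `sigma^2 = 4(n-2)(5n^2 - 2n - 9) / (5n(n+1)(n-1)^2)`.
#' Being rank-based, the statistic is invariant under strictly monotone
#' transformations of the series.
#'
#' @param series ordered numeric values, `n >= 4`, not all equal.
#' @return list with `rvn`, `p`, `n`.
#' @examples
#' rvn_test(1:10)  # rvn = 9/82.5, trend p << 0.05
#' @export
rvn_test <- function(series) {
  x <- as.numeric(series)
  if (anyNA(x)) stop("series contains NA")
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  r <- rank(x)                                  # midranks for ties
  den <- sum((r - (n + 1) / 2)^2)
  if (den == 0) stop("constant series: RVN undefined")
  rvn <- sum(diff(r)^2) / den
  shape <- (5 * n * (n + 1) * (n - 1)^2) / (2 * (n - 2) * (5 * n^2 - 2 * n - 9)) - 0.5
  pb <- stats::pbeta(rvn / 4, shape, shape)
  list(rvn = rvn, p = min(1, 2 * min(pb, 1 - pb)), n = n)
}

#' Per-event preferential-attachment and randomness statistics
#'
#' For every time event of an evolving network, fits the cumulative weighted
#' indegree distribution (regression gamma/R2 and discrete MLE with KS
#' cutoff), secondarily the outdegree distribution (regression only, the
#' less representative side), and applies the rank von Neumann randomness
#' test to the weighted total-degree sequence ordered by node age (ties by
#' label). Events where a statistic is undefined (too few distinct degrees,
#' degenerate tails, constant series) are recorded as `NA` gaps.
#'
#' @param net an `evolving_network`.
#' @param events event ordinals (default all).
#' @return data frame, one row per event: `event`, `nd`, `n_nodes`,
#'   `n_arcs`, `gamma`, `r2`, `alpha`, `xmin`, `ks_fit`, `ks_p`, `loglik`,
#'   `gamma_out`, `r2_out`, `rvn`, `rvn_p`.
#' @export
stat_series <- function(net, events = seq_len(net$timeline$n_events)) {
  stopifnot(inherits(net, "evolving_network"))
  ds <- degree_series(net, events)
  rows <- vector("list", length(events))
  for (k in seq_along(events)) {
    e <- events[k]
    d <- ds[ds$event == e, , drop = FALSE]
    na <- sum(net$arcs$age <= net$timeline$events[e])
    reg_in <- fit_regression(d$w_indegree)
    reg_out <- fit_regression(d$w_outdegree)
    mle <- tryCatch(fit_mle(d$w_indegree), error = function(err) NULL)
    ord <- order(d$nd, d$label)
    tot <- (d$w_indegree + d$w_outdegree)[ord]
    rv <- tryCatch(rvn_test(tot), error = function(err) NULL)
    rows[[k]] <- data.frame(
      event = e, nd = d$nd_event[1L], n_nodes = nrow(d), n_arcs = na,
      gamma = reg_in$gamma, r2 = reg_in$r2,
      alpha = if (is.null(mle)) NA_real_ else mle$alpha,
      xmin = if (is.null(mle)) NA_real_ else mle$xmin,
      ks_fit = if (is.null(mle)) NA_real_ else mle$ks_fit,
      ks_p = if (is.null(mle)) NA_real_ else mle$ks_p,
      loglik = if (is.null(mle)) NA_real_ else mle$loglik,
      gamma_out = reg_out$gamma, r2_out = reg_out$r2,
      rvn = if (is.null(rv)) NA_real_ else rv$rvn,
      rvn_p = if (is.null(rv)) NA_real_ else rv$p)
  }
  out <- do.call(rbind, rows)
  attr(out, "criterion") <- net$criterion
  out
}

#' Write a statistic series as TSV
#' @param stats data frame from [stat_series()].
#' @param path output path.
#' @export
write_stat_series_tsv <- function(stats, path) {
  df <- cbind(stats[, c("event", "nd")],
              criterion = attr(stats, "criterion") %||% NA_character_,
              stats[, setdiff(names(stats), c("event", "nd"))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
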