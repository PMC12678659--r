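# Bootstrap accuracy and stability of estimated networks:
# case-dropping correlation stability (CS) and nonparametric edge CIs.

fit_estimator <- function(pnl, estimator, fit_args) {
  if (estimator == "ising") {
    do.call(ising_fit, c(list(data = pnl), fit_args))
  } else {
    do.call(clpn_fit, c(list(panel = pnl), fit_args))
  }
}

network_centrality <- function(fit, index, partition = NULL) {
  if (inherits(fit, "ising_net")) {
    switch(index,
      strength = strength(fit),
      expected_influence = expected_influence(fit),
      bridge_strength = {
        stopifnot(!is.null(partition))
        bridge_metrics(fit, partition)$bridge_strength
      },
      bridge_expected_influence = {
        stopifnot(!is.null(partition))
        bridge_metrics(fit, partition)$bridge_expected_influence
      },
      stop("unknown undirected centrality index: ", index))
  } else {
    tab <- in_out_indices(fit)
    if (!index %in% c("in_strength", "out_strength", "in_ei", "out_ei"))
      stop("unknown directed centrality index: ", index)
    tab[[index]]
  }
}

network_weights <- function(fit) {
  if (inherits(fit, "ising_net")) fit$weights else fit$weights
}

#' Case-dropping bootstrap of centrality stability
#'
#' For each drop proportion q, repeatedly subsamples ceiling((1-q)*n)
#' subjects without replacement, re-estimates the network, and records the
#' Spearman correlation between the subsample node centralities and the
#' full-sample centralities. Subsamples that produce a constant item column
#' are redrawn (up to 10 retries) before being skipped.
#'
#' @param panel A complete \code{"binary_panel"}.
#' @param estimator \code{"ising"} (wave-1 cross-sectional fit) or
#'   \code{"clpn"}.
#' @param index Centrality to track: for \code{"ising"} one of
#'   \code{"strength"}, \code{"expected_influence"},
#'   \code{"bridge_strength"}, \code{"bridge_expected_influence"}; for
#'   \code{"clpn"} one of \code{"in_strength"}, \code{"out_strength"},
#'   \code{"in_ei"}, \code{"out_ei"}.
#' @param drop_grid Drop proportions tested (default 0.05 to 0.75 by 0.05).
#' @param n_boot Subsamples per proportion (default 1000).
#' @param seed Integer seed; the report is reproducible bit-for-bit.
#' @param group Optional group label to restrict the panel first.
#' @param fit_args Named list of extra arguments for the estimator
#'   ([ising_fit()] or [clpn_fit()]).
#' @return Object of class \code{"case_drop"}: \code{correlations} (named
#'   list, one numeric vector per drop proportion; NA where degenerate),
#'   \code{drop_grid}, \code{index}, \code{estimator}, \code{n_boot},
#'   \code{seed}, \code{n_skipped}.
#' @seealso [cs_coefficient()]
#' @export
case_drop_bootstrap <- function(panel, estimator = c("ising", "clpn"), index,
                                drop_grid = seq(0.05, 0.75, by = 0.05),
                                n_boot = 1000, seed = 1L, group = NULL,
                                fit_args = list()) {
  estimator <- match.arg(estimator)
  if (n_boot < 1) stop("case_drop_bootstrap: n_boot must be >= 1")
  pnl <- panel
  if (!is.null(group)) pnl <- panel_subset(pnl, pnl$group == group)
  n <- n_subjects(pnl)
  partition <- codebook_partition(pnl$codebook)

  full_fit <- fit_estimator(pnl, estimator, fit_args)
  full_cent <- network_centrality(full_fit, index, partition)
  degenerate_full <- stats::sd(full_cent) == 0
  if (degenerate_full)
    warning("case_drop_bootstrap: full-sample centralities are constant; ",
            "correlations undefined")

  cors <- vector("list", length(drop_grid))
  names(cors) <- as.character(drop_grid)
  n_skipped <- 0L
  for (qi in seq_along(drop_grid)) {
    q <- drop_grid[qi]
    m <- ceiling((1 - q) * n)
    if (m < 3) stop("case_drop_bootstrap: drop proportion ", q,
                    " leaves fewer than 3 subjects")
    out <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      sub_fit <- NULL
      for (try in 0:10) {
        sd_b <- derive_seed(seed, qi * 1000003L + b * 101L + try)
        old <- local_seed(sd_b)
        idx <- sample.int(n, m)
        restore_seed(old)
        sub_fit <- tryCatch(
          fit_estimator(panel_subset(pnl, idx), estimator, fit_args),
          error = function(e) NULL)
        if (!is.null(sub_fit)) break
      }
      if (is.null(sub_fit)) { n_skipped <- n_skipped + 1L; next }
      sub_cent <- network_centrality(sub_fit, index, partition)
      if (degenerate_full || stats::sd(sub_cent) == 0) next
      out[b] <- stats::cor(full_cent, sub_cent, method = "spearman")
    }
    cors[[qi]] <- out
  }
  structure(list(correlations = cors, drop_grid = drop_grid, index = index,
                 estimator = estimator, n_boot = n_boot,
                 seed = as.integer(seed), n_skipped = n_skipped),
            class = "case_drop")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion q at which the subsample-vs-full-sample
#' centrality correlation is at least \code{r_min} with probability at least
#' \code{confidence} (estimated as the fraction of bootstrap correlations
#' reaching \code{r_min}); 0 if no tested proportion qualifies. Values above
#' 0.25 are conventionally interpretable, above 0.5 highly stable.
#'
#' @param correlations A \code{"case_drop"} object, or a named list of
#'   numeric correlation vectors whose names are the drop proportions.
#' @param r_min Correlation threshold (default 0.7).
#' @param confidence Required probability (default 0.95).
#' @return Scalar CS-coefficient.
#' @export
cs_coefficient <- function(correlations, r_min = 0.7, confidence = 0.95) {
  if (inherits(correlations, "case_drop")) {
    props <- correlations$drop_grid
    samples <- correlations$correlations
  } else {
    if (length(correlations) == 0) stop("cs_coefficient: empty input")
    props <- as.numeric(names(correlations))
    if (anyNA(props))
      stop("cs_coefficient: list names must be the drop proportions")
    samples <- correlations
  }
  if (length(samples) == 0) stop("cs_coefficient: empty input")
  ok <- vapply(samples, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0 && mean(v >= r_min) >= confidence
  }, logical(1))
  if (!any(ok)) 0 else max(props[ok])
}

#' @export
print.case_drop <- function(x, ...) {
  cat(sprintf("Case-dropping bootstrap: %s / %s, %d subsamples per proportion\n",
              x$estimator, x$index, x$n_boot))
  med <- vapply(x$correlations, function(v) stats::median(v, na.rm = TRUE),
                numeric(1))
  print(data.frame(drop = x$drop_grid, median_cor = round(med, 3),
                   row.names = NULL))
  cat(sprintf("  CS-coefficient (r >= 0.7, 95%%): %.2f\n", cs_coefficient(x)))
  invisible(x)
}

#' Nonparametric bootstrap confidence intervals for edge weights
#'
#' Resamples subjects with replacement, re-estimates the network, and
#' reports 2.5/97.5 percentile intervals per edge, plus an indicator of
#' whether each edge's CI overlaps the next edge's when ranked by absolute
#' estimate (overlapping CIs mean the edge-strength order is uncertain).
#' LASSO zeros are kept as exact zeros in the bootstrap distributions.
#'
#' @inheritParams case_drop_bootstrap
#' @return Object of class \code{"edge_ci"}: data.frame \code{edges} with
#'   from, to, estimate, lower, upper, overlaps_next (ranked by
#'   |estimate|), plus \code{n_boot} and \code{seed}.
#' @export
edge_ci_bootstrap <- function(panel, estimator = c("ising", "clpn"),
                              n_boot = 1000, seed = 1L, group = NULL,
                              fit_args = list()) {
  estimator <- match.arg(estimator)
  pnl <- panel
  if (!is.null(group)) pnl <- panel_subset(pnl, pnl$group == group)
  n <- n_subjects(pnl)

  full_fit <- fit_estimator(pnl, estimator, fit_args)
  W <- network_weights(full_fit)
  p <- nrow(W)
  if (estimator == "ising") {
    idx <- which(upper.tri(W), arr.ind = TRUE)
  } else {
    idx <- as.matrix(expand.grid(row = seq_len(p), col = seq_len(p)))
  }
  est <- W[idx]

  boot <- matrix(NA_real_, n_boot, nrow(idx))
  n_skipped <- 0L
  for (b in seq_len(n_boot)) {
    fit_b <- NULL
    for (try in 0:10) {
      old <- local_seed(derive_seed(seed, b * 7919L + try))
      rs <- sample.int(n, n, replace = TRUE)
      restore_seed(old)
      fit_b <- tryCatch(
        fit_estimator(panel_subset(pnl, rs), estimator, fit_args),
        error = function(e) NULL)
      if (!is.null(fit_b)) break
    }
    if (is.null(fit_b)) { n_skipped <- n_skipped + 1L; next }
    boot[b, ] <- network_weights(fit_b)[idx]
  }
  qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  items <- colnames(W) %||% paste0("V", seq_len(p))
  edges <- data.frame(from = items[idx[, 1]], to = items[idx[, 2]],
                      estimate = est, lower = qs[1, ], upper = qs[2, ],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-abs(edges$estimate)), , drop = FALSE]
  k <- nrow(edges)
  edges$overlaps_next <- c(
    if (k > 1) edges$lower[-k] <= edges$upper[-1] &
               edges$lower[-1] <= edges$upper[-k] else logical(0),
    NA)
  rownames(edges) <- NULL
  structure(list(edges = edges, estimator = estimator, n_boot = n_boot,
                 seed = as.integer(seed), n_skipped = n_skipped),
            class = "edge_ci")
}

#' @export
print.edge_ci <- function(x, ...) {
  cat(sprintf("Bootstrapped edge CIs (%s, %d resamples):\n",
              x$estimator, x$n_boot))
  print(utils::head(x$edges, 10), row.names = FALSE)
  if (nrow(x$edges) > 10) cat("  ...", nrow(x$edges) - 10, "more edges\n")
  invisible(x)
}
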