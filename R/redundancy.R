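#' Test equality of two dependent overlapping correlations
#'
#' Two-sided test of H0: rho_ik = rho_jk when both correlations share the
#' variable k, using the Hittner, May and Silver back-transformed-z variant
#' of Dunn and Clark's statistic. The dependence between r_ik and r_jk enters
#' through the correlation r_ij of the two non-shared variables.
#'
#' @param r_ik,r_jk The two correlations being compared (shared variable k).
#' @param r_ij Correlation between variables i and j.
#' @param n Sample size (> 3).
#' @return Two-sided p-value.
#' @export
dependent_correlation_test <- function(r_ik, r_jk, r_ij, n) {
  if (n <= 3) stop("dependent_correlation_test: n must exceed 3")
  if (abs(r_ik) >= 1 || abs(r_jk) >= 1)
    stop("dependent_correlation_test: compared correlations must lie strictly in (-1, 1)")
  if (abs(r_ij) > 1)
    stop("dependent_correlation_test: |r_ij| cannot exceed 1")
  if (r_ik == r_jk) return(1)   # zero statistic, e.g. exactly duplicated items
  z_ik <- atanh(r_ik)
  z_jk <- atanh(r_jk)
  rbar <- tanh((z_ik + z_jk) / 2)
  covar <- (r_ij * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_ij^2)) /
    (1 - rbar^2)^2
  covar <- min(covar, 1 - 1e-12)
  z <- (z_ik - z_jk) * sqrt((n - 3) / (2 - 2 * covar))
  2 * stats::pnorm(-abs(z))
}

#' Screen item pairs for redundancy (goldbricker)
#'
#' For every item pair whose absolute correlation reaches \code{cor_min},
#' compares the two items' correlations with each remaining item via
#' [dependent_correlation_test()]. A pair is flagged as likely redundant
#' (measuring the same construct) when fewer than
#' \code{proportion_threshold} of those comparisons are significant at
#' \code{p_threshold}.
#'
#' @param data \code{n x p} binary (0/1) matrix with column names; p >= 3.
#' @param p_threshold Significance level per comparison (default 0.05).
#' @param proportion_threshold Flag a pair when the significant fraction is
#'   below this (default 0.25).
#' @param cor_min Minimum absolute pair correlation to consider (default 0.5).
#' @return Object of class \code{"redundancy_report"}: data.frame of tested
#'   pairs (correlation, proportion of significantly different correlations,
#'   flag) and \code{suggested_reductions}.
#' @export
goldbricker <- function(data, p_threshold = 0.05, proportion_threshold = 0.25,
                        cor_min = 0.5) {
  data <- as.matrix(data)
  p <- ncol(data)
  if (p < 3) stop("goldbricker: need at least 3 items")
  if (is.null(colnames(data))) colnames(data) <- paste0("V", seq_len(p))
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0))
    stop("goldbricker: constant column(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "))
  n <- nrow(data)
  R <- stats::cor(data)   # Pearson phi on the 0/1 items

  rows <- list()
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (abs(R[i, j]) < cor_min) next
      ks <- setdiff(seq_len(p), c(i, j))
      pv <- vapply(ks, function(k)
        dependent_correlation_test(R[i, k], R[j, k], R[i, j], n), numeric(1))
      prop_sig <- mean(pv < p_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        item_i = colnames(data)[i], item_j = colnames(data)[j],
        correlation = R[i, j], prop_significant = prop_sig,
        flagged = prop_sig < proportion_threshold,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
  else data.frame(item_i = character(), item_j = character(),
                  correlation = numeric(), prop_significant = numeric(),
                  flagged = logical(), stringsAsFactors = FALSE)
  structure(
    list(pairs = pairs,
         suggested_reductions = if (nrow(pairs))
           sprintf("%s & %s", pairs$item_i[pairs$flagged],
                   pairs$item_j[pairs$flagged]) else character(),
         p_threshold = p_threshold,
         proportion_threshold = proportion_threshold,
         cor_min = cor_min, n = n),
    class = "redundancy_report")
}

#' @export
print.redundancy_report <- function(x, ...) {
  cat(sprintf(
    "Redundancy screen (|r| >= %.2f gate, p < %.2f, flag if < %.0f%% differ):\n",
    x$cor_min, x$p_threshold, 100 * x$proportion_threshold))
  if (nrow(x$pairs) == 0) {
    cat("  no pairs passed the correlation gate\n")
  } else {
    print(x$pairs, row.names = FALSE)
  }
  if (length(x$suggested_reductions))
    cat("  suggested reductions:",
        paste(x$suggested_reductions, collapse = "; "), "\n")
  else cat("  no suggested reduction\n")
  invisible(x)
}
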