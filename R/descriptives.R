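#' Percentage from counts, table-style rounding
#'
#' @param numerator,denominator Non-negative counts, numerator <= denominator,
#'   denominator > 0.
#' @return 100 * numerator / denominator, rounded half-up to one decimal.
#' @export
proportion_pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("proportion_pct: denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("proportion_pct: need 0 <= numerator <= denominator")
  round_half_up(100 * numerator / denominator, 1)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson chi-square (no continuity correction) on an r x c count
#' table, as used for categorical group comparisons in descriptive tables.
#'
#' @param counts An r x c matrix of non-negative counts, at least 2 x 2.
#' @return List with \code{statistic}, \code{df} and \code{p_value}.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("pearson_chi_square: table must be at least 2 x 2")
  if (any(counts < 0)) stop("pearson_chi_square: negative counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("pearson_chi_square: zero row or column margin")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Cronbach's alpha for a set of binary (or numeric) items
#'
#' alpha = k/(k-1) * (1 - sum of item variances / variance of the sum score).
#'
#' @param items \code{n x k} numeric matrix, k >= 2.
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  k <- ncol(items)
  if (k < 2) stop("cronbach_alpha: need at least 2 items")
  if (anyNA(items)) stop("cronbach_alpha: missing values not allowed")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0)
    stop("cronbach_alpha: total-score variance is zero; alpha undefined")
  item_vars <- apply(items, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Group difference in a continuous variable via linear regression
#'
#' Regresses the value on a group indicator; the slope equals the difference
#' in group means and its two-sided p-value is reported (identical to an
#' equal-variance two-sample t-test).
#'
#' @param values Numeric vector.
#' @param group Vector of two group labels, one per value.
#' @return List with \code{difference} (mean of second level minus first,
#'   levels in factor order) and \code{p_value}.
#' @export
group_mean_test <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) != 2)
    stop("group_mean_test: exactly two groups required")
  if (any(table(group) < 2))
    stop("group_mean_test: each group needs at least 2 observations")
  fit <- stats::lm(values ~ group)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2 || is.na(sm[2, 4]))
    return(list(difference = unname(stats::coef(fit)[2]), p_value = 1))
  list(difference = unname(sm[2, 1]), p_value = unname(sm[2, 4]))
}

#' EURO-D caseness from the 12 symptom items
#'
#' Caseness is a symptom count of four or more out of twelve, the
#' conventional cut-off for probable depression on this scale.
#'
#' @param symptoms \code{n x 12} 0/1 matrix of depressive-symptom items.
#' @param cutoff Minimum symptom count for caseness (default 4).
#' @return Integer 0/1 vector of caseness indicators.
#' @export
eurod_caseness <- function(symptoms, cutoff = 4) {
  as.integer(rowSums(as.matrix(symptoms)) >= cutoff)
}

#' Group-comparison descriptives for a two-wave panel
#'
#' Builds a descriptive table in the style of a cohort characteristics table:
#' per item and wave, counts and percentages by group with a Pearson
#' chi-square p-value for group equality, plus depressive caseness per wave
#' and Cronbach's alpha of the symptom items per wave.
#'
#' @param panel A complete \code{"binary_panel"}.
#' @return List with \code{table} (data.frame: item, wave, count/percent per
#'   group, chi-square p), \code{caseness} and \code{alpha} per wave, and
#'   group sizes.
#' @export
describe_panel <- function(panel) {
  stopifnot(inherits(panel, "binary_panel"))
  if (anyNA(panel$values)) stop("describe_panel: run apply_inclusion_filter first")
  cb <- panel$codebook
  gd <- panel$group == "diabetes"
  n_d <- sum(gd); n_n <- sum(!gd)
  if (n_d == 0 || n_n == 0) stop("describe_panel: both groups must be non-empty")
  dep_idx <- which(cb$item_group == "depression")

  rows <- list()
  for (w in 1:2) {
    X <- panel_wave(panel, w)
    for (j in seq_along(cb$item_ids)) {
      cd <- sum(X[gd, j]); cn <- sum(X[!gd, j])
      tab <- rbind(c(cd, n_d - cd), c(cn, n_n - cn))
      p <- if (any(colSums(tab) == 0)) NA_real_ else pearson_chi_square(tab)$p_value
      rows[[length(rows) + 1L]] <- data.frame(
        item = cb$item_ids[j], name = cb$item_names[j], wave = w,
        n_diabetes = cd, pct_diabetes = proportion_pct(cd, n_d),
        n_no_diabetes = cn, pct_no_diabetes = proportion_pct(cn, n_n),
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)

  caseness <- lapply(1:2, function(w) {
    cs <- eurod_caseness(panel_wave(panel, w)[, dep_idx, drop = FALSE])
    cd <- sum(cs[gd]); cn <- sum(cs[!gd])
    list(wave = w,
         n_diabetes = cd, pct_diabetes = proportion_pct(cd, n_d),
         n_no_diabetes = cn, pct_no_diabetes = proportion_pct(cn, n_n),
         p_value = pearson_chi_square(
           rbind(c(cd, n_d - cd), c(cn, n_n - cn)))$p_value)
  })
  alpha <- vapply(1:2, function(w)
    cronbach_alpha(panel_wave(panel, w)[, dep_idx, drop = FALSE]), numeric(1))

  list(table = tab, caseness = caseness, alpha = alpha,
       n_diabetes = n_d, n_no_diabetes = n_n)
}
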