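#' Nodewise L1-penalized logistic regression path
#'
#' Fits the lasso path of one node regressed on all remaining columns
#' (unpenalized intercept, predictors kept on their raw 0/1 scale). The
#' penalty grid is log-spaced from the smallest lambda that zeroes every
#' slope down to \code{lambda_min_ratio} times it.
#'
#' @param data \code{n x p} binary matrix.
#' @param node Column index of the response node.
#' @param nlambda Grid size (default 100).
#' @param lambda_min_ratio Ratio of smallest to largest lambda (default 0.001).
#' @return List with \code{lambda}, \code{coefficients} ((p-1) x nlambda
#'   matrix, rows named by predictor), \code{intercepts}, \code{loglik},
#'   \code{df} (nonzero slopes per lambda) and \code{node}.
#' @export
nodewise_logistic_path <- function(data, node, nlambda = 100,
                                   lambda_min_ratio = 0.001) {
  data <- as.matrix(data)
  y <- data[, node]
  if (stats::var(y) == 0)
    stop("nodewise_logistic_path: node column is constant")
  X <- data[, -node, drop = FALSE]
  fit <- glmnet::glmnet(X, y, family = "binomial", standardize = FALSE,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  beta <- as.matrix(fit$beta)
  # binomial deviance = -2*loglik (saturated loglik = 0 for 0/1 response)
  loglik <- -0.5 * fit$nulldev * (1 - fit$dev.ratio)
  list(lambda = fit$lambda, coefficients = beta,
       intercepts = as.numeric(fit$a0), loglik = loglik,
       df = fit$df, node = node)
}

#' Select a penalized fit by extended BIC
#'
#' EBIC = -2*loglik + k*log(n) + 2*gamma*k*log(p_cand), with k the number of
#' nonzero slopes and p_cand the number of candidate predictors. Ties go to
#' the sparser (larger lambda) candidate.
#'
#' @param path Output of [nodewise_logistic_path()].
#' @param n Sample size.
#' @param p_cand Number of candidate predictors (p - 1 for nodewise Ising).
#' @param gamma EBIC hyperparameter (0 recovers plain BIC).
#' @return List with \code{coefficients} (named slope vector),
#'   \code{intercept}, \code{lambda}, \code{ebic} and \code{index}.
#' @export
ebic_select <- function(path, n, p_cand, gamma = 0.25) {
  k <- path$df
  ebic <- -2 * path$loglik + k * log(n) + 2 * gamma * k * log(p_cand)
  # glmnet lambdas are decreasing, so the first minimum is the sparsest
  idx <- which.min(ebic)
  list(coefficients = path$coefficients[, idx],
       intercept = path$intercepts[idx],
       lambda = path$lambda[idx],
       ebic = ebic[idx], index = idx)
}

#' Assemble nodewise fits into a symmetric Ising network
#'
#' The nodewise regressions give two estimates per pair: the coefficient of
#' j in the regression of i and vice versa. Under the AND rule an edge exists
#' only if both are nonzero; under OR if either is. The edge weight is the
#' mean of the two coefficients (absent coefficients counted as 0 under OR).
#'
#' @param coef_matrix \code{p x p} matrix with \code{[i, j]} the coefficient
#'   of predictor j in the regression of node i (zero diagonal).
#' @param rule \code{"AND"} (default) or \code{"OR"}.
#' @return Symmetric \code{p x p} weight matrix with zero diagonal.
#' @export
assemble_ising <- function(coef_matrix, rule = c("AND", "OR")) {
  rule <- match.arg(rule)
  coef_matrix <- as.matrix(coef_matrix)
  p <- nrow(coef_matrix)
  W <- (coef_matrix + t(coef_matrix)) / 2
  present <- if (rule == "AND") (coef_matrix != 0) & (t(coef_matrix) != 0)
             else (coef_matrix != 0) | (t(coef_matrix) != 0)
  W[!present] <- 0
  diag(W) <- 0
  W
}

#' Fit a sparse Ising network by nodewise lasso with EBIC selection
#'
#' The eLasso procedure: each node is regressed on all others by L1-penalized
#' logistic regression; the penalty per node is chosen by extended BIC; the
#' directed coefficients are symmetrized by the AND (default) or OR rule.
#' Thresholds are the selected nodewise intercepts.
#'
#' @param data \code{n x p} binary 0/1 matrix (columns named), or a
#'   \code{"binary_panel"} (then \code{wave}, \code{group}, \code{items}
#'   select the analysis matrix).
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule Symmetrization rule, \code{"AND"} or \code{"OR"}.
#' @param wave,group,items Panel selectors (wave defaults to 1; group NULL
#'   keeps all subjects; items NULL keeps all items).
#' @param nlambda,lambda_min_ratio Penalty-grid controls, see
#'   [nodewise_logistic_path()].
#' @return Object of class \code{"ising_net"} with elements \code{weights}
#'   (symmetric, zero diagonal), \code{thresholds}, \code{gamma},
#'   \code{rule}, \code{items}, \code{n} and \code{nodewise} (selected
#'   per-node fits).
#' @examples
#' th <- matrix(0, 4, 4); th[1, 2] <- th[2, 1] <- 1.5
#' x <- sample_ising_gibbs(ising_parameters(th, rep(-0.5, 4)), 800, seed = 7,
#'                         burn_in = 200, thin = 5)
#' colnames(x) <- paste0("V", 1:4)
#' fit <- ising_fit(x)
#' coef(fit)
#' @export
ising_fit <- function(data, gamma = 0.25, rule = c("AND", "OR"), wave = 1,
                      group = NULL, items = NULL, nlambda = 100,
                      lambda_min_ratio = 0.001) {
  rule <- match.arg(rule)
  if (inherits(data, "binary_panel")) {
    pnl <- data
    if (!is.null(group)) pnl <- panel_subset(pnl, pnl$group == group)
    X <- panel_wave(pnl, wave)
    if (!is.null(items)) X <- X[, items, drop = FALSE]
  } else {
    X <- as.matrix(data)
  }
  if (anyNA(X)) stop("ising_fit: missing values; filter the panel first")
  p <- ncol(X)
  n <- nrow(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(p))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("ising_fit: constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  if (n <= p)
    warning("ising_fit: n <= p; estimates may be unstable")

  coef_matrix <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  thresholds <- numeric(p)
  nodewise <- vector("list", p)
  for (j in seq_len(p)) {
    path <- nodewise_logistic_path(X, j, nlambda = nlambda,
                                   lambda_min_ratio = lambda_min_ratio)
    sel <- ebic_select(path, n = n, p_cand = p - 1, gamma = gamma)
    coef_matrix[j, -j] <- sel$coefficients
    thresholds[j] <- sel$intercept
    nodewise[[j]] <- sel
  }
  W <- assemble_ising(coef_matrix, rule)
  structure(
    list(weights = W, thresholds = stats::setNames(thresholds, colnames(X)),
         gamma = gamma, rule = rule, items = colnames(X), n = n,
         nodewise = nodewise),
    class = "ising_net")
}

#' Edge density of an undirected network
#'
#' Percentage of possible undirected edges with nonzero weight, rounded
#' half-up to one decimal.
#'
#' @param net An \code{"ising_net"} or symmetric weight matrix.
#' @return Percentage in [0, 100].
#' @export
ising_density <- function(net) {
  W <- if (inherits(net, "ising_net")) net$weights else as.matrix(net)
  p <- nrow(W)
  nnz <- sum(W[upper.tri(W)] != 0)
  proportion_pct(nnz, p * (p - 1) / 2)
}

#' @export
print.ising_net <- function(x, ...) {
  p <- length(x$items)
  cat(sprintf("Ising network: %d nodes, n = %d (eLasso, gamma = %.2f, %s rule)\n",
              p, x$n, x$gamma, x$rule))
  cat(sprintf("  edge density: %.1f%% (%d of %d possible edges)\n",
              ising_density(x), sum(x$weights[upper.tri(x$weights)] != 0),
              p * (p - 1) / 2))
  invisible(x)
}

#' @export
coef.ising_net <- function(object, ...) object$weights

#' @export
summary.ising_net <- function(object, ...) {
  W <- object$weights
  ut <- upper.tri(W)
  edges <- which(ut & W != 0, arr.ind = TRUE)
  etab <- data.frame(from = object$items[edges[, 1]],
                     to = object$items[edges[, 2]],
                     weight = W[edges], stringsAsFactors = FALSE)
  etab <- etab[order(-abs(etab$weight)), , drop = FALSE]
  out <- list(density = ising_density(object),
              n_edges = nrow(etab), edges = etab,
              centrality = centrality_table(W),
              thresholds = object$thresholds,
              gamma = object$gamma, rule = object$rule, n = object$n)
  class(out) <- "summary.ising_net"
  out
}

#' @export
print.summary.ising_net <- function(x, ...) {
  cat(sprintf("Ising network (gamma = %.2f, %s rule), n = %d\n",
              x$gamma, x$rule, x$n))
  cat(sprintf("  %d edges (density %.1f%%)\n", x$n_edges, x$density))
  if (nrow(x$edges)) {
    cat("  strongest edges:\n")
    print(utils::head(x$edges, 5), row.names = FALSE)
  }
  cat("  node centrality:\n")
  print(x$centrality, row.names = FALSE)
  invisible(x)
}

#' Simulate binary data from a fitted Ising network
#'
#' Draws Gibbs samples from the fitted couplings and thresholds; useful for
#' parametric-bootstrap checks.
#'
#' @param object An \code{"ising_net"}.
#' @param nsim Number of samples.
#' @param seed Integer seed.
#' @param ... Passed to [sample_ising_gibbs()] (\code{burn_in}, \code{thin}).
#' @return \code{nsim x p} 0/1 matrix.
#' @export
simulate.ising_net <- function(object, nsim = 1, seed = 1L, ...) {
  x <- sample_ising_gibbs(
    ising_parameters(object$weights, object$thresholds), n = nsim,
    seed = seed, ...)
  colnames(x) <- object$items
  x
}
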