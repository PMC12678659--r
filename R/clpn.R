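#' Fit a cross-lagged panel network (CLPN)
#'
#' Regresses each wave-2 item on all wave-1 items (itself included) by
#' L1-penalized logistic regression, so small paths shrink exactly to zero.
#' Entry \code{weights[i, j]} is the effect of wave-1 node i on wave-2 node j;
#' the diagonal holds the autoregressive effects. Per-node penalties are
#' chosen by 10-fold cross-validated deviance (fold assignment seeded) or by
#' extended BIC.
#'
#' Coefficients are reported as raw log-odds (the scale on which published
#' autoregressive edge weights of 2-5 arise); a standardized-predictor
#' rescaling is returned alongside as \code{weights_std}.
#'
#' @param panel A complete \code{"binary_panel"}, or a list with 0/1
#'   matrices \code{wave1} and \code{wave2} of equal shape.
#' @param group Optional group label to restrict to.
#' @param items Optional item subset (indices or names).
#' @param selection Penalty selection, \code{"cv"} (default) or \code{"ebic"}.
#' @param cv_rule With \code{selection = "cv"}: \code{"1se"} (default) picks
#'   the sparsest penalty within one standard error of the minimum
#'   cross-validated deviance; \code{"min"} picks the minimum itself. The
#'   one-standard-error rule keeps small spurious paths at exactly zero,
#'   which plain deviance minimization does not.
#' @param gamma EBIC hyperparameter when \code{selection = "ebic"}.
#' @param seed Integer seed for the cross-validation fold assignment.
#' @param nfolds Number of CV folds (default 10).
#' @param nlambda,lambda_min_ratio Penalty-grid controls.
#' @return Object of class \code{"clpn_net"} with \code{weights},
#'   \code{weights_std}, \code{intercepts}, \code{lambda_choice},
#'   \code{items}, \code{n}, \code{selection} and \code{seed}.
#' @examples
#' sc <- share_like_scenarios(n_diabetes = 150, n_no_diabetes = 350, seed = 3)
#' pnl <- generate_two_group_panel(sc$diabetes, sc$no_diabetes, sc$codebook)
#' fit <- clpn_fit(pnl, group = "no_diabetes", selection = "ebic", seed = 1)
#' edge_density(fit)
#' @export
clpn_fit <- function(panel, group = NULL, items = NULL,
                     selection = c("cv", "ebic"), cv_rule = c("1se", "min"),
                     gamma = 0.25, seed = 1L, nfolds = 10, nlambda = 100,
                     lambda_min_ratio = 0.001) {
  selection <- match.arg(selection)
  cv_rule <- match.arg(cv_rule)
  if (inherits(panel, "binary_panel")) {
    pnl <- panel
    if (!is.null(group)) pnl <- panel_subset(pnl, pnl$group == group)
    X1 <- panel_wave(pnl, 1)
    X2 <- panel_wave(pnl, 2)
  } else {
    X1 <- as.matrix(panel$wave1)
    X2 <- as.matrix(panel$wave2)
  }
  if (!is.null(items)) {
    X1 <- X1[, items, drop = FALSE]
    X2 <- X2[, items, drop = FALSE]
  }
  if (anyNA(X1) || anyNA(X2))
    stop("clpn_fit: missing values; filter the panel first")
  if (!identical(dim(X1), dim(X2)))
    stop("clpn_fit: wave matrices must have identical shape")
  p <- ncol(X1)
  n <- nrow(X1)
  if (is.null(colnames(X1))) colnames(X1) <- paste0("V", seq_len(p))
  const2 <- apply(X2, 2, stats::sd) == 0
  if (any(const2))
    stop("clpn_fit: constant wave-2 column(s): ",
         paste(colnames(X1)[const2], collapse = ", "))

  old <- local_seed(seed)
  on.exit(restore_seed(old))
  foldid <- sample(rep_len(seq_len(nfolds), n))

  B <- matrix(0, p, p, dimnames = list(colnames(X1), colnames(X1)))
  intercepts <- numeric(p)
  lambda_choice <- numeric(p)
  for (j in seq_len(p)) {
    y <- X2[, j]
    if (selection == "cv") {
      cvfit <- glmnet::cv.glmnet(X1, y, family = "binomial",
                                 standardize = TRUE, foldid = foldid,
                                 nlambda = nlambda,
                                 lambda.min.ratio = lambda_min_ratio)
      s <- if (cv_rule == "1se") "lambda.1se" else "lambda.min"
      cf <- as.numeric(stats::coef(cvfit, s = s))
      lambda_choice[j] <- cvfit[[s]]
    } else {
      fit <- glmnet::glmnet(X1, y, family = "binomial", standardize = TRUE,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio)
      loglik <- -0.5 * fit$nulldev * (1 - fit$dev.ratio)
      ebic <- -2 * loglik + fit$df * log(n) + 2 * gamma * fit$df * log(p)
      idx <- which.min(ebic)
      cf <- c(fit$a0[idx], as.numeric(fit$beta[, idx]))
      lambda_choice[j] <- fit$lambda[idx]
    }
    intercepts[j] <- cf[1]
    B[, j] <- cf[-1]
  }
  sds <- apply(X1, 2, stats::sd)
  structure(
    list(weights = B, weights_std = B * sds,
         intercepts = stats::setNames(intercepts, colnames(X1)),
         lambda_choice = stats::setNames(lambda_choice, colnames(X1)),
         items = colnames(X1), n = n, selection = selection,
         cv_rule = if (selection == "cv") cv_rule else NA_character_,
         gamma = if (selection == "ebic") gamma else NA_real_,
         seed = as.integer(seed)),
    class = "clpn_net")
}

#' Remove autoregressive effects from a directed network
#'
#' Zeroes the diagonal (each node's effect on itself at follow-up), leaving
#' the cross-lagged off-diagonal weights untouched. Idempotent.
#'
#' @param net A \code{"clpn_net"} or a square weight matrix.
#' @return Same type as the input.
#' @export
drop_autoregressive <- function(net) {
  if (inherits(net, "clpn_net")) {
    diag(net$weights) <- 0
    diag(net$weights_std) <- 0
    net
  } else {
    W <- as.matrix(net)
    diag(W) <- 0
    W
  }
}

#' Display-threshold small edges
#'
#' Sets entries with absolute weight at or below \code{cutoff} to zero
#' (edges are kept only if strictly above the cutoff). A display filter
#' only; estimation is untouched.
#'
#' @param net A \code{"clpn_net"} or weight matrix.
#' @param cutoff Non-negative threshold (default 0.24, the published
#'   figure convention).
#' @return Same type as the input.
#' @export
threshold_edges <- function(net, cutoff = 0.24) {
  if (cutoff < 0) stop("threshold_edges: cutoff must be >= 0")
  if (inherits(net, "clpn_net")) {
    net$weights[abs(net$weights) <= cutoff] <- 0
    net$weights_std[abs(net$weights_std) <= cutoff] <- 0
    net
  } else {
    W <- as.matrix(net)
    W[abs(W) <= cutoff] <- 0
    W
  }
}

#' Edge density of a directed network
#'
#' Percentage of nonzero entries among the p^2 possible directed edges
#' (autoregressive diagonal included by default) or among the p(p-1)
#' off-diagonal entries, rounded half-up to one decimal.
#'
#' @param net A \code{"clpn_net"} or square weight matrix.
#' @param include_diagonal Count the diagonal in numerator and denominator
#'   (default TRUE).
#' @return Percentage in [0, 100].
#' @export
edge_density <- function(net, include_diagonal = TRUE) {
  W <- if (inherits(net, "clpn_net")) net$weights else as.matrix(net)
  p <- nrow(W)
  if (include_diagonal) {
    proportion_pct(sum(W != 0), p^2)
  } else {
    off <- W; diag(off) <- 0
    proportion_pct(sum(off != 0), p * (p - 1))
  }
}

#' @export
print.clpn_net <- function(x, ...) {
  p <- length(x$items)
  cat(sprintf(
    "Cross-lagged panel network: %d nodes, n = %d (lasso, %s selection)\n",
    p, x$n, x$selection))
  cat(sprintf("  edge density: %.1f%% of %d directed edges (diagonal included)\n",
              edge_density(x), p^2))
  ar <- sort(diag(x$weights), decreasing = TRUE)
  cat("  strongest autoregressive effects:",
      paste(sprintf("%s (%.2f)", names(ar)[1:min(3, p)],
                    ar[1:min(3, p)]), collapse = ", "), "\n")
  invisible(x)
}

#' @param scale \code{"raw"} log-odds (default) or \code{"std"} for the
#'   standardized-predictor scale.
#' @rdname clpn_fit
#' @param object A \code{"clpn_net"}.
#' @param ... Unused.
#' @export
coef.clpn_net <- function(object, scale = c("raw", "std"), ...) {
  scale <- match.arg(scale)
  if (scale == "raw") object$weights else object$weights_std
}

#' @export
summary.clpn_net <- function(object, ...) {
  W <- object$weights
  cross <- drop_autoregressive(W)
  idx <- which(cross != 0, arr.ind = TRUE)
  etab <- data.frame(from = object$items[idx[, 1]],
                     to = object$items[idx[, 2]],
                     weight = cross[idx], stringsAsFactors = FALSE)
  etab <- etab[order(-abs(etab$weight)), , drop = FALSE]
  out <- list(
    density = edge_density(object),
    density_offdiag = edge_density(object, include_diagonal = FALSE),
    autoregressive = sort(diag(W), decreasing = TRUE),
    cross_lagged = etab,
    centrality = in_out_indices(W),
    n = object$n, selection = object$selection)
  class(out) <- "summary.clpn_net"
  out
}

#' @export
print.summary.clpn_net <- function(x, ...) {
  cat(sprintf("Cross-lagged panel network, n = %d (%s selection)\n",
              x$n, x$selection))
  cat(sprintf("  density: %.1f%% with diagonal, %.1f%% cross-lagged only\n",
              x$density, x$density_offdiag))
  cat("  strongest cross-lagged edges:\n")
  print(utils::head(x$cross_lagged, 5), row.names = FALSE)
  cat("  in/out centrality:\n")
  print(x$centrality, row.names = FALSE)
  invisible(x)
}

#' Predicted wave-2 probabilities from a fitted CLPN
#'
#' @param object A \code{"clpn_net"}.
#' @param newdata \code{n x p} 0/1 matrix of wave-1 states.
#' @param ... Unused.
#' @return \code{n x p} matrix of P(item = 1 at wave 2 | wave 1).
#' @export
predict.clpn_net <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$items))
    stop("predict.clpn_net: newdata must have ", length(object$items),
         " columns")
  eta <- sweep(X %*% object$weights, 2, object$intercepts, `+`)
  pr <- stats::plogis(eta)
  colnames(pr) <- object$items
  pr
}

#' Simulate wave-2 responses from a fitted CLPN
#'
#' @param object A \code{"clpn_net"}.
#' @param nsim Unused (one draw per row of \code{newdata}).
#' @param seed Integer seed.
#' @param newdata \code{n x p} 0/1 matrix of wave-1 states.
#' @param ... Unused.
#' @return \code{n x p} 0/1 matrix.
#' @export
simulate.clpn_net <- function(object, nsim = 1, seed = 1L, newdata, ...) {
  out <- simulate_wave5(newdata,
                        clpn_parameters(object$intercepts, object$weights),
                        seed = seed)
  colnames(out) <- object$items
  out
}
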