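#' Node strength of an undirected network
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param weights Symmetric \code{p x p} matrix with zero diagonal, or an
#'   \code{"ising_net"}.
#' @return Named numeric vector of strengths.
#' @export
strength <- function(weights) {
  W <- check_undirected(weights)
  rowSums(abs(W))
}

#' Expected influence (one-step) of an undirected network
#'
#' Signed sum of edge weights incident to each node, so positive edges can
#' outweigh negative ones.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
expected_influence <- function(weights) {
  W <- check_undirected(weights)
  rowSums(W)
}

check_undirected <- function(weights) {
  W <- if (inherits(weights, "ising_net")) weights$weights else as.matrix(weights)
  if (!isSymmetric(unname(W), tol = 1e-10))
    stop("expected a symmetric weight matrix")
  diag(W) <- 0
  W
}

#' Undirected centrality table
#'
#' Strength and expected influence per node, with z-standardized variants
#' (mean 0, sd 1 across nodes).
#'
#' @inheritParams strength
#' @return data.frame with columns node, strength, expected_influence,
#'   z_strength, z_expected_influence.
#' @export
centrality_table <- function(weights) {
  W <- check_undirected(weights)
  s <- rowSums(abs(W))
  ei <- rowSums(W)
  data.frame(node = colnames(W) %||% paste0("V", seq_len(nrow(W))),
             strength = s, expected_influence = ei,
             z_strength = zscore(s), z_expected_influence = zscore(ei),
             stringsAsFactors = FALSE, row.names = NULL)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Directed in/out centrality indices
#'
#' For a directed network with rows as sources (wave 1) and columns as
#' targets (wave 2): out-strength is the absolute row sum (a node as source
#' of activation), in-strength the absolute column sum (a node as
#' recipient); the expected-influence variants are signed. The
#' autoregressive diagonal is excluded by default.
#'
#' @param net A \code{"clpn_net"} or square weight matrix.
#' @param exclude_diagonal Drop the diagonal before summing (default TRUE).
#' @return data.frame with node, out_strength, in_strength, out_ei, in_ei
#'   and z-standardized variants.
#' @export
in_out_indices <- function(net, exclude_diagonal = TRUE) {
  W <- if (inherits(net, "clpn_net")) net$weights else as.matrix(net)
  if (nrow(W) != ncol(W)) stop("in_out_indices: matrix must be square")
  if (exclude_diagonal) diag(W) <- 0
  out_s <- rowSums(abs(W)); in_s <- colSums(abs(W))
  out_ei <- rowSums(W); in_ei <- colSums(W)
  data.frame(node = colnames(W) %||% paste0("V", seq_len(nrow(W))),
             out_strength = out_s, in_strength = in_s,
             out_ei = out_ei, in_ei = in_ei,
             z_out_strength = zscore(out_s), z_in_strength = zscore(in_s),
             z_out_ei = zscore(out_ei), z_in_ei = zscore(in_ei),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bridge centrality between two node groups
#'
#' Bridge strength is each node's total absolute edge weight to nodes of the
#' other group (e.g. a symptom's links to the behaviours); bridge expected
#' influence is the same sum without taking absolute values.
#'
#' @param weights Symmetric weight matrix or \code{"ising_net"}.
#' @param partition Named vector (or vector aligned with columns) assigning
#'   each node to one of exactly two groups.
#' @return data.frame with node, group, bridge_strength,
#'   bridge_expected_influence.
#' @export
bridge_metrics <- function(weights, partition) {
  W <- check_undirected(weights)
  p <- nrow(W)
  nodes <- colnames(W) %||% paste0("V", seq_len(p))
  part <- if (!is.null(names(partition))) {
    miss <- setdiff(nodes, names(partition))
    if (length(miss))
      stop("bridge_metrics: partition missing nodes: ",
           paste(miss, collapse = ", "))
    as.character(partition[nodes])
  } else {
    if (length(partition) != p)
      stop("bridge_metrics: partition length must match node count")
    as.character(partition)
  }
  if (length(unique(part)) != 2)
    stop("bridge_metrics: partition must define exactly two non-empty groups")
  cross <- outer(part, part, `!=`)
  Wc <- W * cross
  data.frame(node = nodes, group = part,
             bridge_strength = rowSums(abs(Wc)),
             bridge_expected_influence = rowSums(Wc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Newman modularity of a weighted partition
#'
#' Q = sum over communities of (within-community edge weight / total edge
#' weight) minus (community degree share squared); computed on non-negative
#' weights.
#'
#' @param weights Symmetric non-negative weight matrix, zero diagonal.
#' @param assignment Community labels, one per node.
#' @return Scalar Q in [-1, 1].
#' @export
modularity_q <- function(weights, assignment) {
  W <- check_undirected(weights)
  if (any(W < 0)) stop("modularity_q: weights must be non-negative")
  if (length(assignment) != nrow(W))
    stop("modularity_q: assignment length must match node count")
  S <- sum(W)                 # = 2m for undirected graphs
  if (S == 0) return(0)
  q <- 0
  for (comm in unique(assignment)) {
    idx <- assignment == comm
    e_c <- sum(W[idx, idx])   # within weight, both directions
    d_c <- sum(W[idx, ])      # total degree of the community
    q <- q + e_c / S - (d_c / S)^2
  }
  q
}

#' Walktrap community detection on a signed network
#'
#' Runs the walktrap algorithm (agglomerative merging of nodes by t-step
#' random-walk distance) on the absolute edge weights, returning the
#' partition that maximizes modularity along the merge dendrogram.
#' Deterministic.
#'
#' @param weights Symmetric weight matrix or \code{"ising_net"} (absolute
#'   values are used).
#' @param t Random-walk length in steps (default 4).
#' @return Object of class \code{"community_partition"}: named
#'   \code{assignment}, \code{modularity} Q, \code{t} and
#'   \code{n_communities}.
#' @export
walktrap_communities <- function(weights, t = 4) {
  W <- abs(check_undirected(weights))
  p <- nrow(W)
  nodes <- colnames(W) %||% paste0("V", seq_len(p))
  if (all(W == 0)) {
    warning("walktrap_communities: empty graph; each node its own community")
    assignment <- stats::setNames(seq_len(p), nodes)
    return(structure(list(assignment = assignment, modularity = 0, t = t,
                          n_communities = p),
                     class = "community_partition"))
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  wt <- igraph::cluster_walktrap(g, steps = t)
  assignment <- stats::setNames(as.integer(igraph::membership(wt)), nodes)
  structure(list(assignment = assignment,
                 modularity = modularity_q(W, assignment),
                 t = t, n_communities = length(unique(assignment))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Walktrap partition (t = %d): %d communities, Q = %.3f\n",
              x$t, x$n_communities, x$modularity))
  for (comm in sort(unique(x$assignment)))
    cat(sprintf("  [%d] %s\n", comm,
                paste(names(x$assignment)[x$assignment == comm],
                      collapse = ", ")))
  invisible(x)
}
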