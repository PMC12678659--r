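#' Ising model parameters
#'
#' Pairwise couplings and per-node thresholds for a binary (0/1) Markov
#' random field: P(x) is proportional to exp(sum_i tau_i x_i +
#' sum_{i<j} theta_ij x_i x_j). The threshold tau_i encodes a node's
#' preference to be 0 or 1; theta_ij the pairwise association.
#'
#' @param couplings Symmetric p x p matrix with exactly zero diagonal.
#' @param thresholds Length-p numeric vector.
#' @return Object of class \code{"ising_parameters"}.
#' @export
ising_parameters <- function(couplings, thresholds) {
  couplings <- as.matrix(couplings)
  p <- nrow(couplings)
  if (ncol(couplings) != p || !isSymmetric(unname(couplings)))
    stop("ising_parameters: couplings must be a symmetric square matrix")
  if (any(diag(couplings) != 0))
    stop("ising_parameters: couplings diagonal must be exactly zero")
  if (length(thresholds) != p)
    stop("ising_parameters: thresholds length must match couplings dimension")
  structure(list(couplings = couplings, thresholds = as.numeric(thresholds)),
            class = "ising_parameters")
}

#' Cross-lagged transition parameters
#'
#' Logistic transition model for wave-2 items given wave-1 items:
#' P(x2_j = 1 | x1) = logistic(b0_j + sum_i B[i, j] x1_i). Entry B[i, j] is
#' the log-odds effect of wave-1 node i on wave-2 node j; the diagonal holds
#' the autoregressive effects.
#'
#' @param intercepts Length-p numeric vector b0.
#' @param transition p x p numeric matrix B (rows = wave-1 sources,
#'   columns = wave-2 targets).
#' @return Object of class \code{"clpn_parameters"}.
#' @export
clpn_parameters <- function(intercepts, transition) {
  transition <- as.matrix(transition)
  p <- nrow(transition)
  if (ncol(transition) != p)
    stop("clpn_parameters: transition must be square")
  if (length(intercepts) != p)
    stop("clpn_parameters: intercepts length must match transition dimension")
  if (!all(is.finite(intercepts)) || !all(is.finite(transition)))
    stop("clpn_parameters: entries must be finite")
  structure(list(intercepts = as.numeric(intercepts), transition = transition),
            class = "clpn_parameters")
}

#' Group simulation scenario
#'
#' Bundles a group size with the wave-1 Ising model and wave-1 to wave-2
#' cross-lagged transition used to simulate that group, plus a seed.
#'
#' @param n_subjects Positive integer group size.
#' @param ising An [ising_parameters()] object (wave-1 distribution).
#' @param clpn A [clpn_parameters()] object (wave-2 transition).
#' @param seed Integer seed for this group's draws.
#' @return Object of class \code{"group_scenario"}.
#' @export
group_scenario <- function(n_subjects, ising, clpn, seed = 1L) {
  stopifnot(inherits(ising, "ising_parameters"),
            inherits(clpn, "clpn_parameters"))
  if (nrow(ising$couplings) != nrow(clpn$transition))
    stop("group_scenario: ising and clpn dimensions differ")
  if (n_subjects < 0) stop("group_scenario: n_subjects must be >= 0")
  structure(list(n_subjects = as.integer(n_subjects), ising = ising,
                 clpn = clpn, seed = as.integer(seed)),
            class = "group_scenario")
}

#' Gibbs sampler for the 0/1 Ising model
#'
#' Draws n approximately independent samples by running n parallel
#' single-site Gibbs chains (one per requested sample, vectorized across
#' chains) with a systematic sweep over nodes. Each chain starts from an
#' independent Bernoulli(0.5) state and runs \code{burn_in + thin} full
#' sweeps; the final states are returned. Deterministic given \code{seed}.
#'
#' @param params An [ising_parameters()] object.
#' @param n Number of samples (chains).
#' @param seed Integer seed.
#' @param burn_in Number of burn-in sweeps (default 1000).
#' @param thin Extra sweeps after burn-in (default 10).
#' @return An \code{n x p} matrix of 0/1 values.
#' @export
sample_ising_gibbs <- function(params, n, seed = 1L, burn_in = 1000L,
                               thin = 10L) {
  stopifnot(inherits(params, "ising_parameters"))
  if (n < 1) stop("sample_ising_gibbs: n must be >= 1")
  if (burn_in < 0) stop("sample_ising_gibbs: burn_in must be >= 0")
  theta <- params$couplings
  tau <- params$thresholds
  p <- length(tau)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  x <- matrix(as.numeric(stats::runif(n * p) < 0.5), n, p)
  sweeps <- burn_in + thin
  for (s in seq_len(sweeps)) {
    for (j in seq_len(p)) {
      eta <- tau[j] + x %*% theta[, j]   # theta[j, j] == 0, so x_j drops out
      x[, j] <- as.numeric(stats::runif(n) < stats::plogis(eta))
    }
  }
  x
}

#' Exact distribution of a small 0/1 Ising model
#'
#' Enumerates all 2^p states and returns their exact probabilities; the
#' independent reference for validating the Gibbs sampler.
#'
#' @param params An [ising_parameters()] object with p <= 20.
#' @return List with \code{states} (2^p x p matrix of 0/1) and \code{prob}.
#' @export
ising_exact_distribution <- function(params) {
  stopifnot(inherits(params, "ising_parameters"))
  p <- length(params$thresholds)
  if (p > 20) stop("ising_exact_distribution: p too large for enumeration")
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), p)))
  colnames(states) <- NULL
  # log weight: tau'x + sum_{i<j} theta_ij x_i x_j = tau'x + x'Theta x / 2
  logw <- states %*% params$thresholds +
    rowSums((states %*% params$couplings) * states) / 2
  w <- exp(logw - max(logw))
  list(states = states, prob = as.numeric(w / sum(w)))
}

#' Simulate wave-2 responses from wave-1 via the cross-lagged model
#'
#' Each wave-2 item j is an independent Bernoulli draw with success
#' probability logistic(b0_j + sum_i B[i, j] x1_i), independent across
#' subjects and items given wave 1.
#'
#' @param wave1 \code{n x p} 0/1 matrix of wave-1 states.
#' @param params A [clpn_parameters()] object.
#' @param seed Integer seed.
#' @return \code{n x p} 0/1 matrix of wave-2 states.
#' @export
simulate_wave5 <- function(wave1, params, seed = 1L) {
  stopifnot(inherits(params, "clpn_parameters"))
  wave1 <- as.matrix(wave1)
  p <- length(params$intercepts)
  if (ncol(wave1) != p)
    stop("simulate_wave5: wave1 has ", ncol(wave1), " columns, expected ", p)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  eta <- sweep(wave1 %*% params$transition, 2, params$intercepts, `+`)
  pr <- stats::plogis(eta)
  matrix(as.numeric(stats::runif(length(pr)) < pr), nrow(wave1), p)
}

#' Generate a two-group, two-wave binary panel with known ground truth
#'
#' Wave 1 of each group is drawn from its Ising model by Gibbs sampling;
#' wave 2 from the group's cross-lagged logistic transition. Groups are
#' concatenated (diabetes first) with group labels attached.
#'
#' @param scenario_diabetes,scenario_no_diabetes [group_scenario()] objects
#'   of identical dimension p.
#' @param codebook A [codebook()] with matching item count.
#' @return A complete \code{"binary_panel"}.
#' @seealso [share_like_scenarios()] for the calibrated default.
#' @export
generate_two_group_panel <- function(scenario_diabetes, scenario_no_diabetes,
                                     codebook = default_codebook()) {
  stopifnot(inherits(scenario_diabetes, "group_scenario"),
            inherits(scenario_no_diabetes, "group_scenario"))
  p1 <- nrow(scenario_diabetes$ising$couplings)
  p2 <- nrow(scenario_no_diabetes$ising$couplings)
  if (p1 != p2)
    stop("generate_two_group_panel: scenario dimensions differ (",
         p1, " vs ", p2, ")")
  if (p1 != length(codebook$item_ids))
    stop("generate_two_group_panel: codebook has ", length(codebook$item_ids),
         " items, scenarios have ", p1)

  sim_group <- function(sc) {
    if (sc$n_subjects == 0)
      return(array(numeric(0), dim = c(0, p1, 2)))
    w1 <- sample_ising_gibbs(sc$ising, sc$n_subjects, seed = sc$seed)
    w2 <- simulate_wave5(w1, sc$clpn, seed = derive_seed(sc$seed, 1))
    vals <- array(NA_real_, dim = c(sc$n_subjects, p1, 2))
    vals[, , 1] <- w1
    vals[, , 2] <- w2
    vals
  }
  vd <- sim_group(scenario_diabetes)
  vn <- sim_group(scenario_no_diabetes)
  n_d <- dim(vd)[1]; n_n <- dim(vn)[1]
  vals <- array(NA_real_, dim = c(n_d + n_n, p1, 2))
  if (n_d > 0) vals[seq_len(n_d), , ] <- vd
  if (n_n > 0) vals[n_d + seq_len(n_n), , ] <- vn
  binary_panel(vals,
               subject_ids = seq_len(n_d + n_n),
               group = c(rep("diabetes", n_d), rep("no_diabetes", n_n)),
               codebook = codebook)
}

#' Calibrated default simulation scenarios
#'
#' Two-group scenarios emulating the structure of a large European ageing
#' cohort: group sizes 1781 (diabetes) and 20,729 (no diabetes); wave-1
#' couplings built from two positive blocks (12 depressive symptoms, 4
#' behaviours) plus a physical-inactivity-to-symptom bridge; thresholds
#' calibrated so marginal prevalences land near the published descriptives
#' (physical inactivity ~5-9%, smoking ~20%, low fruit/veg ~21%, heavy
#' drinking ~25%, depressive caseness ~21-26%). Wave 2 combines strong
#' autoregressive effects with a planted physical-inactivity -> interest
#' cross-lagged effect. The structure is illustrative, not fitted to any
#' restricted dataset.
#'
#' @param n_diabetes,n_no_diabetes Group sizes.
#' @param seed Base integer seed; group seeds are derived from it.
#' @return List with \code{diabetes} and \code{no_diabetes}
#'   [group_scenario()] objects and the default [codebook()].
#' @export
share_like_scenarios <- function(n_diabetes = 1781L, n_no_diabetes = 20729L,
                                 seed = 2024L) {
  cb <- default_codebook()
  p <- 16L
  dep <- 1:12; beh <- 13:16  # S=13, P=14, F=15, D=16

  make_theta <- function(dep_w, beh_w, bridge_w) {
    theta <- matrix(0, p, p)
    theta[dep, dep] <- dep_w
    theta[beh, beh] <- beh_w
    theta[14, dep] <- bridge_w   # physical inactivity bridges to all symptoms
    theta[dep, 14] <- bridge_w
    diag(theta) <- 0
    theta
  }

  # thresholds chosen once (self-consistent mean-field start, then refined by
  # pilot simulation) to hit the target marginal prevalences
  make_scenario <- function(n, dep_prev, beh_prev, dep_w, beh_w, bridge_w,
                            group_seed) {
    theta <- make_theta(dep_w, beh_w, bridge_w)
    prev <- c(rep(dep_prev, 12), beh_prev)
    # mean-field: tau_i ~= logit(prev_i) - sum_j theta_ij prev_j
    tau <- stats::qlogis(prev) - as.numeric(theta %*% prev)
    ising <- ising_parameters(theta, tau)
    B <- diag(1.8, p)
    B[13, 13] <- 3.0   # smoking is highly persistent
    B[14, 14] <- 2.2   # so is physical inactivity
    B[14, 6] <- 0.9    # planted bridge: inactivity -> loss of interest
    b0 <- stats::qlogis(prev) - diag(B) * prev - as.numeric(B[14, ] * prev[14])
    clpn <- clpn_parameters(b0, B)
    group_scenario(n, ising, clpn, seed = group_seed)
  }

  list(
    diabetes = make_scenario(
      n = n_diabetes,
      dep_prev = 0.19, beh_prev = c(0.171, 0.08, 0.214, 0.244),
      dep_w = 0.25, beh_w = 0.15, bridge_w = 0.35,
      group_seed = derive_seed(seed, 11)),
    no_diabetes = make_scenario(
      n = n_no_diabetes,
      dep_prev = 0.17, beh_prev = c(0.203, 0.04, 0.213, 0.26),
      dep_w = 0.25, beh_w = 0.15, bridge_w = 0.35,
      group_seed = derive_seed(seed, 12)),
    codebook = cb)
}

#' Generate the calibrated default two-group panel
#'
#' Convenience wrapper: [share_like_scenarios()] fed into
#' [generate_two_group_panel()], optionally scaled down while preserving the
#' ~8%/92% group ratio.
#'
#' @param n_total Total subject count (default 22,510).
#' @param seed Base integer seed.
#' @return A \code{"binary_panel"}.
#' @export
generate_default_panel <- function(n_total = 22510L, seed = 2024L) {
  frac_d <- 1781 / 22510
  n_d <- max(1L, round(n_total * frac_d))
  sc <- share_like_scenarios(n_diabetes = n_d, n_no_diabetes = n_total - n_d,
                             seed = seed)
  generate_two_group_panel(sc$diabetes, sc$no_diabetes, sc$codebook)
}
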