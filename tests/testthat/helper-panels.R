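# Shared fixture builders: tiny codebooks and panels constructed in code.

toy_codebook <- function(p = 4, format = "wide") {
  codebook(item_ids = paste0("I", seq_len(p)),
           item_group = c(rep("depression", max(1, p - 1)), "behaviour"),
           format = format)
}

# complete panel with reproducible Bernoulli entries
toy_panel <- function(n = 8, p = 4, seed = 42, group = NULL, format = "wide") {
  cb <- toy_codebook(p, format)
  set.seed(seed)
  vals <- array(rbinom(n * p * 2, 1, 0.4), dim = c(n, p, 2))
  if (is.null(group))
    group <- rep(c("diabetes", "no_diabetes"), length.out = n)
  binary_panel(vals, group = group, codebook = cb)
}

# small two-group panel from the calibrated generator, for pipeline tests
small_default_panel <- function(n_total = 400, seed = 7) {
  generate_default_panel(n_total = n_total, seed = seed)
}

random_symmetric <- function(p, seed, density = 0.5) {
  set.seed(seed)
  W <- matrix(0, p, p)
  ut <- upper.tri(W)
  w <- stats::rnorm(sum(ut)) * rbinom(sum(ut), 1, density)
  W[ut] <- w
  W + t(W)
}
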