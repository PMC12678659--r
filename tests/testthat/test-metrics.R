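test_that("strength and expected influence match their definitions", {
  W <- matrix(c(0, 1, -2,
                1, 0, 3,
                -2, 3, 0), 3, 3, byrow = TRUE)
  expect_equal(unname(strength(W)), c(3, 4, 5))
  expect_equal(unname(expected_influence(W)), c(-1, 4, 1))
  expect_equal(strength(matrix(0, 4, 4)), rep(0, 4))

  Wpos <- abs(random_symmetric(6, seed = 71))
  expect_equal(expected_influence(Wpos), strength(Wpos))
  expect_equal(expected_influence(-W), -expected_influence(W))
  expect_error(strength(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")

  # brute-force oracle on random graphs
  for (seed in 72:76) {
    p <- sample(8:12, 1)
    W <- random_symmetric(p, seed = seed)
    s_oracle <- sapply(seq_len(p), function(i)
      sum(abs(W[i, setdiff(seq_len(p), i)])))
    ei_oracle <- sapply(seq_len(p), function(i)
      sum(W[i, setdiff(seq_len(p), i)]))
    expect_equal(unname(strength(W)), s_oracle)
    expect_equal(unname(expected_influence(W)), ei_oracle)
  }
})

test_that("directed in/out indices split source and recipient roles", {
  W <- matrix(c(0, 2, -1, 0), 2, 2, byrow = TRUE)
  tab <- in_out_indices(W)
  expect_equal(tab$out_strength, c(2, 1))
  expect_equal(tab$in_strength, c(1, 2))
  expect_equal(tab$out_ei, c(2, -1))
  expect_equal(tab$in_ei, c(-1, 2))

  S <- random_symmetric(7, seed = 77)
  tsym <- in_out_indices(S)
  expect_equal(tsym$in_strength, tsym$out_strength)
  expect_equal(tsym$in_ei, tsym$out_ei)

  # diagonal excluded by default, included on request; oracle check
  set.seed(78)
  D <- matrix(rnorm(100), 10, 10)
  t_ex <- in_out_indices(D, exclude_diagonal = TRUE)
  D0 <- D; diag(D0) <- 0
  expect_equal(t_ex$out_strength, unname(rowSums(abs(D0))))
  expect_equal(t_ex$in_ei, unname(colSums(D0)))
  t_in <- in_out_indices(D, exclude_diagonal = FALSE)
  expect_equal(t_in$out_strength, unname(rowSums(abs(D))))

  # standardized variants: mean 0, sd 1
  expect_equal(mean(t_ex$z_out_strength), 0)
  expect_equal(sd(t_ex$z_in_ei), 1)
})

test_that("bridge metrics sum only cross-group edges", {
  W <- matrix(c(0, 1, -2,
                1, 0, 3,
                -2, 3, 0), 3, 3, byrow = TRUE)
  part <- c("depression", "depression", "behaviour")
  bt <- bridge_metrics(W, part)
  expect_equal(bt$bridge_strength, c(2, 3, 5))
  expect_equal(bt$bridge_expected_influence, c(-2, 3, 1))

  # no cross-group edges: all zeros
  Wb <- matrix(0, 4, 4); Wb[1, 2] <- Wb[2, 1] <- 1; Wb[3, 4] <- Wb[4, 3] <- 2
  bt0 <- bridge_metrics(Wb, c("a", "a", "b", "b"))
  expect_equal(bt0$bridge_strength, rep(0, 4))

  # oracle on a random 12-node graph + dominance by total strength
  W12 <- random_symmetric(12, seed = 79)
  part12 <- rep(c("depression", "behaviour"), each = 6)
  bt12 <- bridge_metrics(W12, part12)
  oracle <- sapply(1:12, function(i) {
    other <- which(part12 != part12[i])
    sum(abs(W12[i, other]))
  })
  expect_equal(bt12$bridge_strength, oracle)
  expect_true(all(bt12$bridge_strength <= strength(W12) + 1e-12))
  expect_true(all(abs(bt12$bridge_expected_influence) <=
                  bt12$bridge_strength + 1e-12))

  expect_error(bridge_metrics(W, c("a", "a", "a")), "two")
})

test_that("modularity matches closed forms and the igraph oracle", {
  # two disconnected equal cliques split correctly: Q = 0.5
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  expect_equal(modularity_q(W, rep(1:2, each = 4)), 0.5)
  expect_equal(modularity_q(W, rep(1, 8)), 0)

  for (seed in 81:83) {
    Wr <- abs(random_symmetric(9, seed = seed))
    memb <- sample(1:3, 9, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(Wr, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    expect_equal(modularity_q(Wr, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight))
  }
})

test_that("walktrap recovers separated blocks and handles edge cases", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1; W[5:8, 5:8] <- 1; diag(W) <- 0
  cp <- walktrap_communities(W)
  expect_equal(cp$n_communities, 2)
  expect_equal(length(unique(cp$assignment[1:4])), 1)
  expect_equal(length(unique(cp$assignment[5:8])), 1)
  expect_equal(cp$modularity, 0.5)

  # complete graph: no structure, single community at the Q-maximum
  K <- matrix(1, 6, 6); diag(K) <- 0
  expect_equal(walktrap_communities(K)$n_communities, 1)

  # adding an isolated clique adds exactly one community
  W2 <- matrix(0, 12, 12)
  W2[1:8, 1:8] <- W; W2[9:12, 9:12] <- 1; diag(W2) <- 0
  expect_equal(walktrap_communities(W2)$n_communities,
               cp$n_communities + 1)

  expect_warning(cp0 <- walktrap_communities(matrix(0, 5, 5)), "empty")
  expect_equal(cp0$n_communities, 5)

  # signed weights enter through absolute values
  Wneg <- W; Wneg[1, 2] <- Wneg[2, 1] <- -1
  expect_equal(walktrap_communities(Wneg)$n_communities, 2)
})

test_that("a behaviour bridged into the symptom block joins its community", {
  # ground-truth couplings of the default scenario: physical inactivity (P)
  # is tied to the symptoms, the other behaviours only to each other
  sc <- share_like_scenarios(seed = 84)
  th <- sc$diabetes$ising$couplings
  dimnames(th) <- list(sc$codebook$item_ids, sc$codebook$item_ids)
  cp <- walktrap_communities(th)
  expect_equal(unname(cp$assignment["P"]), unname(cp$assignment["Dep1"]))
  expect_false(cp$assignment["S"] == cp$assignment["Dep1"])
})
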