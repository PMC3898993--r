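# helper: block similarity matrix with two planted cliques
.two_cliques <- function(n1, n2, hi = 10, lo = 1) {
  n <- n1 + n2
  S <- matrix(lo, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
  S[1:n1, 1:n1] <- hi
  S[(n1 + 1):n, (n1 + 1):n] <- hi
  diag(S) <- hi * 5
  S
}

test_that("build_adjacency thresholds, rescales, flags isolated nodes", {
  S <- matrix(c(0, 10, 3, 10, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  adj <- build_adjacency(S, 5)
  expect_equal(adj$W["a", "b"], 1)
  expect_equal(sum(adj$W > 0), 2)
  expect_identical(adj$isolated, "c")
  full <- build_adjacency(S, -Inf)
  expect_true(all(full$W[upper.tri(full$W)] > 0))
  expect_equal(unname(diag(full$W)), rep(0, 3))
  expect_error(build_adjacency(S, 100), "empty graph")
  expect_error(build_adjacency(S, NA), "NA")
})

test_that("planted two-block similarity yields a block-diagonal adjacency", {
  S <- .two_cliques(4, 3)
  adj <- build_adjacency(S, 5)
  W <- adj$W
  expect_true(all(W[1:4, 5:7] == 0))
  expect_true(all(W[1:4, 1:4][upper.tri(matrix(0, 4, 4))] > 0))
})

test_that("normalized Laplacian spectrum has the expected structure", {
  # single edge: eigenvalues {0, 2}
  W2 <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  sp2 <- laplacian_spectrum(W2)
  expect_equal(sp2$values, c(0, 2), tolerance = 1e-12)
  # two disconnected cliques: null eigenvalue with multiplicity 2
  adj <- build_adjacency(.two_cliques(5, 4), 5)
  sp <- laplacian_spectrum(adj)
  expect_equal(sum(abs(sp$values) < 1e-10), 2)
  expect_true(all(sp$values > -1e-10 & sp$values < 2 + 1e-10))
  # zero-degree nodes are refused
  W0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  W0[1, 2] <- W0[2, 1] <- 1
  expect_error(laplacian_spectrum(W0), "isolated")
})

test_that("null multiplicity equals component count for random block graphs", {
  set.seed(15)
  for (rep in 1:5) {
    sizes <- sample(2:5, sample(2:4, 1), replace = TRUE)
    n <- sum(sizes)
    W <- matrix(0, n, n)
    off <- 0
    for (s in sizes) {
      idx <- off + seq_len(s)
      blk <- matrix(stats::runif(s * s, 0.2, 1), s, s)
      blk <- (blk + t(blk)) / 2
      diag(blk) <- 0
      W[idx, idx] <- blk
      off <- off + s
    }
    rownames(W) <- colnames(W) <- paste0("v", 1:n)
    sp <- laplacian_spectrum(W)
    expect_equal(sum(sp$values < 1e-8), length(sizes))
    expect_true(all(sp$values < 2 + 1e-8))
  }
})

test_that("eigengap_k finds the documented gaps and breaks ties low", {
  expect_equal(eigengap_k(c(0, 0.01, 0.02, 0.03, 0.5, 0.55, 0.6))$K, 4L)
  expect_equal(eigengap_k(c(0, 0, 0, 0.8, 0.9, 1.0))$K, 3L)
  expect_equal(eigengap_k(seq(0, 1, by = 0.1))$K, 1L)  # equal gaps
  expect_error(eigengap_k(0.5), "at least 2")
})

test_that("spectral_kmeans recovers disconnected cliques exactly", {
  adj <- build_adjacency(.two_cliques(5, 4), 5)
  sp <- laplacian_spectrum(adj)
  asg <- spectral_kmeans(sp, 2, seed = 1)
  expect_equal(adjusted_rand_index(asg$labels, rep(1:2, c(5, 4))), 1)
  # K = 1 on a connected graph puts everything in one cluster (on a
  # disconnected graph the degenerate null-space basis can zero out rows,
  # which are then reported unassigned by contract)
  conn <- .two_cliques(5, 4, lo = 6)
  one <- spectral_kmeans(laplacian_spectrum(build_adjacency(conn, 5)), 1,
                         seed = 1)
  expect_true(all(one$labels == 1))
  # determinism under a fixed seed
  expect_identical(spectral_kmeans(sp, 2, seed = 9)$labels,
                   spectral_kmeans(sp, 2, seed = 9)$labels)
})

test_that("removing an isolated node leaves the other labels unchanged", {
  S <- .two_cliques(4, 3)
  ids <- rownames(S)
  iso <- matrix(1, 8, 8, dimnames = list(c(ids, "lonely"), c(ids, "lonely")))
  iso[1:7, 1:7] <- S
  iso["lonely", ] <- iso[, "lonely"] <- 0
  adj_all <- build_adjacency(iso, 5)
  expect_identical(adj_all$isolated, "lonely")
  keep <- setdiff(rownames(adj_all$W), adj_all$isolated)
  sp_a <- laplacian_spectrum(adj_all$W[keep, keep])
  sp_b <- laplacian_spectrum(build_adjacency(S, 5))
  la <- spectral_kmeans(sp_a, 2, seed = 3)$labels
  lb <- spectral_kmeans(sp_b, 2, seed = 3)$labels
  expect_equal(adjusted_rand_index(la, lb), 1)
})

test_that("adjusted_rand_index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 7, 7)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 1, 1)), 0)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2, NA), c(1, 1, 2, 2, 9)), 1)
})
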