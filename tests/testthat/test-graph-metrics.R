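complete_graph <- function(n) {
  W <- matrix(1, n, n); diag(W) <- 0; W
}

test_that("closed forms: complete graphs, paths and paired cliques", {
  K6 <- complete_graph(6)
  D <- graph_distances(to_length(normalize_weights(K6)))
  expect_equal(char_path_length(D), 1)
  expect_equal(transitivity_weighted(K6), 1)
  expect_equal(rich_club_mean(K6), 1)
  expect_equal(strength_mean(complete_graph(3)), 2)

  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 1] <- 1; P3[2, 3] <- P3[3, 2] <- 1
  expect_equal(char_path_length(graph_distances(to_length(P3))), 4 / 3)

  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- complete_graph(4); W[5:8, 5:8] <- complete_graph(4)
  expect_equal(modularity_louvain(W, seed = 1)$Q, 0.5)
  expect_equal(modularity_louvain(complete_graph(5), seed = 1)$Q, 0)

  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S <- S + t(S)
  expect_equal(transitivity_weighted(S), 0)  # a star has no triangles
})

test_that("normalization and length conversion behave at the edges", {
  W <- random_weights(6)
  Wn <- normalize_weights(W * 4)
  expect_equal(max(Wn), 1)
  expect_equal(Wn, W / max(W))
  expect_warning(z <- normalize_weights(matrix(0, 3, 3)), "zero")
  expect_equal(z, matrix(0, 3, 3))
  expect_error(normalize_weights(matrix(-1, 2, 2)), "non-negative")
  L <- to_length(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_equal(L[1, 2], 2)
  expect_equal(to_length(matrix(c(0, 1, 1, 0), 2, 2))[1, 2], 1)
  expect_true(is.infinite(to_length(matrix(0, 2, 2) + diag(0, 2))[1, 2]))
})

test_that("distances, transitivity, strength and rich club match loop oracles", {
  set.seed(14)
  for (rep in 1:40) {
    n <- sample(5:12, 1)
    W <- random_weights(n)
    if (max(W) == 0) next
    Wn <- normalize_weights(W)
    L <- to_length(Wn)
    D <- graph_distances(L)
    # Floyd-Warshall oracle
    Df <- L
    for (k in 1:n) for (a in 1:n) for (b in 1:n)
      Df[a, b] <- min(Df[a, b], Df[a, k] + Df[k, b])
    diag(Df) <- 0
    expect_lt(max(abs(ifelse(is.finite(D), D, -1) -
                        ifelse(is.finite(Df), Df, -1))), 1e-10)
    # transitivity triple loop
    num <- 0
    for (a in 1:n) for (b in 1:n) for (cc in 1:n)
      num <- num + (Wn[a, b] * Wn[b, cc] * Wn[cc, a])^(1 / 3)
    k_ <- rowSums(Wn > 0)
    den <- sum(k_ * (k_ - 1))
    expect_equal(transitivity_weighted(Wn), if (den == 0) 0 else num / den,
                 tolerance = 1e-12)
    expect_equal(strength_mean(Wn), mean(rowSums(Wn)), tolerance = 1e-12)
    # rich club direct formula
    deg <- rowSums(Wn > 0)
    wts <- sort(Wn[upper.tri(Wn)][Wn[upper.tri(Wn)] > 0], decreasing = TRUE)
    phis <- c()
    for (k_lev in seq_len(max(deg))) {
      keep <- deg > k_lev
      if (sum(keep) < 2) next
      sub <- Wn[keep, keep, drop = FALSE]
      ne <- sum(sub[upper.tri(sub)] > 0)
      if (ne == 0) next
      phis <- c(phis, sum(sub[upper.tri(sub)]) / sum(wts[seq_len(ne)]))
    }
    expect_equal(rich_club_mean(Wn),
                 if (length(phis)) mean(phis) else NA_real_)
  }
})

test_that("modularity attains the exhaustive-partition maximum on small graphs", {
  set.seed(15)
  hits <- 0; total <- 0
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    W <- random_weights(n, density = 0.6)
    if (sum(W) == 0) next
    best <- -Inf
    for (p in all_partitions(n))
      best <- max(best, clsmverse:::modularity_q(W, p))
    q <- modularity_louvain(W, seed = rep, restarts = 20)$Q
    total <- total + 1
    if (abs(q - best) < 1e-9) hits <- hits + 1
    expect_lte(q, best + 1e-9)
  }
  expect_gte(hits / total, 0.95)
})

test_that("metrics are scale invariant and permutation equivariant", {
  set.seed(16)
  W <- random_weights(9)
  for (metric in list(
    function(w) char_path_length(graph_distances(to_length(normalize_weights(w)))),
    function(w) transitivity_weighted(normalize_weights(w)),
    function(w) rich_club_mean(normalize_weights(w)),
    function(w) strength_mean(normalize_weights(w)))) {
    expect_equal(metric(W * 7.3), metric(W), tolerance = 1e-9)
    perm <- sample(9)
    expect_equal(metric(W[perm, perm]), metric(W), tolerance = 1e-9)
  }
  # modularity is a stochastic optimizer, so value equivariance holds where
  # the search reliably attains the optimum: small graph, generous restarts
  W7 <- random_weights(7, density = 0.6)
  q <- function(w) modularity_louvain(normalize_weights(w), seed = 3,
                                      restarts = 60)$Q
  expect_equal(q(W7 * 7.3), q(W7), tolerance = 1e-9)
  perm7 <- sample(7)
  expect_equal(q(W7[perm7, perm7]), q(W7), tolerance = 1e-9)
})

test_that("small-worldness separates lattices from random graphs, reproducibly", {
  set.seed(17)
  n <- 24; W <- matrix(0, n, n)
  for (i in 1:n) for (d in 1:2) {
    j <- ((i - 1 + d) %% n) + 1
    W[i, j] <- W[j, i] <- 1
  }
  s_lattice <- small_worldness(W, n_null = 30, seed = 5)
  expect_gt(s_lattice, 1)
  expect_identical(small_worldness(W, n_null = 30, seed = 5), s_lattice)
  Wr <- random_weights(20, density = 0.4)
  s_rand <- small_worldness(normalize_weights(Wr), n_null = 30, seed = 5)
  expect_lt(abs(s_rand - 1), 0.25)
  expect_gt(s_lattice, s_rand)
})

test_that("the metric set handles zero matrices and full connectome quadruples", {
  z <- all_graph_metrics(matrix(0, 5, 5))
  expect_equal(unname(z["strength"]), 0)
  expect_true(all(is.na(z[setdiff(names(z), "strength")])))

  co <- small_cohort()
  cn <- participant_connectomes(co, 1)
  sets <- lapply(cn, all_graph_metrics, seed = 2, n_null = 10, restarts = 5)
  expect_length(unlist(sets), 24)  # 4 networks x 6 metrics
  again <- all_graph_metrics(cn$indirect_roi, seed = 2, n_null = 10,
                             restarts = 5)
  expect_identical(again, sets$indirect_roi)
})
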