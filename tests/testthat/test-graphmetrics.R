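path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
k4 <- matrix(1, 4, 4) - diag(4)
star4 <- rbind(c(0, 1, 1, 1), c(1, 0, 0, 0), c(1, 0, 0, 0), c(1, 0, 0, 0))

test_that("sparsity binarization keeps the heaviest edges deterministically", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.8; w[1, 4] <- 0.7
  w[2, 3] <- 0.1; w[2, 4] <- 0.05; w[3, 4] <- 0.02
  w <- w + t(w)
  adj <- binarize_at_sparsity(w, 0.5)
  expect_equal(sum(adj) / 2, 3)
  expect_equal(adj[1, 2] + adj[1, 3] + adj[1, 4], 3)
  expect_equal(binarize_at_sparsity(w, 1), (w != 0) * 1L, ignore_attr = TRUE)
  expect_error(binarize_at_sparsity(w, 0))
  # edge-count arithmetic at the study scale
  set.seed(1)
  big <- matrix(rnorm(308^2), 308); big <- (big + t(big)) / 2; diag(big) <- 0
  expect_equal(sum(binarize_at_sparsity(big, 0.10)) / 2, 4727)
  # deterministic lexicographic tie-break
  tied <- matrix(0.5, 5, 5); diag(tied) <- 0
  a1 <- binarize_at_sparsity(tied, 0.3)
  expect_identical(a1, binarize_at_sparsity(tied, 0.3))
  expect_equal(sum(a1) / 2, 3)
  expect_equal(a1[1, 2] + a1[1, 3] + a1[1, 4], 3)  # first three in (i,j) order
})

test_that("efficiency measures match closed forms on canonical graphs", {
  expect_equal(global_efficiency(k4), 1)
  expect_equal(global_efficiency(path3), 5 / 6)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  expect_equal(local_efficiency(k4), 1)
  expect_equal(local_efficiency(path3), 0)
  expect_equal(transitivity_coef(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0))), 1)
  expect_equal(transitivity_coef(path3), 0)
})

test_that("modularity is the Newman Q of the Louvain partition", {
  two_k4 <- rbind(cbind(k4, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), k4))
  q <- modularity_louvain(two_k4, seed = 1)
  expect_equal(as.numeric(q), 0.5)
  expect_equal(sort(unique(attr(q, "membership"))), 1:2)
  expect_equal(as.numeric(modularity_louvain(k4, seed = 1)), 0)
  expect_identical(as.numeric(modularity_louvain(two_k4, seed = 3)),
                   as.numeric(modularity_louvain(two_k4, seed = 3)))
  expect_error(modularity_louvain(matrix(0, 3, 3)), "empty graph")
})

test_that("nodal measures match hand-derived star-graph values", {
  nm <- nodal_measures(star4)
  expect_equal(nm$degree, c(3L, 1L, 1L, 1L))
  expect_equal(nm$betweenness, c(3, 0, 0, 0))
  expect_equal(nm$eigenvector[1] / nm$eigenvector[2], sqrt(3),
               tolerance = 1e-10)
  expect_equal(sum(nm$eigenvector^2), 1, tolerance = 1e-10)
  expect_equal(nm$nodal_efficiency, c(1, 2 / 3, 2 / 3, 2 / 3))
  # isolated node gets zero eigenvector centrality
  iso <- rbind(cbind(k4, 0), 0)
  expect_equal(nodal_measures(iso)$eigenvector[5], 0)
})

test_that("all eight measures agree with brute-force oracles on random graphs", {
  set.seed(42)
  for (r in 1:40) {
    n <- sample(5:13, 1)
    adj <- random_adjacency(n, runif(1, 0.25, 0.7))
    expect_equal(global_efficiency(adj), oracle_global_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(adj), oracle_local_efficiency(adj),
                 tolerance = 1e-12)
    expect_equal(transitivity_coef(adj), oracle_transitivity(adj),
                 tolerance = 1e-12)
    nm <- nodal_measures(adj)
    expect_equal(nm$degree, as.integer(rowSums(adj)))
    expect_equal(nm$betweenness, oracle_betweenness(adj), tolerance = 1e-10)
    expect_equal(nm$nodal_efficiency, oracle_nodal_efficiency(adj),
                 tolerance = 1e-12)
    if (sum(adj) > 0) {
      q <- modularity_louvain(adj, seed = r)
      expect_equal(as.numeric(q),
                   oracle_modularity_q(adj, attr(q, "membership")),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding an edge never decreases global efficiency or degree", {
  set.seed(7)
  for (r in 1:10) {
    adj <- random_adjacency(10, 0.3)
    missing <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (!nrow(missing)) next
    pick <- missing[sample(nrow(missing), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
    expect_gte(global_efficiency(adj2), global_efficiency(adj))
    expect_true(all(rowSums(adj2) >= rowSums(adj)))
  }
})

test_that("small-worldness behaves on canonical regimes", {
  # complete graph: surrogates are identical, sigma = 1
  sw <- small_worldness(matrix(1, 12, 12) - diag(12), n_random = 4, seed = 1)
  expect_true(sw$estimable)
  expect_equal(sw$sigma, 1)
  # disconnected graph is not estimable
  two_k4 <- rbind(cbind(k4, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), k4))
  expect_false(small_worldness(two_k4, n_random = 4, seed = 1)$estimable)
  # Watts-Strogatz regime: clustered + shortcuts => sigma > 1.1
  ws_sigma <- vapply(1:8, function(r) {
    g <- igraph::sample_smallworld(1, 80, 4, 0.1)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    adj[adj > 1] <- 1
    small_worldness(adj, n_random = 8, seed = r)$sigma
  }, numeric(1))
  expect_gte(mean(ws_sigma > 1.1, na.rm = TRUE), 0.95)
  # Erdos-Renyi graphs are close to their own surrogates
  er_sigma <- vapply(1:8, function(r) {
    set.seed(100 + r)
    adj <- random_adjacency(80, 0.12)
    sw <- small_worldness(adj, n_random = 8, seed = r)
    if (sw$estimable) sw$sigma else NA_real_
  }, numeric(1))
  expect_gte(mean(er_sigma > 0.8 & er_sigma < 1.2, na.rm = TRUE), 0.85)
})

test_that("threshold-range selection applies both criteria per subject", {
  grid <- c(0.05, 0.07, 0.09, 0.11)
  tab <- expand.grid(subject_id = c("a", "b"), sparsity = grid,
                     stringsAsFactors = FALSE)
  tab$estimable <- TRUE
  tab$sigma <- 2
  expect_equal(select_threshold_range(tab), grid)
  # one subject disconnected at 0.05 only -> range starts at 0.07
  tab2 <- tab
  tab2$estimable[tab2$subject_id == "b" & tab2$sparsity == 0.05] <- FALSE
  tab2$sigma[tab2$subject_id == "b" & tab2$sparsity == 0.05] <- NA
  expect_equal(select_threshold_range(tab2), grid[-1])
  # sigma criterion: a low-sigma subject breaks the run; longest run wins
  tab3 <- tab
  tab3$sigma[tab3$subject_id == "a" & tab3$sparsity == 0.09] <- 1.05
  expect_equal(select_threshold_range(tab3), c(0.05, 0.07))
  tab4 <- tab
  tab4$sigma[tab4$sparsity <= 0.09] <- 1.0
  expect_equal(select_threshold_range(tab4), 0.11)
  tab4$sigma <- 1.0
  expect_error(select_threshold_range(tab4), "no sparsity threshold")
})

test_that("threshold averaging is the unweighted mean and permutation-safe", {
  m1 <- list(global = c(global_efficiency = 0.5, local_efficiency = 0.4,
                        modularity = 0.3, transitivity = 0.2),
             nodal = matrix(1, 3, 4))
  m2 <- list(global = c(global_efficiency = 0.7, local_efficiency = 0.6,
                        modularity = 0.1, transitivity = 0.4),
             nodal = matrix(3, 3, 4))
  avg <- average_over_thresholds(list(m1, m2))
  expect_equal(unname(avg$global["global_efficiency"]), 0.6)
  expect_equal(avg$nodal, matrix(2, 3, 4))
  expect_equal(average_over_thresholds(list(m1)), m1)
  # averaging commutes with node permutation on nodal measures
  set.seed(5)
  ms <- subject_ms_matrix(matrix(rnorm(150), 15, 10))
  perm <- sample(15)
  a <- subject_network_measures(ms, c(0.2, 0.4), seed = 2)
  b <- subject_network_measures(unclass(ms)[perm, perm], c(0.2, 0.4), seed = 2)
  expect_equal(b$nodal[, "degree"], a$nodal[perm, "degree"])
  expect_equal(b$nodal[, "nodal_efficiency"], a$nodal[perm, "nodal_efficiency"],
               tolerance = 1e-10)
})
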