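# Independent brute-force graph oracles for metric verification.
# Everything here is written from the definitions (Floyd-Warshall,
# exhaustive triple counts, BFS path counting) and never calls igraph or
# the package's metric functions.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj != 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

oracle_nodal_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

oracle_transitivity <- function(adj) {
  n <- nrow(adj)
  triangles <- 0
  triples <- 0
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] != 0)
    k <- length(nb)
    if (k < 2) next
    triples <- triples + choose(k, 2)
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] != 0) triangles <- triangles + 1
      }
    }
  }
  # each triangle counted once per corner vertex = 3 times, so the count
  # above already equals 3 * (number of distinct triangles)
  if (triples == 0) return(0)
  triangles / triples
}

# shortest-path betweenness by explicit path counting (BFS level DP per
# source); undirected pairs counted once. sigma[s, v] = number of shortest
# s-v paths; paths through v = sigma[s, v] * sigma[t, v] / sigma[s, t]
# whenever d(s, v) + d(v, t) = d(s, t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sg <- numeric(n)
    sg[s] <- 1
    for (v in order(d[s, ])) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(adj[v, ] != 0 & d[s, ] == d[s, v] - 1)
      sg[v] <- sum(sg[pred])
    }
    sigma[s, ] <- sg
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t]) || d[s, t] < 2) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[t, v] / sigma[s, t]
        }
      }
    }
  }
  btw
}

# modularity Q of a given partition, straight from the definition
oracle_modularity_q <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(NA_real_)
  q <- 0
  for (c in unique(membership)) {
    idx <- which(membership == c)
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(adj[idx, , drop = FALSE])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# leading eigenvector by shifted power iteration (A + I keeps the Perron
# vector and avoids bipartite sign oscillation); restricted to the same
# largest-component convention as the implementation
oracle_eigenvector <- function(adj, tol = 1e-14, max_iter = 100000) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(d[v, ])] <- cid
    }
  }
  sizes <- tabulate(comp)
  giant <- which.max(sizes)
  idx <- which(comp == giant)
  ev <- numeric(n)
  if (length(idx) == 1) {
    ev[idx] <- 1
    return(ev)
  }
  a <- adj[idx, idx, drop = FALSE] + diag(length(idx))
  v <- rep(1 / sqrt(length(idx)), length(idx))
  for (it in seq_len(max_iter)) {
    w <- as.numeric(a %*% v)
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < tol) break
    v <- w
  }
  ev[idx] <- w
  ev
}

random_adjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- as.integer(stats::runif(sum(up)) < p)
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  adj
}

# tiny deterministic cohort for structural tests
tiny_cohort <- function(n_regions = 20, n_hc = 6, n_scz = 6, seed = 3,
                        sites = default_sites("siteA"), ...) {
  generate_cohort(cohort_config(n_regions = n_regions, n_hc = n_hc,
                                n_scz = n_scz, sites = sites,
                                seed = seed, ...))
}
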