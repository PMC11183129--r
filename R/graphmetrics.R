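# Binarized graph construction over a sparsity range and graph-theoretic
# global/nodal measures, with the small-worldness threshold selection rule.

#' Binarize an MS matrix at a sparsity level
#'
#' Ranks the unique edges by weight (signed value, descending: the most
#' similar region pairs are retained first) and keeps the top
#' `floor(s * C(N,2))`. Ties are broken by lexicographic (i, j) order, so
#' the result is deterministic.
#'
#' @param ms An `ms_matrix` (or any symmetric weight matrix).
#' @param s Sparsity: proportion of edges retained, in (0, 1].
#' @param abs_rank If `TRUE`, rank by absolute weight instead.
#' @return N x N symmetric 0/1 adjacency matrix with zero diagonal.
#' @export
binarize_at_sparsity <- function(ms, s, abs_rank = FALSE) {
  assert_scalar_number(s, "s", .Machine$double.eps, 1)
  n <- nrow(ms)
  pairs <- edge_pairs(n)
  w <- edge_vector(unclass(ms), pairs)
  if (abs_rank) w <- abs(w)
  m <- floor(s * pairs$n_edges)
  ord <- order(-w, pairs$i, pairs$j)
  keep <- ord[seq_len(m)]
  adj <- matrix(0L, n, n)
  adj[cbind(pairs$i[keep], pairs$j[keep])] <- 1L
  adj[cbind(pairs$j[keep], pairs$i[keep])] <- 1L
  adj
}

.graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' `1/Inf := 0` for disconnected pairs.
#' @param adj Binary symmetric adjacency matrix.
#' @return A number in \[0, 1\].
#' @export
global_efficiency <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- igraph::distances(.graph_from_adj(adj))
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbours; nodes with fewer than 2 neighbours contribute 0.
#' @param adj Binary symmetric adjacency matrix.
#' @return A number in \[0, 1\].
#' @export
local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    global_efficiency(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

#' Transitivity (whole-graph clustering coefficient)
#'
#' `3 * triangles / connected triples`; 0 by convention when the graph has
#' no connected triple.
#' @param adj Binary symmetric adjacency matrix.
#' @return A number in \[0, 1\].
#' @export
transitivity_coef <- function(adj) {
  tr <- igraph::transitivity(.graph_from_adj(adj), type = "global")
  if (is.nan(tr) || is.na(tr)) 0 else tr
}

#' Newman modularity of the Louvain partition
#'
#' Runs Louvain community detection under a fixed seed and returns the
#' modularity Q of the partition found.
#' @param adj Binary symmetric adjacency matrix.
#' @param seed Integer seed (Louvain is stochastic).
#' @return Modularity Q and the membership vector (as attribute
#'   `membership`).
#' @export
modularity_louvain <- function(adj, seed = 1L) {
  g <- .graph_from_adj(adj)
  if (igraph::ecount(g) == 0) stop("modularity is undefined on an empty graph")
  cl <- local_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(cl)
  q <- igraph::modularity(g, memb)
  attr(q, "membership") <- as.integer(memb)
  q
}

#' Nodal network measures
#'
#' Degree (row sum), betweenness centrality (unnormalized shortest-path
#' betweenness), eigenvector centrality (leading eigenvector of the
#' adjacency restricted to the largest connected component, nonnegative,
#' unit Euclidean norm; nodes outside that component get 0), and nodal
#' efficiency (mean inverse distance to the other N - 1 nodes).
#'
#' @param adj Binary symmetric adjacency matrix.
#' @return A data frame with columns `degree`, `betweenness`,
#'   `eigenvector`, `nodal_efficiency`.
#' @export
nodal_measures <- function(adj) {
  n <- nrow(adj)
  g <- .graph_from_adj(adj)
  degree <- as.integer(rowSums(adj != 0))
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  nodal_eff <- rowSums(inv) / (n - 1)
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  in_giant <- which(comp$membership == giant)
  ev <- numeric(n)
  if (length(in_giant) >= 2) {
    sub <- adj[in_giant, in_giant, drop = FALSE]
    es <- eigen(sub, symmetric = TRUE)
    v <- es$vectors[, 1]
    if (sum(v) < 0) v <- -v
    v[v < 0 & v > -1e-10] <- 0
    ev[in_giant] <- v / sqrt(sum(v^2))
  } else if (length(in_giant) == 1) {
    ev[in_giant] <- 1
  }
  data.frame(degree = degree, betweenness = as.numeric(btw),
             eigenvector = ev, nodal_efficiency = nodal_eff)
}

#' Small-worldness scalar
#'
#' `sigma = (C / C_rand) / (L / L_rand)`, where C is the transitivity-based
#' clustering coefficient, L the characteristic path length, and the
#' reference values are means over degree-preserving rewired surrogates
#' (Maslov-Sneppen, 10 swap attempts per edge). The graph must be
#' connected, otherwise sigma is not estimable and `NA` is returned with
#' `estimable = FALSE`; surrogate path lengths are averaged over reachable
#' pairs so an occasionally disconnected surrogate stays finite.
#'
#' @param adj Binary symmetric adjacency matrix.
#' @param n_random Number of rewired surrogates (default 20).
#' @param seed Integer seed.
#' @return A list `list(sigma, estimable, C, L, C_rand, L_rand)`.
#' @export
small_worldness <- function(adj, n_random = 20L, seed = 1L) {
  g <- .graph_from_adj(adj)
  if (igraph::vcount(g) < 3 || !igraph::is_connected(g)) {
    return(list(sigma = NA_real_, estimable = FALSE,
                C = NA_real_, L = NA_real_,
                C_rand = NA_real_, L_rand = NA_real_))
  }
  C <- transitivity_coef(adj)
  L <- igraph::mean_distance(g)
  sur <- local_seed(seed, {
    lapply(seq_len(n_random), function(k) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
      c(igraph::transitivity(gr, type = "global"),
        igraph::mean_distance(gr, unconnected = TRUE))
    })
  })
  sur <- do.call(rbind, sur)
  C_rand <- mean(sur[, 1], na.rm = TRUE)
  L_rand <- mean(sur[, 2], na.rm = TRUE)
  if (!is.finite(C_rand) || !is.finite(L_rand) || C_rand == 0 || L_rand == 0) {
    return(list(sigma = NA_real_, estimable = FALSE, C = C, L = L,
                C_rand = C_rand, L_rand = L_rand))
  }
  sigma <- (C / C_rand) / (L / L_rand)
  list(sigma = sigma, estimable = TRUE, C = C, L = L,
       C_rand = C_rand, L_rand = L_rand)
}

#' Candidate sparsity grid
#' @param from,to,by Grid limits and step (defaults 0.05 to 0.45 by 0.02).
#' @return Numeric vector.
#' @export
sparsity_grid <- function(from = 0.05, to = 0.45, by = 0.02) {
  g <- seq(from, to, by = by)
  if (any(g <= 0 | g > 1)) stop("sparsity grid must lie in (0, 1]")
  g
}

#' Small-worldness of every subject at every candidate sparsity
#'
#' @param ms_list Named list of `ms_matrix` objects.
#' @param grid Candidate sparsity grid.
#' @param n_random Surrogates per sigma estimate.
#' @param seed Integer seed.
#' @return Data frame with `subject_id`, `sparsity`, `estimable`, `sigma`.
#' @export
evaluate_smallworld_grid <- function(ms_list, grid = sparsity_grid(),
                                     n_random = 20L, seed = 1L) {
  ids <- names(ms_list) %||% as.character(seq_along(ms_list))
  rows <- list()
  for (s_idx in seq_along(grid)) {
    for (m_idx in seq_along(ms_list)) {
      adj <- binarize_at_sparsity(ms_list[[m_idx]], grid[s_idx])
      sw <- small_worldness(adj, n_random = n_random,
                            seed = seed + 7919L * s_idx + m_idx)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[m_idx], sparsity = grid[s_idx],
        estimable = sw$estimable, sigma = sw$sigma)
    }
  }
  do.call(rbind, rows)
}

#' Select the analysis sparsity range
#'
#' Applies the two construction criteria at every candidate threshold:
#' (1) the small-worldness scalar must be estimable (connected network) for
#' every subject, and (2) every subject's sigma must exceed `sigma_min`
#' (default 1.1). Returns the longest contiguous run of qualifying
#' thresholds (the first such run on ties).
#'
#' @param sw_table Data frame from [evaluate_smallworld_grid()].
#' @param sigma_min Minimum small-worldness scalar (default 1.1).
#' @return Numeric vector: the selected contiguous sparsity grid.
#' @export
select_threshold_range <- function(sw_table, sigma_min = 1.1) {
  grid <- sort(unique(sw_table$sparsity))
  ok <- vapply(grid, function(s) {
    rows <- sw_table[sw_table$sparsity == s, ]
    all(rows$estimable) && all(rows$sigma > sigma_min)
  }, logical(1))
  if (!any(ok)) {
    diag_counts <- vapply(grid, function(s) {
      rows <- sw_table[sw_table$sparsity == s, ]
      sum(!rows$estimable | !(rows$sigma > sigma_min), na.rm = TRUE)
    }, numeric(1))
    stop("no sparsity threshold satisfies the construction criteria; ",
         "failing subjects per threshold: ",
         paste(sprintf("%.2f:%d", grid, diag_counts), collapse = ", "))
  }
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  true_runs <- which(runs$values)
  best <- true_runs[which.max(runs$lengths[true_runs])]
  grid[starts[best]:ends[best]]
}

#' Global measures of one binarized graph
#' @param adj Binary symmetric adjacency matrix.
#' @param seed Seed for the Louvain partition.
#' @return Named numeric vector: `global_efficiency`, `local_efficiency`,
#'   `modularity`, `transitivity`.
#' @export
global_measures <- function(adj, seed = 1L) {
  c(global_efficiency = global_efficiency(adj),
    local_efficiency = local_efficiency(adj),
    modularity = as.numeric(modularity_louvain(adj, seed = seed)),
    transitivity = transitivity_coef(adj))
}

#' Threshold-averaged network measures for one subject
#'
#' Binarizes the subject's MS matrix at each sparsity of the selected grid,
#' computes the four global and four nodal measures, and averages them
#' unweighted over the grid.
#'
#' @param ms An `ms_matrix`.
#' @param grid Selected sparsity grid.
#' @param seed Integer seed (Louvain).
#' @return A list with `global` (named length-4 vector) and `nodal`
#'   (regions x 4 matrix).
#' @export
subject_network_measures <- function(ms, grid, seed = 1L) {
  per_thr <- lapply(seq_along(grid), function(k) {
    adj <- binarize_at_sparsity(ms, grid[k])
    list(global = global_measures(adj, seed = seed + k),
         nodal = as.matrix(nodal_measures(adj)))
  })
  average_over_thresholds(per_thr)
}

#' Average measures over sparsity thresholds
#'
#' Unweighted elementwise mean of per-threshold measure sets.
#' @param measure_list List of `list(global, nodal)` entries, one per
#'   threshold.
#' @return A single `list(global, nodal)`.
#' @export
average_over_thresholds <- function(measure_list) {
  stopifnot(length(measure_list) >= 1)
  g <- Reduce(`+`, lapply(measure_list, `[[`, "global")) / length(measure_list)
  nodal <- Reduce(`+`, lapply(measure_list, `[[`, "nodal")) / length(measure_list)
  list(global = g, nodal = nodal)
}

#' Threshold-averaged measures for a whole cohort
#'
#' @param ms_list Named list of `ms_matrix` objects.
#' @param grid Selected sparsity grid.
#' @param seed Integer seed.
#' @return A list with `global` (subjects x 4 matrix) and `nodal`
#'   (subjects x regions x 4 array).
#' @export
cohort_network_measures <- function(ms_list, grid, seed = 1L) {
  ids <- names(ms_list) %||% as.character(seq_along(ms_list))
  first <- subject_network_measures(ms_list[[1]], grid, seed = seed)
  n_reg <- nrow(first$nodal)
  global <- matrix(NA_real_, length(ms_list), 4,
                   dimnames = list(ids, names(first$global)))
  nodal <- array(NA_real_, c(length(ms_list), n_reg, 4),
                 dimnames = list(ids, NULL, colnames(first$nodal)))
  global[1, ] <- first$global
  nodal[1, , ] <- first$nodal
  if (length(ms_list) > 1) {
    for (s in 2:length(ms_list)) {
      m <- subject_network_measures(ms_list[[s]], grid, seed = seed + 131L * s)
      global[s, ] <- m$global
      nodal[s, , ] <- m$nodal
    }
  }
  list(global = global, nodal = nodal)
}
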