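# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's `.Random.seed` afterwards so that seeded package
#' operations never perturb the global RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Upper-triangle edge enumeration in lexicographic (i, j) order
#'
#' Fixed edge ordering used everywhere an N x N symmetric matrix is
#' flattened to its C(N,2) unique edges; lexicographic order is also the
#' deterministic tie-break for sparsity thresholding.
#' @noRd
edge_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  list(i = i, j = j, n_edges = (n * (n - 1L)) %/% 2L)
}

#' Flatten the unique edges of a symmetric matrix (lexicographic order)
#' @noRd
edge_vector <- function(mat, pairs = edge_pairs(nrow(mat))) {
  mat[cbind(pairs$i, pairs$j)]
}

#' Rebuild a symmetric matrix (zero diagonal) from an edge vector
#' @noRd
edge_matrix <- function(values, n, pairs = edge_pairs(n)) {
  m <- matrix(0, n, n)
  m[cbind(pairs$i, pairs$j)] <- values
  m[cbind(pairs$j, pairs$i)] <- values
  m
}

#' Vectorized OLS t-statistics for one coefficient across many responses
#'
#' Fits y ~ X by least squares for every column of `Y` at once and returns
#' the estimate, t statistic and residual df for the coefficient in column
#' `coef_index` of `X`. Shared by the edge-wise GLM and the unit-wise group
#' comparisons.
#' @noRd
ols_tstats <- function(Y, X, coef_index) {
  Y <- as.matrix(Y)
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(Y) != n) stop("Y and X disagree on the number of observations")
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qx))
  A <- xtx_inv %*% t(X)               # p x n pseudo-inverse
  coefs <- A %*% Y                    # p x E
  fitted <- X %*% coefs
  rss <- colSums((Y - fitted)^2)
  df <- n - p
  sigma2 <- rss / df
  se <- sqrt(sigma2 * xtx_inv[coef_index, coef_index])
  est <- coefs[coef_index, ]
  tval <- ifelse(se > 0, est / se, 0)
  list(estimate = est, t = tval, df = df, rss = rss, se = se)
}

#' Connected components of an edge list via union-find
#'
#' Path-compressed union-find over integer node ids; independent of igraph
#' so the permutation loop of the network-based statistic stays cheap.
#' Returns a membership vector over `seq_len(n)`.
#' @noRd
uf_components <- function(i, j, n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(i)) {
    ri <- find(i[k]); rj <- find(j[k])
    if (ri != rj) parent[ri] <- rj
  }
  vapply(seq_len(n), find, integer(1))
}

#' Maximum component extent (edge count) of a supra-threshold edge set
#' @noRd
max_component_extent <- function(i, j, n) {
  if (length(i) == 0L) return(0L)
  nodes <- sort(unique(c(i, j)))
  idx <- match(c(i, j), nodes)
  ii <- idx[seq_along(i)]
  jj <- idx[seq_along(i) + length(i)]
  memb <- uf_components(ii, jj, length(nodes))
  max(tabulate(memb[ii], nbins = length(nodes)))
}

#' Write a data frame as CSV without row names
#' @noRd
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
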