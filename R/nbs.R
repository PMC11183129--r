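# Network-based statistic: edge-wise covariate-adjusted group inference
# with permutation family-wise error control over component extents.

#' Bonferroni-derived initial edge threshold
#'
#' The NBS primary threshold used here is alpha divided by the number of
#' unique region-region connections.
#' @param alpha Family-wise alpha (in (0, 1)).
#' @param n_edges Number of unique connections.
#' @return A single p-value threshold.
#' @examples
#' bonferroni_initial_threshold(0.05, 47228)  # ~1.06e-6
#' @export
bonferroni_initial_threshold <- function(alpha, n_edges) {
  assert_scalar_number(alpha, "alpha", .Machine$double.eps, 1 - 1e-12)
  if (!is.numeric(n_edges) || n_edges < 1) stop("n_edges must be >= 1")
  alpha / n_edges
}

#' Build the group-comparison design matrix
#'
#' Columns: intercept, group (SCZ = 1), age, sex (male = 1), age x sex.
#' The estimate sign convention is SCZ - HC, so "lower in patients" means a
#' negative t.
#' @param meta Metadata data frame with `group`, `age`, `sex`.
#' @return A list with `X` (n x 5), `coef_index` (the group column).
#' @export
group_design <- function(meta) {
  group <- as.numeric(meta$group == "SCZ")
  sex <- as.numeric(meta$sex == "male")
  age <- as.numeric(meta$age)
  if (length(unique(group)) < 2) stop("both groups must be present")
  X <- cbind(intercept = 1, group = group)
  if (qr(X)$rank < 2L) stop("design matrix is rank deficient")
  # degenerate covariates (constant age or single-sex cohorts) are dropped so
  # the model gracefully reduces to the pooled two-sample comparison
  covs <- list(age = age, sex = sex, age_sex = age * sex)
  kept <- c("intercept", "group")
  for (nm in names(covs)) {
    cand <- cbind(X, covs[[nm]])
    if (qr(cand)$rank == ncol(cand)) {
      X <- cand
      kept <- c(kept, nm)
    }
  }
  colnames(X) <- kept
  list(X = X, coef_index = 2L)
}

#' Edge-wise group GLM over an MS edge stack
#'
#' Ordinary least squares of each edge weight on
#' \[intercept, group, age, sex, age x sex\], with a one-sided t test of
#' the group coefficient in the requested direction.
#'
#' @param stack An edge stack from [ms_edge_stack()].
#' @param meta Metadata data frame (rows aligned with the stack).
#' @param direction `"HC_gt_SCZ"` (controls stronger) or `"HC_lt_SCZ"`.
#' @return A list of class `edge_stat_map`: `t` and `p` as N x N symmetric
#'   matrices (diagonal 0 / 1), the flat `t_edges`, `p_edges`, `df`,
#'   `pairs`, `direction`.
#' @export
edgewise_glm <- function(stack, meta, direction = c("HC_gt_SCZ", "HC_lt_SCZ")) {
  direction <- match.arg(direction)
  des <- group_design(meta)
  groups <- table(meta$group)
  if (any(groups < 2)) stop("need at least 2 subjects per group")
  fit <- ols_tstats(stack$edges, des$X, des$coef_index)
  p_edges <- one_sided_p(fit$t, fit$df, direction)
  n <- stack$n_regions
  pm <- edge_matrix(p_edges, n, stack$pairs)
  diag(pm) <- 1
  structure(list(
    t = edge_matrix(fit$t, n, stack$pairs),
    p = pm,
    t_edges = fit$t, p_edges = p_edges, estimate = fit$estimate,
    df = fit$df, pairs = stack$pairs, n_regions = n,
    direction = direction
  ), class = "edge_stat_map")
}

# One-sided p for the SCZ - HC coefficient. HC_gt_SCZ looks for negative t.
one_sided_p <- function(tval, df, direction) {
  switch(direction,
         HC_gt_SCZ = stats::pt(tval, df, lower.tail = TRUE),
         HC_lt_SCZ = stats::pt(tval, df, lower.tail = FALSE),
         stop("unknown direction"))
}

#' Connected components of the supra-threshold edge graph
#'
#' Keeps edges with p below the threshold and returns the connected
#' components of the resulting graph, each with its edge list and extent
#' (edge count).
#' @param stat An `edge_stat_map`.
#' @param threshold Primary p-value threshold.
#' @return List of components, each `list(edges, extent)`; empty list when
#'   no edge survives.
#' @export
suprathreshold_components <- function(stat, threshold) {
  keep <- which(stat$p_edges < threshold)
  if (!length(keep)) return(list())
  i <- stat$pairs$i[keep]; j <- stat$pairs$j[keep]
  nodes <- sort(unique(c(i, j)))
  memb <- uf_components(match(i, nodes), match(j, nodes), length(nodes))
  comp_of_edge <- memb[match(i, nodes)]
  comps <- lapply(split(seq_along(keep), comp_of_edge), function(idx) {
    list(edges = data.frame(i = i[idx], j = j[idx],
                            t = stat$t_edges[keep][idx],
                            p = stat$p_edges[keep][idx]),
         extent = length(idx))
  })
  comps <- unname(comps[order(vapply(comps, `[[`, 0L, "extent"),
                              decreasing = TRUE)])
  comps
}

#' Network-based statistic test
#'
#' Observed supra-threshold components are compared against a permutation
#' null distribution of the maximum component extent. Nuisance covariates
#' (age, sex, age x sex) are handled by Freedman-Lane residual permutation
#' by default: residuals of the reduced (nuisance-only) model are permuted,
#' added back to the reduced fit, and the full model is refitted. Each
#' component's family-wise error p is
#' `(1 + #\{null max extent >= observed extent\}) / (1 + n_perm)`.
#'
#' @param stack Edge stack from [ms_edge_stack()].
#' @param meta Metadata data frame aligned with the stack.
#' @param direction `"HC_gt_SCZ"` or `"HC_lt_SCZ"`.
#' @param initial_threshold Primary edge p threshold (see
#'   [bonferroni_initial_threshold()]).
#' @param n_perm Number of permutations (default 5000).
#' @param seed Integer seed (required for reproducibility).
#' @param perm_scheme `"manly"` (default: permute whole subject rows and
#'   recompute the nuisance-residualized pivot; exact when subjects are
#'   exchangeable under the null, and the scheme used by the original NBS
#'   implementation), `"freedman_lane"` (permute residuals of the reduced
#'   model) or `"labels"` (simple permutation of the group labels).
#' @param chunk_size Permutations per vectorized block.
#' @return A list of class `nbs_result`: `components` (with `fwer_p`),
#'   `null_max_extent`, `initial_threshold`, `n_perm`, `direction`,
#'   `edge_stats`.
#' @export
nbs_test <- function(stack, meta,
                     direction = c("HC_gt_SCZ", "HC_lt_SCZ"),
                     initial_threshold, n_perm = 5000L, seed,
                     perm_scheme = c("manly", "freedman_lane", "labels"),
                     chunk_size = 250L) {
  direction <- match.arg(direction)
  perm_scheme <- match.arg(perm_scheme)
  if (missing(seed)) stop("a seed is required for a reproducible NBS run")
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  assert_scalar_number(initial_threshold, "initial_threshold", 0, 1)

  obs <- edgewise_glm(stack, meta, direction)
  components <- suprathreshold_components(obs, initial_threshold)

  des <- group_design(meta)
  X <- des$X
  gidx <- des$coef_index
  Y <- stack$edges
  n <- nrow(Y)
  df <- n - ncol(X)
  tcrit <- stats::qt(initial_threshold, df,
                     lower.tail = (direction == "HC_gt_SCZ"))
  # supra-threshold rule on t directly (equivalent to p < threshold)
  supra_fun <- if (direction == "HC_gt_SCZ") {
    function(tv) tv < tcrit
  } else {
    function(tv) tv > tcrit
  }

  if (perm_scheme != "labels") {
    # Partial-correlation pivot: with u the unit-norm nuisance residual of
    # the group regressor, r_e = u'M_Z y_e / ||M_Z y_e|| maps monotonically
    # onto the full-model t, and the observed statistic is exactly the
    # identity permutation of the permuted formula — so observed and null
    # statistics are symmetric by construction.
    #   manly:          permute raw subject rows of Y, re-residualize
    #                   (numerator needs no re-projection since u is
    #                   already orthogonal to the nuisance space)
    #   freedman_lane:  permute rows of the reduced-model residuals R,
    #                   whose norms are permutation-invariant
    Z <- X[, -gidx, drop = FALSE]
    qz <- qr(Z)
    Qz <- qr.Q(qz)
    gam <- solve(crossprod(Z), crossprod(Z, Y))
    R <- Y - Z %*% gam
    g_res <- stats::lm.fit(Z, X[, gidx])$residuals
    u <- g_res / sqrt(sum(g_res^2))
    rcrit <- tcrit / sqrt(df + tcrit^2)           # same threshold on r scale
    supra_r <- if (direction == "HC_gt_SCZ") {
      function(rv) rv < rcrit
    } else {
      function(rv) rv > rcrit
    }
    if (perm_scheme == "freedman_lane") {
      edge_norm <- sqrt(colSums(R^2))
      edge_norm[edge_norm == 0] <- Inf
    } else {
      tot_norm2 <- colSums(Y^2)
    }
  }

  null_max <- integer(n_perm)
  perms_done <- 0L
  local_seed(seed, {
    while (perms_done < n_perm) {
      m <- min(chunk_size, n_perm - perms_done)
      perms <- replicate(m, sample.int(n), simplify = FALSE)
      if (perm_scheme == "freedman_lane") {
        U <- matrix(0, m, n)                      # permuted unit contrasts
        for (k in seq_len(m)) U[k, perms[[k]]] <- u
        rv_all <- (U %*% R) / rep(edge_norm, each = m)
        for (k in seq_len(m)) {
          keep <- which(supra_r(rv_all[k, ]))
          null_max[perms_done + k] <- max_component_extent(
            stack$pairs$i[keep], stack$pairs$j[keep], stack$n_regions)
        }
      } else if (perm_scheme == "manly") {
        # gather u and the nuisance basis rows per permutation; one matmul
        # per chunk gives both the numerators and the projection norms
        q <- ncol(Qz)
        big <- matrix(0, m * (q + 1L), n)
        for (k in seq_len(m)) {
          pk <- perms[[k]]
          r0 <- (k - 1L) * (q + 1L)
          big[r0 + 1L, pk] <- u
          big[r0 + 1L + seq_len(q), pk] <- t(Qz)
        }
        cp <- big %*% Y
        for (k in seq_len(m)) {
          r0 <- (k - 1L) * (q + 1L)
          res_norm2 <- tot_norm2 -
            colSums(cp[r0 + 1L + seq_len(q), , drop = FALSE]^2)
          res_norm2[res_norm2 <= 0] <- Inf
          rv <- cp[r0 + 1L, ] / sqrt(res_norm2)
          keep <- which(supra_r(rv))
          null_max[perms_done + k] <- max_component_extent(
            stack$pairs$i[keep], stack$pairs$j[keep], stack$n_regions)
        }
      } else {
        for (k in seq_len(m)) {
          Xp <- X
          Xp[, gidx] <- X[perms[[k]], gidx]
          fit <- ols_tstats(Y, Xp, gidx)
          tv <- fit$t
          keep <- which(supra_fun(tv))
          null_max[perms_done + k] <- max_component_extent(
            stack$pairs$i[keep], stack$pairs$j[keep], stack$n_regions)
        }
      }
      perms_done <- perms_done + m
    }
  })

  for (c in seq_along(components)) {
    ext <- components[[c]]$extent
    components[[c]]$fwer_p <- (1 + sum(null_max >= ext)) / (1 + n_perm)
  }
  structure(list(components = components, null_max_extent = null_max,
                 initial_threshold = initial_threshold, n_perm = n_perm,
                 direction = direction, edge_stats = obs,
                 perm_scheme = perm_scheme),
            class = "nbs_result")
}

#' Tidy tables from an NBS result
#'
#' @param res An `nbs_result`.
#' @param region_names Optional region names for edge labelling.
#' @return A list with `edges` (region_i, region_j, t, p, component_id) and
#'   `summary` (component_id, extent, fwer_p, n_nodes).
#' @export
nbs_tables <- function(res, region_names = NULL) {
  if (!length(res$components)) {
    return(list(edges = data.frame(), summary = data.frame()))
  }
  edges <- do.call(rbind, lapply(seq_along(res$components), function(c) {
    e <- res$components[[c]]$edges
    e$component_id <- c
    e
  }))
  if (!is.null(region_names)) {
    edges$region_i <- region_names[edges$i]
    edges$region_j <- region_names[edges$j]
  }
  summary <- data.frame(
    component_id = seq_along(res$components),
    extent = vapply(res$components, `[[`, 0L, "extent"),
    fwer_p = vapply(res$components, `[[`, 0, "fwer_p"),
    n_nodes = vapply(res$components, function(c)
      length(unique(c(c$edges$i, c$edges$j))), 0L)
  )
  list(edges = edges, summary = summary)
}
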