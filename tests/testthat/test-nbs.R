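meta_basic <- function(n_per_group, age = NULL, sex = NULL, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  data.frame(group = rep(c("HC", "SCZ"), each = n_per_group),
             age = age %||% rnorm(n, 35, 10),
             sex = sex %||% sample(c("male", "female"), n, replace = TRUE))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("Bonferroni initial threshold reproduces the published rounding", {
  expect_equal(round(bonferroni_initial_threshold(0.05, 47228), 7), 0.0000011)
  expect_equal(round(bonferroni_initial_threshold(0.05, choose(308, 2)), 7),
               0.0000011)  # the computed C(308,2) rounds identically
  expect_equal(bonferroni_initial_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_initial_threshold(1.5, 10))
  expect_error(bonferroni_initial_threshold(0.05, 0))
})

test_that("edge-wise GLM reduces to the pooled two-sample t without covariates", {
  set.seed(3)
  n <- 30
  pairs <- mscortex:::edge_pairs(6)
  Y <- matrix(rnorm(n * pairs$n_edges), n)
  stack <- list(edges = Y, pairs = pairs, n_regions = 6)
  meta <- meta_basic(15, age = rep(40, n), sex = rep("male", n))
  res <- edgewise_glm(stack, meta, "HC_lt_SCZ")
  for (e in c(1, 7, 15)) {
    tt <- t.test(Y[16:30, e], Y[1:15, e], var.equal = TRUE)
    expect_equal(unname(res$t_edges[e]), unname(tt$statistic),
                 tolerance = 1e-10)
  }
  # identical groups give t = 0
  Y2 <- rbind(Y[1:15, ], Y[1:15, ])
  stack2 <- list(edges = Y2, pairs = pairs, n_regions = 6)
  res2 <- edgewise_glm(stack2, meta, "HC_gt_SCZ")
  expect_lt(max(abs(res2$t_edges)), 1e-10)
  # symmetric matrices, p in [0, 1]
  expect_equal(res$t, t(res$t))
  expect_true(all(res$p_edges >= 0 & res$p_edges <= 1))
})

test_that("an implanted strong edge shift is detected below the initial threshold", {
  thr <- bonferroni_initial_threshold(0.05, 47228)
  hits <- vapply(1:20, function(r) {
    set.seed(r)
    n <- 100
    pairs <- mscortex:::edge_pairs(5)
    Y <- matrix(rnorm(n * pairs$n_edges), n)
    Y[51:100, 4] <- Y[51:100, 4] + 2      # 2 pooled SDs, n = 50/group
    stack <- list(edges = Y, pairs = pairs, n_regions = 5)
    meta <- data.frame(group = rep(c("HC", "SCZ"), each = 50),
                       age = rnorm(n, 35, 8),
                       sex = sample(c("male", "female"), n, TRUE))
    res <- edgewise_glm(stack, meta, "HC_lt_SCZ")
    res$p_edges[4] < thr
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("supra-threshold component extraction matches hand-worked graphs", {
  pairs <- mscortex:::edge_pairs(6)
  p_edges <- rep(0.9, pairs$n_edges)
  stat <- list(p_edges = p_edges, t_edges = rep(0, pairs$n_edges),
               pairs = pairs, n_regions = 6)
  expect_equal(suprathreshold_components(stat, 0.01), list())
  # edges (1,2), (2,3), (4,5): components of extents 2 and 1
  idx <- function(i, j) which(pairs$i == i & pairs$j == j)
  stat$p_edges[c(idx(1, 2), idx(2, 3), idx(4, 5))] <- 1e-5
  comps <- suprathreshold_components(stat, 1e-4)
  expect_equal(length(comps), 2)
  expect_equal(vapply(comps, `[[`, 0L, "extent"), c(2L, 1L))
  expect_setequal(c(comps[[1]]$edges$i, comps[[1]]$edges$j), c(1, 2, 3))
  # cross-check against igraph components on a random supra set
  set.seed(8)
  stat$p_edges <- runif(pairs$n_edges)
  comps2 <- suprathreshold_components(stat, 0.3)
  keep <- which(stat$p_edges < 0.3)
  g <- igraph::graph_from_edgelist(cbind(pairs$i[keep], pairs$j[keep]),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  ext <- sort(as.integer(table(memb[pairs$i[keep]])), decreasing = TRUE)
  expect_equal(vapply(comps2, `[[`, 0L, "extent"), ext[ext > 0])
})

test_that("NBS runs are reproducible and fwer_p is monotone in extent", {
  co <- tiny_cohort(n_regions = 15, n_hc = 10, n_scz = 10, seed = 31,
                    effect_regions = c(1L, 2L, 3L), effect_strength = 0.8)
  stack <- ms_edge_stack(cohort_ms_matrices(co))
  meta <- cohort_metadata(co)
  r1 <- nbs_test(stack, meta, "HC_gt_SCZ", 0.005, n_perm = 300, seed = 5)
  r2 <- nbs_test(stack, meta, "HC_gt_SCZ", 0.005, n_perm = 300, seed = 5)
  expect_identical(vapply(r1$components, `[[`, 0, "fwer_p"),
                   vapply(r2$components, `[[`, 0, "fwer_p"))
  if (length(r1$components) >= 2) {
    ext <- vapply(r1$components, `[[`, 0L, "extent")
    fp <- vapply(r1$components, `[[`, 0, "fwer_p")
    expect_true(all(diff(fp[order(-ext)]) >= 0))
  }
  # permutation p never exactly zero (add-one correction)
  expect_true(all(vapply(r1$components, `[[`, 0, "fwer_p") > 0))
  expect_error(nbs_test(stack, meta, "HC_gt_SCZ", 0.005, n_perm = 300),
               "seed")
  expect_warning(nbs_test(stack, meta, "HC_gt_SCZ", 0.005, n_perm = 50,
                          seed = 1), "100 permutations")
})

test_that("both one-sided directions find their own planted effects", {
  set.seed(12)
  n <- 60
  nreg <- 12
  pairs <- mscortex:::edge_pairs(nreg)
  Y <- matrix(rnorm(n * pairs$n_edges), n)
  up_edges <- which(pairs$i <= 4 & pairs$j <= 4)     # clique raised in SCZ
  down_edges <- which(pairs$i >= 9 & pairs$j >= 9)   # clique lowered in SCZ
  scz <- 31:60
  Y[scz, up_edges] <- Y[scz, up_edges] + 2
  Y[scz, down_edges] <- Y[scz, down_edges] - 2
  stack <- list(edges = Y, pairs = pairs, n_regions = nreg)
  meta <- meta_basic(30, seed = 2)
  r_dn <- nbs_test(stack, meta, "HC_gt_SCZ", 0.001, n_perm = 500, seed = 3)
  r_up <- nbs_test(stack, meta, "HC_lt_SCZ", 0.001, n_perm = 500, seed = 3)
  top_dn <- r_dn$components[[1]]$edges
  top_up <- r_up$components[[1]]$edges
  expect_true(all(unique(c(top_dn$i, top_dn$j)) %in% 9:12))
  expect_true(all(unique(c(top_up$i, top_up$j)) %in% 1:4))
  expect_lt(r_dn$components[[1]]$fwer_p, 0.05)
  expect_lt(r_up$components[[1]]$fwer_p, 0.05)
})
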