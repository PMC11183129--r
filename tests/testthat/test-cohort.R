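test_that("cohort generation respects group counts, metadata and determinism", {
  cfg <- cohort_config(n_regions = 24, n_hc = 8, n_scz = 7,
                       sites = default_sites(), seed = 11)
  co <- generate_cohort(cfg)
  meta <- cohort_metadata(co)
  expect_equal(sum(meta$group == "HC"), 8)
  expect_equal(sum(meta$group == "SCZ"), 7)
  expect_equal(dim(co$subjects[[1]]$features), c(24, 10))
  expect_false(anyNA(co$subjects[[5]]$features))
  expect_true(all(meta$age > 0))
  # controls carry no illness-specific clinical values
  expect_true(all(is.na(meta$illness_duration[meta$group == "HC"])))
  expect_true(all(meta$illness_duration[meta$group == "SCZ"] >= 0))
  expect_identical(generate_cohort(cfg), co)
})

test_that("single reference site leaves features undistorted (identity site step)", {
  base_site <- list(list(name = "only", location_shift = rep(0, 10),
                         scale_factor = rep(1, 10)))
  co <- generate_cohort(cohort_config(n_regions = 12, n_hc = 3, n_scz = 3,
                                      sites = base_site, seed = 4))
  # distorted variant of the same cohort: same seed, shifted/scaled site
  shifted <- list(list(name = "only", location_shift = rep(1, 10),
                       scale_factor = rep(2, 10)))
  co2 <- generate_cohort(cohort_config(n_regions = 12, n_hc = 3, n_scz = 3,
                                       sites = shifted, seed = 4))
  f1 <- co$subjects[[1]]$features
  f2 <- co2$subjects[[1]]$features
  expect_equal(f2, sweep(f1 * 2, 2, MS_FEATURES$base_sd, "+"),
               tolerance = 1e-12)
})

test_that("illness duration tracks age (the collinearity the model flags)", {
  co <- generate_cohort(cohort_config(n_regions = 10, n_hc = 5, n_scz = 120,
                                      sites = default_sites("s"), seed = 8))
  meta <- cohort_metadata(co)
  scz <- meta[meta$group == "SCZ", ]
  expect_gt(cor(scz$age, scz$illness_duration), 0.5)
})

test_that("pooled feature columns look Gaussian (no gross skew)", {
  co <- generate_cohort(cohort_config(n_regions = 60, n_hc = 6, n_scz = 6,
                                      sites = default_sites("s"), seed = 13))
  arr <- cohort_features(co)
  for (f in seq_len(dim(arr)[3])) {
    x <- as.vector(arr[, , f])
    x <- (x - mean(x)) / sd(x)
    expect_lt(abs(mean(x^3)), 0.5)
  }
})

test_that("null cohorts keep MS summaries independent of group label", {
  # with no implanted effect a two-sample t on a region's mean MS rejects
  # at about the nominal rate (feature marginals themselves are pinned by
  # the generator's rank-gaussianization, so MS is the informative scale)
  p <- vapply(1:150, function(r) {
    co <- generate_cohort(cohort_config(n_regions = 12, n_hc = 10, n_scz = 10,
                                        sites = default_sites("s"),
                                        seed = 900 + r))
    reg <- t(vapply(cohort_ms_matrices(co), regional_mean_ms, numeric(12)))
    grp <- cohort_metadata(co)$group
    t.test(reg[grp == "HC", 3], reg[grp == "SCZ", 3])$p.value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.005)
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("implant_group_effect changes only SCZ rows of target regions", {
  co <- tiny_cohort(n_regions = 15, seed = 21)
  expect_identical(implant_group_effect(co, c(2L, 5L), 0, seed = 1), co)
  co2 <- implant_group_effect(co, c(2L, 5L), 0.7, seed = 1)
  for (s in seq_along(co$subjects)) {
    delta <- abs(co2$subjects[[s]]$features - co$subjects[[s]]$features)
    if (co$subjects[[s]]$group == "HC") {
      expect_equal(max(delta), 0)
    } else {
      changed <- which(rowSums(delta) > 0)
      expect_setequal(changed, c(3L, 6L))
    }
  }
  expect_error(implant_group_effect(co, 99L, 0.5, seed = 1), "unknown region")
})

test_that("full decorrelation pushes a hub region's mean MS to zero in patients", {
  diffs <- vapply(1:6, function(r) {
    co <- generate_cohort(cohort_config(n_regions = 40, n_hc = 12, n_scz = 12,
                                        sites = default_sites("s"),
                                        seed = 400 + r))
    meta <- cohort_metadata(co)
    reg0 <- t(vapply(cohort_ms_matrices(co), regional_mean_ms, numeric(40)))
    hub <- which.max(colMeans(reg0[meta$group == "HC", ]))
    co2 <- implant_group_effect(co, hub - 1L, 1, seed = r)
    reg <- t(vapply(cohort_ms_matrices(co2), regional_mean_ms, numeric(40)))
    scz_mean <- mean(reg[meta$group == "SCZ", hub])
    # decorrelated region: mean MS ~ 0 up to finite-sample noise
    # (12 subjects x 39 partners)
    expect_lt(abs(scz_mean), 0.06)
    mean(reg[meta$group == "HC", hub]) - scz_mean
  }, numeric(1))
  # HC - SCZ difference at the hub is systematically positive
  expect_lt(t.test(diffs, alternative = "greater")$p.value, 0.05)
  expect_true(all(diffs > 0))
})

test_that("cohort CSV layout round-trips", {
  co <- tiny_cohort(n_regions = 10, n_hc = 3, n_scz = 2, seed = 6)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 5)
  expect_equal(back$subjects[[2]]$features, co$subjects[[2]]$features,
               tolerance = 1e-12)
  expect_equal(back$subjects[[4]]$group, co$subjects[[4]]$group)
  expect_equal(as.data.frame(back$atlas), as.data.frame(co$atlas))
})

test_that("demographic summaries reproduce the standard table arithmetic", {
  co <- generate_cohort(cohort_config(n_regions = 10, n_hc = 40, n_scz = 30,
                                      sites = default_sites(), seed = 2))
  d <- describe_cohort(cohort_metadata(co))
  expect_equal(d$age_df, 40 + 30 - 2)
  expect_equal(d$sex_df, 1)
  expect_equal(d$n, c(40, 30))
  expect_equal(d$male_pct[1], 100 * d$male_n[1] / 40)
})
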