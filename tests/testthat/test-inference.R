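test_that("group comparison reduces to the pooled t and calibrates under the null", {
  set.seed(6)
  v <- rnorm(40)
  grp <- rep(c("HC", "SCZ"), each = 20)
  res <- group_compare(v, grp, age = rep(30, 40), sex = rep("female", 40))
  tt <- t.test(v[grp == "SCZ"], v[grp == "HC"], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  # identical group values
  res0 <- group_compare(rep(v[1:20], 2), grp, rep(30, 40), rep("male", 40))
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  # sign convention: lower in patients => negative estimate and t
  v2 <- c(rnorm(20, 1), rnorm(20, 0))
  res2 <- group_compare(v2, grp, age = rnorm(40, 35, 5),
                        sex = sample(c("male", "female"), 40, TRUE))
  expect_lt(res2$t, 0)
  # type-I calibration with covariates in the model
  p <- vapply(1:400, function(r) {
    set.seed(1000 + r)
    meta_age <- rnorm(40, 35, 10)
    meta_sex <- sample(c("male", "female"), 40, TRUE)
    group_compare(rnorm(40), grp, meta_age, meta_sex)$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("BH step-up matches the hand-computed example and its invariants", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03, 0.04)), c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_fdr(0.013), 0.013)
  # order invariance
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_gte(min(bh_fdr(p)), min(p))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)))
  expect_error(bh_fdr(runif(10), m = 5), "family size")
})

test_that("run_family corrects once across the whole family", {
  set.seed(9)
  n <- 60
  meta <- data.frame(group = rep(c("HC", "SCZ"), each = 30),
                     age = rnorm(n, 35, 9),
                     sex = sample(c("male", "female"), n, TRUE))
  units <- matrix(rnorm(20 * n), 20, n,
                  dimnames = list(paste0("u", 1:20), NULL))
  units[3, meta$group == "SCZ"] <- units[3, meta$group == "SCZ"] + 3
  tab <- run_family(units, meta, "demo", m_override = 20)
  expect_s3_class(tab, "comparison_table")
  expect_equal(nrow(tab), 20)
  expect_equal(tab$q, bh_fdr(tab$p))
  expect_equal(tab$unit_id[which.min(tab$q)], "u3")
  expect_true(tab$significant[tab$unit_id == "u3"])
  expect_gt(tab$estimate[tab$unit_id == "u3"], 0)
  expect_error(run_family(units, meta, "demo", m_override = 1232),
               "family size mismatch")
  expect_error(run_family(units[, 1:10], meta, "demo"), "align")
})

test_that("empirical FDR of the family pipeline stays controlled", {
  set.seed(14)
  n <- 40
  grp <- rep(c("HC", "SCZ"), each = 20)
  fdp <- vapply(1:60, function(r) {
    meta <- data.frame(group = grp, age = rnorm(n, 35, 10),
                       sex = sample(c("male", "female"), n, TRUE))
    units <- matrix(rnorm(50 * n), 50, n,
                    dimnames = list(paste0("u", 1:50), NULL))
    units[1:5, grp == "SCZ"] <- units[1:5, grp == "SCZ"] + 2.5
    tab <- run_family(units, meta, "mix")
    rej <- which(tab$significant)
    if (!length(rej)) return(0)
    sum(rej > 5) / length(rej)
  }, numeric(1))
  expect_lte(mean(fdp), 0.06)
})

test_that("Spearman associations handle monotone, missing and confounded data", {
  expect_equal(spearman_assoc(1:5, c(2, 4, 9, 11, 30))$rho, 1)
  expect_equal(spearman_assoc(1:5, c(30, 11, 9, 4, 2))$rho, -1)
  # missing clinical values are dropped pairwise
  res <- spearman_assoc(1:6, c(1, 2, NA, 4, 5, 6))
  expect_equal(res$n_used, 5)
  expect_error(spearman_assoc(1:3, c(5, NA, NA)), "at least 4")
  expect_error(spearman_assoc(rep(1, 6), 1:6), "all-tied")
  # age confounding: raw association inflated, age-adjusted near zero
  # (n = 400 so the partial-rho standard error 1/sqrt(n-3) ~ 0.05 keeps
  # |rho| < 0.1 with ~95% probability under conditional independence)
  ok <- vapply(1:40, function(r) {
    set.seed(2000 + r)
    age <- runif(400, 20, 60)
    x <- age + rnorm(400, 0, 6)
    y <- 0.5 * age + rnorm(400, 0, 3)
    raw <- spearman_assoc(x, y, method = "raw")$rho
    adj <- spearman_assoc(x, y, age = age, method = "age_adjusted")$rho
    raw > 0.5 && abs(adj) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("association families correct per clinical variable", {
  set.seed(4)
  n <- 50
  clin <- rnorm(n, 20, 5)
  units <- matrix(rnorm(8 * n), 8, n, dimnames = list(paste0("r", 1:8), NULL))
  units[2, ] <- clin + rnorm(n, 0, 2)
  tab <- run_association_family(units, clin, "illness_duration")
  expect_s3_class(tab, "association_table")
  expect_equal(nrow(tab), 8)
  expect_equal(tab$q, bh_fdr(tab$p))
  expect_equal(tab$unit_id[which.max(abs(tab$rho))], "r2")
  expect_true(all(abs(tab$rho) <= 1))
})
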