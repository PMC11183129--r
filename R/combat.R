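# Empirical-Bayes location/scale site harmonization (parametric ComBat).
#
# Model per target g (a region x feature pair), subject j of site i:
#   y_ijg = alpha_g + X_j beta_g + gamma_ig + delta_ig * eps_ijg
# Site location effects gamma get a normal prior, scale effects delta^2 an
# inverse-gamma prior; both are shrunk towards their site-level prior means
# by fixed-point iteration of the conditional posterior means.

#' Fit a parametric empirical-Bayes site-harmonization model
#'
#' @param data Targets x subjects numeric matrix.
#' @param batch Per-subject site labels (character or factor).
#' @param design Optional per-subject covariate matrix (subjects x k,
#'   without intercept) whose effects are preserved, e.g. age, sex, group.
#' @param conv Convergence tolerance of the EB fixed-point iteration.
#' @param max_iter Maximum fixed-point iterations.
#' @param on_zero_variance `"error"` (default) or `"pass"`: behaviour for
#'   targets with zero pooled variance.
#' @return A list of class `combat_model` with the standardization
#'   parameters and the EB-shrunk site effects `site_gamma_star`,
#'   `site_delta2_star` (both sites x targets).
#' @export
fit_combat <- function(data, batch, design = NULL,
                       conv = 1e-4, max_iter = 100L,
                       on_zero_variance = c("error", "pass")) {
  on_zero_variance <- match.arg(on_zero_variance)
  data <- as.matrix(data)
  G <- nrow(data); n <- ncol(data)
  batch <- factor(batch)
  if (length(batch) != n) stop("batch length must match the number of subjects")
  sites <- levels(batch)
  n_i <- table(batch)
  if (any(n_i < 2)) {
    stop("every site needs at least 2 subjects; offending site(s): ",
         paste(sites[n_i < 2], collapse = ", "))
  }
  if (length(sites) == 1L) {
    warning("single site: harmonization model is the identity")
    model <- list(identity = TRUE, site_order = sites)
    class(model) <- "combat_model"
    return(model)
  }
  B <- stats::model.matrix(~ batch - 1)
  colnames(B) <- sites
  X <- if (is.null(design)) B else cbind(B, as.matrix(design))
  if (qr(X)$rank < ncol(X)) {
    stop("design is not full rank after adding site indicators")
  }
  n_b <- length(sites)
  beta_hat <- solve(crossprod(X), crossprod(X, t(data)))  # p x G
  grand_mean <- crossprod(as.numeric(n_i) / n, beta_hat[seq_len(n_b), , drop = FALSE])
  fitted <- t(X %*% beta_hat)
  var_pooled <- rowMeans((data - fitted)^2)
  zero_var <- which(var_pooled <= 0)
  if (length(zero_var) && on_zero_variance == "error") {
    stop("zero-variance target row(s): ", paste(zero_var, collapse = ", "))
  }
  var_safe <- ifelse(var_pooled > 0, var_pooled, 1)

  # covariate-predicted mean (grand mean + preserved covariate effects)
  stand_mean <- matrix(grand_mean, G, n)
  if (!is.null(design)) {
    stand_mean <- stand_mean +
      t(as.matrix(design) %*% beta_hat[-seq_len(n_b), , drop = FALSE])
  }
  s_data <- (data - stand_mean) / sqrt(var_safe)

  gamma_hat <- matrix(NA_real_, n_b, G)
  delta2_hat <- matrix(NA_real_, n_b, G)
  for (i in seq_len(n_b)) {
    cols <- which(batch == sites[i])
    gamma_hat[i, ] <- rowMeans(s_data[, cols, drop = FALSE])
    delta2_hat[i, ] <- apply(s_data[, cols, drop = FALSE], 1, stats::var)
  }

  aprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
  bprior <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  for (i in seq_len(n_b)) {
    g_hat <- gamma_hat[i, ]; d2_hat <- delta2_hat[i, ]
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    a <- aprior(d2_hat); b <- bprior(d2_hat)
    cols <- which(batch == sites[i])
    sd_i <- s_data[, cols, drop = FALSE]
    ni <- length(cols)
    g_old <- g_hat; d_old <- d2_hat
    for (it in seq_len(max_iter)) {
      g_new <- (ni * t2 * g_hat + d_old * g_bar) / (ni * t2 + d_old)
      sum2 <- rowSums((sd_i - g_new)^2)
      d_new <- (0.5 * sum2 + b) / (ni / 2 + a - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new; d_old <- d_new
      if (change < conv) break
    }
    gamma_star[i, ] <- g_old
    delta2_star[i, ] <- pmax(d_old, .Machine$double.eps)
  }

  model <- list(
    identity = FALSE,
    site_order = sites,
    n_covariates = if (is.null(design)) 0L else ncol(as.matrix(design)),
    grand_mean = as.numeric(grand_mean),
    beta_covariates = if (is.null(design)) NULL else
      beta_hat[-seq_len(n_b), , drop = FALSE],
    pooled_var = var_pooled,
    zero_variance_targets = zero_var,
    site_gamma_star = gamma_star,
    site_delta2_star = delta2_star
  )
  class(model) <- "combat_model"
  model
}

#' Apply a fitted harmonization model
#'
#' `y_adj = (y_std - gamma*_site) / sqrt(delta2*_site) * sqrt(pooled_var)
#'  + covariate-predicted mean`; the output has the shape of the input.
#'
#' @param model A `combat_model` from [fit_combat()].
#' @param data Targets x subjects matrix (same targets as at fit time).
#' @param batch Per-subject site labels; only sites seen at fit time.
#' @param design Covariate matrix matching the one used at fit time.
#' @return Harmonized matrix of the same shape.
#' @export
apply_combat <- function(model, data, batch, design = NULL) {
  stopifnot(inherits(model, "combat_model"))
  data <- as.matrix(data)
  if (isTRUE(model$identity)) return(data)
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$site_order)
  if (length(unseen)) stop("unseen site label(s): ", paste(unseen, collapse = ", "))
  k <- model$n_covariates
  if (k > 0 && (is.null(design) || ncol(as.matrix(design)) != k)) {
    stop("design must have the ", k, " covariate column(s) used at fit time")
  }
  G <- nrow(data); n <- ncol(data)
  stand_mean <- matrix(model$grand_mean, G, n)
  if (k > 0) {
    stand_mean <- stand_mean + t(as.matrix(design) %*% model$beta_covariates)
  }
  var_safe <- ifelse(model$pooled_var > 0, model$pooled_var, 1)
  s_data <- (data - stand_mean) / sqrt(var_safe)
  site_idx <- match(batch, model$site_order)
  adj <- s_data
  for (i in seq_along(model$site_order)) {
    cols <- which(site_idx == i)
    if (!length(cols)) next
    adj[, cols] <- (s_data[, cols, drop = FALSE] - model$site_gamma_star[i, ]) /
      sqrt(model$site_delta2_star[i, ])
  }
  out <- adj * sqrt(var_safe) + stand_mean
  if (length(model$zero_variance_targets)) {
    out[model$zero_variance_targets, ] <- data[model$zero_variance_targets, ]
  }
  dimnames(out) <- dimnames(data)
  out
}

#' Harmonize a cohort's feature tables across sites
#'
#' Flattens every subject's regions x features matrix into one column of a
#' (region, feature) x subjects matrix, fits the EB model with the
#' requested preserved covariates (default age, sex, group — sex coded
#' male = 1, group coded SCZ = 1), applies it and writes the harmonized
#' values back into the cohort. With a single site the cohort is returned
#' unchanged (with a warning from the fitter).
#'
#' @param cohort An `ms_cohort`.
#' @param covariates Character subset of `c("age", "sex", "group")`.
#' @return A list with `cohort` (harmonized) and `model`.
#' @export
combat_cohort <- function(cohort, covariates = c("age", "sex", "group")) {
  meta <- cohort_metadata(cohort)
  n_sub <- length(cohort$subjects)
  f1 <- cohort$subjects[[1]]$features
  data <- vapply(cohort$subjects, function(s) as.numeric(s$features),
                 numeric(length(f1)))
  design <- NULL
  if (length(covariates)) {
    cols <- list(age = meta$age,
                 sex = as.numeric(meta$sex == "male"),
                 group = as.numeric(meta$group == "SCZ"))
    design <- do.call(cbind, cols[covariates])
  }
  model <- withCallingHandlers(
    fit_combat(data, meta$site, design),
    warning = function(w) {
      message(conditionMessage(w)); invokeRestart("muffleWarning")
    })
  adj <- apply_combat(model, data, meta$site, design)
  for (s in seq_len(n_sub)) {
    m <- matrix(adj[, s], nrow(f1), ncol(f1), dimnames = dimnames(f1))
    cohort$subjects[[s]]$features <- m
  }
  list(cohort = cohort, model = model)
}

#' Serialize / restore a harmonization model as JSON
#' @param model A `combat_model`.
#' @param path JSON path.
#' @return `write_combat_model` returns the path invisibly;
#'   `read_combat_model` the model.
#' @export
write_combat_model <- function(model, path) {
  obj <- unclass(model)
  obj$beta_covariates <- if (!is.null(obj$beta_covariates))
    as.data.frame(obj$beta_covariates)
  obj$site_gamma_star <- as.data.frame(obj$site_gamma_star)
  obj$site_delta2_star <- as.data.frame(obj$site_delta2_star)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!isTRUE(obj$identity)) {
    obj$site_gamma_star <- as.matrix(obj$site_gamma_star)
    obj$site_delta2_star <- as.matrix(obj$site_delta2_star)
    if (!is.null(obj$beta_covariates)) {
      obj$beta_covariates <- as.matrix(obj$beta_covariates)
    }
    obj$zero_variance_targets <- as.integer(obj$zero_variance_targets)
  }
  class(obj) <- "combat_model"
  obj
}
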