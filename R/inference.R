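# Covariate-adjusted group comparisons, BH-FDR by test family, and
# Spearman clinical associations (raw and age-adjusted).

#' Covariate-adjusted group comparison for one unit
#'
#' OLS of the values on \[intercept, group, age, sex, age x sex\] with a
#' two-sided t test of the group coefficient. Group is coded SCZ = 1 and
#' sex male = 1, so the estimate is the adjusted SCZ - HC difference and
#' "lower in patients" shows as a negative t.
#'
#' @param values Per-subject numeric vector.
#' @param group Per-subject group (`"HC"` / `"SCZ"` or 0/1).
#' @param age Per-subject age.
#' @param sex Per-subject sex (`"male"` / `"female"` or 1/0).
#' @return A list `list(estimate, t, p, df)`.
#' @export
group_compare <- function(values, group, age, sex) {
  meta <- normalize_meta(group, age, sex)
  des <- group_design(meta)
  fit <- ols_tstats(matrix(values, ncol = 1), des$X, des$coef_index)
  p <- 2 * stats::pt(abs(fit$t), fit$df, lower.tail = FALSE)
  list(estimate = unname(fit$estimate), t = unname(fit$t), p = unname(p),
       df = fit$df)
}

#' @noRd
normalize_meta <- function(group, age, sex) {
  grp <- if (is.numeric(group)) ifelse(group > 0, "SCZ", "HC") else as.character(group)
  sx <- if (is.numeric(sex)) ifelse(sex > 0, "male", "female") else as.character(sex)
  data.frame(group = grp, age = as.numeric(age), sex = sx,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment `q_(i) = min_{k >= i} min(1, p_(k) * m / k)`,
#' returned in input order. `m` defaults to the number of tests and may be
#' set to the nominal family size.
#'
#' @param p_values Vector of raw p-values in \[0, 1\].
#' @param m Family size (>= number of p-values).
#' @return Vector of q-values in input order.
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.03, 0.04))  # 0.004 0.020 0.040 0.040
#' @export
bh_fdr <- function(p_values, m = length(p_values)) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m < length(p_values)) stop("family size m cannot be below the number of tests")
  stats::p.adjust(p_values, method = "BH", n = m)
}

#' Run one BH-FDR test family of group comparisons
#'
#' Applies the covariate-adjusted group comparison to every unit (a region,
#' subnetwork, global measure or nodal measure) and corrects once over the
#' whole family.
#'
#' @param unit_values Units x subjects numeric matrix (rownames are unit ids).
#' @param meta Metadata data frame (`group`, `age`, `sex`), subjects in the
#'   column order of `unit_values`.
#' @param family_name Label stored with every record.
#' @param m_override Optional nominal family size; must equal the number of
#'   units when given (guards against accidentally split families).
#' @param alpha Significance level on q (default 0.05).
#' @return A `comparison_table` data frame: `unit_id`, `estimate`, `t`,
#'   `p`, `q`, `family`, `significant`.
#' @export
run_family <- function(unit_values, meta, family_name,
                       m_override = NULL, alpha = 0.05) {
  unit_values <- as.matrix(unit_values)
  if (ncol(unit_values) != nrow(meta)) {
    stop("unit_values columns and metadata rows must align")
  }
  if (!is.null(m_override) && m_override != nrow(unit_values)) {
    stop("family size mismatch: ", m_override, " declared vs ",
         nrow(unit_values), " units")
  }
  des <- group_design(meta)
  fit <- ols_tstats(t(unit_values), des$X, des$coef_index)
  p <- 2 * stats::pt(abs(fit$t), fit$df, lower.tail = FALSE)
  q <- bh_fdr(p)
  out <- data.frame(
    unit_id = rownames(unit_values) %||% as.character(seq_len(nrow(unit_values))),
    estimate = fit$estimate, t = fit$t, p = p, q = q,
    family = family_name, significant = q < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Spearman association with a clinical variable
#'
#' Raw Spearman correlation (asymptotic p in the presence of ties) or an
#' age-adjusted Spearman partial correlation: both variables and age are
#' ranked, each variable's ranks are regressed on the ranks of age, and the
#' residuals are correlated (p from a t approximation on n - 3 df).
#' Missing clinical values are dropped pairwise.
#'
#' @param values Numeric vector (e.g. a nodal measure per subject).
#' @param clinical Numeric vector of the clinical variable (may contain NA).
#' @param age Numeric vector, required for `method = "age_adjusted"`.
#' @param method `"raw"` or `"age_adjusted"`.
#' @return A list `list(rho, p, n_used)`.
#' @export
spearman_assoc <- function(values, clinical, age = NULL,
                           method = c("raw", "age_adjusted")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(values, clinical)
  if (method == "age_adjusted") {
    if (is.null(age)) stop("age is required for the age-adjusted method")
    ok <- ok & !is.na(age)
  }
  v <- values[ok]; cl <- clinical[ok]
  if (length(v) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(v) == 0 || stats::sd(cl) == 0) {
    stop("Spearman correlation undefined for all-tied values")
  }
  if (method == "raw") {
    ct <- suppressWarnings(stats::cor.test(v, cl, method = "spearman"))
    return(list(rho = unname(ct$estimate), p = ct$p.value, n_used = length(v)))
  }
  a <- age[ok]
  rv <- rank(v); rc <- rank(cl); ra <- rank(a)
  res_v <- stats::lm.fit(cbind(1, ra), rv)$residuals
  res_c <- stats::lm.fit(cbind(1, ra), rc)$residuals
  rho <- stats::cor(res_v, res_c)
  n <- length(v)
  tval <- rho * sqrt((n - 3) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tval), n - 3, lower.tail = FALSE)
  list(rho = rho, p = p, n_used = n)
}

#' Clinical association family
#'
#' Spearman associations of every unit with one clinical variable, BH
#' corrected within that clinical variable (one family per variable).
#'
#' @param unit_values Units x subjects matrix.
#' @param clinical Numeric vector (NA allowed).
#' @param variable_name Clinical variable label.
#' @param age Optional ages for `method = "age_adjusted"`.
#' @param method `"raw"` or `"age_adjusted"`.
#' @param alpha Significance level on q.
#' @return An `association_table` data frame: `unit_id`,
#'   `clinical_variable`, `rho`, `p`, `q`, `n_used`, `significant`.
#' @export
run_association_family <- function(unit_values, clinical, variable_name,
                                   age = NULL,
                                   method = c("raw", "age_adjusted"),
                                   alpha = 0.05) {
  method <- match.arg(method)
  unit_values <- as.matrix(unit_values)
  res <- lapply(seq_len(nrow(unit_values)), function(u) {
    spearman_assoc(unit_values[u, ], clinical, age = age, method = method)
  })
  p <- vapply(res, `[[`, 0, "p")
  out <- data.frame(
    unit_id = rownames(unit_values) %||% as.character(seq_len(nrow(unit_values))),
    clinical_variable = variable_name,
    rho = vapply(res, `[[`, 0, "rho"),
    p = p, q = bh_fdr(p),
    n_used = vapply(res, `[[`, 0, "n_used"),
    stringsAsFactors = FALSE
  )
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}
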