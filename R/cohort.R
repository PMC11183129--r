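# Synthetic two-group, multi-site cohort generator.
#
# Each subject carries a regions x 10 morphometric feature matrix. The
# latent model is chosen so that, after the downstream per-subject
# z-scoring, morphometric similarity (MS) matrices look like real cortical
# MS networks: strong short-range similarity along a smooth latent gradient
# (so binarized graphs are clustered and small-world), a skewed global
# "hubness" factor giving most regions a slightly positive and a minority a
# negative regional mean MS, stable region identities across subjects, and
# moderate subject-level noise.

#' Morphometric feature table
#'
#' The ten per-region features the pipeline expects, with typical raw
#' scales (FreeSurfer-style surface measures plus cortical diffusion
#' summaries). Scales only matter for realism of the raw tables; MS
#' construction z-scores each feature within subject.
#' @keywords internal
#' @export
MS_FEATURES <- data.frame(
  feature = c("surface_area", "gray_volume", "thickness_mean",
              "thickness_sd", "gaussian_curvature", "mean_curvature",
              "folding_index", "curvature_index", "fa_mean", "md_mean"),
  base_mean = c(700, 2000, 2.5, 0.5, 0.15, 0.12, 15, 2, 0.18, 9e-4),
  base_sd = c(180, 550, 0.25, 0.1, 0.05, 0.03, 6, 0.9, 0.04, 1.2e-4),
  stringsAsFactors = FALSE
)

# Frozen latent-model constants (see the methods vignette for rationale).
# Hubness is a smooth function of ring position: a high plateau with one
# localized negative dip (the anti-correlated limbic/insular-like arc), so
# adjacent regions always stay strongly similar and low-sparsity graphs
# remain connected, while most regions get a positive regional mean MS.
.LATENT <- list(
  hub_high          = 0.55,   # plateau hub loading
  hub_low           = -2.6,   # centre of the anti-correlated dip
  hub_dip_kappa     = 20,     # von Mises concentration of the dip (~12% of ring below 0)
  hub_noise_sd      = 0.15,   # region-level jitter on the hub loading
  n_harmonics       = 4,      # ring-gradient harmonics
  gradient_sd       = 1.0,    # loading scale of harmonic k is gradient_sd/k
  idio_sd           = 0.15,    # region-specific profile, shared across subjects
  subject_sd        = 0.25    # per-subject measurement/biology noise
)

#' Default four-site layout
#'
#' Site names, per-site group counts (proportions of a 239 HC / 190 SCZ
#' cohort) and per-site location/scale distortions. Shifts are expressed in
#' units of each feature's base SD and scales multiply the feature values,
#' matching the additive/multiplicative model that empirical-Bayes site
#' harmonization assumes. The first site is the reference (no distortion).
#' @param names Site names.
#' @return A list of site descriptors.
#' @export
default_sites <- function(names = c("AMC", "COBRE", "NMorphCH", "UCLA_CNP")) {
  shift <- c(0, 0.25, -0.2, 0.15)
  scale <- c(1, 1.15, 0.9, 1.05)
  hc_n <- c(23, 72, 32, 112)
  scz_n <- c(47, 57, 40, 46)
  k <- length(names)
  lapply(seq_len(k), function(s) {
    list(name = names[s],
         location_shift = rep(shift[((s - 1) %% 4) + 1], nrow(MS_FEATURES)),
         scale_factor = rep(scale[((s - 1) %% 4) + 1], nrow(MS_FEATURES)),
         prop_hc = hc_n[((s - 1) %% 4) + 1] / sum(hc_n[seq_len(min(k, 4))]),
         prop_scz = scz_n[((s - 1) %% 4) + 1] / sum(scz_n[seq_len(min(k, 4))]))
  })
}

#' Default covariate model
#'
#' Age and sex distributions per group follow the demographic table of the
#' four-site case-control cohort this generator emulates (HC 33.3 (10.0)
#' years, 59.0% male; SCZ 34.2 (10.0) years, 65.8% male). Illness duration
#' is generated as `slope * (age - onset_age) + noise`, which reproduces the
#' strong age/illness-duration collinearity that complicates clinical
#' association analyses.
#' @return A list of covariate-model parameters.
#' @export
default_covariate_model <- function() {
  list(
    age_mean = c(HC = 33.3, SCZ = 34.2),
    age_sd = c(HC = 10.0, SCZ = 10.0),
    age_range = c(18, 65),
    male_frac = c(HC = 0.59, SCZ = 0.658),
    onset_mean = 24, onset_sd = 5,
    duration_age_slope = 1.0, duration_noise_sd = 1.0,
    panss_pos_mean = 17.5, panss_pos_sd = 6,
    panss_neg_mean = 18, panss_neg_sd = 6,
    dose_log_mean = log(15), dose_log_sd = 0.6, dose_missing_frac = 0.25,
    fsiq_mean = c(HC = 100, SCZ = 95), fsiq_sd = 15
  )
}

#' Cohort configuration
#'
#' Validates and bundles everything that determines a synthetic cohort.
#' Given the same configuration (including `seed`) the generated cohort is
#' bit-for-bit identical.
#'
#' @param n_regions Number of cortical regions.
#' @param n_hc,n_scz Group sizes (healthy controls / schizophrenia).
#' @param sites List of site descriptors as from [default_sites()]; a single
#'   site with zero shift and unit scale makes the site step the identity.
#' @param effect_regions Integer vector of 0-based region ids receiving the
#'   patient-group decorrelation effect (empty for a null cohort).
#' @param effect_strength Decorrelation fraction lambda in \[0, 1\].
#' @param covariate_model As from [default_covariate_model()].
#' @param seed Integer seed.
#' @return A list of class `ms_cohort_config`.
#' @export
cohort_config <- function(n_regions = 308L,
                          n_hc = 239L, n_scz = 190L,
                          sites = default_sites(),
                          effect_regions = integer(0),
                          effect_strength = 0,
                          covariate_model = default_covariate_model(),
                          seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_hc <- as.integer(n_hc); n_scz <- as.integer(n_scz)
  if (n_regions < 2L || n_hc < 2L || n_scz < 2L) {
    stop("n_regions, n_hc and n_scz must all be at least 2")
  }
  assert_scalar_number(effect_strength, "effect_strength", 0, 1)
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 0L) || any(effect_regions >= n_regions))) {
    stop("effect_regions must be 0-based region ids below n_regions")
  }
  if (!length(sites)) stop("at least one site is required")
  structure(list(n_regions = n_regions, n_hc = n_hc, n_scz = n_scz,
                 sites = sites, effect_regions = effect_regions,
                 effect_strength = effect_strength,
                 covariate_model = covariate_model,
                 seed = as.integer(seed)),
            class = "ms_cohort_config")
}

# Gaussian-direction noise with a fixed per-region norm: every region gets
# the same noise energy, so no region's whole correlation row is attenuated
# by an unlucky draw (homogeneous measurement reliability).
.fixed_norm_noise <- function(n_regions, n_features, sd) {
  m <- matrix(stats::rnorm(n_regions * n_features), n_regions, n_features)
  m * (sd * sqrt(n_features) / sqrt(rowSums(m^2)))
}

# Latent cortical structure shared by all subjects of one cohort.
.draw_latent <- function(n_regions, n_features) {
  L <- .LATENT
  theta <- 2 * pi * (seq_len(n_regions) - 1) / n_regions
  dip_centre <- stats::runif(1, 0, 2 * pi)
  bump <- exp(L$hub_dip_kappa * (cos(theta - dip_centre) - 1))
  hub <- L$hub_high - (L$hub_high - L$hub_low) * bump +
    stats::rnorm(n_regions, 0, L$hub_noise_sd)
  minority <- which(hub < 0)
  hub_pattern <- sample(c(-1, 1), n_features, replace = TRUE) *
    stats::runif(n_features, 0.8, 1.2)
  profile <- outer(hub, hub_pattern)
  for (k in seq_len(L$n_harmonics)) {
    a <- stats::rnorm(n_features, 0, L$gradient_sd / k)
    b <- stats::rnorm(n_features, 0, L$gradient_sd / k)
    profile <- profile + outer(cos(k * theta), a) + outer(sin(k * theta), b)
  }
  # equalize signal power across regions: correlations depend only on the
  # direction of each region's profile and its signal-to-noise ratio, so a
  # common row norm gives every region the same edge-weight reliability
  # without changing the similarity structure
  row_norm <- sqrt(rowSums(profile^2))
  profile <- profile * (mean(row_norm) / row_norm)
  profile <- profile + .fixed_norm_noise(n_regions, n_features, L$idio_sd)
  list(profile = profile, hub_loading = hub, theta = theta,
       minority = minority)
}

.draw_clinical <- function(group, age, cm) {
  if (group == "HC") {
    return(list(illness_duration = NA_real_, panss_positive = NA_real_,
                panss_negative = NA_real_, antipsychotic_dose = NA_real_,
                fsiq = max(40, round(stats::rnorm(1, cm$fsiq_mean["HC"], cm$fsiq_sd))),
                color_trail_1 = round(stats::rnorm(1, 50, 10), 1),
                word_fluency = round(stats::rnorm(1, 50, 10), 1)))
  }
  onset <- min(stats::rnorm(1, cm$onset_mean, cm$onset_sd), age - 0.5)
  onset <- max(onset, 13)
  dur <- cm$duration_age_slope * (age - onset) +
    stats::rnorm(1, 0, cm$duration_noise_sd)
  dose <- if (stats::runif(1) < cm$dose_missing_frac) NA_real_ else
    round(stats::rlnorm(1, cm$dose_log_mean, cm$dose_log_sd), 1)
  list(
    illness_duration = round(max(dur, 0.1), 1),
    panss_positive = min(49, max(7, round(stats::rnorm(1, cm$panss_pos_mean, cm$panss_pos_sd)))),
    panss_negative = min(49, max(7, round(stats::rnorm(1, cm$panss_neg_mean, cm$panss_neg_sd)))),
    antipsychotic_dose = dose,
    fsiq = max(40, round(stats::rnorm(1, cm$fsiq_mean["SCZ"], cm$fsiq_sd))),
    color_trail_1 = round(stats::rnorm(1, 50, 10), 1),
    word_fluency = round(stats::rnorm(1, 50, 10), 1)
  )
}

#' Generate a synthetic two-group multi-site cohort
#'
#' Draws the shared latent cortical structure, then one regions x 10
#' feature matrix per subject (latent profile + subject noise, mapped to
#' realistic feature scales, then per-site location/scale distortion), plus
#' demographic and clinical covariates. If the configuration names effect
#' regions with a positive effect strength, [implant_group_effect()] is
#' applied to the patient group.
#'
#' @param config An [cohort_config()] object.
#' @return A list of class `ms_cohort` with elements `atlas`, `subjects`
#'   (list of per-subject records), `latent` (generator diagnostics) and
#'   `config`.
#' @examples
#' cfg <- cohort_config(n_regions = 20, n_hc = 4, n_scz = 4,
#'                      sites = default_sites("siteA"), seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort$subjects[[1]]$features)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "ms_cohort_config")) {
    config <- do.call(cohort_config, config)
  }
  n_feat <- nrow(MS_FEATURES)
  cm <- config$covariate_model
  atlas <- build_atlas(config$n_regions, seed = config$seed)
  cohort <- local_seed(config$seed, {
    latent <- .draw_latent(config$n_regions, n_feat)
    groups <- c(rep("HC", config$n_hc), rep("SCZ", config$n_scz))
    # proportional site assignment, largest-remainder rounding
    assign_sites <- function(n, props) {
      raw <- props / sum(props) * n
      base <- floor(raw)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
      }
      sample(rep(seq_along(props), times = base))
    }
    site_idx <- c(
      assign_sites(config$n_hc, vapply(config$sites, function(s) s$prop_hc %||% 1, 1)),
      assign_sites(config$n_scz, vapply(config$sites, function(s) s$prop_scz %||% 1, 1))
    )
    subjects <- vector("list", length(groups))
    for (s in seq_along(groups)) {
      grp <- groups[s]
      site <- config$sites[[site_idx[s]]]
      age <- 0
      while (age < cm$age_range[1] || age > cm$age_range[2]) {
        age <- stats::rnorm(1, cm$age_mean[grp], cm$age_sd[grp])
      }
      age <- round(age, 1)
      sex <- if (stats::runif(1) < cm$male_frac[grp]) "male" else "female"
      latent_feat <- latent$profile +
        .fixed_norm_noise(config$n_regions, n_feat, .LATENT$subject_sd)
      # rank-gaussianize each feature across regions: preserves the ordering
      # (hence the correlation structure) while giving every pooled feature
      # column a Gaussian marginal, as raw morphometry is usually normalized
      latent_feat <- apply(latent_feat, 2, function(x) {
        stats::qnorm((rank(x, ties.method = "first") - 0.5) / length(x))
      })
      features <- sweep(sweep(latent_feat, 2, MS_FEATURES$base_sd, "*"),
                        2, MS_FEATURES$base_mean, "+")
      features <- sweep(features, 2, site$scale_factor, "*")
      features <- features +
        matrix(site$location_shift * MS_FEATURES$base_sd,
               config$n_regions, n_feat, byrow = TRUE)
      colnames(features) <- MS_FEATURES$feature
      rownames(features) <- atlas$region_name
      subjects[[s]] <- list(
        subject_id = sprintf("sub_%03d", s),
        group = grp, site = site$name, age = age, sex = sex,
        clinical = .draw_clinical(grp, age, cm),
        features = features
      )
    }
    list(atlas = atlas, subjects = subjects, latent = latent,
         config = config)
  })
  class(cohort) <- "ms_cohort"
  if (length(config$effect_regions) && config$effect_strength > 0) {
    cohort <- implant_group_effect(cohort, config$effect_regions,
                                   config$effect_strength,
                                   seed = config$seed + 1000L)
  }
  cohort
}

#' Implant a regional decorrelation effect in the patient group
#'
#' For every patient (SCZ) subject, each target region's 10-feature vector
#' `v` is replaced by `(1 - lambda) * v + lambda * eps`, where `eps` is
#' noise standardized to the subject's per-feature location and scale.
#' This lowers the target region's correlation with every other region —
#' the kind of focal loss of morphometric similarity reported in patients —
#' while leaving controls and non-target regions untouched. `lambda = 0` is
#' the identity; `lambda = 1` makes the region pure noise (expected MS ~ 0).
#'
#' @param cohort An `ms_cohort`.
#' @param effect_regions 0-based region ids.
#' @param effect_strength Decorrelation fraction lambda in \[0, 1\].
#' @param seed Integer seed for the implanted noise.
#' @return The modified cohort.
#' @export
implant_group_effect <- function(cohort, effect_regions, effect_strength,
                                 seed = 1L) {
  stopifnot(inherits(cohort, "ms_cohort"))
  assert_scalar_number(effect_strength, "effect_strength", 0, 1)
  n_regions <- nrow(cohort$atlas)
  effect_regions <- as.integer(effect_regions)
  if (length(effect_regions) &&
      (any(effect_regions < 0L) || any(effect_regions >= n_regions))) {
    stop("unknown region id in effect_regions")
  }
  if (effect_strength == 0 || !length(effect_regions)) return(cohort)
  rows <- effect_regions + 1L
  lambda <- effect_strength
  cohort$subjects <- local_seed(seed, {
    lapply(cohort$subjects, function(subj) {
      if (subj$group != "SCZ") return(subj)
      f <- subj$features
      mu <- colMeans(f)
      sd_f <- apply(f, 2, stats::sd)
      for (r in rows) {
        eps <- stats::rnorm(ncol(f), mu, sd_f)
        f[r, ] <- (1 - lambda) * f[r, ] + lambda * eps
      }
      subj$features <- f
      subj
    })
  })
  cohort$implanted <- list(effect_regions = effect_regions,
                           effect_strength = effect_strength)
  cohort
}

#' Cohort metadata as a data frame
#'
#' One row per subject: id, group, site, age, sex and the clinical columns
#' (missing for controls where not applicable).
#' @param cohort An `ms_cohort`.
#' @return A data frame.
#' @export
cohort_metadata <- function(cohort) {
  stopifnot(inherits(cohort, "ms_cohort"))
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group, site = s$site,
               age = s$age, sex = s$sex,
               as.data.frame(s$clinical), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stack the cohort's feature matrices
#'
#' @param cohort An `ms_cohort`.
#' @return A 3-d array subjects x regions x features.
#' @export
cohort_features <- function(cohort) {
  n <- length(cohort$subjects)
  f1 <- cohort$subjects[[1]]$features
  arr <- array(NA_real_, c(n, nrow(f1), ncol(f1)),
               dimnames = list(vapply(cohort$subjects, `[[`, "", "subject_id"),
                               rownames(f1), colnames(f1)))
  for (s in seq_len(n)) arr[s, , ] <- cohort$subjects[[s]]$features
  arr
}

#' Write / read a cohort in the documented CSV layout
#'
#' `dir/atlas.csv`, `dir/metadata.csv` and one wide CSV per subject under
#' `dir/subjects/` (rows = regions, columns = the 10 named features).
#' @param cohort An `ms_cohort`.
#' @param dir Target directory (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a cohort
#'   (without generator diagnostics).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.csv"))
  write_table_csv(cohort_metadata(cohort), file.path(dir, "metadata.csv"))
  for (s in cohort$subjects) {
    df <- data.frame(region_name = rownames(s$features), s$features,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_table_csv(df, file.path(dir, "subjects",
                                  paste0(s$subject_id, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  atlas <- read_atlas(file.path(dir, "atlas.csv"))
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  clin_cols <- setdiff(names(meta), c("subject_id", "group", "site", "age", "sex"))
  subjects <- lapply(seq_len(nrow(meta)), function(k) {
    row <- meta[k, ]
    f <- utils::read.csv(file.path(dir, "subjects",
                                   paste0(row$subject_id, ".csv")),
                         check.names = FALSE, stringsAsFactors = FALSE)
    features <- as.matrix(f[, -1, drop = FALSE])
    rownames(features) <- f$region_name
    list(subject_id = row$subject_id, group = row$group, site = row$site,
         age = row$age, sex = row$sex,
         clinical = as.list(row[clin_cols]),
         features = features)
  })
  structure(list(atlas = atlas, subjects = subjects, latent = NULL,
                 config = NULL),
            class = "ms_cohort")
}

#' Demographic summary statistics for a cohort
#'
#' Reproduces the arithmetic of a standard case-control demographics table:
#' Student's two-sample t test (pooled variance) for age, a Yates-corrected
#' chi-square test for sex, and per-group male counts/percentages.
#' @param meta A metadata data frame as from [cohort_metadata()] (columns
#'   `group`, `age`, `sex`).
#' @return A list with `age_t`, `age_df`, `age_p`, `sex_chisq`, `sex_df`,
#'   `sex_p`, `male_n`, `male_pct`, `n`.
#' @export
describe_cohort <- function(meta) {
  stopifnot(all(c("group", "age", "sex") %in% names(meta)))
  grp <- factor(meta$group, levels = c("HC", "SCZ"))
  tt <- stats::t.test(age ~ grp, data = meta, var.equal = TRUE)
  tab <- table(grp, factor(meta$sex, levels = c("male", "female")))
  cs <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  male_n <- tab[, "male"]
  n <- rowSums(tab)
  list(age_t = unname(tt$statistic), age_df = unname(tt$parameter),
       age_p = tt$p.value,
       sex_chisq = unname(cs$statistic), sex_df = unname(cs$parameter),
       sex_p = cs$p.value,
       male_n = as.vector(male_n), male_pct = as.vector(100 * male_n / n),
       n = as.vector(n))
}
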