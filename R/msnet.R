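# Morphometric similarity matrices and node/subnetwork summaries.

#' Z-score morphometric features within a subject
#'
#' Each of the 10 feature columns is standardized to mean 0, SD 1 across
#' that subject's regions (sample SD, n - 1). Within-subject normalization
#' puts the differently scaled MRI parameters on a common scale before
#' region-by-region correlation.
#'
#' @param features Regions x features numeric matrix.
#' @return Matrix of the same shape with standardized columns.
#' @export
zscore_features <- function(features) {
  features <- as.matrix(features)
  sds <- apply(features, 2, stats::sd)
  bad <- which(sds == 0 | !is.finite(sds))
  if (length(bad)) {
    nm <- colnames(features)[bad] %||% as.character(bad)
    stop("zero-variance feature column(s): ", paste(nm, collapse = ", "))
  }
  scale(features)[, , drop = FALSE]
}

#' Compute a subject's morphometric similarity matrix
#'
#' MS between two regions is the Pearson correlation of their (z-scored)
#' 10-feature vectors. The diagonal is stored as 0 and is excluded from
#' every downstream summary.
#'
#' @param zfeatures Regions x features matrix of z-scored features.
#' @return An N x N symmetric matrix of class `ms_matrix` with zero
#'   diagonal and off-diagonal entries in \[-1, 1\].
#' @examples
#' f <- matrix(rnorm(50), 5, 10)
#' ms <- compute_ms_matrix(zscore_features(f))
#' @export
compute_ms_matrix <- function(zfeatures) {
  zfeatures <- as.matrix(zfeatures)
  row_sds <- apply(zfeatures, 1, stats::sd)
  bad <- which(row_sds == 0 | !is.finite(row_sds))
  if (length(bad)) {
    stop("region(s) with zero variance across features; correlation undefined: ",
         paste(bad, collapse = ", "))
  }
  ms <- stats::cor(t(zfeatures))
  diag(ms) <- 0
  ms <- (ms + t(ms)) / 2
  class(ms) <- c("ms_matrix", class(ms))
  ms
}

#' Per-subject MS matrix from raw features
#'
#' Convenience wrapper: z-score within subject, then correlate regions.
#' @param features Regions x features raw matrix.
#' @return An `ms_matrix`.
#' @export
subject_ms_matrix <- function(features) {
  compute_ms_matrix(zscore_features(features))
}

#' MS matrices for every subject of a cohort
#' @param cohort An `ms_cohort`.
#' @return A named list of `ms_matrix` objects, one per subject.
#' @export
cohort_ms_matrices <- function(cohort) {
  out <- lapply(cohort$subjects, function(s) subject_ms_matrix(s$features))
  names(out) <- vapply(cohort$subjects, `[[`, "", "subject_id")
  out
}

#' Stack MS matrices into a subjects x edges matrix
#'
#' Flattens each subject's unique edges (upper triangle, lexicographic
#' order) into one row; the edge order is shared with every other module.
#' @param ms_list List of `ms_matrix` objects.
#' @return A list with `edges` (subjects x n_edges matrix), `pairs`
#'   (edge index), `n_regions`.
#' @export
ms_edge_stack <- function(ms_list) {
  n <- nrow(ms_list[[1]])
  pairs <- edge_pairs(n)
  edges <- t(vapply(ms_list, edge_vector, numeric(pairs$n_edges),
                    pairs = pairs))
  rownames(edges) <- names(ms_list)
  list(edges = edges, pairs = pairs, n_regions = n)
}

#' Regional mean morphometric similarity
#'
#' For each region, the mean MS with the remaining N - 1 regions — the
#' hub-like node summary of the MS network.
#' @param ms An `ms_matrix`.
#' @return Numeric vector of length N.
#' @export
regional_mean_ms <- function(ms) {
  n <- nrow(ms)
  (rowSums(ms)) / (n - 1)
}

#' Subnetwork mean morphometric similarity
#'
#' Unweighted mean of the member regions' regional mean MS for each class
#' of a subnetwork scheme.
#' @param regional Per-region vector from [regional_mean_ms()].
#' @param atlas An `ms_atlas`.
#' @param scheme `"yeo"` or `"voneconomo"`.
#' @return Named numeric vector, one entry per subnetwork.
#' @export
subnetwork_mean_ms <- function(regional, atlas, scheme = c("yeo", "voneconomo")) {
  scheme <- match.arg(scheme)
  labels <- switch(scheme, yeo = atlas$yeo_label,
                   voneconomo = atlas$voneconomo_label)
  if (length(labels) != length(regional)) {
    stop("atlas and regional vector disagree on the number of regions")
  }
  groups <- split(regional, labels)
  if (any(!lengths(groups))) stop("empty subnetwork in scheme ", scheme)
  vapply(groups, mean, numeric(1))
}

#' Node and subnetwork MS summaries for a whole cohort
#'
#' @param ms_list Named list of `ms_matrix` objects.
#' @param atlas An `ms_atlas`.
#' @return A list with `regional` (subjects x regions matrix) and
#'   `subnetwork` (subjects x 14 matrix, columns prefixed by scheme).
#' @export
cohort_ms_summaries <- function(ms_list, atlas) {
  regional <- t(vapply(ms_list, regional_mean_ms,
                       numeric(nrow(ms_list[[1]]))))
  colnames(regional) <- atlas$region_name
  sub <- t(vapply(ms_list, function(ms) {
    r <- regional_mean_ms(ms)
    y <- subnetwork_mean_ms(r, atlas, "yeo")
    v <- subnetwork_mean_ms(r, atlas, "voneconomo")
    c(stats::setNames(y, paste0("yeo.", names(y))),
      stats::setNames(v, paste0("voneconomo.", names(v))))
  }, numeric(length(unique(atlas$yeo_label)) +
               length(unique(atlas$voneconomo_label)))))
  list(regional = regional, subnetwork = sub)
}

#' Write an MS matrix as a square CSV with region-name headers
#' @param ms An `ms_matrix`.
#' @param region_names Region names for header row/column.
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_ms_matrix <- function(ms, region_names, path) {
  m <- as.matrix(unclass(ms))
  dimnames(m) <- list(region_names, region_names)
  utils::write.csv(m, path)
  invisible(path)
}
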