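# Cortical atlas: region labels and subnetwork membership.

#' Yeo 7-network labels
#' @keywords internal
#' @export
YEO_LABELS <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
                "limbic", "frontoparietal", "default_mode")

#' von Economo 7-class labels
#' @keywords internal
#' @export
VONECONOMO_LABELS <- c("primary_motor", "association_1", "association_2",
                       "secondary_sensory", "primary_sensory", "limbic",
                       "insular")

LOBE_LABELS <- c("frontal", "temporal", "parietal", "occipital",
                 "cingulate", "insula")

#' Build a synthetic cortical atlas
#'
#' Creates a region table with hemisphere, lobe and two 7-class subnetwork
#' membership schemes (resting-state style and cytoarchitectonic style),
#' mirroring the structure of a high-resolution Desikan-Killiany
#' parcellation. Labels are assigned as balanced as possible and then
#' shuffled deterministically by `seed`.
#'
#' @param n_regions Number of cortical regions (e.g. 308 for the
#'   high-resolution parcellation this package emulates).
#' @param yeo_labels Character vector of functional subnetwork names.
#' @param voneconomo_labels Character vector of cytoarchitectonic class names.
#' @param seed Integer seed; the same seed always yields the same atlas.
#' @return A data frame of class `ms_atlas` with columns `region_id`
#'   (0-based), `region_name`, `hemisphere`, `lobe`, `yeo_label`,
#'   `voneconomo_label`.
#' @examples
#' atlas <- build_atlas(14, seed = 1)
#' table(atlas$yeo_label)
#' @export
build_atlas <- function(n_regions,
                        yeo_labels = YEO_LABELS,
                        voneconomo_labels = VONECONOMO_LABELS,
                        seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_classes <- max(length(yeo_labels), length(voneconomo_labels))
  if (n_regions < n_classes) {
    stop("n_regions must be at least the number of subnetwork classes (",
         n_classes, ")")
  }
  balanced <- function(labels) {
    rep_len(labels, n_regions)
  }
  atlas <- local_seed(seed, {
    hemisphere <- sample(balanced(c("left", "right")))
    lobe <- sample(balanced(LOBE_LABELS))
    yeo <- sample(balanced(yeo_labels))
    voneconomo <- sample(balanced(voneconomo_labels))
    data.frame(
      region_id = 0:(n_regions - 1L),
      region_name = sprintf("%s_region_%03d",
                            ifelse(hemisphere == "left", "lh", "rh"),
                            seq_len(n_regions)),
      hemisphere = hemisphere,
      lobe = lobe,
      yeo_label = yeo,
      voneconomo_label = voneconomo,
      stringsAsFactors = FALSE
    )
  })
  class(atlas) <- c("ms_atlas", "data.frame")
  atlas
}

#' @noRd
validate_atlas <- function(atlas) {
  stopifnot(is.data.frame(atlas))
  needed <- c("region_id", "region_name", "hemisphere", "lobe",
              "yeo_label", "voneconomo_label")
  missing <- setdiff(needed, names(atlas))
  if (length(missing)) stop("atlas is missing columns: ",
                            paste(missing, collapse = ", "))
  if (!identical(as.integer(atlas$region_id), 0:(nrow(atlas) - 1L))) {
    stop("atlas region_id must be 0..N-1 with no gaps")
  }
  invisible(atlas)
}

#' Write / read an atlas as CSV
#' @param atlas An `ms_atlas` data frame.
#' @param path CSV path.
#' @return `write_atlas` returns the path invisibly; `read_atlas` the atlas.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  write_table_csv(as.data.frame(atlas), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(atlas)
  class(atlas) <- c("ms_atlas", "data.frame")
  atlas
}
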