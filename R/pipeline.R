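# End-to-end whole-slide HER2 patch pipeline.

#' Run the whole-slide clustering pipeline on a cohort
#'
#' For every slide: tissue detection, grid patch extraction and black/white
#' filtering, descriptor computation. Features are pooled over all slides,
#' normalized, clustered with mini-batch k-means at every candidate k, and
#' the Davies-Bouldin-optimal model is kept. Per-slide cluster-proportion
#' profiles are derived from the winning labels; when a response vector is
#' supplied the cluster-response association is appended.
#'
#' @param slides List of [slide_image()] objects.
#' @param response Optional logical vector of confirmed response, one entry
#'   per slide.
#' @param k_range Candidate cluster counts (default 7:12).
#' @param seed Seed for the clustering fits.
#' @param extractor Descriptor extractor (default
#'   [descriptor_handcrafted()]).
#' @param tissue_cfg A [tissue_config()].
#' @param patch_size Patch side in px.
#' @return List with `patches` (per slide), `features` (normalized pooled
#'   matrix), `selection` (from [select_k()]), `profiles` (list of
#'   [slide_profile()]), `profile_matrix`, and `association` (when
#'   `response` given).
#' @export
her2_pipeline <- function(slides, response = NULL, k_range = 7:12,
                          seed = 1L, extractor = descriptor_handcrafted(),
                          tissue_cfg = tissue_config(), patch_size = 64) {
  stopifnot(length(slides) >= 1L)
  patches <- lapply(slides, function(s)
    extract_patches(s, detect_tissue(s, tissue_cfg), size = patch_size))
  nonempty <- vapply(patches, function(p) nrow(p$meta) > 0L, logical(1))
  if (!any(nonempty)) stop("no tissue patches found on any slide", call. = FALSE)
  feats <- normalize_features(
    compute_descriptors(patches[nonempty], extractor))
  sel <- select_k(feats, k_range = k_range, seed = seed)
  meta <- attr(feats, "meta")
  ids <- vapply(slides[nonempty], function(s) s$slide_id, character(1))
  profiles <- lapply(ids, function(id)
    slide_profile(sel$model$labels[meta$slide_id == id], sel$k_best, id))
  pm <- profile_matrix(profiles)
  assoc <- NULL
  if (!is.null(response)) {
    stopifnot(length(response) == length(slides))
    assoc <- associate_clusters(pm, response[nonempty])
  }
  list(patches = patches, features = feats, selection = sel,
       profiles = profiles, profile_matrix = pm, association = assoc)
}
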