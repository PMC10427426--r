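# Non-overlapping grid patch extraction and per-slide cluster profiles.

#' Extract non-overlapping tissue patches
#'
#' Tiles the full-resolution slide with grid-aligned `size`-px squares
#' anchored at pixel (0, 0). A tile is retained when at least
#' `tissue_frac` of its footprint maps into the tissue mask (and, when ROI
#' polygons are present on the slide, into the ROI as well), and is then
#' discarded when more than 70% of its RGB values (all three channels
#' jointly, strict inequalities) are below 2 (black) or more than 80% are
#' above 250 (white).
#'
#' @param slide A [slide_image()].
#' @param mask A `tissue_mask` from [detect_tissue()].
#' @param size Patch side in px (default 64).
#' @param tissue_frac Minimum tissue (and ROI) coverage of the footprint.
#' @param black_value,black_frac Black-patch rule: drop when
#'   `frac(values < black_value) > black_frac`.
#' @param white_value,white_frac White-patch rule: drop when
#'   `frac(values > white_value) > white_frac`.
#' @return A `patch_set`: list with `slide_id`, `size`, `meta` (data frame
#'   `patch_id`, `x0`, `y0`, 0-based origins) and `tiles` (list of RGB
#'   arrays). May be empty.
#' @export
extract_patches <- function(slide, mask, size = 64, tissue_frac = 0.5,
                            black_value = 2, black_frac = 0.7,
                            white_value = 250, white_frac = 0.8) {
  stopifnot(inherits(slide, "slide_image"), inherits(mask, "tissue_mask"))
  px <- slide$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  f <- mask$downsample
  cover <- mask$mask
  if (!is.null(slide$rois) && length(slide$rois))
    cover <- cover & roi_mask(slide$rois, nrow(cover), ncol(cover), f)
  x0s <- seq(0L, W - size, by = size)
  y0s <- seq(0L, H - size, by = size)
  meta <- list(); tiles <- list(); id <- 0L
  for (y0 in y0s) for (x0 in x0s) {
    # footprint maps exactly onto downsampled rows/cols
    rr <- (y0 %/% f + 1L):min(nrow(cover), (y0 + size - 1L) %/% f + 1L)
    cc <- (x0 %/% f + 1L):min(ncol(cover), (x0 + size - 1L) %/% f + 1L)
    if (mean(cover[rr, cc]) < tissue_frac) next
    tile <- px[y0 + seq_len(size), x0 + seq_len(size), , drop = FALSE]
    if (mean(tile < black_value) > black_frac) next
    if (mean(tile > white_value) > white_frac) next
    id <- id + 1L
    meta[[id]] <- data.frame(patch_id = id, x0 = x0, y0 = y0)
    tiles[[id]] <- tile
  }
  meta <- if (id > 0L) do.call(rbind, meta)
          else data.frame(patch_id = integer(0), x0 = integer(0),
                          y0 = integer(0))
  structure(list(slide_id = slide$slide_id, size = size,
                 meta = meta, tiles = tiles),
            class = "patch_set")
}

# rasterize ROI polygon rings (full-res px coords) on the downsampled grid;
# a grid cell is inside when its centre falls in any ring
roi_mask <- function(rois, nr, nc, f) {
  cy <- (seq_len(nr) - 0.5) * f   # grid-cell centres, full-res coords
  cx <- (seq_len(nc) - 0.5) * f
  pts <- cbind(rep(cx, each = nr), rep(cy, nc))
  inside <- rep(FALSE, nrow(pts))
  for (ring in rois) {
    ring <- as.matrix(as.data.frame(ring)[, c("x", "y")])
    inside <- inside | mgcv::in.out(rbind(ring, ring[1, ]), pts)
  }
  matrix(inside, nr, nc)
}

#' Per-slide cluster proportion profile
#'
#' Converts per-patch cluster labels of one slide into the k-vector of
#' label proportions \eqn{v[c] = N_i^{-1} \sum 1\{L = c\}}.
#'
#' @param labels Integer vector of patch labels in `0..k-1`.
#' @param k Number of clusters.
#' @param slide_id Optional identifier carried through.
#' @return A `slide_profile` list with `slide_id`, `v` (proportions summing
#'   to 1) and `n_patches`.
#' @export
slide_profile <- function(labels, k, slide_id = NULL) {
  if (length(labels) == 0L)
    stop("empty-slide: no patch labels supplied", call. = FALSE)
  stopifnot_count(k, "k")
  if (any(labels < 0 | labels > k - 1))
    stop("invalid-domain: labels must lie in 0..k-1", call. = FALSE)
  v <- tabulate(labels + 1L, nbins = k) / length(labels)
  structure(list(slide_id = slide_id, v = v, n_patches = length(labels)),
            class = "slide_profile")
}

#' Stack slide profiles into a matrix
#'
#' @param profiles List of [slide_profile()] objects with a common `k`.
#' @return Numeric matrix, one row per slide, rownames = slide ids.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0L)
  k <- length(profiles[[1]]$v)
  m <- t(vapply(profiles, function(p) {
    stopifnot(length(p$v) == k)
    p$v
  }, numeric(k)))
  rownames(m) <- vapply(profiles, function(p)
    if (is.null(p$slide_id)) "" else as.character(p$slide_id), character(1))
  m
}
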