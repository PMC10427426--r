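# Whole-slide tissue detection by Law's spot texture energy.

#' Construct a slide image
#'
#' @param pixels Numeric array `height x width x 3`, 8-bit intensities.
#' @param microns_per_pixel Physical scale (um/px); default 0.325.
#' @param slide_id Opaque identifier.
#' @param rois Optional list of polygon rings, each a matrix/data frame with
#'   columns `x`, `y` in full-resolution pixel coordinates.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, microns_per_pixel = 0.325,
                        slide_id = "slide", rois = NULL) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (dim(pixels)[1] < 64 || dim(pixels)[2] < 64)
    stop("invalid-domain: slide must be at least 64 x 64 px", call. = FALSE)
  stopifnot(microns_per_pixel > 0)
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 slide_id = slide_id, rois = rois),
            class = "slide_image")
}

#' Tissue detection configuration
#'
#' @param downsample Integer downsampling factor applied first.
#' @param mean_window Side of the local-average window subtracted from the
#'   grayscale image (an even 30 is anchored 15 px before / 14 px after the
#'   centre).
#' @param energy_window Side of the absolute-value averaging window of the
#'   spot texture energy.
#' @param threshold Binarization threshold on the spot energy map.
#' @param min_area Minimum connected-component area (downsampled px) kept;
#'   components must exceed this strictly.
#' @param erode_radius Radius (downsampled px) of the disc erosion applied
#'   to the binarized energy map; compensates the known support dilation
#'   of the energy-averaging filter so contours stay tight; the default
#'   (one less than the energy-window radius, accounting for the part of
#'   the halo cut off by the threshold) places boundaries without bias on
#'   synthetic tissue discs of known extent.
#' @return A list of settings.
#' @export
tissue_config <- function(downsample = 8, mean_window = 30,
                          energy_window = 15, threshold = 20,
                          min_area = 1500,
                          erode_radius = energy_window %/% 2L - 1L) {
  list(downsample = downsample, mean_window = mean_window,
       energy_window = energy_window, threshold = threshold,
       min_area = min_area, erode_radius = erode_radius)
}

# ---- small image helpers -------------------------------------------------

# block-mean downsample of a matrix; output dims = ceiling(dim / f)
block_downsample <- function(m, f) {
  ri <- (seq_len(nrow(m)) - 1L) %/% f
  ci <- (seq_len(ncol(m)) - 1L) %/% f
  sums <- rowsum(m, ri, reorder = TRUE)
  sums <- t(rowsum(t(sums), ci, reorder = TRUE))
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  sums / cnt
}

# Rec.601 luma from an RGB array
rgb_to_gray <- function(px) {
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# symmetric (reflect) padding, possibly asymmetric per side
pad_reflect <- function(m, before_y, after_y = before_y,
                        before_x = before_y, after_x = before_x) {
  ri <- c(rev(seq_len(min(before_y, nrow(m)))), seq_len(nrow(m)),
          nrow(m) + 1 - rev(seq_len(min(after_y, nrow(m)))))
  ci <- c(rev(seq_len(min(before_x, ncol(m)))), seq_len(ncol(m)),
          ncol(m) + 1 - rev(seq_len(min(after_x, ncol(m)))))
  m[ri, ci, drop = FALSE]
}

# exact local box mean over an n x n window with reflect padding, via
# integral images; an even n has no centre pixel, so the two opposite
# anchorings are averaged to keep the filter symmetric
box_mean_reflect <- function(m, n) {
  one_anchor <- function(b) {
    a <- n - b - 1L
    p <- pad_reflect(m, b, a, b, a)
    # integral image with a zero top row/left column
    S <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
    S[-1, -1] <- t(apply(apply(p, 2L, cumsum), 1L, cumsum))
    r1 <- seq_len(nrow(m)); c1 <- seq_len(ncol(m))
    (S[r1 + n, c1 + n] - S[r1, c1 + n] - S[r1 + n, c1] + S[r1, c1]) / n^2
  }
  if (n %% 2L) one_anchor(n %/% 2L)
  else (one_anchor(n %/% 2L) + one_anchor(n %/% 2L - 1L)) / 2
}

# separable 2-D convolution with a pair of centred odd-length 1-D kernels
# (rows filtered with `ky`, columns with `kx`), reflect padding; computed
# as sums of shifted submatrices (no FFT, no dispatch overhead)
conv2_sep_reflect <- function(m, ky, kx) {
  stopifnot(length(ky) %% 2L == 1L, length(kx) %% 2L == 1L)
  py <- (length(ky) - 1L) %/% 2L
  px <- (length(kx) - 1L) %/% 2L
  p <- pad_reflect(m, py, py, px, px)
  n <- nrow(m)
  tmp <- matrix(0, n, ncol(p))
  Tk <- length(ky)
  for (t in seq_len(Tk))
    tmp <- tmp + ky[t] * p[seq_len(n) + (Tk - t), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  Tk <- length(kx)
  for (t in seq_len(Tk))
    out <- out + kx[t] * tmp[, seq_len(ncol(m)) + (Tk - t), drop = FALSE]
  out
}

# Law's 1-D texture kernels (level, edge, spot)
laws_kernels <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1))
}

# Law's texture energy: convolve with outer(a, b), then average |.| locally
laws_energy <- function(m, a, b, window) {
  resp <- conv2_sep_reflect(m, a, b)
  box_mean_reflect(abs(resp), window)
}

# binary erosion by a disc of the given radius, reflect-padded so the
# image border is not treated as background
erode_reflect <- function(bw, radius) {
  if (radius <= 0) return(bw)
  p <- pad_reflect(bw, radius) + 0
  er <- EBImage::erode(p, EBImage::makeBrush(2L * radius + 1L, "disc")) > 0
  er[radius + seq_len(nrow(bw)), radius + seq_len(ncol(bw)), drop = FALSE]
}

# 4-connected component labelling of a logical matrix via the pixel
# adjacency graph
label_components4 <- function(bw) {
  lab <- matrix(0L, nrow(bw), ncol(bw))
  idx <- which(bw)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(bw)
  pos <- match(seq_len(length(bw)), idx)      # linear index -> vertex id
  edges <- integer(0)
  r <- ((idx - 1L) %% nr) + 1L
  # down neighbour
  ok <- r < nr & bw[pmin(idx + 1L, length(bw))]
  ok[r == nr] <- FALSE
  if (any(ok)) edges <- c(edges, rbind(pos[idx[ok]], pos[idx[ok] + 1L]))
  # right neighbour
  ok <- idx + nr <= length(bw)
  ok[ok] <- bw[idx[ok] + nr]
  if (any(ok)) edges <- c(edges, rbind(pos[idx[ok]], pos[idx[ok] + nr]))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- comp
  lab
}

# ---- main operation ------------------------------------------------------

#' Detect tissue on a brightfield slide
#'
#' Downsamples the slide, converts to grayscale, subtracts a local average
#' to obtain a near-zero-mean image, computes Law's spot (S5'S5) texture
#' energy, binarizes the energy map, fills interior holes, and drops small
#' connected components.
#'
#' @param slide A [slide_image()].
#' @param config A [tissue_config()].
#' @return A `tissue_mask` object: list with logical `mask` (downsampled
#'   grid) and `downsample` factor.
#' @export
detect_tissue <- function(slide, config = tissue_config()) {
  stopifnot(inherits(slide, "slide_image"))
  f <- config$downsample
  gray <- rgb_to_gray(slide$pixels)
  ds <- block_downsample(gray, f)
  if (nrow(ds) < config$mean_window || ncol(ds) < config$mean_window)
    stop("degenerate-image: slide smaller than the local-mean window after ",
         "downsampling", call. = FALSE)
  zm <- ds - box_mean_reflect(ds, config$mean_window)
  k <- laws_kernels()
  energy <- laws_energy(zm, k$S5, k$S5, config$energy_window)
  bw <- erode_reflect(energy > config$threshold, config$erode_radius)
  filled <- EBImage::fillHull(bw) > 0
  lab <- label_components4(filled)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas > config$min_area)
    filled <- matrix(lab %in% keep, nrow(lab), ncol(lab))
  }
  structure(list(mask = filled, downsample = f,
                 config = config, slide_id = slide$slide_id),
            class = "tissue_mask")
}
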