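# Classical nuclei segmentation stand-in plus the dedup/shape/intensity
# feature rules, aggregated per 64 px patch.
#
# Image convention throughout: matrices are indexed [row = y, col = x];
# centroids are reported as 0-based (centroid_x, centroid_y) pixel
# coordinates so that the patch with origin (x0, y0) owns the half-open
# square [x0, x0 + size) x [y0, y0 + size).

#' Nuclei segmentation configuration
#'
#' @param min_perimeter,max_perimeter Retained perimeter range (px).
#' @param min_circularity Circularity floor, `4*pi*area/perimeter^2`.
#' @param min_area Minimum object area (px^2) before shape filtering.
#' @param watershed_tolerance Tolerance of the distance-transform watershed
#'   that splits touching nuclei.
#' @param dedup_px Centroid distance (px) under which a later nucleus is
#'   discarded as a duplicate (strict `<`).
#' @param tile_um Diameter (micrometres) of the circular tile over which
#'   DAB optical density is averaged per nucleus.
#' @return A list of settings.
#' @export
nuclei_config <- function(min_perimeter = 8, max_perimeter = 200,
                          min_circularity = 0.15, min_area = 6,
                          watershed_tolerance = 1, dedup_px = 20,
                          tile_um = 30) {
  list(min_perimeter = min_perimeter, max_perimeter = max_perimeter,
       min_circularity = min_circularity, min_area = min_area,
       watershed_tolerance = watershed_tolerance, dedup_px = dedup_px,
       tile_um = tile_um)
}

#' Segment nuclei from a hematoxylin optical-density map
#'
#' Classical pipeline: Otsu threshold on the OD map, distance-transform
#' watershed to split touching nuclei, then shape filters on perimeter and
#' circularity. When a DAB OD map is supplied, each nucleus additionally
#' carries the mean DAB OD within a circular tile (default 30 um diameter,
#' rounded to the nearest odd pixel count, clipped at image borders)
#' centred on its centroid.
#'
#' @param od_h Matrix of hematoxylin optical densities.
#' @param od_dab Optional matrix of DAB optical densities (same shape).
#' @param microns_per_pixel Physical scale, um/px.
#' @param config A [nuclei_config()].
#' @return Data frame with one row per nucleus: `centroid_x`, `centroid_y`
#'   (0-based px), `area`, `perimeter`, `circularity`, `dab_tile_mean`
#'   (NA without `od_dab`). The watershed label image is attached as
#'   attribute `"labels"`.
#' @export
segment_nuclei <- function(od_h, od_dab = NULL, microns_per_pixel = 0.325,
                           config = nuclei_config()) {
  stopifnot(is.matrix(od_h), all(is.finite(od_h)))
  empty <- data.frame(centroid_x = numeric(0), centroid_y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), dab_tile_mean = numeric(0))
  rng <- range(od_h)
  if (diff(rng) < 1e-12) return(empty)
  thr <- otsu_threshold(od_h)
  bw <- od_h > thr
  if (!any(bw)) return(empty)
  labels <- EBImage::watershed(EBImage::distmap(bw),
                               tolerance = config$watershed_tolerance)
  n_obj <- max(labels)
  if (n_obj == 0) return(empty)
  sh <- EBImage::computeFeatures.shape(labels)
  mo <- EBImage::computeFeatures.moment(labels)
  # matrices are [row = y, col = x], so m.cx (first dim) is y; 1-based -> 0-based
  nuc <- data.frame(
    centroid_x = mo[, "m.cy"] - 1,
    centroid_y = mo[, "m.cx"] - 1,
    area = sh[, "s.area"],
    perimeter = sh[, "s.perimeter"],
    circularity = pmin(1, 4 * pi * sh[, "s.area"] /
                          pmax(sh[, "s.perimeter"], 1e-9)^2)
  )
  keep <- nuc$area >= config$min_area &
    nuc$perimeter >= config$min_perimeter &
    nuc$perimeter <= config$max_perimeter &
    nuc$circularity >= config$min_circularity
  nuc <- nuc[keep, , drop = FALSE]
  nuc$dab_tile_mean <- if (is.null(od_dab)) NA_real_ else
    dab_tile_means(nuc, od_dab, microns_per_pixel, config$tile_um)
  rownames(nuc) <- NULL
  attr(nuc, "labels") <- labels
  attr(nuc, "threshold") <- thr
  nuc
}

# Otsu's threshold by between-class variance maximization on a histogram
otsu_threshold <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) < 1e-12) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = levels + 1L)
  mids <- (br[-1] + br[-length(br)]) / 2
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), levels)
  w1 <- cumsum(h)
  m1 <- cumsum(h * mids)
  n <- w1[levels]; mt <- m1[levels]
  between <- (mt * w1 - n * m1)^2 / (w1 * (n - w1))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between[-levels])]
}

# mean DAB OD within an odd-diameter disc around each centroid, border-clipped
dab_tile_means <- function(nuc, od_dab, microns_per_pixel, tile_um) {
  if (nrow(nuc) == 0L) return(numeric(0))
  d_px <- tile_um / microns_per_pixel
  d_odd <- 2 * floor(d_px / 2) + 1        # nearest odd diameter
  r <- (d_odd - 1) / 2
  h <- nrow(od_dab); w <- ncol(od_dab)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= r^2, ]
  vapply(seq_len(nrow(nuc)), function(i) {
    cy <- round(nuc$centroid_y[i]) + 1     # back to 1-based rows
    cx <- round(nuc$centroid_x[i]) + 1
    ys <- cy + off$dy; xs <- cx + off$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    mean(od_dab[cbind(ys[ok], xs[ok])])
  }, numeric(1))
}

#' Discard duplicate nuclei by centroid proximity
#'
#' Greedy scan in a deterministic order (descending area, then raster order
#' of centroids): a nucleus is dropped when its centroid lies strictly
#' within `min_dist_px` (Euclidean) of any previously kept centroid.
#' Idempotent.
#'
#' @param nuclei Data frame as returned by [segment_nuclei()].
#' @param min_dist_px Distance threshold in pixels (default 20, i.e. 6.5 um
#'   at 0.325 um/px).
#' @return The kept subset, in scan order.
#' @export
dedup_nuclei <- function(nuclei, min_dist_px = 20) {
  stopifnot(is.data.frame(nuclei))
  if (nrow(nuclei) <= 1L) return(nuclei)
  ord <- order(-nuclei$area, nuclei$centroid_y, nuclei$centroid_x)
  nuc <- nuclei[ord, , drop = FALSE]
  kept <- logical(nrow(nuc))
  kx <- numeric(0); ky <- numeric(0)
  for (i in seq_len(nrow(nuc))) {
    if (length(kx) == 0L ||
        min((kx - nuc$centroid_x[i])^2 + (ky - nuc$centroid_y[i])^2) >=
          min_dist_px^2) {
      kept[i] <- TRUE
      kx <- c(kx, nuc$centroid_x[i]); ky <- c(ky, nuc$centroid_y[i])
    }
  }
  out <- nuc[kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize nuclei per patch
#'
#' Assigns every nucleus to the unique patch whose half-open footprint
#' `[x0, x0 + size) x [y0, y0 + size)` contains its centroid, then reports
#' the nucleus count (cell-density measure) and per-patch means of area,
#' perimeter, circularity and DAB tile intensity. Feature means are NA for
#' patches without nuclei.
#'
#' @param nuclei Data frame of (deduplicated) nuclei.
#' @param patches A `patch_set` (see [extract_patches()]) or a data frame
#'   with columns `patch_id`, `x0`, `y0` and attribute/column `size`.
#' @return Data frame with one row per patch: `patch_id`, `nuclei_count`,
#'   `mean_area`, `mean_perimeter`, `mean_circularity`, `mean_dab_tile`.
#' @export
summarize_patches <- function(nuclei, patches) {
  meta <- if (inherits(patches, "patch_set")) patches$meta else patches
  size <- if (inherits(patches, "patch_set")) patches$size
          else if (!is.null(meta$size)) meta$size[1] else 64
  out <- data.frame(patch_id = meta$patch_id,
                    nuclei_count = 0L,
                    mean_area = NA_real_, mean_perimeter = NA_real_,
                    mean_circularity = NA_real_, mean_dab_tile = NA_real_)
  if (nrow(nuclei) == 0L) return(out)
  key <- paste(floor(nuclei$centroid_x / size) * size,
               floor(nuclei$centroid_y / size) * size)
  pkey <- paste(meta$x0, meta$y0)
  idx <- match(key, pkey)
  ok <- !is.na(idx)
  if (!any(ok)) return(out)
  sp <- split(which(ok), idx[ok])
  for (j in names(sp)) {
    i <- as.integer(j); rows <- sp[[j]]
    out$nuclei_count[i] <- length(rows)
    out$mean_area[i] <- mean(nuclei$area[rows])
    out$mean_perimeter[i] <- mean(nuclei$perimeter[rows])
    out$mean_circularity[i] <- mean(nuclei$circularity[rows])
    out$mean_dab_tile[i] <- mean(nuclei$dab_tile_mean[rows])
  }
  out
}
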