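# Optical-density stain unmixing for hematoxylin/DAB brightfield IHC.

#' Define a hematoxylin/DAB stain basis
#'
#' Unit optical-density direction per stain in RGB space plus the background
#' (blank glass) intensity. Defaults are the standard published
#' hematoxylin and DAB OD vectors used in brightfield color deconvolution.
#'
#' @param hematoxylin,dab Length-3 OD direction vectors (normalized
#'   internally).
#' @param I0 Background transmitted intensity per channel (scalar or
#'   length 3), 8-bit scale.
#' @return A `stain_basis` object.
#' @export
stain_basis <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        dab = c(0.269, 0.568, 0.778),
                        I0 = 255) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  ang <- acos(min(1, sum(h * d))) * 180 / pi
  if (!is.finite(ang) || ang <= 10)
    stop("collinear-basis: stain vectors must differ by more than 10 degrees",
         call. = FALSE)
  if (length(I0) == 1L) I0 <- rep(I0, 3L)
  stopifnot(length(I0) == 3L, all(I0 > 0))
  structure(list(h = h, d = d, I0 = I0, angle_deg = ang),
            class = "stain_basis")
}

#' Unmix an RGB tile into hematoxylin and DAB optical densities
#'
#' Per pixel, optical density is \eqn{-\log_{10}((I + \epsilon)/I_0)} per
#' channel (Beer-Lambert), projected onto the two stain directions by least
#' squares; negative projections are clipped to zero.
#'
#' @param pixels Numeric array `height x width x 3` of transmitted
#'   intensities (0-255), or an `n x 3` matrix of pixels.
#' @param basis A [stain_basis()].
#' @param eps Offset added before the log to avoid log(0); 1 on the 8-bit
#'   count scale.
#' @return A list with matrices `h` and `dab` of per-pixel optical densities
#'   (same spatial shape as the input).
#' @export
deconvolve <- function(pixels, basis = stain_basis(), eps = 1) {
  stopifnot(inherits(basis, "stain_basis"))
  dims <- dim(pixels)
  if (length(dims) == 3L) {
    stopifnot(dims[3] == 3L)
    flat <- matrix(pixels, ncol = 3L)
  } else {
    stopifnot(length(dims) == 2L, dims[2] == 3L)
    flat <- pixels
  }
  od <- -log10(sweep(flat + eps, 2L, basis$I0, "/"))
  S <- cbind(basis$h, basis$d)                 # 3 x 2 stain matrix
  coef <- od %*% (S %*% solve(crossprod(S)))   # least-squares projection
  coef[coef < 0] <- 0
  shape <- if (length(dims) == 3L) dims[1:2] else c(dims[1], 1L)
  list(h = matrix(coef[, 1L], shape[1], shape[2]),
       dab = matrix(coef[, 2L], shape[1], shape[2]))
}

#' Forward Beer-Lambert stain mixing
#'
#' Renders transmitted RGB intensities from per-pixel hematoxylin and DAB
#' optical densities under a stain basis; the inverse of [deconvolve()]
#' (with matching `eps`) up to clipping.
#'
#' @param h,dab Matrices of optical densities.
#' @param basis A [stain_basis()].
#' @param eps Offset convention matching [deconvolve()].
#' @return Array `nrow(h) x ncol(h) x 3` of intensities (not yet noised,
#'   rounded or clipped).
#' @export
stain_mix <- function(h, dab, basis = stain_basis(), eps = 1) {
  stopifnot(all(dim(h) == dim(dab)))
  od <- outer(c(h), basis$h) + outer(c(dab), basis$d)  # n x 3
  I <- sweep(10^(-od), 2L, basis$I0, "*") - eps
  array(I, c(nrow(h), ncol(h), 3L))
}
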