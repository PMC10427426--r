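# Per-patch visual appearance descriptors and feature normalization.

#' Handcrafted patch descriptor
#'
#' The default descriptor concatenates, per patch: hematoxylin and DAB
#' optical-density statistics (mean, s.d., quantiles 0.1/0.25/0.5/0.9),
#' four Law's texture energies (E5E5, S5S5, L5E5, L5S5 on the zero-mean
#' grayscale tile), and the nuclei-density proxy from the morphometrics
#' module (deduplicated nucleus count in the tile). It is deterministic
#' given the tile.
#'
#' @param basis A [stain_basis()].
#' @param microns_per_pixel Physical scale forwarded to nuclei features.
#' @param nuclei_cfg A [nuclei_config()].
#' @return A `descriptor_extractor` object (callable on one RGB tile).
#' @export
descriptor_handcrafted <- function(basis = stain_basis(),
                                   microns_per_pixel = 0.325,
                                   nuclei_cfg = nuclei_config()) {
  qs <- c(0.1, 0.25, 0.5, 0.9)
  od_stats <- function(m, prefix) {
    v <- c(mean(m), stats::sd(c(m)), stats::quantile(c(m), qs, names = FALSE))
    names(v) <- paste0(prefix, c("_mean", "_sd", paste0("_q", qs * 100)))
    v
  }
  k <- laws_kernels()
  fn <- function(tile) {
    od <- deconvolve(tile, basis)
    gray <- rgb_to_gray(tile)
    zm <- gray - mean(gray)
    law <- c(law_E5E5 = mean(laws_energy(zm, k$E5, k$E5, 15)),
             law_S5S5 = mean(laws_energy(zm, k$S5, k$S5, 15)),
             law_L5E5 = mean(laws_energy(zm, k$L5, k$E5, 15)),
             law_L5S5 = mean(laws_energy(zm, k$L5, k$S5, 15)))
    nuc <- dedup_nuclei(segment_nuclei(od$h, NULL, microns_per_pixel,
                                       nuclei_cfg),
                        nuclei_cfg$dedup_px)
    c(od_stats(od$h, "h"), od_stats(od$dab, "dab"), law,
      nuc_count = nrow(nuc))
  }
  structure(list(fn = fn, dim = 17L, name = "handcrafted"),
            class = "descriptor_extractor")
}

#' Plug in an external fixed-dimension descriptor
#'
#' Interface for deep-feature extractors (e.g. a truncated convolutional
#' network emitting 1,024 descriptors): any deterministic function mapping
#' one RGB tile to a fixed-length numeric vector satisfies the contract.
#' No network weights ship with the package.
#'
#' @param fn Function of one tile returning a numeric vector of length
#'   `dim`.
#' @param dim Descriptor length.
#' @param name Label recorded in outputs.
#' @return A `descriptor_extractor`.
#' @export
descriptor_plugin <- function(fn, dim, name = "plugin") {
  stopifnot(is.function(fn), dim >= 1)
  structure(list(fn = fn, dim = as.integer(dim), name = name),
            class = "descriptor_extractor")
}

#' Compute raw patch descriptors
#'
#' Applies the extractor to every tile of one or several patch sets and
#' stacks the rows. Rows are unnormalized; pool all slides and call
#' [normalize_features()] before clustering.
#'
#' @param patches A `patch_set` or list of `patch_set`s.
#' @param extractor A `descriptor_extractor` (default
#'   [descriptor_handcrafted()]).
#' @return Numeric matrix, one row per patch, with a `meta` attribute
#'   (data frame `slide_id`, `patch_id`, `x0`, `y0`).
#' @export
compute_descriptors <- function(patches, extractor = descriptor_handcrafted()) {
  stopifnot(inherits(extractor, "descriptor_extractor"))
  sets <- if (inherits(patches, "patch_set")) list(patches) else patches
  stopifnot(all(vapply(sets, inherits, logical(1), "patch_set")))
  n <- sum(vapply(sets, function(s) nrow(s$meta), integer(1)))
  if (n == 0L) stop("invalid-domain: at least one patch required", call. = FALSE)
  rows <- vector("list", n); meta <- vector("list", n); i <- 0L
  for (s in sets) {
    for (j in seq_len(nrow(s$meta))) {
      v <- extractor$fn(s$tiles[[j]])
      if (length(v) != extractor$dim)
        stop("descriptor-dimension mismatch: extractor returned ",
             length(v), " values, expected ", extractor$dim, call. = FALSE)
      i <- i + 1L
      rows[[i]] <- v
      meta[[i]] <- data.frame(slide_id = s$slide_id,
                              patch_id = s$meta$patch_id[j],
                              x0 = s$meta$x0[j], y0 = s$meta$y0[j])
    }
  }
  x <- do.call(rbind, rows)
  if (any(!is.finite(x)))
    stop("descriptor produced non-finite values", call. = FALSE)
  attr(x, "meta") <- do.call(rbind, meta)
  attr(x, "extractor") <- extractor$name
  x
}

#' Normalize a pooled feature matrix
#'
#' Standardizes every feature to mean 0 and s.d. 1 over all patches of all
#' slides. Features with s.d. below `tol` are dropped (not divided) and
#' reported via a message.
#'
#' @param x Feature matrix from [compute_descriptors()].
#' @param tol Standard-deviation floor under which a feature is dropped.
#' @return The normalized matrix with attributes `center`, `scale` and
#'   `dropped` (names of removed features); `meta` is carried through.
#' @export
normalize_features <- function(x, tol = 1e-12) {
  stopifnot(is.matrix(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  drop <- scl < tol
  if (any(drop))
    message("normalize_features: dropping near-constant feature(s): ",
            paste(colnames(x)[drop], collapse = ", "))
  out <- sweep(sweep(x[, !drop, drop = FALSE], 2L, ctr[!drop], "-"),
               2L, scl[!drop], "/")
  attr(out, "meta") <- attr(x, "meta")
  attr(out, "center") <- ctr[!drop]
  attr(out, "scale") <- scl[!drop]
  attr(out, "dropped") <- colnames(x)[drop]
  out
}
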