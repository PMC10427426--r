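# Readers and writers for the package's plain-text interchange formats.

#' Read per-patient response records
#'
#' CSV with header `patient_id,cohort,best_response,confirmed,
#' best_change_pct`; `confirmed` is parsed as logical.
#'
#' @param path CSV file path.
#' @return Data frame of response records.
#' @export
read_response_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "cohort", "best_response", "confirmed")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("response CSV lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$confirmed <- as.logical(df$confirmed)
  df
}

#' Write per-patient response records
#' @param records Data frame of response records.
#' @param path Output CSV path.
#' @export
write_response_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a multiplex-IF cell table
#'
#' CSV with `x_um`, `y_um` and one logical (0/1 or TRUE/FALSE) column per
#' marker.
#'
#' @param path CSV file path.
#' @return Data frame with marker columns coerced to logical.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("cell CSV needs x_um and y_um columns", call. = FALSE)
  for (m in setdiff(names(df), c("x_um", "y_um", "sample_id", "patient_id",
                                 "timepoint")))
    df[[m]] <- as.logical(df[[m]])
  df
}

#' Read a MAF-like variant call TSV
#' @param path TSV path with the columns documented in the genomics module.
#' @return Data frame of variant calls.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("germline_flag" %in% names(df))
    df$germline_flag <- as.logical(df$germline_flag)
  df
}

#' Read variant calls from a VCF file
#'
#' Thin convenience converter (requires the suggested vcfR package): pulls
#' CHROM/POS/REF/ALT plus per-sample AD and DP into the package's
#' flat call-table schema. Multi-allelic records are split into biallelic
#' events.
#'
#' @param path VCF path.
#' @param sample_id,timepoint Identity assigned to the rows.
#' @return Data frame of variant calls.
#' @export
read_variant_vcf <- function(path, sample_id, timepoint) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variant_vcf needs the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1]))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    counts <- suppressWarnings(
      as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    for (j in seq_along(alts)) {
      altn <- if (length(counts) > j) counts[j + 1L] else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, timepoint = timepoint,
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[j],
        vaf = if (!is.na(altn) && !is.na(dp[i]) && dp[i] > 0)
          altn / dp[i] else NA_real_,
        depth = dp[i], alt_reads = altn, germline_flag = FALSE,
        gene = NA_character_, consequence = NA_character_)
    }
  }
  do.call(rbind, rows)
}

#' Read a pileup-count TSV
#' @param path TSV with columns chrom, pos, ref, alt, coverage, alt_reads.
#' @return Data frame.
#' @export
read_pileup_table <- function(path) utils::read.delim(path,
                                                      stringsAsFactors = FALSE)

#' Read a SEG-like copy-number segment TSV
#' @param path TSV with columns sample_id, run, chrom, start, end,
#'   category, gene.
#' @return Data frame.
#' @export
read_seg_table <- function(path) utils::read.delim(path,
                                                   stringsAsFactors = FALSE)

#' Read a driver-gene list
#'
#' Two-column TSV (`gene`, `is_oncogene`). The package ships a small
#' synthetic list at
#' `system.file("extdata", "driver_genes_synthetic.tsv", package =
#' "trialpatch")`.
#'
#' @param path TSV path; defaults to the packaged synthetic list.
#' @return Data frame with `gene` and logical `is_oncogene`.
#' @export
read_driver_list <- function(path = system.file("extdata",
                                                "driver_genes_synthetic.tsv",
                                                package = "trialpatch")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$is_oncogene <- as.logical(df$is_oncogene)
  df
}

#' Read ROI polygons from a JSON annotation file
#'
#' Expects a JSON array of rings, each an array of `[x, y]` pixel
#' coordinates (or an object with `x`/`y` arrays).
#'
#' @param path JSON path.
#' @return List of data frames with columns `x`, `y`.
#' @export
read_roi_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  lapply(raw, function(ring) {
    if (is.list(ring) && !is.null(ring$x))
      data.frame(x = as.numeric(ring$x), y = as.numeric(ring$y))
    else {
      m <- do.call(rbind, ring)
      data.frame(x = as.numeric(m[, 1]), y = as.numeric(m[, 2]))
    }
  })
}

#' Read a slide image from PNG or TIFF
#'
#' @param path Image path (.png or .tif/.tiff; TIFF requires the
#'   suggested tiff package).
#' @param microns_per_pixel,slide_id,rois Passed to [slide_image()].
#' @return A [slide_image()] with 0-255 intensities.
#' @export
read_slide <- function(path, microns_per_pixel = 0.325,
                       slide_id = basename(path), rois = NULL) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  slide_image(px * 255, microns_per_pixel, slide_id, rois)
}

#' Write a slide image to PNG
#' @param slide A [slide_image()].
#' @param path Output PNG path.
#' @export
write_slide_png <- function(slide, path) {
  png::writePNG(slide$pixels / 255, path)
  invisible(path)
}

#' Write cluster associations to CSV
#' @param association Data frame from [associate_clusters()].
#' @param path Output CSV path.
#' @export
write_association_csv <- function(association, path) {
  utils::write.csv(association, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-slide cluster profiles to CSV
#'
#' @param profiles List of [slide_profile()] objects or a profile matrix.
#' @param path Output CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  df <- data.frame(slide_id = rownames(m), m, check.names = FALSE)
  names(df)[-1] <- paste0("cluster_", seq_len(ncol(m)) - 1L)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a cluster overlay PNG
#'
#' Paints every retained patch of a slide with its cluster's color over a
#' dimmed copy of the slide, for visual inspection of the spatial layout
#' of clusters.
#'
#' @param slide A [slide_image()].
#' @param patches The slide's `patch_set`.
#' @param labels 0-based cluster labels, one per patch of this slide.
#' @param k Number of clusters (governs the palette).
#' @param path Output PNG path.
#' @param alpha Blend weight of the cluster color (0-1).
#' @export
write_cluster_overlay <- function(slide, patches, labels, k, path,
                                  alpha = 0.45) {
  stopifnot(inherits(slide, "slide_image"), inherits(patches, "patch_set"),
            length(labels) == nrow(patches$meta))
  pal <- grDevices::col2rgb(grDevices::hcl.colors(max(k, 2L), "Dark 3"))
  img <- slide$pixels / 255
  sz <- patches$size
  for (i in seq_len(nrow(patches$meta))) {
    ys <- patches$meta$y0[i] + seq_len(sz)
    xs <- patches$meta$x0[i] + seq_len(sz)
    col <- pal[, labels[i] + 1L] / 255
    for (ch in 1:3)
      img[ys, xs, ch] <- (1 - alpha) * img[ys, xs, ch] + alpha * col[ch]
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Export nucleus masks as a labeled TIFF
#'
#' Writes the watershed label image attached to a [segment_nuclei()]
#' result (one integer label per nucleus) as a 16-bit grayscale TIFF.
#' Requires the suggested tiff package.
#'
#' @param nuclei Result of [segment_nuclei()].
#' @param path Output TIFF path.
#' @export
write_nuclei_labels_tiff <- function(nuclei, path) {
  labels <- attr(nuclei, "labels")
  if (is.null(labels))
    stop("nuclei table carries no label image", call. = FALSE)
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF requires the tiff package", call. = FALSE)
  tiff::writeTIFF(labels / max(1, max(labels)), path, bits.per.sample = 16L)
  invisible(path)
}
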