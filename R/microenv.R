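# Multiplex-immunofluorescence microenvironment quantification: cell
# densities per mm^2, nearest-tumor-cell distances, and paired
# pre/on-treatment statistics.
#
# Cell tables are data frames with coordinates x_um, y_um and one logical
# column per marker (CK, PDL1, CD3, CD8, CD68, FoxP3, PD1, CD4, ...).

#' Marker-positive cell density
#'
#' Counts cells positive for every queried marker and divides by the
#' analyzed tissue area.
#'
#' @param cells Cell table.
#' @param markers Character vector of marker columns that must all be TRUE
#'   (conjunctive query, e.g. `c("CK", "PDL1")`).
#' @param area_mm2 Analyzed tissue area in mm^2.
#' @return Cells per mm^2.
#' @export
cell_density <- function(cells, markers, area_mm2) {
  if (!is.numeric(area_mm2) || area_mm2 <= 0)
    stop("nonpositive-area: area_mm2 must be > 0", call. = FALSE)
  if (nrow(cells) == 0L) return(0)
  miss <- setdiff(markers, names(cells))
  if (length(miss))
    stop("unknown marker column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  hit <- rep(TRUE, nrow(cells))
  for (m in markers) hit <- hit & cells[[m]]
  sum(hit) / area_mm2
}

#' Distance from every cell to the nearest CK+ cell
#'
#' Euclidean distance in micrometres; CK+ cells measure to the nearest
#' *other* CK+ cell (NA when the slide has a single CK+ cell). Distances
#' are binned into half-open intervals `[0,10), [10,20), ...` by default,
#' so the tumor-cell-proximate bin is 0-10 um.
#'
#' @param cells Cell table.
#' @param ref_marker Reference marker column (default `"CK"`).
#' @param bin_width Bin width in um (default 10).
#' @return The input table with added columns `dist_to_ref_um` and `bin`
#'   (factor); attribute `"bin_counts"` holds the per-bin totals.
#' @export
nearest_ck_distance <- function(cells, ref_marker = "CK", bin_width = 10) {
  stopifnot(is.data.frame(cells))
  if (!ref_marker %in% names(cells))
    stop("unknown marker column: ", ref_marker, call. = FALSE)
  ref <- which(cells[[ref_marker]])
  if (length(ref) == 0L)
    stop("no-reference-cell: no ", ref_marker, "+ cell present", call. = FALSE)
  rx <- cells$x_um[ref]; ry <- cells$y_um[ref]
  n <- nrow(cells)
  d <- numeric(n)
  is_ref <- seq_len(n) %in% ref
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(n, start + chunk - 1L)
    d2 <- outer(cells$x_um[rows], rx, "-")^2 +
          outer(cells$y_um[rows], ry, "-")^2
    # a reference cell must not match itself
    self <- cbind(which(is_ref[rows]), match(rows[is_ref[rows]], ref))
    if (nrow(self)) d2[self] <- Inf
    mins <- apply(d2, 1L, min)
    d[rows] <- ifelse(is.finite(mins), sqrt(mins), NA_real_)
  }
  out <- cells
  out$dist_to_ref_um <- d
  top <- max(d[is.finite(d)], 0, na.rm = TRUE)
  breaks <- seq(0, (floor(top / bin_width) + 1) * bin_width, by = bin_width)
  out$bin <- cut(d, breaks = breaks, right = FALSE)
  attr(out, "bin_counts") <- table(out$bin)
  out
}

#' Paired pre/on-treatment test
#'
#' Two-sided Wilcoxon matched-pairs signed-rank test on per-patient
#' (baseline, on-treatment) values. Zero differences are dropped before
#' ranking (Wilcoxon's rule); with at most `exact_max` non-zero
#' differences and no ties among their magnitudes the exact null is used,
#' otherwise the normal approximation with tie and continuity corrections.
#' All-zero differences give p = 1 with a warning.
#'
#' @param baseline,on_treatment Numeric vectors of equal length.
#' @param exact_max Largest number of non-zero differences for the exact
#'   null (default 25).
#' @return List with `p.value`, `statistic` (V), `n_pairs`, `n_used` and
#'   `method`.
#' @export
paired_test <- function(baseline, on_treatment, exact_max = 25) {
  stopifnot(length(baseline) == length(on_treatment),
            length(baseline) >= 1L)
  d <- on_treatment - baseline
  dnz <- d[d != 0]
  if (length(dnz) == 0L) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(p.value = 1, statistic = NA_real_,
                n_pairs = length(d), n_used = 0L,
                method = "degenerate (all zero differences)"))
  }
  ties <- any(duplicated(abs(dnz)))
  exact <- length(dnz) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(dnz, mu = 0, exact = exact, correct = TRUE))
  list(p.value = ht$p.value, statistic = unname(ht$statistic),
       n_pairs = length(d), n_used = length(dnz),
       method = if (exact) "exact" else "normal approximation")
}

#' Batch paired tests with FDR adjustment
#'
#' Runs [paired_test()] once per family (marker or distance bin) and
#' adjusts the p-values across families with Benjamini-Hochberg.
#'
#' @param data Data frame with columns `family`, `baseline`,
#'   `on_treatment` (one row per patient and family).
#' @return Tidy data frame `family`, `n_pairs`, `p`, `q`.
#' @export
paired_test_batch <- function(data) {
  stopifnot(all(c("family", "baseline", "on_treatment") %in% names(data)))
  fams <- unique(data$family)
  res <- lapply(fams, function(f) {
    rows <- data[data$family == f, , drop = FALSE]
    ht <- paired_test(rows$baseline, rows$on_treatment)
    data.frame(family = f, n_pairs = ht$n_pairs, p = ht$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Marker-positive cell fraction
#'
#' Fraction of cells positive for every queried marker among cells
#' positive for the reference markers (e.g. the PD-L1-positive fraction
#' among CK+ tumor cells) — the proportion-based alternative to
#' [cell_density()].
#'
#' @param cells Cell table.
#' @param markers Marker columns that must all be TRUE in the numerator.
#' @param among Marker columns defining the denominator population.
#' @return Fraction in `[0, 1]`; NA when no cell matches `among`.
#' @export
cell_fraction <- function(cells, markers, among) {
  miss <- setdiff(c(markers, among), names(cells))
  if (length(miss))
    stop("unknown marker column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  denom <- rep(TRUE, nrow(cells))
  for (m in among) denom <- denom & cells[[m]]
  if (!any(denom)) return(NA_real_)
  num <- denom
  for (m in markers) num <- num & cells[[m]]
  sum(num) / sum(denom)
}
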