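# Post-calling rules for paired baseline/resistance tumor biopsies:
# coverage-dependent mutation rescue, unmatched-germline discard, focal CNA
# filtering with two-run reconciliation, and acquired-alteration calling.
#
# Variant tables are data frames with columns sample_id, timepoint
# ("baseline"/"resistance"), chrom, pos (1-based), ref, alt, vaf, depth,
# alt_reads, germline_flag, gene, consequence. Pileup tables carry chrom,
# pos, ref, alt, coverage, alt_reads. Segment tables carry sample_id, run
# ("primary"/"sensitive"), chrom, start, end (1-based inclusive), category,
# gene.

variant_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Read threshold of the coverage-dependent rescue rule
#'
#' At least one supporting read below coverage 100, two from 100 to below
#' 500, three at coverage 500 and above (the boundary at exactly 500 is
#' undefined in the source rule and resolved conservatively upward).
#'
#' @param coverage Integer vector of pileup coverages.
#' @return Integer vector of minimal alt-read counts.
#' @export
rescue_threshold <- function(coverage) {
  ifelse(coverage < 100, 1L, ifelse(coverage < 500, 2L, 3L))
}

#' Rescue mutations in the paired sample from pileup evidence
#'
#' For every retained call of one timepoint, the mutation is also called in
#' the paired sample when the pileup there shows at least
#' [rescue_threshold()] reads supporting the alternative allele. Rescued
#' calls carry provenance columns and an audit log (attribute `"audit"`)
#' recording every decision.
#'
#' @param calls Variant calls of the source sample (one sample/timepoint).
#' @param pileup Pileup counts at those positions in the paired sample.
#' @param target_sample_id,target_timepoint Identity given to rescued calls.
#' @return Data frame of additional calls for the paired sample (possibly
#'   zero rows) with columns as `calls` plus `rescued` and `rescued_from`;
#'   attribute `"audit"` holds the per-candidate decision table.
#' @export
rescue_mutations <- function(calls, pileup, target_sample_id = NA_character_,
                             target_timepoint = NA_character_) {
  stopifnot(is.data.frame(calls), is.data.frame(pileup))
  if (nrow(calls) == 0L) {
    out <- calls
    out$rescued <- logical(0); out$rescued_from <- character(0)
    attr(out, "audit") <- data.frame()
    return(out)
  }
  idx <- match(variant_key(calls), variant_key(pileup))
  if (anyNA(idx)) {
    missing <- variant_key(calls)[is.na(idx)]
    stop("missing-pileup: no pileup counts for position(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cov <- pileup$coverage[idx]
  alt <- pileup$alt_reads[idx]
  thr <- rescue_threshold(cov)
  hit <- alt >= thr
  audit <- data.frame(chrom = calls$chrom, pos = calls$pos,
                      ref = calls$ref, alt = calls$alt,
                      source_sample = calls$sample_id,
                      coverage = cov, alt_reads = alt,
                      threshold = thr, rescued = hit)
  out <- calls[hit, , drop = FALSE]
  out$rescued_from <- out$sample_id
  out$sample_id <- rep(target_sample_id, nrow(out))
  out$timepoint <- rep(target_timepoint, nrow(out))
  out$depth <- cov[hit]
  out$alt_reads <- alt[hit]
  out$vaf <- ifelse(cov[hit] > 0, alt[hit] / cov[hit], 0)
  out$rescued <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Discard germline-flagged mutations in unmatched patients
#'
#' For patients without a matched normal, any variant flagged germline at
#' either timepoint is removed from both call sets; with a matched normal
#' the sets pass through unchanged.
#'
#' @param baseline,resistance Variant call data frames of one patient.
#' @param has_matched_normal Logical.
#' @return List with filtered `baseline` and `resistance`.
#' @export
discard_unmatched_germline <- function(baseline, resistance,
                                       has_matched_normal) {
  stopifnot(is.data.frame(baseline), is.data.frame(resistance),
            is.logical(has_matched_normal))
  if (has_matched_normal) return(list(baseline = baseline,
                                      resistance = resistance))
  bad <- unique(c(
    variant_key(baseline)[which(baseline$germline_flag)],
    variant_key(resistance)[which(resistance$germline_flag)]))
  list(baseline = baseline[!variant_key(baseline) %in% bad, , drop = FALSE],
       resistance = resistance[!variant_key(resistance) %in% bad, ,
                               drop = FALSE])
}

cna_categories <- c("high_amp", "medium_amp", "low_gain", "neutral",
                    "hemizygous_del", "homozygous_del")

#' Filter gene-level copy-number events
#'
#' Three steps per sample and gene: (1) start from the primary-run segment;
#' for driver genes, substitute the sensitive-run segment when it is
#' shorter than `replace_max_bp` or more than three times shorter than the
#' primary segment; (2) discard segments spanning `focal_max_bp` or more
#' (only focal events are kept); (3) keep high-level amplifications and
#' homozygous deletions, plus medium-level amplifications on oncogenes
#' (and, optionally, hemizygous deletions).
#'
#' @param segments Segment table (see module header); one row per
#'   gene-overlapping segment, columns `sample_id`, `run`, `chrom`,
#'   `start`, `end`, `category`, `gene`.
#' @param driver_genes Character vector of driver symbols (substitution and
#'   reporting scope).
#' @param oncogenes Subset of `driver_genes` treated as oncogenes.
#' @param keep_hemizygous Also keep hemizygous deletions (default FALSE).
#' @param focal_max_bp Focality bound: kept segments span strictly fewer bp.
#' @param replace_max_bp Sensitive-run substitution bound (strictly fewer bp).
#' @return Data frame of surviving events: `sample_id`, `gene`, `category`,
#'   `run_used`, `length_bp`. Invariant to the input row order.
#' @export
filter_cna <- function(segments, driver_genes, oncogenes = character(0),
                       keep_hemizygous = FALSE,
                       focal_max_bp = 10e6, replace_max_bp = 3e6) {
  stopifnot(is.data.frame(segments))
  bad <- setdiff(unique(segments$category), cna_categories)
  if (length(bad))
    stop("unknown-category: ", paste(bad, collapse = ", "), call. = FALSE)
  seg <- segments[order(segments$sample_id, segments$gene, segments$run,
                        segments$chrom, segments$start), , drop = FALSE]
  seg$length_bp <- seg$end - seg$start + 1
  out <- list(); i <- 0L
  for (key in unique(paste(seg$sample_id, seg$gene, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- seg[seg$sample_id == parts[1] & seg$gene == parts[2], ,
                drop = FALSE]
    prim <- rows[rows$run == "primary", , drop = FALSE]
    sens <- rows[rows$run == "sensitive", , drop = FALSE]
    if (nrow(prim) == 0L && nrow(sens) == 0L) next
    use <- if (nrow(prim) > 0L) prim[1, ] else NULL
    if (parts[2] %in% driver_genes && nrow(sens) > 0L) {
      s <- sens[1, ]
      if (is.null(use) ||
          s$length_bp < replace_max_bp ||
          s$length_bp * 3 < use$length_bp) use <- s
    }
    if (is.null(use)) next
    if (use$length_bp >= focal_max_bp) next
    keep_cat <- use$category == "high_amp" ||
      use$category == "homozygous_del" ||
      (use$category == "medium_amp" && parts[2] %in% oncogenes) ||
      (keep_hemizygous && use$category == "hemizygous_del")
    if (!keep_cat) next
    i <- i + 1L
    out[[i]] <- data.frame(sample_id = parts[1], gene = parts[2],
                           category = use$category, run_used = use$run,
                           length_bp = use$length_bp)
  }
  if (i == 0L)
    return(data.frame(sample_id = character(0), gene = character(0),
                      category = character(0), run_used = character(0),
                      length_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a gene alteration table
#'
#' Combines filtered driver mutations and surviving CNA events into the
#' long-format gene x sample event table consumed by [call_acquired()].
#'
#' @param mutations Variant call data frame (post filtering/rescue); only
#'   rows whose `gene` is in `driver_genes` count as alterations.
#' @param cna_events Output of [filter_cna()] (may have zero rows).
#' @param driver_genes Gene universe of the table.
#' @return Data frame `gene`, `sample_id`, `event_type` ("mutation"/"cna")
#'   with attribute `"genes"` recording the universe.
#' @export
gene_alteration_table <- function(mutations, cna_events, driver_genes) {
  mut <- mutations[mutations$gene %in% driver_genes, , drop = FALSE]
  parts <- list()
  if (nrow(mut))
    parts[[length(parts) + 1L]] <-
      data.frame(gene = mut$gene, sample_id = mut$sample_id,
                 event_type = "mutation")
  if (nrow(cna_events))
    parts[[length(parts) + 1L]] <-
      data.frame(gene = cna_events$gene, sample_id = cna_events$sample_id,
                 event_type = "cna")
  out <- if (length(parts)) unique(do.call(rbind, parts))
         else data.frame(gene = character(0), sample_id = character(0),
                         event_type = character(0))
  rownames(out) <- NULL
  attr(out, "genes") <- sort(unique(driver_genes))
  out
}

#' Call acquired alterations
#'
#' A gene is reported as acquired when it is altered in none of the
#' baseline samples and altered in at least `min_samples` resistance
#' samples, the requirement rising to `min_samples_cna_only` when every
#' resistance event for the gene is a copy-number event.
#'
#' @param baseline,resistance Tables from [gene_alteration_table()] over
#'   the paired baseline and resistance samples (same gene universe).
#' @param min_samples Resistance-sample threshold (default 2).
#' @param min_samples_cna_only Threshold when all events are CNAs
#'   (default 3).
#' @return Data frame `gene`, `n_resistance_samples`, `all_cna`,
#'   `acquired`; acquired genes sorted first.
#' @export
call_acquired <- function(baseline, resistance, min_samples = 2,
                          min_samples_cna_only = 3) {
  gb <- attr(baseline, "genes"); gr <- attr(resistance, "genes")
  if (is.null(gb) || is.null(gr) || !identical(gb, gr))
    stop("mismatched-gene-universe: both tables must come from ",
         "gene_alteration_table() over the same driver list", call. = FALSE)
  res <- lapply(gr, function(g) {
    if (g %in% baseline$gene) return(NULL)
    ev <- resistance[resistance$gene == g, , drop = FALSE]
    n <- length(unique(ev$sample_id))
    if (n == 0L) return(NULL)
    all_cna <- all(ev$event_type == "cna")
    need <- if (all_cna) min_samples_cna_only else min_samples
    data.frame(gene = g, n_resistance_samples = n, all_cna = all_cna,
               acquired = n >= need)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(gene = character(0), n_resistance_samples = integer(0),
                      all_cna = logical(0), acquired = logical(0)))
  out <- do.call(rbind, res)
  out <- out[order(-out$acquired, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
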