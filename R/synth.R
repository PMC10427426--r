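# Seeded synthetic-data generators producing every input the pipeline
# consumes, with ground truth, so all stages are verifiable offline. All
# generators are pure functions of (config, seed): one master seed spawns
# per-artifact substreams via derive_seed(), so regenerating one artifact
# never shifts another.

# ---- IHC cohort ----------------------------------------------------------

#' Synthetic IHC cohort configuration
#'
#' Defines the study conditions the image generator emulates: two response
#' groups of whole-slide ROI-cropped HER2 IHC fields, tiled by 64 px
#' region cells, each cell drawn from one of eight tissue classes that
#' differ in DAB (HER2) staining level, DAB staining pattern (diffuse
#' cytoplasmic versus membranous, the two patterns seen in HER2 IHC) and
#' nuclei density. Class 1 is the stroma-like class: near-absent DAB and
#' moderate cell density; its proportion is inflated by `effect_size` in
#' non-responders.
#'
#' @param n_per_group Slides per response group.
#' @param width,height Slide size in px.
#' @param microns_per_pixel Physical scale (um/px).
#' @param class_dab Per-class DAB optical density.
#' @param class_pattern Per-class staining pattern, `"diffuse"` (whole
#'   cell at `class_dab`) or `"membranous"` (DAB confined to an annulus
#'   around each nucleus).
#' @param class_density Per-class mean nuclei count per 64 px cell.
#' @param class_radius Per-class mean nucleus radius (px).
#' @param membrane_width Annulus width (px) of membranous staining.
#' @param membranous_background_od Residual DAB OD outside membranes in
#'   membranous cells.
#' @param mixture_responder Class mixture in responders (simplex).
#' @param excess_class Index (1-based) of the class inflated in
#'   non-responders.
#' @param effect_size Absolute excess proportion of `excess_class` in
#'   non-responders.
#' @param nucleus_radius_sd Within-class s.d. of the nucleus radius (px).
#' @param density_dispersion_sd S.d. of the per-cell nucleus count around
#'   the class mean (packed epithelium is underdispersed relative to a
#'   Poisson process, so counts are drawn as a rounded Gaussian).
#' @param nucleus_h_od Hematoxylin OD inside nuclei.
#' @param tissue_h_od Hematoxylin OD of anuclear tissue background.
#' @param I0 Blank-glass transmitted intensity (8-bit).
#' @param noise_sd Gaussian sensor noise s.d. in transmitted intensity.
#' @param cell_px Region-cell (and patch) side in px.
#' @return A `synth_ihc_config` list.
#' @export
synth_ihc_config <- function(n_per_group = 12, width = 512, height = 512,
                             microns_per_pixel = 0.325,
                             class_dab = c(0.02, 0.02, 0.35, 0.35,
                                           0.90, 0.90, 0.90, 0.90),
                             class_pattern = c("diffuse", "diffuse",
                                               "diffuse", "diffuse",
                                               "diffuse", "diffuse",
                                               "membranous", "membranous"),
                             class_density = c(6, 16, 6, 16, 6, 16, 6, 16),
                             class_radius = rep(3.5, 8),
                             membrane_width = 3,
                             membranous_background_od = 0.03,
                             mixture_responder = NULL,
                             excess_class = 1, effect_size = 0.15,
                             nucleus_radius_sd = 0.6,
                             density_dispersion_sd = 1.0,
                             nucleus_h_od = 1.0, tissue_h_od = 0.06,
                             I0 = 240, noise_sd = 2, cell_px = 64) {
  k <- length(class_dab)
  stopifnot(length(class_density) == k, length(class_radius) == k,
            length(class_pattern) == k, k >= 1,
            all(class_pattern %in% c("diffuse", "membranous")))
  if (is.null(mixture_responder)) mixture_responder <- rep(1 / k, k)
  stopifnot(abs(sum(mixture_responder) - 1) < 1e-9,
            all(mixture_responder >= 0),
            effect_size >= 0,
            mixture_responder[excess_class] + effect_size <= 1)
  mx_nr <- mixture_responder * (1 - mixture_responder[excess_class] -
                                  effect_size) /
    (1 - mixture_responder[excess_class])
  mx_nr[excess_class] <- mixture_responder[excess_class] + effect_size
  structure(list(
    n_per_group = n_per_group, width = width, height = height,
    microns_per_pixel = microns_per_pixel, class_dab = class_dab,
    class_pattern = class_pattern,
    class_density = class_density, class_radius = class_radius,
    membrane_width = membrane_width,
    membranous_background_od = membranous_background_od,
    mixture_responder = mixture_responder,
    mixture_nonresponder = mx_nr, excess_class = excess_class,
    effect_size = effect_size,
    nucleus_radius_sd = nucleus_radius_sd,
    density_dispersion_sd = density_dispersion_sd,
    nucleus_h_od = nucleus_h_od,
    tissue_h_od = tissue_h_od, I0 = I0, noise_sd = noise_sd,
    cell_px = cell_px, n_classes = k), class = "synth_ihc_config")
}

#' Generate one synthetic IHC slide
#'
#' Renders a slide by forward Beer-Lambert stain mixing: hematoxylin from
#' planted nuclei discs over a faint tissue background, DAB from the
#' per-cell class level, plus Gaussian sensor noise, rounded and clipped
#' to 8 bits. `shape = "disc"` places the tissue on blank glass (for
#' tissue-detection tests); `shape = "full"` fills the frame (an
#' ROI-cropped tumor field).
#'
#' @param config A [synth_ihc_config()].
#' @param seed Integer seed (this one artifact's substream).
#' @param slide_id Identifier for the slide.
#' @param mixture Class mixture to draw region cells from.
#' @param shape `"full"` or `"disc"`.
#' @param disc_radius Tissue disc radius in px (shape `"disc"`).
#' @param extra_speck Optionally adds a small textured speck (a list with
#'   `x`, `y`, `radius`, px) outside the main tissue, for the
#'   minimum-area filter tests.
#' @return List with `slide` (a [slide_image()]) and `truth` (class matrix
#'   of region cells with NA off-tissue, nuclei table, full-resolution
#'   logical tissue mask, mixture used).
#' @export
gen_ihc_slide <- function(config = synth_ihc_config(), seed = 1L,
                          slide_id = "S1",
                          mixture = config$mixture_responder,
                          shape = c("full", "disc"), disc_radius = 200,
                          extra_speck = NULL) {
  shape <- match.arg(shape)
  cp <- config$cell_px
  H <- config$height; W <- config$width
  ny <- H %/% cp; nx <- W %/% cp
  with_seed(seed, {
    # tissue support at full resolution
    if (shape == "full") {
      tissue <- matrix(TRUE, H, W)
    } else {
      cyx <- c(H, W) / 2
      tissue <- (outer(seq_len(H) - cyx[1], rep(1, W)))^2 +
        (outer(rep(1, H), seq_len(W) - cyx[2]))^2 <= disc_radius^2
    }
    if (!is.null(extra_speck))
      tissue <- tissue |
        (outer(seq_len(H) - extra_speck$y, rep(1, W)))^2 +
        (outer(rep(1, H), seq_len(W) - extra_speck$x))^2 <=
          extra_speck$radius^2
    # region-cell classes: a cell belongs to tissue when >= half its
    # pixels do
    cell_tissue <- matrix(FALSE, ny, nx)
    classes <- matrix(NA_integer_, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      rows <- (i - 1) * cp + seq_len(cp); cols <- (j - 1) * cp + seq_len(cp)
      cell_tissue[i, j] <- mean(tissue[rows, cols]) >= 0.5
    }
    n_cells <- sum(cell_tissue)
    classes[cell_tissue] <- sample.int(config$n_classes, n_cells,
                                       replace = TRUE, prob = mixture)
    # optical-density maps
    od_h <- matrix(0, H, W); od_d <- matrix(0, H, W)
    od_h[tissue] <- config$tissue_h_od
    nuclei <- list(); nn <- 0L
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      if (!cell_tissue[i, j]) next
      cl <- classes[i, j]
      membranous <- config$class_pattern[cl] == "membranous"
      od_d[(i - 1) * cp + seq_len(cp), (j - 1) * cp + seq_len(cp)] <-
        if (membranous) config$membranous_background_od
        else config$class_dab[cl]
      n_nuc <- max(0L, as.integer(round(
        stats::rnorm(1, config$class_density[cl],
                     config$density_dispersion_sd))))
      if (n_nuc == 0) next
      # jittered-lattice placement: epithelial nuclei are near-regularly
      # packed, not completely spatially random
      side <- ceiling(sqrt(n_nuc))
      slots <- sample.int(side^2, n_nuc)
      sx <- (slots - 1L) %% side; sy <- (slots - 1L) %/% side
      pitch <- cp / side
      cx <- (j - 1) * cp + (sx + stats::runif(n_nuc, 0.15, 0.85)) * pitch
      cy <- (i - 1) * cp + (sy + stats::runif(n_nuc, 0.15, 0.85)) * pitch
      r <- pmax(2, stats::rnorm(n_nuc, config$class_radius[cl],
                                config$nucleus_radius_sd))
      for (q in seq_len(n_nuc)) {
        rr <- r[q] + if (membranous) config$membrane_width else 0
        ys <- max(1, floor(cy[q] - rr)):min(H, ceiling(cy[q] + rr))
        xs <- max(1, floor(cx[q] - rr)):min(W, ceiling(cx[q] + rr))
        d2 <- outer(ys - cy[q], rep(1, length(xs)))^2 +
          outer(rep(1, length(ys)), xs - cx[q])^2
        disc <- d2 <= r[q]^2
        sub <- od_h[ys, xs, drop = FALSE]
        sub[disc] <- pmax(sub[disc], config$nucleus_h_od)
        od_h[ys, xs] <- sub
        if (membranous) {
          ring <- d2 > r[q]^2 & d2 <= rr^2
          subd <- od_d[ys, xs, drop = FALSE]
          subd[ring] <- pmax(subd[ring], config$class_dab[cl])
          od_d[ys, xs] <- subd
        }
        nn <- nn + 1L
        nuclei[[nn]] <- data.frame(x = cx[q] - 1, y = cy[q] - 1,
                                   radius = r[q], class = cl)
      }
    }
    # also stain the speck so it is textured
    basis <- stain_basis(I0 = config$I0)
    px <- stain_mix(od_h, od_d, basis)
    px <- px + stats::rnorm(length(px), 0, config$noise_sd)
    px <- round(pmin(pmax(px, 0), 255))
    slide <- slide_image(px, config$microns_per_pixel, slide_id)
    nuclei <- if (nn > 0L) do.call(rbind, nuclei)
              else data.frame(x = numeric(0), y = numeric(0),
                              radius = numeric(0), class = integer(0))
    list(slide = slide,
         truth = list(classes = classes, cell_tissue = cell_tissue,
                      nuclei = nuclei, tissue = tissue,
                      mixture = mixture, seed = seed))
  })
}

#' Generate a two-group synthetic IHC cohort
#'
#' Responder slides draw region-cell classes from the responder mixture;
#' non-responder slides carry the planted excess of the stroma-like class.
#' Each slide is rendered on its own seed substream.
#'
#' @param config A [synth_ihc_config()].
#' @param seed Master seed.
#' @return List with `slides` (list of [slide_image()]), `response`
#'   (logical vector), and `truth` (per-slide class matrices and nuclei,
#'   plus the config).
#' @export
gen_ihc_cohort <- function(config = synth_ihc_config(), seed = 1L) {
  n <- config$n_per_group
  response <- rep(c(TRUE, FALSE), each = n)
  ids <- sprintf("%s%02d", ifelse(response, "R", "N"),
                 c(seq_len(n), seq_len(n)))
  out <- vector("list", 2L * n)
  for (i in seq_along(ids)) {
    mx <- if (response[i]) config$mixture_responder
          else config$mixture_nonresponder
    out[[i]] <- gen_ihc_slide(config, derive_seed(seed, i), ids[i],
                              mixture = mx, shape = "full")
  }
  list(slides = lapply(out, `[[`, "slide"),
       response = response,
       slide_ids = ids,
       truth = list(per_slide = lapply(out, `[[`, "truth"),
                    config = config, seed = seed))
}

# ---- paired variant tables ----------------------------------------------

#' Synthetic paired-variant cohort configuration
#'
#' Study conditions for the paired-biopsy generator: patients with
#' whole-exome calls at baseline and resistance, shared clonal mutations
#' across the three coverage regimes, planted acquired driver events at
#' resistance, germline contaminants in unmatched patients, and
#' copy-number segments exercising the focality, two-run-replacement and
#' category rules.
#'
#' @param n_patients Number of paired patients.
#' @param n_shared Shared clonal (passenger) mutations per patient.
#' @param coverage_regimes Coverages sampled for shared mutations (one per
#'   regime: below 100, 100-499, 500 and above).
#' @param acquired_mut_genes Driver genes planted as acquired mutations,
#'   with `acquired_mut_samples` resistance samples each.
#' @param acquired_mut_samples Integer vector, same length.
#' @param cna_only_acquired_gene Driver gene with CNA-only events in
#'   exactly 3 resistance samples (acquired under the CNA-only rule).
#' @param cna_only_insufficient_gene Driver gene with CNA-only events in
#'   exactly 2 resistance samples (not acquired).
#' @param baseline_blocked_gene Driver gene mutated in 1 baseline sample
#'   and several resistance samples (never acquired).
#' @param germline_rate Expected germline contaminants per unmatched
#'   patient.
#' @param unmatched_patients Indices of patients without a matched normal.
#' @param rescue_grid Data frame of planted rescue cases (`coverage`,
#'   `alt_reads`), one baseline-only call each with the paired pileup at
#'   those counts; default is the full 5 x 3 boundary grid.
#' @return A `synth_variant_config` list.
#' @export
synth_variant_config <- function(
    n_patients = 11, n_shared = 6,
    coverage_regimes = c(60, 250, 800),
    acquired_mut_genes = c("NF1", "SLX4"),
    acquired_mut_samples = c(2, 3),
    cna_only_acquired_gene = "MYC",
    cna_only_insufficient_gene = "CCND1",
    baseline_blocked_gene = "TP53",
    germline_rate = 2,
    unmatched_patients = c(2, 5, 9),
    rescue_grid = expand.grid(coverage = c(99, 100, 499, 500, 501),
                              alt_reads = 1:3)) {
  stopifnot(length(acquired_mut_samples) == length(acquired_mut_genes),
            all(acquired_mut_samples <= n_patients))
  structure(as.list(environment()), class = "synth_variant_config")
}

new_variant_row <- function(sample_id, timepoint, chrom, pos, ref, alt,
                            vaf, depth, gene, germline = FALSE,
                            consequence = "missense_variant") {
  data.frame(sample_id = sample_id, timepoint = timepoint, chrom = chrom,
             pos = pos, ref = ref, alt = alt, vaf = vaf, depth = depth,
             alt_reads = round(vaf * depth), germline_flag = germline,
             gene = gene, consequence = consequence)
}

#' Generate paired baseline/resistance variant, pileup and segment tables
#'
#' Emits, per patient, Mutect2-style retained calls at both timepoints,
#' mpileup-style counts in the paired sample at every called position,
#' SEG-like copy-number tables from a primary and a sensitive run, and a
#' truth list sufficient to score every downstream rule without rerunning
#' the generator.
#'
#' @param config A [synth_variant_config()].
#' @param seed Master seed.
#' @return List with `calls`, `pileups` (columns `patient_id`,
#'   `target_timepoint`, position, `coverage`, `alt_reads`), `segments`,
#'   `patients` (ids + matched-normal flag) and `truth`.
#' @export
gen_paired_variants <- function(config = synth_variant_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_variant_config"))
  pid <- sprintf("P%02d", seq_len(config$n_patients))
  calls <- list(); pile <- list(); segs <- list()
  pos_counter <- 1000L
  next_pos <- function() {
    pos_counter <<- pos_counter + 977L
    pos_counter
  }
  truth <- list()

  # shared clonal passenger mutations, seen at both timepoints
  shared <- with_seed(derive_seed(seed, 1L), {
    rows <- list(); pl <- list(); n <- 0L
    for (i in seq_along(pid)) {
      for (s in seq_len(config$n_shared)) {
        cov <- sample(config$coverage_regimes, 1L)
        p <- next_pos(); g <- sprintf("PSG%03d", (i - 1) * 50 + s)
        vaf <- stats::runif(1, 0.15, 0.6)
        for (tp in c("baseline", "resistance")) {
          n <- n + 1L
          rows[[n]] <- new_variant_row(paste0(pid[i], "_", substr(tp, 1, 1)),
                                       tp, "chr1", p, "A", "T", vaf, cov, g)
        }
        # pileup in each paired sample mirrors the call
        for (tp in c("baseline", "resistance")) {
          pl[[length(pl) + 1L]] <- data.frame(
            patient_id = pid[i], target_timepoint = tp, chrom = "chr1",
            pos = p, ref = "A", alt = "T", coverage = cov,
            alt_reads = round(vaf * cov))
        }
      }
    }
    list(calls = do.call(rbind, rows), pileups = do.call(rbind, pl))
  })
  calls[[1]] <- shared$calls; pile[[1]] <- shared$pileups

  # rescue boundary grid: baseline-only calls whose resistance pileup
  # carries the planted (coverage, alt_reads)
  grid <- config$rescue_grid
  grid$patient_id <- pid[(seq_len(nrow(grid)) - 1L) %% length(pid) + 1L]
  grid$chrom <- "chr2"; grid$pos <- vapply(seq_len(nrow(grid)),
                                           function(i) next_pos(), integer(1))
  grid$ref <- "G"; grid$alt <- "C"
  grid$gene <- sprintf("RSG%03d", seq_len(nrow(grid)))
  calls[[2]] <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    new_variant_row(paste0(grid$patient_id[i], "_b"), "baseline", "chr2",
                    grid$pos[i], "G", "C", 0.3, 120, grid$gene[i])))
  pile[[2]] <- data.frame(patient_id = grid$patient_id,
                          target_timepoint = "resistance",
                          chrom = "chr2", pos = grid$pos, ref = "G",
                          alt = "C", coverage = grid$coverage,
                          alt_reads = grid$alt_reads)
  truth$rescue_cases <- grid

  # acquired driver mutations at resistance
  acq <- list()
  for (gi in seq_along(config$acquired_mut_genes)) {
    g <- config$acquired_mut_genes[gi]
    n_s <- config$acquired_mut_samples[gi]
    carriers <- pid[seq_len(n_s) + gi]   # deterministic, distinct offsets
    p <- next_pos()
    for (cp in carriers) {
      acq[[length(acq) + 1L]] <-
        new_variant_row(paste0(cp, "_r"), "resistance", "chr3", p, "C", "A",
                        0.25, 200, g)
      pile[[length(pile) + 1L]] <- data.frame(
        patient_id = cp, target_timepoint = "baseline", chrom = "chr3",
        pos = p, ref = "C", alt = "A", coverage = 200, alt_reads = 0L)
    }
  }
  # baseline-blocked gene: altered once at baseline, often at resistance
  p <- next_pos()
  acq[[length(acq) + 1L]] <-
    new_variant_row(paste0(pid[1], "_b"), "baseline", "chr3", p, "T", "G",
                    0.4, 150, config$baseline_blocked_gene)
  pile[[length(pile) + 1L]] <- data.frame(
    patient_id = pid[1], target_timepoint = "resistance", chrom = "chr3",
    pos = p, ref = "T", alt = "G", coverage = 150, alt_reads = 0L)
  for (cp in pid[2:5]) {
    p2 <- next_pos()
    acq[[length(acq) + 1L]] <-
      new_variant_row(paste0(cp, "_r"), "resistance", "chr3", p2, "T", "G",
                      0.3, 150, config$baseline_blocked_gene)
    pile[[length(pile) + 1L]] <- data.frame(
      patient_id = cp, target_timepoint = "baseline", chrom = "chr3",
      pos = p2, ref = "T", alt = "G", coverage = 150, alt_reads = 0L)
  }
  calls[[3]] <- do.call(rbind, acq)

  # germline contaminants in unmatched patients, flagged at one timepoint
  germ <- with_seed(derive_seed(seed, 2L), {
    rows <- list()
    for (i in config$unmatched_patients) {
      n_g <- stats::rpois(1, config$germline_rate)
      for (q in seq_len(n_g)) {
        p <- next_pos()
        flag_tp <- sample(c("baseline", "resistance"), 1L)
        for (tp in c("baseline", "resistance")) {
          rows[[length(rows) + 1L]] <-
            new_variant_row(paste0(pid[i], "_", substr(tp, 1, 1)), tp,
                            "chr4", p, "A", "G", 0.5, 180,
                            sprintf("GLG%03d", p %% 997L),
                            germline = tp == flag_tp)
        }
        for (tp in c("baseline", "resistance"))
          pile[[length(pile) + 1L]] <- data.frame(
            patient_id = pid[i], target_timepoint = tp, chrom = "chr4",
            pos = p, ref = "A", alt = "G", coverage = 180, alt_reads = 90L)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(germ)) calls[[4]] <- germ
  truth$germline_keys <- if (is.null(germ)) character(0) else
    unique(variant_key(germ))

  # copy-number segments
  seg_row <- function(sample_id, run, chrom, start, len, category, gene)
    data.frame(sample_id = sample_id, run = run, chrom = chrom,
               start = start, end = start + len - 1, category = category,
               gene = gene)
  # CNA-only acquired gene: focal high_amp in 3 resistance samples
  for (cp in pid[1:3])
    segs[[length(segs) + 1L]] <- seg_row(paste0(cp, "_r"), "primary",
                                         "chr8", 1e6, 2e6, "high_amp",
                                         config$cna_only_acquired_gene)
  # CNA-only insufficient gene: focal high_amp in 2 resistance samples
  for (cp in pid[4:5])
    segs[[length(segs) + 1L]] <- seg_row(paste0(cp, "_r"), "primary",
                                         "chr11", 1e6, 2e6, "high_amp",
                                         config$cna_only_insufficient_gene)
  # filter constructions (each in a single sample: never acquired)
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[6], "_r"), "primary",
                                       "chr17", 1e6, 12e6, "high_amp",
                                       "ERBB2")
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[6], "_r"), "sensitive",
                                       "chr17", 4e6, 2.5e6, "high_amp",
                                       "ERBB2")
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[7], "_r"), "primary",
                                       "chr10", 1e6, 9.9e6, "homozygous_del",
                                       "PTEN")
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[8], "_r"), "primary",
                                       "chr13", 1e6, 10e6, "homozygous_del",
                                       "RB1")
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[9], "_r"), "primary",
                                       "chr3", 1e6, 2e6, "medium_amp",
                                       "PIK3CA")
  segs[[length(segs) + 1L]] <- seg_row(paste0(pid[10], "_r"), "primary",
                                       "chr16", 1e6, 2e6, "medium_amp",
                                       "CDH1")
  truth$cna_cases <- data.frame(
    case = c("replacement_kept", "focal_kept", "focal_dropped",
             "medium_oncogene_kept", "medium_nononcogene_dropped"),
    sample_id = paste0(pid[6:10], "_r"),
    gene = c("ERBB2", "PTEN", "RB1", "PIK3CA", "CDH1"),
    expected_kept = c(TRUE, TRUE, FALSE, TRUE, FALSE))

  truth$acquired_genes <- sort(c(config$acquired_mut_genes,
                                 config$cna_only_acquired_gene))
  truth$not_acquired_genes <- c(config$cna_only_insufficient_gene,
                                config$baseline_blocked_gene)

  patients <- data.frame(
    patient_id = pid,
    has_matched_normal = !seq_along(pid) %in% config$unmatched_patients)
  calls <- do.call(rbind, calls); rownames(calls) <- NULL
  pileups <- do.call(rbind, pile); rownames(pileups) <- NULL
  segments <- do.call(rbind, segs); rownames(segments) <- NULL
  list(calls = calls, pileups = pileups, segments = segments,
       patients = patients, truth = truth, config = config, seed = seed)
}

# ---- trial outcomes ------------------------------------------------------

#' Synthetic trial-outcome configuration
#'
#' @param cohorts Data frame with columns `cohort`, `n`, `p_response`
#'   (per-cohort confirmed-response probability). Defaults mirror a
#'   three-cohort single-arm trial with assessable sizes 68/72/37.
#' @return A `synth_trial_config` list.
#' @export
synth_trial_config <- function(
    cohorts = data.frame(cohort = c(1, 2, 3), n = c(68, 72, 37),
                         p_response = c(0.706, 0.375, 0.297))) {
  stopifnot(all(cohorts$p_response >= 0 & cohorts$p_response <= 1))
  structure(list(cohorts = cohorts), class = "synth_trial_config")
}

#' Generate synthetic per-patient response records
#'
#' Bernoulli confirmed responses per cohort; RECIST categories and
#' target-lesion changes are drawn consistently with the response
#' (responders CR/PR with shrinkage of at least 30%, non-responders
#' SD/PD/NE).
#'
#' @param config A [synth_trial_config()].
#' @param seed Integer seed.
#' @return Data frame of response records (`patient_id`, `cohort`,
#'   `best_response`, `confirmed`, `best_change_pct`).
#' @export
gen_trial_outcomes <- function(config = synth_trial_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_trial_config"))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(config$cohorts))) {
      co <- config$cohorts[i, ]
      resp <- stats::runif(co$n) < co$p_response
      best <- ifelse(resp,
                     ifelse(stats::runif(co$n) < 0.1, "CR", "PR"),
                     sample(c("SD", "PD", "NE"), co$n, replace = TRUE,
                            prob = c(0.45, 0.45, 0.10)))
      chg <- numeric(co$n)
      chg[best == "CR"] <- -100
      chg[best == "PR"] <- stats::runif(sum(best == "PR"), -100, -30)
      chg[best == "SD"] <- stats::runif(sum(best == "SD"), -29, 19)
      chg[best == "PD"] <- stats::runif(sum(best == "PD"), 20, 120)
      chg[best == "NE"] <- NA_real_
      rows[[i]] <- data.frame(
        patient_id = sprintf("C%d-%03d", co$cohort, seq_len(co$n)),
        cohort = co$cohort, best_response = best, confirmed = resp,
        best_change_pct = round(chg, 1))
    }
    do.call(rbind, rows)
  })
}

# ---- multiplex-IF cell maps ---------------------------------------------

#' Synthetic cell-map cohort configuration
#'
#' Paired pre/on-treatment multiplex-IF fields: spatial Poisson processes
#' per phenotype over a square tissue field, patient-level intensity
#' heterogeneity, and a planted multiplicative on-treatment change of the
#' CK+/PDL1+ (tumor PD-L1) density.
#'
#' @param n_pairs Number of paired patients.
#' @param field_um Square field side in micrometres (1000 um = 1 mm^2).
#' @param intensities Named base intensities (cells per mm^2) per
#'   phenotype.
#' @param pdl1_frac_ck PD-L1-positive fraction among CK+ cells at baseline.
#' @param pdl1_frac_immune PD-L1-positive fraction among immune cells.
#' @param on_treatment_ratio Multiplicative change of the CK+/PDL1+
#'   density on treatment (1 = no effect).
#' @param patient_lognorm_sd Log-normal s.d. of the per-patient intensity
#'   multiplier.
#' @return A `synth_cell_config` list.
#' @export
synth_cell_config <- function(n_pairs = 18, field_um = 1000,
                              intensities = c(CK = 250, CD3 = 150,
                                              CD8 = 80, CD4 = 70,
                                              CD68 = 60, FoxP3 = 20,
                                              PD1 = 40),
                              pdl1_frac_ck = 0.3, pdl1_frac_immune = 0.1,
                              on_treatment_ratio = 0.3,
                              patient_lognorm_sd = 0.3) {
  structure(as.list(environment()), class = "synth_cell_config")
}

#' Generate paired pre/on-treatment cell maps
#'
#' @param config A [synth_cell_config()].
#' @param seed Master seed.
#' @return List with `cells` (one data frame: `sample_id`, `patient_id`,
#'   `timepoint`, `x_um`, `y_um`, logical marker columns), `area_mm2`, and
#'   `truth` (per-patient multipliers and the planted ratio).
#' @export
gen_cell_maps <- function(config = synth_cell_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_cell_config"))
  area <- (config$field_um / 1000)^2
  markers <- c(names(config$intensities), "PDL1")
  gen_field <- function(pat, tp, mult, sub_seed) with_seed(sub_seed, {
    rows <- list()
    for (ph in names(config$intensities)) {
      n <- stats::rpois(1, config$intensities[[ph]] * mult * area)
      if (n == 0) next
      df <- data.frame(x_um = stats::runif(n, 0, config$field_um),
                       y_um = stats::runif(n, 0, config$field_um))
      for (m in markers) df[[m]] <- FALSE
      df[[ph]] <- TRUE
      pdl1_frac <- if (ph == "CK") {
        if (tp == "on_treatment")
          config$pdl1_frac_ck * config$on_treatment_ratio
        else config$pdl1_frac_ck
      } else config$pdl1_frac_immune
      df$PDL1 <- stats::runif(n) < pdl1_frac
      rows[[length(rows) + 1L]] <- df
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else {
             df <- data.frame(x_um = numeric(0), y_um = numeric(0))
             for (m in markers) df[[m]] <- logical(0)
             df
           }
    out$patient_id <- pat
    out$timepoint <- tp
    out$sample_id <- paste0(pat, "_", substr(tp, 1, 1))
    out
  })
  mult <- with_seed(derive_seed(seed, 1L),
                    exp(stats::rnorm(config$n_pairs, 0,
                                     config$patient_lognorm_sd)))
  pats <- sprintf("M%02d", seq_len(config$n_pairs))
  fields <- list()
  for (i in seq_len(config$n_pairs)) {
    fields[[2 * i - 1]] <- gen_field(pats[i], "baseline", mult[i],
                                     derive_seed(seed, 100 + i))
    fields[[2 * i]] <- gen_field(pats[i], "on_treatment", mult[i],
                                 derive_seed(seed, 200 + i))
  }
  cells <- do.call(rbind, fields)
  rownames(cells) <- NULL
  list(cells = cells, area_mm2 = area,
       truth = list(multipliers = stats::setNames(mult, pats),
                    on_treatment_ratio = config$on_treatment_ratio,
                    seed = seed))
}
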