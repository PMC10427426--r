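# Synthetic-data generators: determinism, planted structure, ground truth.

test_that("slide generation is a pure function of (config, seed)", {
  cfg <- synth_ihc_config(width = 256, height = 256)
  g1 <- gen_ihc_slide(cfg, seed = 5)
  g2 <- gen_ihc_slide(cfg, seed = 5)
  expect_identical(g1$slide$pixels, g2$slide$pixels)
  expect_identical(g1$truth$classes, g2$truth$classes)
  g3 <- gen_ihc_slide(cfg, seed = 6)
  expect_false(identical(g1$slide$pixels, g3$slide$pixels))
})

test_that("a single anuclear class with zero noise gives identical patches", {
  cfg <- synth_ihc_config(width = 256, height = 256,
                          class_dab = 0.4, class_pattern = "diffuse",
                          class_density = 0, class_radius = 3,
                          density_dispersion_sd = 0, noise_sd = 0,
                          mixture_responder = 1, excess_class = 1,
                          effect_size = 0)
  g <- gen_ihc_slide(cfg, seed = 2)
  mask <- structure(list(mask = matrix(TRUE, 32, 32), downsample = 8),
                    class = "tissue_mask")
  p <- extract_patches(g$slide, mask)
  x <- compute_descriptors(p)
  expect_equal(nrow(x), 16L)
  spread <- apply(x, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-6)
})

test_that("distinct DAB classes separate far beyond sensor noise", {
  cfg <- synth_ihc_config(width = 256, height = 256,
                          class_dab = c(0.1, 0.8),
                          class_pattern = c("diffuse", "diffuse"),
                          class_density = c(8, 8), class_radius = c(3, 3),
                          mixture_responder = c(0.5, 0.5),
                          excess_class = 1, effect_size = 0)
  g <- gen_ihc_slide(cfg, seed = 9)
  mask <- structure(list(mask = matrix(TRUE, 32, 32), downsample = 8),
                    class = "tissue_mask")
  p <- extract_patches(g$slide, mask)
  x <- compute_descriptors(p)
  cls <- g$truth$classes[cbind(attr(x, "meta")$y0 / 64 + 1,
                               attr(x, "meta")$x0 / 64 + 1)]
  m1 <- mean(x[cls == 1, "dab_mean"]); m2 <- mean(x[cls == 2, "dab_mean"])
  noise_sd <- max(sd(x[cls == 1, "dab_mean"]), sd(x[cls == 2, "dab_mean"]))
  expect_gt(abs(m2 - m1), 5 * noise_sd)
})

test_that("cohort truth records mixtures and responses consistently", {
  cfg <- synth_ihc_config(n_per_group = 2, width = 128, height = 128)
  co <- gen_ihc_cohort(cfg, seed = 3)
  expect_length(co$slides, 4L)
  expect_equal(co$response, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(co$truth$per_slide[[1]]$mixture, cfg$mixture_responder)
  expect_equal(co$truth$per_slide[[3]]$mixture, cfg$mixture_nonresponder)
  expect_equal(sum(cfg$mixture_nonresponder), 1, tolerance = 1e-12)
  expect_equal(cfg$mixture_nonresponder[1] - cfg$mixture_responder[1],
               cfg$effect_size, tolerance = 1e-12)
})

test_that("paired-variant cohorts plant the documented structure", {
  gv <- gen_paired_variants(synth_variant_config(), seed = 11)
  gv2 <- gen_paired_variants(synth_variant_config(), seed = 11)
  expect_identical(gv$calls, gv2$calls)
  expect_identical(gv$segments, gv2$segments)
  # rescue grid covers the full coverage x alt boundary design
  expect_equal(nrow(gv$truth$rescue_cases), 15L)
  expect_setequal(unique(gv$truth$rescue_cases$coverage),
                  c(99, 100, 499, 500, 501))
  # every planted rescue case has its pileup in the resistance direction
  pk <- paste(gv$pileups$chrom, gv$pileups$pos)
  expect_true(all(paste(gv$truth$rescue_cases$chrom,
                        gv$truth$rescue_cases$pos) %in% pk))
  # zero contamination config: germline filter is a no-op
  gv0 <- gen_paired_variants(
    synth_variant_config(unmatched_patients = integer(0)), seed = 11)
  expect_length(gv0$truth$germline_keys, 0L)
  expect_false(any(gv0$calls$germline_flag))
})

test_that("trial outcome generation matches its response probabilities", {
  cfg <- synth_trial_config(data.frame(cohort = 1, n = 20, p_response = 1))
  rec <- gen_trial_outcomes(cfg, seed = 2)
  orr <- confirmed_orr(rec, 1)
  expect_equal(orr$estimate, 1)
  expect_equal(orr$ci$hi, 1)
  expect_true(all(rec$best_response[rec$confirmed] %in% c("CR", "PR")))
  expect_true(all(rec$best_change_pct[rec$confirmed] <= -30))

  # binomial sampling check: mean ORR over replicates near p
  cfg2 <- synth_trial_config(data.frame(cohort = 2, n = 72,
                                        p_response = 0.375))
  est <- vapply(1:400, function(i)
    confirmed_orr(gen_trial_outcomes(cfg2, seed = i), 2)$estimate,
    numeric(1))
  se <- sqrt(0.375 * 0.625 / 72) / sqrt(400)
  expect_lt(abs(mean(est) - 0.375), 3 * se)
  expect_identical(gen_trial_outcomes(cfg2, seed = 7),
                   gen_trial_outcomes(cfg2, seed = 7))
})

test_that("cell-map generation respects intensities and pairing", {
  cfg <- synth_cell_config(n_pairs = 3)
  gm <- gen_cell_maps(cfg, seed = 4)
  expect_identical(gm$cells, gen_cell_maps(cfg, seed = 4)$cells)
  expect_equal(length(unique(gm$cells$patient_id)), 3L)
  expect_setequal(unique(gm$cells$timepoint),
                  c("baseline", "on_treatment"))
  # zero intensity for a phenotype means zero density
  cfg0 <- synth_cell_config(n_pairs = 2,
                            intensities = c(CK = 200, CD3 = 0))
  gm0 <- gen_cell_maps(cfg0, seed = 4)
  expect_equal(cell_density(gm0$cells, "CD3", gm0$area_mm2 * 4), 0)
  # planted multiplicative drop in CK+/PDL1+ density
  cfg_eff <- synth_cell_config(n_pairs = 40, on_treatment_ratio = 0.3)
  gme <- gen_cell_maps(cfg_eff, seed = 6)
  d <- function(tp) cell_density(
    gme$cells[gme$cells$timepoint == tp, ], c("CK", "PDL1"),
    gme$area_mm2 * 40)
  expect_lt(d("on_treatment") / d("baseline"), 0.45)
  expect_gt(d("on_treatment") / d("baseline"), 0.18)
})
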