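# Paired-biopsy post-calling rules.

call_row <- function(pos, gene = "PSG001", sample = "P01_b",
                     tp = "baseline", germ = FALSE) {
  data.frame(sample_id = sample, timepoint = tp, chrom = "chr1", pos = pos,
             ref = "A", alt = "T", vaf = 0.3, depth = 100, alt_reads = 30,
             germline_flag = germ, gene = gene,
             consequence = "missense_variant")
}

pileup_row <- function(pos, coverage, alt_reads) {
  data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T",
             coverage = coverage, alt_reads = alt_reads)
}

test_that("rescue thresholds follow the printed coverage regimes", {
  expect_equal(rescue_threshold(c(1, 99, 100, 499, 500, 501, 2000)),
               c(1L, 1L, 2L, 2L, 3L, 3L, 3L))
  cases <- data.frame(
    coverage = c(99, 100, 600, 600),
    alt = c(1, 1, 2, 3),
    rescued = c(TRUE, FALSE, FALSE, TRUE))
  for (i in seq_len(nrow(cases))) {
    out <- rescue_mutations(call_row(1000 + i),
                            pileup_row(1000 + i, cases$coverage[i],
                                       cases$alt[i]),
                            target_sample_id = "P01_r",
                            target_timepoint = "resistance")
    expect_equal(nrow(out) == 1L, cases$rescued[i])
    audit <- attr(out, "audit")
    expect_equal(audit$rescued, cases$rescued[i])
    expect_equal(audit$coverage, cases$coverage[i])
  }
})

test_that("rescued calls carry provenance and pileup-derived counts", {
  out <- rescue_mutations(call_row(5000), pileup_row(5000, 250, 12),
                          target_sample_id = "P01_r",
                          target_timepoint = "resistance")
  expect_equal(out$sample_id, "P01_r")
  expect_equal(out$timepoint, "resistance")
  expect_true(out$rescued)
  expect_equal(out$rescued_from, "P01_b")
  expect_equal(out$depth, 250)
  expect_equal(out$vaf, 12 / 250)
})

test_that("missing pileup positions are an error naming the site", {
  expect_error(rescue_mutations(call_row(7777), pileup_row(1, 100, 5)),
               "missing-pileup.*7777")
})

test_that("one rescue round per direction is a fixed point", {
  a <- rbind(call_row(1), call_row(2))
  b <- call_row(3, sample = "P01_r", tp = "resistance")
  pile_b <- rbind(pileup_row(1, 80, 2), pileup_row(2, 80, 0))
  pile_a <- pileup_row(3, 400, 5)
  res_b <- rescue_mutations(a, pile_b, "P01_r", "resistance")
  res_a <- rescue_mutations(b, pile_a, "P01_b", "baseline")
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  b2 <- union(key(b), key(res_b)); a2 <- union(key(a), key(res_a))
  # a second round adds nothing new in either order
  a2_calls <- rbind(a, call_row(3, sample = "P01_b"))  # pos 3 now rescued
  again_b <- rescue_mutations(a2_calls,
                              rbind(pile_b, pileup_row(3, 80, 9)),
                              "P01_r", "resistance")
  expect_true(all(key(again_b) %in% b2))
  expect_setequal(b2, c(key(b), "chr1 1 A T"))  # only coverage-80/alt-2 site
  expect_equal(nrow(res_a), 1L)                 # 5 reads at coverage 400
})

test_that("unmatched-germline discard removes flagged sites from both", {
  base <- rbind(call_row(1, germ = TRUE), call_row(2))
  res <- rbind(call_row(1, sample = "P01_r", tp = "resistance"),
               call_row(2, sample = "P01_r", tp = "resistance"))
  out <- discard_unmatched_germline(base, res, has_matched_normal = FALSE)
  expect_equal(out$baseline$pos, 2)
  expect_equal(out$resistance$pos, 2)
  kept <- discard_unmatched_germline(base, res, has_matched_normal = TRUE)
  expect_equal(nrow(kept$baseline), 2L)
  empty <- base[0, ]
  out0 <- discard_unmatched_germline(empty, empty, FALSE)
  expect_equal(nrow(out0$baseline), 0L)
})

seg_row <- function(run, len, category, gene, sample = "S1",
                    start = 1e6) {
  data.frame(sample_id = sample, run = run, chrom = "chr17",
             start = start, end = start + len - 1, category = category,
             gene = gene)
}

test_that("CNA filtering applies replacement, focality and category rules", {
  drivers <- c("ERBB2", "PTEN", "RB1", "PIK3CA", "CDH1")
  oncogenes <- c("ERBB2", "PIK3CA")
  segs <- rbind(
    seg_row("primary", 12e6, "high_amp", "ERBB2"),
    seg_row("sensitive", 2.5e6, "high_amp", "ERBB2"),
    seg_row("primary", 9.9e6, "homozygous_del", "PTEN"),
    seg_row("primary", 10e6, "homozygous_del", "RB1"),
    seg_row("primary", 2e6, "medium_amp", "PIK3CA"),
    seg_row("primary", 2e6, "medium_amp", "CDH1"))
  out <- filter_cna(segs, drivers, oncogenes)
  expect_setequal(out$gene, c("ERBB2", "PTEN", "PIK3CA"))
  erbb2 <- out[out$gene == "ERBB2", ]
  expect_equal(erbb2$run_used, "sensitive")
  expect_equal(erbb2$length_bp, 2.5e6)
  # hemizygous deletions configurable
  hemi <- seg_row("primary", 2e6, "hemizygous_del", "PTEN")
  expect_equal(nrow(filter_cna(hemi, drivers)), 0L)
  expect_equal(nrow(filter_cna(hemi, drivers, keep_hemizygous = TRUE)), 1L)
  expect_error(filter_cna(seg_row("primary", 1e6, "weird", "PTEN"), drivers),
               "unknown-category")
})

test_that("sensitive-run replacement also applies via the 3x rule", {
  segs <- rbind(seg_row("primary", 15e6, "high_amp", "ERBB2"),
                seg_row("sensitive", 4e6, "high_amp", "ERBB2"))
  out <- filter_cna(segs, "ERBB2", "ERBB2")
  # 4 Mb is not < 3 Mb but is under a third of 15 Mb
  expect_equal(out$run_used, "sensitive")
  # non-driver genes never get substituted
  out2 <- filter_cna(rbind(seg_row("primary", 15e6, "high_amp", "OTHER"),
                           seg_row("sensitive", 2e6, "high_amp", "OTHER")),
                     "ERBB2")
  expect_equal(nrow(out2), 0L)  # 15 Mb primary fails focality
})

test_that("CNA filtering is invariant to segment order", {
  drivers <- c("ERBB2", "PTEN", "RB1", "PIK3CA", "CDH1")
  segs <- rbind(
    seg_row("primary", 12e6, "high_amp", "ERBB2"),
    seg_row("sensitive", 2.5e6, "high_amp", "ERBB2"),
    seg_row("primary", 9.9e6, "homozygous_del", "PTEN", sample = "S2"),
    seg_row("primary", 2e6, "medium_amp", "PIK3CA", sample = "S2"))
  out1 <- filter_cna(segs, drivers, "PIK3CA")
  set.seed(2)
  out2 <- filter_cna(segs[sample(nrow(segs)), ], drivers, "PIK3CA")
  expect_equal(out1, out2)
})

test_that("acquired calling needs 2 mutated or 3 CNA-only samples", {
  drivers <- c("NF1", "MYC", "TP53")
  tab <- function(df) gene_alteration_table(df$mut, df$cna, drivers)
  mut0 <- call_row(1)[0, ]
  cna0 <- filter_cna(seg_row("primary", 1e6, "high_amp", "X")[0, ], drivers)
  base <- tab(list(mut = mut0, cna = cna0))
  res_mut2 <- gene_alteration_table(
    rbind(call_row(1, gene = "NF1", sample = "P01_r"),
          call_row(2, gene = "NF1", sample = "P02_r")), cna0, drivers)
  out <- call_acquired(base, res_mut2)
  expect_true(out$acquired[out$gene == "NF1"])

  cna2 <- data.frame(sample_id = c("P01_r", "P02_r"), gene = "MYC",
                     category = "high_amp", run_used = "primary",
                     length_bp = 2e6)
  out2 <- call_acquired(base, gene_alteration_table(mut0, cna2, drivers))
  expect_false(out2$acquired[out2$gene == "MYC"])
  cna3 <- rbind(cna2, data.frame(sample_id = "P03_r", gene = "MYC",
                                 category = "high_amp",
                                 run_used = "primary", length_bp = 2e6))
  out3 <- call_acquired(base, gene_alteration_table(mut0, cna3, drivers))
  expect_true(out3$acquired[out3$gene == "MYC"])

  # one baseline-altered sample blocks acquisition entirely
  base1 <- gene_alteration_table(call_row(9, gene = "TP53"), cna0, drivers)
  res11 <- gene_alteration_table(
    do.call(rbind, lapply(1:11, function(i)
      call_row(9, gene = "TP53", sample = sprintf("P%02d_r", i)))),
    cna0, drivers)
  out4 <- call_acquired(base1, res11)
  expect_false("TP53" %in% out4$gene)

  wrong <- gene_alteration_table(mut0, cna0, c("NF1"))
  expect_error(call_acquired(base, wrong), "mismatched-gene-universe")
})
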