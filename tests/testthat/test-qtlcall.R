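# build a lod_track-shaped data.frame from a vector of per-bin LODs
lod_track_from <- function(lod, res = 100, f_high = 0.9, f_low = 0.1,
                           contig = "c") {
  B <- length(lod)
  bs <- (seq_len(B) - 1) * res + 1
  structure(data.frame(contig = contig, bin_start = bs,
                       bin_end = bs + res - 1, mid = bs + (res - 1) / 2,
                       lod = lod, f_high = f_high, f_low = f_low),
            class = c("lod_track", "data.frame"))
}

test_that("the LOD>=5-over->=20kb rule governs interval calling", {
  # 25 kb at LOD 6 -> called
  tr <- lod_track_from(c(rep(0, 10), rep(6, 250), rep(0, 10)))
  iv <- call_intervals(tr, qtl_call_params())
  expect_equal(nrow(iv), 1)
  expect_equal(iv$run_end - iv$run_start + 1, 25000)
  # 10 kb at LOD 6 -> span below 20 kb, not called
  tr2 <- lod_track_from(c(rep(0, 10), rep(6, 100), rep(0, 10)))
  expect_equal(nrow(call_intervals(tr2, qtl_call_params())), 0)
  # a single sub-threshold bin splits a run into two candidates
  tr3 <- lod_track_from(c(rep(6, 250), 4.9, rep(6, 250)))
  iv3 <- call_intervals(tr3, qtl_call_params())
  expect_equal(nrow(iv3), 2)
  # loosening min_lod or min_span never removes intervals
  iv_loose <- call_intervals(tr2, qtl_call_params(min_lod = 4,
                                                  min_span_bp = 5000))
  expect_gte(nrow(iv_loose), nrow(call_intervals(tr2, qtl_call_params())))
})

test_that("support intervals follow the drop-from-peak rule", {
  # flat track: support is the whole contig
  flat <- lod_track_from(rep(6, 300))
  ivf <- call_intervals(flat, qtl_call_params())
  expect_equal(ivf$support_start, 1)
  expect_equal(ivf$support_end, 300 * 100)

  # triangular peak of 8 crossing 7 at +/- 5 kb -> support = peak +/- 5 kb
  B <- 401
  peak_bin <- 201
  lod <- 8 - abs(seq_len(B) - peak_bin) / 50   # 1 LOD per 50 bins = 5 kb
  tri <- lod_track_from(lod)
  ivt <- call_intervals(tri, qtl_call_params())
  expect_equal(ivt$peak_pos, tri$mid[peak_bin])
  expect_equal(ivt$support_start, tri$bin_start[peak_bin - 50])
  expect_equal(ivt$support_end, tri$bin_end[peak_bin + 50])
  # support contains the peak and the peak is the run maximum
  expect_true(ivt$support_start <= ivt$peak_pos &
                ivt$peak_pos <= ivt$support_end)

  # peak at the contig edge: one-sided support
  edge <- lod_track_from(c(8, 8 - seq_len(600) / 100))
  ive <- call_intervals(edge, qtl_call_params())
  expect_equal(ive$support_start, 1)

  # support may extend beyond the LOD>=5 run (drop from a high peak)
  spike <- lod_track_from(c(rep(4.8, 50), rep(5.5, 250), rep(4.8, 50)))
  ivs <- call_intervals(spike, qtl_call_params())
  expect_lt(ivs$support_start, ivs$run_start)
  expect_gt(ivs$support_end, ivs$run_end)
})

test_that("the opposite-trend requirement is enforced at the peak bin", {
  expect_true(opposite_trend(0.9, 0.1))
  expect_false(opposite_trend(0.9, 0.7))
  expect_false(opposite_trend(0.5, 0.1))    # exactly 1/2: no trend
  same_side <- lod_track_from(rep(6, 300), f_high = 0.9, f_low = 0.7)
  expect_equal(nrow(call_intervals(same_side, qtl_call_params())), 0)
  kept <- call_intervals(same_side,
                         qtl_call_params(require_opposite_trend = FALSE))
  expect_equal(nrow(kept), 1)
  expect_false(kept$opposite_trend)
})

test_that("gene annotation uses >=1 bp overlap with the support interval", {
  genes <- GenomicRanges::GRanges(
    "c", IRanges::IRanges(start = c(5000, 9950, 30000),
                          end = c(6000, 10100, 31000)),
    type = "gene", Name = c("GENE_IN", "GENE_EDGE", "GENE_OUT"))
  iv <- data.frame(condition = "drug", sub_genome = "Sc", contig = "c",
                   run_start = 1, run_end = 25000, peak_pos = 7000,
                   peak_lod = 8, support_start = 4000,
                   support_end = 10000, f_high = 0.9, f_low = 0.1)
  ann <- annotate_genes(iv, genes)
  expect_equal(ann$genes, "GENE_IN;GENE_EDGE")   # sorted by start
  iv2 <- iv; iv2$support_end <- 9949
  expect_equal(annotate_genes(iv2, genes)$genes, "GENE_IN")
  iv3 <- iv; iv3$contig <- "nowhere"
  expect_warning(ann3 <- annotate_genes(iv3, genes), "absent")
  expect_equal(ann3$genes, "")
})
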