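test_that("simulated marker positions are in-bounds, sorted, unique and deterministic", {
  cfg <- sim_config(seed = 5, contigs = data.frame(
    contig = "c1", length = 1e4, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500)
  p1 <- sim_founder_markers(cfg)
  expect_gt(nrow(p1$markers), 5)
  expect_true(all(p1$markers$pos >= 1 & p1$markers$pos <= 1e4))
  expect_true(all(diff(p1$markers$pos) > 0))
  p2 <- sim_founder_markers(cfg)
  expect_identical(p1, p2)

  # degenerate spacing: at most one marker fits
  cfg2 <- sim_config(seed = 5, contigs = data.frame(
    contig = "c1", length = 1e4, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 1e9)
  expect_lte(nrow(sim_founder_markers(cfg2)$markers), 1)
})

test_that("progeny haplotypes are two-state Markov mosaics with the configured switch rate", {
  cfg <- sim_config(seed = 11, n_progeny = 1000, contigs = data.frame(
    contig = "c1", length = 2e5, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500,
    bp_per_cM = 2500, map_expansion = 6)
  panel <- sim_founder_markers(cfg)
  prog <- sim_progeny(panel, cfg)
  org <- prog$origins$c1

  # founder origin at each marker is Bernoulli(1/2) across progeny
  freq <- colMeans(org == 2L)
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 1000)))

  # realized switch rate across all gaps matches Haldane within 3 SE
  d <- diff(prog$marker_pos$c1)
  r_exp <- 0.5 * (1 - exp(-2 * cfg$map_expansion * d /
                            (100 * cfg$bp_per_cM)))
  sw <- org[, -1L] != org[, -ncol(org)]
  n_sw <- sum(sw)
  mu <- 1000 * sum(r_exp)
  se <- sqrt(1000 * sum(r_exp * (1 - r_exp)))
  expect_lt(abs(n_sw - mu), 3 * se)

  # mosaic segments tile the contig exactly
  seg <- haplotype_segments(prog, "F12_001", "c1")
  expect_equal(seg$start[1], 1)
  expect_equal(seg$end[nrow(seg)], 2e5)
  if (nrow(seg) > 1)
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1))
})

test_that("zero-recombination limit yields single-founder haplotypes", {
  cfg <- sim_config(seed = 2, n_progeny = 50, contigs = data.frame(
    contig = "c1", length = 5e4, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500,
    bp_per_cM = 1e12)
  prog <- sim_progeny(sim_founder_markers(cfg), cfg)
  per_row_states <- apply(prog$origins$c1, 1L, function(x)
    length(unique(x)))
  expect_true(all(per_row_states == 1L))
})

test_that("phenotypes reflect planted QTL effects and replicate structure", {
  cfg <- sim_config(seed = 9, n_progeny = 500, contigs = data.frame(
    contig = "c1", length = 1e5, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500,
    replicate_cv = 0, outlier_rate = 0)
  panel <- sim_founder_markers(cfg)
  prog <- sim_progeny(panel, cfg)

  # noise-free: exactly two phenotype values, baseline and baseline+e
  tr <- trait_model(qtls = data.frame(contig = "c1", pos = 5e4,
                                      effect = 7, founder = "B"),
                    baseline = 100, noise_sd = 0)
  ph <- sim_phenotypes(prog, tr, cfg, "drug")
  expect_setequal(round(unique(ph$rep1), 9), c(100, 107))
  expect_true(all(c("rep1", "rep2", "rep3", "rep4") %in% names(ph)))
  expect_equal(nrow(ph), 500)

  # zero effect: phenotype independent of genotype
  tr0 <- trait_model(qtls = data.frame(contig = "c1", pos = 5e4,
                                       effect = 0, founder = "B"),
                     baseline = 100, noise_sd = 5)
  ph0 <- sim_phenotypes(prog, tr0, cfg, "drug")
  g <- origin_at(prog, "c1", 5e4)
  expect_lt(abs(cor(ph0$rep1, g == 2L)), 0.15)

  # unknown contig is an error naming it
  bad <- trait_model(qtls = data.frame(contig = "nope", pos = 1,
                                       effect = 1, founder = "B"))
  expect_error(sim_phenotypes(prog, bad, cfg), "nope")
})

test_that("pool read counts follow the binomial sampling model", {
  cfg <- sim_config(seed = 13, n_progeny = 40, contigs = data.frame(
    contig = "c1", length = 5e5, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500,
    read_depth = 50, seq_error = 0)
  panel <- sim_founder_markers(cfg)
  prog <- sim_progeny(panel, cfg)
  expect_error(sim_pool_reads(character(), prog, panel, cfg), "empty")

  # fixed pool: every member carries the same single founder genome
  cfg_fix <- sim_config(seed = 13, n_progeny = 40, contigs = data.frame(
    contig = "c1", length = 5e5, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")), marker_spacing_bp = 500,
    read_depth = 50, seq_error = 0, bp_per_cM = 1e12)
  prog_fix <- sim_progeny(sim_founder_markers(cfg_fix), cfg_fix)
  all_b <- prog_fix$ids[prog_fix$origins$c1[, 1] == 2L]
  rd <- sim_pool_reads(all_b, prog_fix, sim_founder_markers(cfg_fix),
                       cfg_fix)
  is_b_marker <- sim_founder_markers(cfg_fix)$markers$alt_founder == "B"
  expect_true(all(rd$ao[is_b_marker] == (rd$ro + rd$ao)[is_b_marker]))
  expect_true(all(rd$ao[!is_b_marker] == 0))

  # half-frequency pool: mean observed frequency ~ 0.5 over ~1000 markers
  half <- prog$ids[1:20]
  rd2 <- sim_pool_reads(half, prog, panel, cfg)
  keep <- abs(rd2$true_f_alt - 0.5) < 0.26
  f_obs <- rd2$ao[keep] / (rd2$ro + rd2$ao)[keep]
  expect_lt(abs(mean(f_obs - rd2$true_f_alt[keep])), 0.02)
})

test_that("marker panels and pool counts round-trip through VCF bit-exactly", {
  cfg <- sim_config(seed = 21, n_progeny = 20, contigs = data.frame(
    contig = c("c1", "c2"), length = c(3e4, 2e4),
    sub_genome = c("Sc", "Sk")),
    founders = list(Sc = c("OS104", "OS253"), Sk = c("IF01802", "OS575")))
  panel <- sim_founder_markers(cfg)
  d <- tempfile()
  paths <- write_founder_vcfs(panel, d, depth = 30)
  sites <- load_founder_variants(paths, panel$contig_map)
  got <- derive_markers(sites, panel$contig_map, min_depth = 10)
  cols <- c("contig", "pos", "sub_genome", "ref", "alt", "alt_founder")
  expect_equal(got$panel$markers[, cols], panel$markers[, cols])

  # explicit counts survive the pool VCF round trip
  counts <- data.frame(contig = "c1", pos = 123, ref = "A", alt = "G",
                       ro = 12, ao = 8)
  pv <- file.path(d, "pool.vcf.gz")
  write_pool_vcf(counts, pv, contig_lengths = c(c1 = 3e4))
  back <- read_vcf_table(pv)
  expect_equal(back$ro, 12)
  expect_equal(back$ao, 8)

  # empty panel gives a header-only VCF that reads back as zero records
  p0 <- marker_panel(panel$markers[0, ], panel$contig_map)
  f0 <- write_founder_vcfs(p0, tempfile(), contig_lengths = c(c1 = 100))
  expect_equal(nrow(read_vcf_table(f0[[1]])), 0)
  unlink(d, recursive = TRUE)
})

test_that("the generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 33, n_progeny = 30, contigs = data.frame(
    contig = "c1", length = 2e4, sub_genome = "Sc"),
    founders = list(Sc = c("A", "B")))
  panel <- sim_founder_markers(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_founder_vcfs(panel, d1)
  f2 <- write_founder_vcfs(panel, d2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})
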