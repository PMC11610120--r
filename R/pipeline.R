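# End-to-end orchestration: simulate (optional) -> phenotype QC -> pool
# selection -> markers -> pool counts -> HMM LOD scan -> QTL calling ->
# cross-condition comparison. Plain TSV files are the single interface
# between stages, so any stage can be re-run from the previous stage's
# output.

write_tsv_ <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv_ <- function(path) {
  if (!file.exists(path))
    stop("missing intermediate file for this stage: ", path)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Assemble and validate a pipeline run configuration
#'
#' @param sim A [sim_config()] describing the synthetic cross (or `NULL`
#'   when analysing pre-existing files; the synthetic path is the one
#'   exercised here).
#' @param traits Named list `condition -> trait_model` for the drug
#'   conditions; the control condition is always added with a null trait.
#' @param out_dir Output directory for all intermediates.
#' @param control Control condition label (default `"YPD"`).
#' @param pool_size Strains per tail pool (default 20).
#' @param founder_depth Simulated founder call depth.
#' @param min_depth Depth filter shared by marker derivation and pool
#'   counting (default 10).
#' @param res_bp LOD scan bin width.
#' @param eps Per-read error assumed by the scan.
#' @param scan_bp_per_cM Decorrelation scale (bp per cM) of the scan's
#'   latent chain. This is a smoothing bandwidth, not an estimate of the
#'   physical recombination density: with pools of only 20 haplotypes,
#'   random drift between the two pools is real signal to the tied-state
#'   likelihood ratio, and a chain matched to the physical density
#'   resolves it into spurious 20 kb runs of LOD >= 5. The default (25)
#'   shortens the chain's memory so that the LOD >= 5 across >= 20 kb
#'   decision rule retains its specificity under the null while strong
#'   selection signals still span their full recombination footprint; see
#'   the methods vignette for the calibration. Set to
#'   `sim$bp_per_cM / sim$map_expansion` for a physically matched chain.
#' @param call Interval-calling parameters ([qtl_call_params()]).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim, traits, out_dir,
                       control = "YPD", pool_size = 20,
                       founder_depth = 30, min_depth = 10,
                       res_bp = 100, eps = 0.002,
                       scan_bp_per_cM = 25,
                       call = qtl_call_params()) {
  stopifnot(inherits(sim, "sim_config"), is.list(traits),
            length(traits) > 0, !is.null(names(traits)))
  for (tr in traits) stopifnot(inherits(tr, "trait_model"))
  if (sim$n_progeny < 2 * pool_size)
    stop("n_progeny must be at least twice the pool size")
  if (is.null(scan_bp_per_cM))
    scan_bp_per_cM <- sim$bp_per_cM / sim$map_expansion
  structure(list(sim = sim, traits = traits, out_dir = out_dir,
                 control = control, pool_size = pool_size,
                 founder_depth = founder_depth, min_depth = min_depth,
                 res_bp = res_bp, eps = eps,
                 scan_bp_per_cM = scan_bp_per_cM, call = call),
            class = "run_config")
}

#' Run the full pooled-segregant QTL pipeline on a synthetic cross
#'
#' Executes simulate -> phenotype summary -> two-tailed pool selection ->
#' founder-marker derivation (through VCF files) -> pool allele counting
#' (through VCF files) -> HMM contrast LOD scan -> interval calling with
#' gene annotation -> pleiotropy/shared-QTL comparison, writing every
#' intermediate as TSV (and VCF/GFF3) under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return A run manifest (list): per-stage row counts, called QTL table,
#'   parameters, file checksums. Also written as `manifest.yaml`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- config$sim
  od <- config$out_dir
  lens <- setNames(sim$contigs$length, sim$contigs$contig)

  # --- simulate ---------------------------------------------------------
  panel_true <- sim_founder_markers(sim)
  progeny <- sim_progeny(panel_true, sim)
  founder_vcfs <- write_founder_vcfs(panel_true, file.path(od, "founders"),
                                     depth = config$founder_depth,
                                     contig_lengths = lens)
  write_tsv_(panel_true$contig_map, file.path(od, "contig_map.tsv"))
  gff <- sim_gff(sim)
  gff_path <- file.path(od, "genes.gff3")
  rtracklayer::export(gff, gff_path, format = "gff3")
  conds <- names(config$traits)
  pheno <- do.call(rbind, c(
    list(sim_phenotypes(progeny, trait_model(baseline = 100,
                                             noise_sd = 5),
                        sim, condition = config$control)),
    lapply(conds, function(cd)
      sim_phenotypes(progeny, config$traits[[cd]], sim, condition = cd))))
  write_tsv_(pheno, file.path(od, "phenotypes.tsv"))
  truth <- do.call(rbind, lapply(conds, function(cd) {
    q <- config$traits[[cd]]$qtls
    if (nrow(q)) cbind(condition = cd, q) else NULL
  }))
  if (is.null(truth))
    truth <- data.frame(condition = character(), contig = character(),
                        pos = numeric(), effect = numeric(),
                        founder = character())
  write_tsv_(truth, file.path(od, "truth.tsv"))

  # --- phenotype QC and pools ------------------------------------------
  pheno_in <- read_tsv_(file.path(od, "phenotypes.tsv"))
  summary_tab <- summarize_phenotypes(pheno_in, control = config$control)
  write_tsv_(summary_tab, file.path(od, "pheno_summary.tsv"))
  pools <- lapply(conds, function(cd)
    select_pools(summary_tab, cd, n = config$pool_size))
  names(pools) <- conds
  pools_tab <- do.call(rbind, lapply(conds, function(cd)
    data.frame(condition = cd,
               pool = rep(c("high", "low"), each = config$pool_size),
               strain = c(pools[[cd]]$high, pools[[cd]]$low))))
  write_tsv_(pools_tab, file.path(od, "pools.tsv"))

  # --- markers ----------------------------------------------------------
  cmap <- read_tsv_(file.path(od, "contig_map.tsv"))
  sites <- load_founder_variants(founder_vcfs, cmap)
  mk <- derive_markers(sites, cmap, min_depth = config$min_depth)
  write_tsv_(mk$panel$markers, file.path(od, "markers.tsv"))
  write_tsv_(mk$rejections, file.path(od, "marker_rejections.tsv"))
  panel <- mk$panel

  # --- pool counts, scan, call (per condition x sub-genome) ------------
  params_by_sg <- lapply(unique(cmap$sub_genome), function(sg)
    lod_params(N = config$pool_size, res_bp = config$res_bp,
               bp_per_cM = config$scan_bp_per_cM, eps = config$eps))
  names(params_by_sg) <- unique(cmap$sub_genome)
  all_qtl <- list()
  counts_rows <- 0L
  for (cd in conds) {
    ptab <- read_tsv_(file.path(od, "pools.tsv"))
    for (side in c("high", "low")) {
      members <- ptab$strain[ptab$condition == cd & ptab$pool == side]
      reads <- sim_pool_reads(members, progeny, panel_true, sim,
                              stream = match(cd, conds) * 2L +
                                (side == "low"))
      write_pool_vcf(reads,
                     file.path(od, sprintf("pool_%s_%s.vcf.gz", cd, side)),
                     sample = paste(cd, side, sep = "_"),
                     contig_lengths = lens)
    }
    for (sg in unique(cmap$sub_genome)) {
      sub_panel <- marker_panel(
        panel$markers[panel$markers$sub_genome == sg, , drop = FALSE],
        cmap[cmap$sub_genome == sg, , drop = FALSE])
      if (!nrow(sub_panel$markers)) next
      tracks <- lapply(c("high", "low"), function(side) {
        cnt <- count_alleles(
          file.path(od, sprintf("pool_%s_%s.vcf.gz", cd, side)),
          sub_panel, min_depth = config$min_depth,
          condition = cd, pool = side)
        cnt$track
      })
      names(tracks) <- c("high", "low")
      counts_rows <- counts_rows + nrow(tracks$high) + nrow(tracks$low)
      write_tsv_(rbind(tracks$high, tracks$low),
                 file.path(od, sprintf("counts_%s_%s.tsv", cd, sg)))
      sg_lens <- lens[cmap$contig[cmap$sub_genome == sg]]
      binned <- lapply(tracks, bin_counts, res_bp = config$res_bp,
                       contig_lengths = sg_lens)
      lt <- contrast_lod(binned$high, binned$low, params_by_sg[[sg]])
      lt_out <- lt
      lt_out$lod <- pmin(lt_out$lod, 1000)   # file-friendly sentinel cap
      write_tsv_(lt_out, file.path(od, sprintf("lod_%s_%s.tsv", cd, sg)))
      iv <- call_intervals(lt, config$call, condition = cd,
                           sub_genome = sg)
      if (nrow(iv)) iv <- annotate_genes(iv, gff)
      else iv$genes <- character(0)
      all_qtl[[paste(cd, sg)]] <- iv
    }
  }
  qtl <- do.call(rbind, all_qtl)
  if (is.null(qtl)) {
    qtl <- call_intervals(data.frame(contig = character(),
                                     bin_start = numeric(),
                                     bin_end = numeric(), mid = numeric(),
                                     lod = numeric(), f_high = numeric(),
                                     f_low = numeric()), config$call)
    qtl$genes <- character(0)
  }
  rownames(qtl) <- NULL
  write_tsv_(qtl, file.path(od, "qtl.tsv"))

  # --- comparison -------------------------------------------------------
  pleio <- pleiotropic_groups(qtl)
  write_tsv_(pleio, file.path(od, "pleiotropy.tsv"))
  summary_q <- summarize_counts(qtl)
  write_tsv_(summary_q, file.path(od, "qtl_summary.tsv"))

  files <- list.files(od, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    seed = sim$seed,
    parameters = list(n_progeny = sim$n_progeny,
                      pool_size = config$pool_size,
                      min_depth = config$min_depth,
                      res_bp = config$res_bp, eps = config$eps,
                      scan_bp_per_cM = config$scan_bp_per_cM,
                      min_lod = config$call$min_lod,
                      min_span_bp = config$call$min_span_bp),
    rows = list(phenotypes = nrow(pheno), pools = nrow(pools_tab),
                markers = nrow(panel$markers), counts = counts_rows,
                qtl = nrow(qtl), pleiotropy = nrow(pleio)),
    checksums = as.list(tools::md5sum(files)))
  yaml::write_yaml(manifest, file.path(od, "manifest.yaml"))
  c(manifest, list(qtl = qtl, pleiotropy = pleio, summary = summary_q))
}
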