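# VCF emission for the synthetic cross, built on vcfR. One file per founder
# (haploid calls, GT:DP:RO:AO) and one per sequenced pool (DP:RO:AO), so the
# simulator's output is consumed by exactly the same readers as real data.

vcf_meta <- function(contigs, lengths, format_lines) {
  c("##fileformat=VCFv4.2",
    "##source=hybridqtl",
    sprintf("##contig=<ID=%s,length=%d>", contigs, as.integer(lengths)),
    format_lines)
}

new_vcfR <- function(meta, fix, gt) {
  methods::new("vcfR", meta = meta, fix = fix, gt = gt)
}

fix_matrix <- function(df) {
  cbind(CHROM = as.character(df$contig),
        POS = as.character(as.integer(df$pos)),
        ID = rep(NA_character_, nrow(df)),
        REF = as.character(df$ref),
        ALT = as.character(df$alt),
        QUAL = rep(NA_character_, nrow(df)),
        FILTER = rep(NA_character_, nrow(df)),
        INFO = rep(NA_character_, nrow(df)))
}

#' Write per-founder haploid-call VCFs for a simulated marker panel
#'
#' Each founder's VCF carries a record at every panel site of its
#' sub-genome with a haploid genotype (`GT` 0 or 1), read depth `DP`, and
#' reference/alternate observation counts `RO`/`AO`. Sites are emitted for
#' both founders (reference calls included) so that the depth filter of
#' marker derivation can be evaluated on either side of the contrast.
#'
#' @param panel A [marker_panel()].
#' @param dir Output directory (created if missing).
#' @param depth Simulated founder call depth at every site.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   VCF header; defaults to the last marker position per contig.
#' @return Named character vector of file paths (one per founder),
#'   `<founder>.vcf.gz`.
#' @export
write_founder_vcfs <- function(panel, dir, depth = 30,
                               contig_lengths = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cm <- panel$contig_map
  founders <- unique(c(cm$founder_a, cm$founder_b))
  fmt <- c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="Reference observations">',
           '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate observations">')
  paths <- setNames(file.path(dir, paste0(founders, ".vcf.gz")), founders)
  for (f in founders) {
    ctgs <- cm$contig[cm$founder_a == f | cm$founder_b == f]
    mk <- panel$markers[panel$markers$contig %in% ctgs, , drop = FALSE]
    lens <- if (is.null(contig_lengths))
      vapply(ctgs, function(ct) {
        p <- mk$pos[mk$contig == ct]
        if (length(p)) max(p) else 1
      }, numeric(1))
    else contig_lengths[ctgs]
    is_alt <- mk$alt_founder == f
    gt_str <- ifelse(is_alt,
                     sprintf("1:%d:0:%d", depth, depth),
                     sprintf("0:%d:%d:0", depth, depth))
    gt <- cbind(FORMAT = rep("GT:DP:RO:AO", nrow(mk)), gt_str)
    colnames(gt) <- c("FORMAT", f)
    v <- new_vcfR(vcf_meta(ctgs, lens, fmt), fix_matrix(mk), gt)
    vcfR::write.vcf(v, file = paths[[f]])
  }
  paths
}

#' Write a pooled-sequencing VCF from simulated pool counts
#'
#' @param counts Output of [sim_pool_reads()] (`contig, pos, ref, alt, ro,
#'   ao` columns).
#' @param path Output path; vcfR writes gzipped, so use `.vcf.gz`.
#' @param sample Sample column name.
#' @param contig_lengths Optional named contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(counts, path, sample = "pool",
                           contig_lengths = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("contig", "pos", "ref", "alt", "ro", "ao") %in%
                  names(counts)))
  ctgs <- unique(counts$contig)
  lens <- if (is.null(contig_lengths))
    vapply(ctgs, function(ct) max(counts$pos[counts$contig == ct]),
           numeric(1))
  else contig_lengths[ctgs]
  fmt <- c('##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=RO,Number=1,Type=Integer,Description="Reference observations">',
           '##FORMAT=<ID=AO,Number=A,Type=Integer,Description="Alternate observations">')
  gt_str <- sprintf("%d:%d:%d", counts$ro + counts$ao, counts$ro, counts$ao)
  gt <- cbind(FORMAT = rep("DP:RO:AO", nrow(counts)), gt_str)
  colnames(gt) <- c("FORMAT", sample)
  v <- new_vcfR(vcf_meta(ctgs, lens, fmt), fix_matrix(counts), gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

# Read one VCF into a plain data.frame of (contig, pos, ref, alt,
# gt, dp, ro, ao) for the single sample it carries. Multi-allelic ALT is
# kept verbatim (comma-joined) and flagged downstream.
read_vcf_table <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L)
    return(data.frame(contig = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      gt = character(), dp = numeric(),
                      ro = numeric(), ao = numeric()))
  grab <- function(el) {
    if (!el %in% unlist(strsplit(v@gt[1, "FORMAT"], ":")))
      return(rep(NA_character_, n))
    vcfR::extract.gt(v, element = el)[, 1]
  }
  dp <- suppressWarnings(as.numeric(grab("DP")))
  ro <- suppressWarnings(as.numeric(grab("RO")))
  ao <- suppressWarnings(as.numeric(grab("AO")))
  data.frame(contig = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             gt = unname(grab("GT")), dp = dp, ro = ro, ao = ao,
             row.names = NULL)
}
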