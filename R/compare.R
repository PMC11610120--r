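#' Group QTL intervals shared across drug conditions (pleiotropy)
#'
#' Within each (sub-genome, contig), builds the overlap graph of support
#' intervals coming from different conditions (>= 1 bp coordinate overlap)
#' and reports each connected component touching at least two distinct
#' conditions as one pleiotropic region. The group span is the
#' intersection of the member intervals when non-empty, else their union
#' (flagged).
#'
#' @param intervals Annotated interval table(s): a data.frame as produced
#'   by [annotate_genes()] covering one or more conditions.
#' @return `data.frame(sub_genome, contig, start, end, span_is_union,
#'   conditions, genes)`; `conditions` is a semicolon-joined sorted list,
#'   `genes` the genes common to all member intervals (semicolon-joined).
#' @export
pleiotropic_groups <- function(intervals) {
  empty <- data.frame(sub_genome = character(), contig = character(),
                      start = numeric(), end = numeric(),
                      span_is_union = logical(), conditions = character(),
                      genes = character())
  if (!nrow(intervals)) return(empty)
  groups <- list()
  for (key in unique(paste(intervals$sub_genome, intervals$contig))) {
    sub <- intervals[paste(intervals$sub_genome, intervals$contig) == key, ,
                     drop = FALSE]
    ir <- IRanges::IRanges(sub$support_start, sub$support_end)
    # connected components of the >=1 bp overlap graph on a line are the
    # merged ranges (no gap bridging)
    comp <- IRanges::reduce(ir, min.gapwidth = 0L)
    memb <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, comp))
    for (cc in unique(memb)) {
      mi <- sub[memb == cc, , drop = FALSE]
      conds <- sort(unique(mi$condition))
      if (length(conds) < 2L) next
      istart <- max(mi$support_start); iend <- min(mi$support_end)
      is_union <- istart > iend
      if (is_union) {
        istart <- min(mi$support_start); iend <- max(mi$support_end)
      }
      gsets <- lapply(strsplit(mi$genes, ";", fixed = TRUE),
                      function(g) g[nzchar(g)])
      shared <- Reduce(intersect, gsets)
      groups[[length(groups) + 1L]] <- data.frame(
        sub_genome = mi$sub_genome[1], contig = mi$contig[1],
        start = istart, end = iend, span_is_union = is_union,
        conditions = paste(conds, collapse = ";"),
        genes = paste(shared, collapse = ";"), row.names = NULL)
    }
  }
  if (!length(groups)) return(empty)
  do.call(rbind, groups)
}

#' QTLs shared across sub-genomes through orthologous genes
#'
#' Two intervals from the same condition but different sub-genomes are
#' reported as a shared QTL iff their annotated gene sets contain at least
#' one ortholog pair. Matching is by gene identity, never by coordinates:
#' orthologous regions may occupy different relative positions on the two
#' species' chromosomes.
#'
#' @param intervals_a,intervals_b Annotated interval tables for the two
#'   sub-genomes (same condition set).
#' @param orthologs `data.frame(gene_a, gene_b)`; many-to-many allowed.
#' @return `data.frame(condition, contig_a, start_a, end_a, contig_b,
#'   start_b, end_b, shared_genes)` where `shared_genes` lists the
#'   `gene_a=gene_b` pairs joining the two intervals.
#' @export
shared_across_subgenomes <- function(intervals_a, intervals_b, orthologs) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(orthologs)))
  empty <- data.frame(condition = character(), contig_a = character(),
                      start_a = numeric(), end_a = numeric(),
                      contig_b = character(), start_b = numeric(),
                      end_b = numeric(), shared_genes = character())
  if (!nrow(orthologs)) {
    warning("empty ortholog map; no shared QTLs can be detected")
    return(empty)
  }
  if (!nrow(intervals_a) || !nrow(intervals_b)) return(empty)
  out <- list()
  for (cond in intersect(unique(intervals_a$condition),
                         unique(intervals_b$condition))) {
    ia <- intervals_a[intervals_a$condition == cond, , drop = FALSE]
    ib <- intervals_b[intervals_b$condition == cond, , drop = FALSE]
    for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
      ga <- strsplit(ia$genes[i], ";", fixed = TRUE)[[1]]
      gb <- strsplit(ib$genes[j], ";", fixed = TRUE)[[1]]
      hit <- orthologs$gene_a %in% ga & orthologs$gene_b %in% gb
      if (!any(hit)) next
      pairs <- paste(orthologs$gene_a[hit], orthologs$gene_b[hit],
                     sep = "=")
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, contig_a = ia$contig[i],
        start_a = ia$support_start[i], end_a = ia$support_end[i],
        contig_b = ib$contig[j], start_b = ib$support_start[j],
        end_b = ib$support_end[j],
        shared_genes = paste(sort(unique(pairs)), collapse = ";"),
        row.names = NULL)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Per condition x sub-genome summary of called QTLs
#'
#' Counts intervals and distinct annotated genes and summarises support
#' interval lengths (kb, sample sd; sd blank for a single interval).
#'
#' @param intervals Annotated interval table.
#' @return `data.frame(condition, sub_genome, n_intervals, n_genes,
#'   mean_length_kb, sd_length_kb)`.
#' @export
summarize_counts <- function(intervals) {
  if (!nrow(intervals))
    return(data.frame(condition = character(), sub_genome = character(),
                      n_intervals = integer(), n_genes = integer(),
                      mean_length_kb = numeric(), sd_length_kb = numeric()))
  keys <- unique(intervals[, c("condition", "sub_genome")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- intervals[intervals$condition == keys$condition[i] &
                       intervals$sub_genome == keys$sub_genome[i], ,
                     drop = FALSE]
    len_kb <- (sub$support_end - sub$support_start + 1) / 1000
    genes <- unique(unlist(strsplit(sub$genes, ";", fixed = TRUE)))
    genes <- genes[nzchar(genes)]
    data.frame(condition = keys$condition[i],
               sub_genome = keys$sub_genome[i],
               n_intervals = nrow(sub), n_genes = length(genes),
               mean_length_kb = mean(len_kb),
               sd_length_kb = if (nrow(sub) > 1) sd(len_kb) else NA_real_,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
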