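#' Parameters of the QTL interval-calling rule
#'
#' A QTL is reported where a minimum LOD score of `min_lod` extends across
#' at least `min_span_bp`, and is located by a `support_drop`-LOD support
#' interval around the peak. Intervals whose posterior pool frequencies do
#' not straddle 1/2 in opposite directions at the peak can be filtered out
#' (`require_opposite_trend`), matching the requirement that allele
#' frequencies in the two pools show a diametrically opposite trend.
#'
#' @param min_lod Minimum LOD (default 5).
#' @param min_span_bp Minimum run length in bp (default 20000).
#' @param support_drop LOD drop defining the support interval (default 1).
#' @param require_opposite_trend Drop intervals failing the opposite-trend
#'   check (default TRUE).
#' @return An object of class `qtl_call_params`.
#' @export
qtl_call_params <- function(min_lod = 5, min_span_bp = 20000,
                            support_drop = 1,
                            require_opposite_trend = TRUE) {
  if (min_lod <= 0 || min_span_bp < 1 || support_drop <= 0)
    stop("min_lod and support_drop must be > 0 and min_span_bp >= 1")
  structure(list(min_lod = min_lod, min_span_bp = min_span_bp,
                 support_drop = support_drop,
                 require_opposite_trend = require_opposite_trend),
            class = "qtl_call_params")
}

#' Call QTL intervals from a LOD track
#'
#' Finds, per contig, the maximal runs of consecutive bins with
#' `LOD >= min_lod`; a run qualifies iff its outer bin edges span at least
#' `min_span_bp`. Each qualifying run yields one interval whose peak is
#' its maximum-LOD bin (leftmost on ties) and whose support interval is
#' the widest contiguous range around the peak with
#' `LOD >= peak - support_drop` — which may extend beyond the run itself.
#'
#' @param track A `lod_track` ([contrast_lod()]).
#' @param params A [qtl_call_params()].
#' @param condition,sub_genome Labels copied onto the output rows.
#' @return A `data.frame(condition, sub_genome, contig, run_start, run_end,
#'   peak_pos, peak_lod, support_start, support_end, f_high, f_low,
#'   opposite_trend)`, zero rows when nothing qualifies. When
#'   `require_opposite_trend` is set, same-side intervals are dropped (the
#'   number dropped is in `attr(, "n_dropped_trend")`).
#' @export
call_intervals <- function(track, params = qtl_call_params(),
                           condition = NA_character_,
                           sub_genome = NA_character_) {
  rows <- list()
  n_trend_dropped <- 0L
  for (ctg in unique(track$contig)) {
    sub <- track[track$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$bin_start), , drop = FALSE]
    above <- sub$lod >= params$min_lod
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i0 <- starts[k]; i1 <- ends[k]
      span <- sub$bin_end[i1] - sub$bin_start[i0] + 1
      if (span < params$min_span_bp) next
      seg <- sub$lod[i0:i1]
      pk <- i0 - 1L + which.max(seg)       # leftmost max (which.max ties)
      sup <- support_interval(sub, pk, drop = params$support_drop)
      opp <- (sub$f_high[pk] - 0.5) * (sub$f_low[pk] - 0.5) < 0
      if (params$require_opposite_trend && !opp) {
        n_trend_dropped <- n_trend_dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, sub_genome = sub_genome, contig = ctg,
        run_start = sub$bin_start[i0], run_end = sub$bin_end[i1],
        peak_pos = sub$mid[pk], peak_lod = sub$lod[pk],
        support_start = sup[1], support_end = sup[2],
        f_high = sub$f_high[pk], f_low = sub$f_low[pk],
        opposite_trend = opp, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(condition = character(), sub_genome = character(),
                  contig = character(), run_start = numeric(),
                  run_end = numeric(), peak_pos = numeric(),
                  peak_lod = numeric(), support_start = numeric(),
                  support_end = numeric(), f_high = numeric(),
                  f_low = numeric(), opposite_trend = logical())
  attr(out, "n_dropped_trend") <- n_trend_dropped
  out
}

#' 1-LOD (or drop-LOD) support interval around a peak bin
#'
#' Widest contiguous bin range containing the peak whose LOD stays within
#' `drop` of the peak LOD, bounded by the contig, converted to bp.
#'
#' @param contig_track Sorted single-contig slice of a `lod_track`.
#' @param peak_idx Row index of the peak bin within `contig_track`.
#' @param drop LOD drop (default 1).
#' @return `c(start, end)` in bp (outer bin edges).
#' @export
support_interval <- function(contig_track, peak_idx, drop = 1) {
  thr <- contig_track$lod[peak_idx] - drop
  i0 <- peak_idx
  while (i0 > 1L && contig_track$lod[i0 - 1L] >= thr) i0 <- i0 - 1L
  i1 <- peak_idx
  while (i1 < nrow(contig_track) && contig_track$lod[i1 + 1L] >= thr)
    i1 <- i1 + 1L
  c(contig_track$bin_start[i0], contig_track$bin_end[i1])
}

#' Opposite-trend check at the peak bin
#'
#' TRUE iff the posterior-mean designated-allele frequencies of the two
#' pools lie on opposite sides of 1/2 (a frequency of exactly 1/2 in
#' either pool fails).
#'
#' @param f_high,f_low Posterior-mean frequencies at the peak bin.
#' @return Logical.
#' @export
opposite_trend <- function(f_high, f_low) {
  (f_high - 0.5) * (f_low - 0.5) < 0
}

#' Annotate QTL intervals with overlapping genes
#'
#' A gene is reported for an interval when its 1-based inclusive
#' coordinates overlap the support interval by at least one bp; genes are
#' listed in order of their start coordinate.
#'
#' @param intervals Output of [call_intervals()].
#' @param gff Path to a GFF3 file, or a `GRanges` of gene features.
#' @param feature_type GFF3 `type` to use (default `"gene"`).
#' @return `intervals` with a `genes` column (semicolon-joined ids; gene
#'   `Name` when present, else `ID`). Contigs absent from the annotation
#'   give an empty gene list with a warning.
#' @export
annotate_genes <- function(intervals, gff, feature_type = "gene") {
  genes <- if (is.character(gff)) rtracklayer::import(gff) else gff
  if (!is.null(S4Vectors::mcols(genes)$type))
    genes <- genes[S4Vectors::mcols(genes)$type == feature_type]
  ids <- S4Vectors::mcols(genes)$Name
  if (is.null(ids) || all(is.na(ids))) ids <- S4Vectors::mcols(genes)$ID
  intervals$genes <- vapply(seq_len(nrow(intervals)), function(i) {
    ctg <- intervals$contig[i]
    if (!ctg %in% as.character(GenomeInfoDb::seqnames(genes))) {
      warning("contig ", ctg, " absent from annotation")
      return("")
    }
    q <- GenomicRanges::GRanges(ctg, IRanges::IRanges(
      intervals$support_start[i], intervals$support_end[i]))
    hit <- genes[as.logical(GenomicRanges::countOverlaps(genes, q))]
    hit_ids <- ids[as.logical(GenomicRanges::countOverlaps(genes, q))]
    paste(hit_ids[order(GenomicRanges::start(hit))], collapse = ";")
  }, "")
  intervals
}
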