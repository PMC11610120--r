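#' Founder-diagnostic marker panel
#'
#' A marker panel is the central lookup of the analysis: the set of
#' bi-allelic SNP sites at which the two founder strains of a sub-genome
#' carry different alleles, each site oriented to the founder that carries
#' the alternate allele. Pooled reads at these sites can be assigned a
#' parental origin.
#'
#' @param markers `data.frame` with columns `contig`, `pos` (1-based),
#'   `sub_genome`, `ref`, `alt` (single bases), `alt_founder`.
#' @param contig_map `data.frame` with columns `contig`, `sub_genome`,
#'   `founder_a`, `founder_b`; `founder_a` is the founder matching the
#'   reference assembly of its sub-genome.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(markers, contig_map) {
  stopifnot(is.data.frame(markers), is.data.frame(contig_map),
            all(c("contig", "pos", "sub_genome", "ref", "alt",
                  "alt_founder") %in% names(markers)),
            all(c("contig", "sub_genome", "founder_a", "founder_b") %in%
                  names(contig_map)))
  if (nrow(markers)) {
    if (any(markers$pos < 1)) stop("marker positions must be >= 1")
    if (any(nchar(markers$ref) != 1L) || any(nchar(markers$alt) != 1L))
      stop("markers must be single-nucleotide on both alleles")
    if (any(markers$ref == markers$alt))
      stop("ref and alt alleles must differ")
    absent <- setdiff(unique(markers$contig), contig_map$contig)
    if (length(absent))
      stop("marker contig(s) absent from contig map: ",
           paste(absent, collapse = ", "))
    ord <- order(markers$contig, markers$pos)
    markers <- markers[ord, , drop = FALSE]
    if (anyDuplicated(markers[, c("contig", "pos")]))
      stop("duplicate (contig, pos) in marker set")
    fa <- contig_map$founder_a[match(markers$contig, contig_map$contig)]
    fb <- contig_map$founder_b[match(markers$contig, contig_map$contig)]
    if (any(markers$alt_founder != fa & markers$alt_founder != fb))
      stop("alt_founder must be one of the sub-genome's two founders")
    rownames(markers) <- NULL
  }
  structure(list(markers = markers, contig_map = contig_map),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel:", nrow(x$markers), "markers on",
      length(unique(x$markers$contig)), "contig(s),",
      length(unique(x$contig_map$sub_genome)), "sub-genome(s)\n")
  invisible(x)
}

# contig map implied by a sim_config (founder_a = reference-like founder)
contig_map_from_config <- function(config) {
  sg <- config$contigs$sub_genome
  data.frame(contig = config$contigs$contig,
             sub_genome = sg,
             founder_a = vapply(sg, function(s) config$founders[[s]][1], ""),
             founder_b = vapply(sg, function(s) config$founders[[s]][2], ""),
             row.names = NULL)
}
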