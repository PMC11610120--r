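#' Count the designated founder's allele in a sequenced pool
#'
#' Matches a pool VCF's reference (RO) and alternate (AO) observation
#' counts to the founder-diagnostic marker panel, orienting every site to a
#' single designated founder per sub-genome: at a marker whose alternate
#' allele belongs to the designated founder, `a = AO`; otherwise `a = RO`.
#' Records with depth below `min_depth`, with alleles that do not match the
#' marker's, or absent from the pool VCF are dropped and tallied. Absent
#' records are no-data, not zero counts.
#'
#' @param pool_vcf Path to the pool's VCF.
#' @param panel A [marker_panel()].
#' @param designated Named character vector `sub_genome -> founder` giving
#'   the founder whose allele is counted; defaults per sub-genome to the
#'   founder carrying the most alternate alleles in the panel (the
#'   non-reference strain).
#' @param min_depth Minimum pool depth (RO + AO) at a marker (default 10).
#' @param condition,pool Labels stored on the output rows.
#' @return A list with `track` — a `pool_counts` data.frame
#'   `(contig, pos, sub_genome, condition, pool, ro, ao, a, depth, freq)` —
#'   and `dropped` (`data.frame(reason, n)`).
#' @export
count_alleles <- function(pool_vcf, panel, designated = NULL,
                          min_depth = 10, condition = "condition",
                          pool = "pool") {
  stopifnot(inherits(panel, "marker_panel"))
  mk <- panel$markers
  if (!nrow(mk)) stop("marker panel is empty")
  if (is.null(designated)) designated <- default_designated(panel)
  bad <- setdiff(unique(mk$sub_genome), names(designated))
  if (length(bad))
    stop("no designated founder for sub-genome(s): ",
         paste(bad, collapse = ", "))
  tab <- read_vcf_table(pool_vcf)
  absent <- setdiff(unique(tab$contig), panel$contig_map$contig)
  if (length(absent))
    stop("pool VCF contig(s) not in the panel's contig map: ",
         paste(absent, collapse = ", "))
  key_m <- paste(mk$contig, mk$pos)
  key_p <- paste(tab$contig, tab$pos)
  hit <- match(key_m, key_p)
  dropped <- c(no_record = sum(is.na(hit)), allele_mismatch = 0L,
               low_depth = 0L)
  idx <- which(!is.na(hit))
  p <- tab[hit[idx], , drop = FALSE]
  m <- mk[idx, , drop = FALSE]
  match_ok <- p$ref == m$ref & p$alt == m$alt
  dropped["allele_mismatch"] <- sum(!match_ok)
  p <- p[match_ok, , drop = FALSE]
  m <- m[match_ok, , drop = FALSE]
  ro <- ifelse(is.na(p$ro), 0, p$ro)
  ao <- ifelse(is.na(p$ao), 0, p$ao)
  depth <- ro + ao
  deep <- depth >= min_depth
  dropped["low_depth"] <- sum(!deep)
  m <- m[deep, , drop = FALSE]
  ro <- ro[deep]; ao <- ao[deep]; depth <- depth[deep]
  des <- unname(designated[m$sub_genome])
  wrong <- vapply(unique(m$sub_genome), function(sg) {
    cm <- panel$contig_map
    f <- unique(unlist(cm[cm$sub_genome == sg, c("founder_a", "founder_b")]))
    !designated[[sg]] %in% f
  }, logical(1))
  if (any(wrong))
    stop("designated founder is not a founder of its sub-genome: ",
         paste(unique(m$sub_genome)[wrong], collapse = ", "))
  a <- ifelse(m$alt_founder == des, ao, ro)
  track <- data.frame(contig = m$contig, pos = m$pos,
                      sub_genome = m$sub_genome, condition = condition,
                      pool = pool, ro = ro, ao = ao, a = a, depth = depth,
                      freq = ifelse(depth > 0, a / depth, NA_real_),
                      row.names = NULL)
  class(track) <- c("pool_counts", "data.frame")
  list(track = track,
       dropped = data.frame(reason = names(dropped),
                            n = as.integer(dropped), row.names = NULL))
}

# the alt-richer founder per sub-genome (the non-reference strain)
default_designated <- function(panel) {
  mk <- panel$markers
  vapply(split(mk$alt_founder, mk$sub_genome), function(x)
    names(sort(table(x), decreasing = TRUE))[1], "")
}

#' Observed designated-allele frequency per marker
#'
#' @param track A `pool_counts` data.frame from [count_alleles()].
#' @return `data.frame(contig, pos, freq)` with frequencies in `[0, 1]`.
#' @export
observed_frequency <- function(track) {
  data.frame(contig = track$contig, pos = track$pos, freq = track$freq,
             row.names = NULL)
}
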