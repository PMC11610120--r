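#' Load founder haploid variant calls from VCFs
#'
#' Reads one haploid-call VCF per founder strain and applies the SNP
#' filter: only records whose REF and every ALT allele are single
#' nucleotides are retained. Multi-allelic records (two or more ALT
#' alleles) survive this stage but are flagged for rejection during marker
#' derivation.
#'
#' @param vcf_paths Named character vector, `founder name -> VCF path`.
#' @param contig_map `data.frame(contig, sub_genome, founder_a, founder_b)`.
#' @return `data.frame(contig, pos, ref, alt, founder, gt, depth,
#'   multiallelic)`, one row per founder per retained record.
#' @export
load_founder_variants <- function(vcf_paths, contig_map) {
  stopifnot(length(vcf_paths) > 0, !is.null(names(vcf_paths)))
  out <- lapply(names(vcf_paths), function(f) {
    tab <- read_vcf_table(vcf_paths[[f]])
    if (!nrow(tab)) {
      tab$founder <- character(0)
      return(tab)
    }
    absent <- setdiff(unique(tab$contig), contig_map$contig)
    if (length(absent))
      stop("VCF for founder ", f, " has contig(s) absent from the map: ",
           paste(absent, collapse = ", "))
    tab$founder <- f
    tab
  })
  sites <- do.call(rbind, out)
  alts <- strsplit(sites$alt, ",", fixed = TRUE)
  snp <- nchar(sites$ref) == 1L &
    vapply(alts, function(a) all(nchar(a) == 1L), logical(1))
  sites <- sites[snp, , drop = FALSE]
  sites$multiallelic <- lengths(strsplit(sites$alt, ",", fixed = TRUE)) > 1L
  sites$depth <- ifelse(is.na(sites$dp), 0, sites$dp)
  rownames(sites) <- NULL
  sites[, c("contig", "pos", "ref", "alt", "founder", "gt", "depth",
            "multiallelic")]
}

#' Derive founder-diagnostic markers from founder variant calls
#'
#' A site becomes a marker for a sub-genome iff (i) both founders of the
#' sub-genome are called there with depth >= `min_depth`, (ii) exactly one
#' founder carries a single alternate allele while the other carries the
#' reference, and (iii) the site is bi-allelic across the two founders.
#' A founder with no record at a site is treated as depth 0 and therefore
#' fails the depth filter (conservative). Heterozygous-looking genotypes,
#' impossible under haploid calling, are rejected.
#'
#' @param sites Output of [load_founder_variants()].
#' @param contig_map `data.frame(contig, sub_genome, founder_a, founder_b)`.
#' @param min_depth Minimum founder call depth at the site (default 10).
#' @return A list with `panel` (a [marker_panel()]) and `rejections`
#'   (`data.frame(reason, n)` tallying why candidate sites were dropped).
#' @export
derive_markers <- function(sites, contig_map, min_depth = 10) {
  rej <- c(low_depth_or_missing = 0L, both_reference = 0L,
           both_alternate_same = 0L, triallelic = 0L,
           heterozygous_call = 0L, multiallelic_record = 0L,
           ref_mismatch = 0L)
  rows <- vector("list", nrow(contig_map))
  for (i in seq_len(nrow(contig_map))) {
    ctg <- contig_map$contig[i]
    fa <- contig_map$founder_a[i]
    fb <- contig_map$founder_b[i]
    sub <- sites[sites$contig == ctg & sites$founder %in% c(fa, fb), ,
                 drop = FALSE]
    if (!nrow(sub)) next
    het <- grepl("[/|]", sub$gt) &
      vapply(strsplit(sub$gt, "[/|]"), function(g) length(unique(g)) > 1L,
             logical(1))
    rej["heterozygous_call"] <- rej["heterozygous_call"] + sum(het)
    sub <- sub[!het, , drop = FALSE]
    ma <- sub$multiallelic
    rej["multiallelic_record"] <- rej["multiallelic_record"] + sum(ma)
    sub <- sub[!ma, , drop = FALSE]
    a <- sub[sub$founder == fa, , drop = FALSE]
    b <- sub[sub$founder == fb, , drop = FALSE]
    pos_all <- sort(unique(c(a$pos, b$pos)))
    ia <- match(pos_all, a$pos)
    ib <- match(pos_all, b$pos)
    dep_a <- ifelse(is.na(ia), 0, a$depth[ia])
    dep_b <- ifelse(is.na(ib), 0, b$depth[ib])
    ok_depth <- dep_a >= min_depth & dep_b >= min_depth &
      !is.na(ia) & !is.na(ib)
    rej["low_depth_or_missing"] <-
      rej["low_depth_or_missing"] + sum(!ok_depth)
    keep <- which(ok_depth)
    if (!length(keep)) next
    # haploid GT "0" = reference call, "1" = the (single) alternate allele
    gt_a <- sub("^([01]).*", "\\1", a$gt[ia[keep]])
    gt_b <- sub("^([01]).*", "\\1", b$gt[ib[keep]])
    alt_a <- a$alt[ia[keep]]
    alt_b <- b$alt[ib[keep]]
    ref_a <- a$ref[ia[keep]]
    ref_b <- b$ref[ib[keep]]
    mismatch <- ref_a != ref_b
    rej["ref_mismatch"] <- rej["ref_mismatch"] + sum(mismatch, na.rm = TRUE)
    both_ref <- gt_a == "0" & gt_b == "0"
    rej["both_reference"] <- rej["both_reference"] +
      sum(both_ref & !mismatch)
    both_alt <- gt_a == "1" & gt_b == "1"
    tri <- both_alt & alt_a != alt_b
    rej["triallelic"] <- rej["triallelic"] + sum(tri & !mismatch)
    rej["both_alternate_same"] <- rej["both_alternate_same"] +
      sum(both_alt & !tri & !mismatch)
    is_marker <- !mismatch & ((gt_a == "1" & gt_b == "0") |
                                (gt_a == "0" & gt_b == "1"))
    if (!any(is_marker)) next
    k <- keep[is_marker]
    from_a <- (gt_a == "1")[is_marker]
    rows[[i]] <- data.frame(
      contig = ctg, pos = pos_all[k],
      sub_genome = contig_map$sub_genome[i],
      ref = ifelse(from_a, ref_a[is_marker], ref_b[is_marker]),
      alt = ifelse(from_a, alt_a[is_marker], alt_b[is_marker]),
      alt_founder = ifelse(from_a, fa, fb), row.names = NULL)
  }
  markers <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(markers))
    markers <- data.frame(contig = character(), pos = numeric(),
                          sub_genome = character(), ref = character(),
                          alt = character(), alt_founder = character())
  list(panel = marker_panel(markers, contig_map),
       rejections = data.frame(reason = names(rej), n = as.integer(rej),
                               row.names = NULL))
}
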