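#' Simulate a founder-diagnostic marker panel
#'
#' Draws marker positions independently per contig with exponential
#' inter-marker spacing (mean `marker_spacing_bp`), assigns each site
#' distinct reference/alternate nucleotides, and picks which founder carries
#' the alternate allele. The second founder of each sub-genome plays the
#' non-reference strain and so carries most alternate alleles.
#'
#' @param config A [sim_config()].
#' @param p_alt_b Probability that the alternate allele belongs to the
#'   second (non-reference) founder of the sub-genome.
#' @return A [marker_panel()].
#' @export
sim_founder_markers <- function(config, p_alt_b = 0.9) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  cmap <- contig_map_from_config(config)
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(nrow(config$contigs)), function(i) {
    ctg <- config$contigs$contig[i]
    len <- config$contigs$length[i]
    sg <- config$contigs$sub_genome[i]
    n_guess <- ceiling(len / config$marker_spacing_bp * 1.5) + 20L
    gaps <- pmax(1, round(rexp(n_guess, 1 / config$marker_spacing_bp)))
    pos <- cumsum(gaps)
    pos <- pos[pos <= len]
    if (!length(pos))
      return(data.frame(contig = character(), pos = numeric(),
                        sub_genome = character(), ref = character(),
                        alt = character(), alt_founder = character()))
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    f <- config$founders[[sg]]
    alt_founder <- ifelse(runif(length(pos)) < p_alt_b, f[2], f[1])
    data.frame(contig = ctg, pos = pos, sub_genome = sg, ref = ref,
               alt = alt, alt_founder = alt_founder, row.names = NULL)
  })
  marker_panel(do.call(rbind, out), cmap)
}

#' Simulate F12 recombinant hybrid progeny
#'
#' Each progeny carries one recombinant haplotype per sub-genome, modelled
#' as a two-state Markov mosaic over that sub-genome's two founders.
#' Founder origin at the left end of each contig is Bernoulli(1/2); between
#' adjacent markers separated by `d` bp the origin switches with the Haldane
#' recombination fraction `r = (1 - exp(-2c))/2`, where
#' `c = map_expansion * d / (100 * bp_per_cM)` Morgans. The map-expansion
#' multiplier stands in for the breakpoint accumulation of twelve
#' intercross generations.
#'
#' @param panel A [marker_panel()].
#' @param config The [sim_config()] used to build the panel.
#' @return An object of class `progeny_set`: progeny ids plus, per contig,
#'   an integer matrix (progeny x markers) of founder origins (1 = first
#'   founder, 2 = second founder of the sub-genome).
#' @export
sim_progeny <- function(panel, config) {
  stopifnot(inherits(panel, "marker_panel"), inherits(config, "sim_config"))
  set.seed(config$seed + 23L)
  n <- config$n_progeny
  ids <- sprintf("F12_%03d", seq_len(n))
  contigs <- unique(panel$markers$contig)
  origins <- vector("list", length(contigs))
  names(origins) <- contigs
  marker_pos <- vector("list", length(contigs))
  names(marker_pos) <- contigs
  for (ctg in contigs) {
    pos <- panel$markers$pos[panel$markers$contig == ctg]
    m <- length(pos)
    first <- rbinom(n, 1L, 0.5)
    if (m > 1L) {
      d <- diff(pos)
      c_morgan <- config$map_expansion * d / (100 * config$bp_per_cM)
      r <- 0.5 * (1 - exp(-2 * c_morgan))
      sw <- matrix(runif(n * (m - 1L)) < rep(r, each = n), nrow = n)
      cs <- cbind(0L, t(apply(sw, 1L, cumsum)))
    } else {
      cs <- matrix(0L, nrow = n, ncol = 1L)
    }
    origins[[ctg]] <- ((first + cs) %% 2L) + 1L
    marker_pos[[ctg]] <- pos
  }
  structure(list(ids = ids, origins = origins, marker_pos = marker_pos,
                 contig_map = panel$contig_map,
                 contig_lengths = setNames(config$contigs$length,
                                           config$contigs$contig)),
            class = "progeny_set")
}

#' @export
print.progeny_set <- function(x, ...) {
  cat("progeny_set:", length(x$ids), "progeny,",
      length(x$origins), "contig(s)\n")
  invisible(x)
}

#' Founder origin of every progeny haplotype at a genomic position
#'
#' The mosaic is defined at marker loci; between two markers of different
#' origin the breakpoint is placed at their midpoint.
#'
#' @param progeny A `progeny_set`.
#' @param contig Contig name.
#' @param pos 1-based position.
#' @return Integer vector over progeny: 1 or 2 (founder index within the
#'   sub-genome).
#' @export
origin_at <- function(progeny, contig, pos) {
  mp <- progeny$marker_pos[[contig]]
  if (is.null(mp)) stop("contig not in progeny set: ", contig)
  j <- findInterval(pos, mp)
  if (j == 0L) idx <- 1L
  else if (j == length(mp)) idx <- j
  else idx <- if (pos <= (mp[j] + mp[j + 1L]) / 2) j else j + 1L
  progeny$origins[[contig]][, idx]
}

#' Haplotype mosaic of one progeny as tiling segments
#'
#' @param progeny A `progeny_set`.
#' @param id Progeny id (as in `progeny$ids`).
#' @param contig Contig name.
#' @return `data.frame(start, end, origin)` tiling `[1, contig length]`
#'   without gaps or overlaps; `origin` is the founder strain name.
#' @export
haplotype_segments <- function(progeny, id, contig) {
  i <- match(id, progeny$ids)
  if (is.na(i)) stop("unknown progeny id: ", id)
  org <- progeny$origins[[contig]][i, ]
  mp <- progeny$marker_pos[[contig]]
  len <- progeny$contig_lengths[[contig]]
  chg <- which(diff(org) != 0L)
  bounds <- floor((mp[chg] + mp[chg + 1L]) / 2)
  starts <- c(1, bounds + 1)
  ends <- c(bounds, len)
  cm <- progeny$contig_map
  f <- unlist(cm[match(contig, cm$contig), c("founder_a", "founder_b")])
  data.frame(start = starts, end = ends,
             origin = f[org[c(1L, chg + 1L)]], row.names = NULL)
}

#' Simulate colony-size phenotypes with planted QTLs
#'
#' Per progeny the latent fitness is `baseline` plus the sum of QTL effects
#' whose advantaged founder matches the haplotype origin at the QTL
#' position, plus Gaussian environmental noise. Each of the four technical
#' replicates multiplies the latent value by a log-normal factor
#' (sdlog = `replicate_cv`), with occasional 3--10x outliers, floored at 0.
#'
#' @param progeny A `progeny_set`.
#' @param trait A [trait_model()].
#' @param config The [sim_config()].
#' @param condition Condition label for the output rows.
#' @return `data.frame(strain, condition, rep1..rep4)`.
#' @export
sim_phenotypes <- function(progeny, trait, config, condition = "drug") {
  stopifnot(inherits(progeny, "progeny_set"), inherits(trait, "trait_model"))
  set.seed(config$seed + 37L +
             sum(utf8ToInt(condition)) %% 997L)
  n <- length(progeny$ids)
  true_val <- rep(trait$baseline, n)
  if (nrow(trait$qtls)) {
    for (q in seq_len(nrow(trait$qtls))) {
      ctg <- trait$qtls$contig[q]
      if (!ctg %in% names(progeny$origins))
        stop("QTL contig not present in the simulated panel: ", ctg)
      cm <- progeny$contig_map
      f <- unlist(cm[match(ctg, cm$contig), c("founder_a", "founder_b")])
      fi <- match(trait$qtls$founder[q], f)
      if (is.na(fi))
        stop("advantaged founder ", trait$qtls$founder[q],
             " is not a founder of contig ", ctg)
      org <- origin_at(progeny, ctg, trait$qtls$pos[q])
      true_val <- true_val + trait$qtls$effect[q] * (org == fi)
    }
  }
  true_val <- true_val + rnorm(n, 0, trait$noise_sd)
  reps <- matrix(true_val, nrow = n, ncol = 4L) *
    exp(matrix(rnorm(n * 4L, 0, config$replicate_cv), nrow = n))
  out_mask <- matrix(runif(n * 4L) < config$outlier_rate, nrow = n)
  if (any(out_mask))
    reps[out_mask] <- reps[out_mask] * runif(sum(out_mask), 3, 10)
  reps <- pmax(reps, 0)
  data.frame(strain = progeny$ids, condition = condition,
             rep1 = reps[, 1], rep2 = reps[, 2],
             rep3 = reps[, 3], rep4 = reps[, 4], row.names = NULL)
}

#' Simulate pooled sequencing reads over a marker panel
#'
#' At each marker the true pool frequency of the alternate allele is the
#' fraction of member haplotypes whose origin is the marker's alt-carrying
#' founder. Depth is Poisson(`read_depth`); the alternate-allele count is
#' Binomial with success probability `f (1 - eps) + (1 - f) eps`, i.e. each
#' read mis-reports its parental allele with probability `eps`.
#'
#' @param pool_members Character vector of progeny ids in the pool.
#' @param progeny A `progeny_set`.
#' @param panel The [marker_panel()].
#' @param config The [sim_config()].
#' @param stream Integer sub-stream index so the high and low pools draw
#'   independent reads under one seed.
#' @return `data.frame(contig, pos, ref, alt, ro, ao, true_f_alt)` with one
#'   row per marker.
#' @export
sim_pool_reads <- function(pool_members, progeny, panel, config,
                           stream = 0L) {
  if (!length(pool_members)) stop("pool is empty")
  idx <- match(pool_members, progeny$ids)
  if (anyNA(idx))
    stop("unknown pool member(s): ",
         paste(pool_members[is.na(idx)], collapse = ", "))
  set.seed(config$seed + 53L + as.integer(stream))
  mk <- panel$markers
  cm <- panel$contig_map
  out <- vector("list", length(unique(mk$contig)))
  names(out) <- unique(mk$contig)
  for (ctg in unique(mk$contig)) {
    sub <- mk[mk$contig == ctg, , drop = FALSE]
    org <- progeny$origins[[ctg]][idx, , drop = FALSE]
    f <- unlist(cm[match(ctg, cm$contig), c("founder_a", "founder_b")])
    alt_idx <- match(sub$alt_founder, f)
    f_alt <- colMeans(org == matrix(alt_idx, nrow = nrow(org),
                                    ncol = ncol(org), byrow = TRUE))
    d <- rpois(nrow(sub), config$read_depth)
    p <- f_alt * (1 - config$seq_error) + (1 - f_alt) * config$seq_error
    ao <- rbinom(nrow(sub), d, p)
    out[[ctg]] <- data.frame(contig = ctg, pos = sub$pos, ref = sub$ref,
                             alt = sub$alt, ro = d - ao, ao = ao,
                             true_f_alt = f_alt, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Synthetic gene annotation for a simulated genome
#'
#' Lays non-overlapping gene features across each contig so that called QTL
#' intervals can be annotated. Gene ids are synthetic (`SYNG_<contig>_<n>`).
#'
#' @param config A [sim_config()].
#' @param gene_every Mean start-to-start distance between genes (bp).
#' @param gene_width Gene length (bp).
#' @return A [GenomicRanges::GRanges] of `type = "gene"` features with a
#'   `Name` column, 1-based inclusive coordinates.
#' @export
sim_gff <- function(config, gene_every = 2000, gene_width = 1500) {
  stopifnot(inherits(config, "sim_config"))
  grl <- lapply(seq_len(nrow(config$contigs)), function(i) {
    ctg <- config$contigs$contig[i]
    len <- config$contigs$length[i]
    starts <- seq(1, max(1, len - gene_width), by = gene_every)
    GenomicRanges::GRanges(
      seqnames = ctg,
      ranges = IRanges::IRanges(start = starts,
                                end = pmin(starts + gene_width - 1, len)),
      type = "gene",
      ID = sprintf("SYNG_%s_%04d", ctg, seq_along(starts)),
      Name = sprintf("SYNG_%s_%04d", ctg, seq_along(starts)))
  })
  g <- do.call(c, grl)
  S4Vectors::mcols(g)$source <- "hybridqtl_sim"
  g
}
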