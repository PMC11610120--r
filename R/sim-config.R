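#' Simulation configuration for a synthetic F12 hybrid cross
#'
#' Bundles every knob of the synthetic-data generator: the contig layout of
#' the two sub-genomes, marker density, recombination density, the breakpoint
#' accumulation of twelve intercross generations (as a single map-expansion
#' multiplier), pooled-sequencing depth and error, and colony-size replicate
#' noise.
#'
#' @param seed Integer seed; all generator stages derive documented
#'   sub-streams from it (see Details).
#' @param n_progeny Number of F12 diploid hybrid progeny (default 228, the
#'   size of the screened collection).
#' @param contigs `data.frame` with columns `contig`, `length`,
#'   `sub_genome`. Each sub-genome is the haploid complement contributed by
#'   one parental species; every progeny carries exactly one recombinant
#'   haplotype per sub-genome.
#' @param founders Named list mapping each sub-genome label to its two
#'   founder strain names, e.g. `list(Sc = c("OS104", "OS253"))`. The first
#'   founder plays the role of the reference assembly.
#' @param marker_spacing_bp Mean spacing between founder-diagnostic markers
#'   (exponential inter-marker distances).
#' @param bp_per_cM Physical-to-genetic density of a single meiosis.
#' @param map_expansion Multiplier on recombination density accounting for
#'   the accumulated meioses of an advanced intercross (default 6.0, the
#'   g/2 expectation for g = 12 generations).
#' @param read_depth Mean per-marker pool sequencing depth (Poisson).
#' @param seq_error Probability a pooled read reports the wrong parental
#'   allele.
#' @param replicate_cv Log-scale coefficient of variation of the four
#'   technical colony-size replicates.
#' @param outlier_rate Probability that a replicate is inflated by a
#'   3--10x outlier factor (mimicking plate artefacts).
#'
#' @details Stage sub-streams are derived as fixed offsets from `seed`:
#' markers use `seed + 11L`, progeny `seed + 23L`, phenotypes
#' `seed + 37L` plus a per-condition index, pool reads `seed + 53L` plus a
#' per-pool index. Identical configurations therefore give byte-identical
#' outputs, and later stages can be re-run without re-running earlier ones.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_progeny = 228L,
                       contigs = data.frame(
                         contig = c("Sc_chrI", "Sk_chrI"),
                         length = c(1e6, 1e6),
                         sub_genome = c("Sc", "Sk")
                       ),
                       founders = list(Sc = c("OS104", "OS253"),
                                       Sk = c("IF01802", "OS575")),
                       marker_spacing_bp = 500,
                       bp_per_cM = 2500,
                       map_expansion = 6.0,
                       read_depth = 100,
                       seq_error = 0.002,
                       replicate_cv = 0.1,
                       outlier_rate = 0.01) {
  stopifnot(is.data.frame(contigs),
            all(c("contig", "length", "sub_genome") %in% names(contigs)))
  if (n_progeny < 2L) stop("n_progeny must be at least 2")
  if (any(contigs$length <= 0)) stop("all contig lengths must be > 0")
  if (seq_error < 0 || seq_error >= 0.5)
    stop("seq_error must lie in [0, 0.5)")
  if (map_expansion < 1) stop("map_expansion must be >= 1")
  if (marker_spacing_bp <= 0 || bp_per_cM <= 0 || read_depth <= 0)
    stop("marker_spacing_bp, bp_per_cM and read_depth must be positive")
  missing_sg <- setdiff(unique(contigs$sub_genome), names(founders))
  if (length(missing_sg))
    stop("no founder pair given for sub-genome(s): ",
         paste(missing_sg, collapse = ", "))
  bad <- vapply(founders, function(f) length(f) != 2L || anyDuplicated(f) > 0L,
                logical(1))
  if (any(bad)) stop("each sub-genome needs exactly two distinct founders")
  structure(list(seed = as.integer(seed), n_progeny = as.integer(n_progeny),
                 contigs = contigs, founders = founders,
                 marker_spacing_bp = marker_spacing_bp,
                 bp_per_cM = bp_per_cM, map_expansion = map_expansion,
                 read_depth = read_depth, seq_error = seq_error,
                 replicate_cv = replicate_cv, outlier_rate = outlier_rate),
            class = "sim_config")
}

#' Trait model with planted QTLs
#'
#' Ground truth for recovery experiments: additive QTL effects on colony
#' size. A progeny gains `effect` phenotype units at each QTL where its
#' haplotype origin matches the advantaged founder.
#'
#' @param qtls `data.frame` with columns `contig`, `pos`, `effect`,
#'   `founder` (the advantaged founder label); zero rows give a null trait.
#' @param baseline Mean colony size of a progeny carrying no advantaged
#'   allele.
#' @param noise_sd Environmental (per-progeny) standard deviation.
#' @return An object of class `trait_model`.
#' @export
trait_model <- function(qtls = data.frame(contig = character(),
                                          pos = numeric(),
                                          effect = numeric(),
                                          founder = character()),
                        baseline = 100, noise_sd = 5) {
  stopifnot(is.data.frame(qtls))
  if (nrow(qtls)) {
    stopifnot(all(c("contig", "pos", "effect", "founder") %in% names(qtls)))
    if (any(!is.finite(qtls$effect))) stop("QTL effects must be finite")
  }
  structure(list(qtls = qtls, baseline = baseline, noise_sd = noise_sd),
            class = "trait_model")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_progeny, "progeny;",
      nrow(x$contigs), "contig(s) across",
      length(unique(x$contigs$sub_genome)), "sub-genome(s);",
      "mean marker spacing", x$marker_spacing_bp, "bp;",
      "map expansion", x$map_expansion, "\n")
  invisible(x)
}
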