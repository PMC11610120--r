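#' Parameters of the pooled-allele-frequency hidden Markov model
#'
#' The latent state at a genomic bin is the number `j` in `0..N` of the
#' pool's `N` haploid genomes carrying the designated founder allele. Along
#' the chromosome each haplotype independently forgets its origin with the
#' Haldane recombination fraction and redraws it Bernoulli(1/2) — the null
#' expectation for random segregants — so the chain's stationary (and
#' initial) distribution is Binomial(N, 1/2). Reads sampled from the pool
#' report the designated allele with probability `j/N` flipped by a
#' per-read error `eps`.
#'
#' @param N Haploid pool size (default 20, the two-tailed pool design).
#' @param res_bp Bin width in bp (default 100).
#' @param bp_per_cM Physical-to-genetic density seen by the pooled
#'   haplotypes. For an advanced intercross this is the single-meiosis
#'   density divided by the map expansion.
#' @param eps Per-read error probability (default 0.002); keeps
#'   likelihoods finite in the face of single miscalled reads.
#' @return An object of class `lod_params` (includes the Binomial(N, 1/2)
#'   state prior `prior`).
#' @export
lod_params <- function(N = 20, res_bp = 100, bp_per_cM = 2500,
                       eps = 0.002) {
  if (N < 1) stop("N must be >= 1")
  if (res_bp < 1) stop("res_bp must be >= 1")
  if (eps < 0 || eps >= 0.5) stop("eps must lie in [0, 0.5)")
  if (bp_per_cM <= 0) stop("bp_per_cM must be positive")
  structure(list(N = as.integer(N), res_bp = res_bp,
                 bp_per_cM = bp_per_cM, eps = eps,
                 prior = dbinom(0:N, N, 0.5)),
            class = "lod_params")
}

#' Aggregate per-marker pool counts onto a uniform bin grid
#'
#' Markers are assigned to bins of width `res_bp` by
#' `floor((pos - 1) / res_bp)` (1-based positions, so position `res_bp` is
#' the last base of the first bin). Bins without markers are carried with
#' `(a, depth) = (0, 0)`; aggregation conserves total counts.
#'
#' @param track A `pool_counts` data.frame from [count_alleles()], or any
#'   data.frame with `contig`, `pos`, `a`, `depth`.
#' @param res_bp Bin width (bp).
#' @param contig_lengths Optional named vector; defaults to the last
#'   marker position per contig.
#' @return A `binned_counts` data.frame
#'   `(contig, bin_start, bin_end, mid, a, depth)`.
#' @export
bin_counts <- function(track, res_bp = 100, contig_lengths = NULL) {
  stopifnot(all(c("contig", "pos", "a", "depth") %in% names(track)))
  out <- lapply(unique(track$contig), function(ctg) {
    sub <- track[track$contig == ctg, , drop = FALSE]
    len <- if (is.null(contig_lengths)) max(sub$pos)
    else contig_lengths[[ctg]]
    nb <- max(1L, ceiling(len / res_bp))
    bin <- floor((sub$pos - 1) / res_bp)
    a <- numeric(nb); d <- numeric(nb)
    agg_a <- tapply(sub$a, bin, sum)
    agg_d <- tapply(sub$depth, bin, sum)
    ix <- as.integer(names(agg_a)) + 1L
    a[ix] <- agg_a; d[ix] <- agg_d
    bs <- (seq_len(nb) - 1L) * res_bp + 1
    be <- seq_len(nb) * res_bp
    data.frame(contig = ctg, bin_start = bs, bin_end = be,
               mid = (bs + be) / 2, a = a, depth = d, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "res_bp") <- res_bp
  class(res) <- c("binned_counts", "data.frame")
  res
}

#' Transition matrix of the pool-count chain over a physical distance
#'
#' Over `d_bp` each of the `N` pooled haplotypes independently switches
#' founder origin to a fresh Bernoulli(1/2) draw with the Haldane
#' probability `r = (1 - exp(-2 d / (100 bp_per_cM))) / 2`; a carrier
#' therefore remains a carrier with probability `1 - r/2`. From state `j`
#' the next count is `Binomial(j, 1 - r/2) + Binomial(N - j, r/2)`.
#'
#' @param d_bp Physical distance (bp), `>= 0`.
#' @param params A [lod_params()].
#' @return `(N+1) x (N+1)` row-stochastic matrix.
#' @export
transition_matrix <- function(d_bp, params) {
  if (d_bp < 0) stop("distance must be non-negative")
  N <- params$N
  r <- 0.5 * (1 - exp(-2 * d_bp / (100 * params$bp_per_cM)))
  T <- matrix(0, N + 1L, N + 1L)
  for (j in 0:N) {
    stay <- dbinom(0:j, j, 1 - r / 2)
    gain <- dbinom(0:(N - j), N - j, r / 2)
    T[j + 1L, ] <- convolve_pmf(stay, gain)
  }
  T
}

# exact convolution of two small pmfs (outer product diagonal sums)
convolve_pmf <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1L)
    out[idx] <- out[idx] + p[i] * q
  }
  out
}

#' Binomial read-sampling emission likelihood
#'
#' With `j` of `N` pooled haplotypes carrying the designated allele, a read
#' reports it with probability `q = (j/N)(1 - eps) + (1 - j/N) eps`; the
#' bin's likelihood is the Binomial pmf of `a` designated reads out of
#' `depth`. An empty bin `(0, 0)` has likelihood 1.
#'
#' @param a Designated-allele count in the bin.
#' @param depth Total reads in the bin.
#' @param j Latent state, `0..N`.
#' @param params A [lod_params()].
#' @return The emission likelihood.
#' @export
emission <- function(a, depth, j, params) {
  if (any(a > depth)) stop("a cannot exceed depth")
  q <- (j / params$N) * (1 - params$eps) +
    (1 - j / params$N) * params$eps
  dbinom(a, depth, q)
}

# B x (N+1) emission matrix for one contig
emission_matrix <- function(a, depth, params) {
  if (any(a > depth)) stop("a cannot exceed depth")
  q <- (0:params$N / params$N) * (1 - params$eps) +
    (1 - 0:params$N / params$N) * params$eps
  vapply(q, function(p) dbinom(a, depth, p), numeric(length(a)))
}

#' Forward-backward smoothing of binned pool counts
#'
#' Scaled forward-backward over each contig's bin chain, starting from the
#' Binomial(N, 1/2) prior. Returns the total data log10-likelihood and,
#' per contig, the smoothed state posteriors `gamma` (rows sum to 1; the
#' unnormalised marginals of the model are `gamma * L`) and the
#' posterior-mean designated-allele frequency per bin.
#'
#' @param binned A `binned_counts` data.frame ([bin_counts()]).
#' @param params A [lod_params()]; `params$res_bp` must match the grid.
#' @return A list: `log10_lik` (total over contigs), `contigs` (per contig:
#'   `log10_lik`, `gamma`, `fhat`), `flagged` (TRUE when some bin had zero
#'   likelihood under the model, giving `-Inf` log-likelihood).
#' @export
forward_backward <- function(binned, params) {
  stopifnot(inherits(params, "lod_params"), nrow(binned) >= 1)
  Tm <- transition_matrix(params$res_bp, params)
  pr <- params$prior
  flagged <- FALSE
  res <- lapply(split(binned, binned$contig), function(sub) {
    sub <- sub[order(sub$bin_start), , drop = FALSE]
    B <- nrow(sub)
    E <- emission_matrix(sub$a, sub$depth, params)
    if (B == 1L) E <- matrix(E, nrow = 1L)
    alpha <- matrix(0, B, params$N + 1L)
    cs <- numeric(B)
    a <- pr * E[1L, ]
    cs[1] <- sum(a)
    if (cs[1] > 0) alpha[1L, ] <- a / cs[1]
    for (x in seq_len(B - 1L) + 1L) {
      a <- (alpha[x - 1L, ] %*% Tm) * E[x, ]
      cs[x] <- sum(a)
      if (cs[x] == 0) break
      alpha[x, ] <- a / cs[x]
    }
    if (any(cs == 0)) {
      flagged <<- TRUE
      return(list(log10_lik = -Inf,
                  gamma = matrix(NA_real_, B, params$N + 1L),
                  fhat = rep(NA_real_, B)))
    }
    beta <- matrix(0, B, params$N + 1L)
    beta[B, ] <- 1
    for (x in rev(seq_len(B - 1L)))
      beta[x, ] <- (Tm %*% (beta[x + 1L, ] * E[x + 1L, ])) / cs[x + 1L]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    list(log10_lik = sum(log10(cs)), gamma = gamma,
         fhat = as.numeric(gamma %*% (0:params$N)) / params$N)
  })
  list(log10_lik = sum(vapply(res, `[[`, numeric(1), "log10_lik")),
       contigs = res, flagged = flagged)
}

#' Contrast LOD track between the high- and low-fitness pools
#'
#' For each bin `x` the statistic compares two generative models of the
#' pair of pools: independent chains (likelihood `L_high * L_low`) versus a
#' tied model in which one latent state is drawn from the Binomial(N, 1/2)
#' prior at `x`, shared by both pools, with chain dynamics otherwise
#' independent. Because the chain is reversible with respect to its prior,
#' the tied likelihood reduces to
#' `L_high * L_low * sum_j gamma_high(j) gamma_low(j) / prior(j)`, so
#' `LOD(x) = -log10 sum_j gamma_high,x(j) gamma_low,x(j) / prior(j)`.
#' A bin where the tied model is impossible (`eps = 0` with contradictory
#' fixed pools) gets a `+Inf` sentinel.
#'
#' @param high,low `binned_counts` on an identical grid.
#' @param params A [lod_params()].
#' @return A `lod_track` data.frame
#'   `(contig, bin_start, bin_end, mid, lod, f_high, f_low)` with the two
#'   pools' per-contig log10-likelihoods in `attr(, "log10_lik")`.
#' @export
contrast_lod <- function(high, low, params) {
  if (nrow(high) != nrow(low) ||
      !all(high$contig == low$contig & high$bin_start == low$bin_start))
    stop("high and low pools must share an identical bin grid")
  fb_h <- forward_backward(high, params)
  fb_l <- forward_backward(low, params)
  inv_pr <- 1 / params$prior
  out <- lapply(names(fb_h$contigs), function(ctg) {
    gh <- fb_h$contigs[[ctg]]$gamma
    gl <- fb_l$contigs[[ctg]]$gamma
    s <- as.numeric((gh * gl) %*% inv_pr)
    lod <- ifelse(s == 0, Inf, -log10(s))
    sub <- high[high$contig == ctg, , drop = FALSE]
    data.frame(contig = ctg, bin_start = sub$bin_start,
               bin_end = sub$bin_end, mid = sub$mid, lod = lod,
               f_high = fb_h$contigs[[ctg]]$fhat,
               f_low = fb_l$contigs[[ctg]]$fhat, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "log10_lik") <- c(high = fb_h$log10_lik, low = fb_l$log10_lik)
  attr(res, "params") <- params
  class(res) <- c("lod_track", "data.frame")
  res
}
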