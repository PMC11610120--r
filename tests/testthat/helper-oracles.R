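# Independent oracles and small fixtures, built in code.

# binned_counts for a single contig from raw (a, depth) vectors
make_binned <- function(a, d, res_bp = 100, contig = "ctg") {
  B <- length(a)
  bs <- (seq_len(B) - 1L) * res_bp + 1
  structure(data.frame(contig = contig, bin_start = bs,
                       bin_end = bs + res_bp - 1,
                       mid = bs + (res_bp - 1) / 2, a = a, depth = d),
            class = c("binned_counts", "data.frame"))
}

# Exhaustive path enumeration of the chain likelihood and the per-bin
# unnormalised state marginals u_x(j); independent of forward_backward.
enum_chain <- function(a, d, params) {
  N <- params$N
  B <- length(a)
  Tm <- transition_matrix(params$res_bp, params)
  E <- sapply(0:N, function(j) emission(a, d, j, params))
  if (B == 1L) E <- matrix(E, nrow = 1L)
  paths <- as.matrix(expand.grid(rep(list(0:N), B)))
  w <- apply(paths, 1L, function(pp) {
    pr <- params$prior[pp[1] + 1L]
    if (B > 1L) for (x in 2:B) pr <- pr * Tm[pp[x - 1] + 1L, pp[x] + 1L]
    for (x in 1:B) pr <- pr * E[x, pp[x] + 1L]
    pr
  })
  u <- sapply(0:N, function(j)
    sapply(seq_len(B), function(x) sum(w[paths[, x] == j])))
  list(L = sum(w), u = matrix(u, nrow = B))
}

# Tied likelihood at bin x by enumeration over PAIRS of state paths with
# the equality constraint at x (one shared state drawn from the prior).
enum_tied <- function(aH, dH, aL, dL, x, params) {
  eH <- enum_chain(aH, dH, params)
  eL <- enum_chain(aL, dL, params)
  sum(eH$u[x, ] * eL$u[x, ] / params$prior)
}

# log-space forward pass (log-sum-exp), an independent check of the
# scaled-arithmetic implementation
logspace_loglik <- function(binned, params) {
  lTm <- log(transition_matrix(params$res_bp, params))
  q <- (0:params$N / params$N) * (1 - params$eps) +
    (1 - 0:params$N / params$N) * params$eps
  lse <- function(v) { m <- max(v); m + log(sum(exp(v - m))) }
  total <- 0
  for (ctg in unique(binned$contig)) {
    sub <- binned[binned$contig == ctg, , drop = FALSE]
    la <- log(params$prior) +
      dbinom(sub$a[1], sub$depth[1], q, log = TRUE)
    for (x in seq_len(nrow(sub) - 1L) + 1L) {
      la <- apply(lTm, 2L, function(col) lse(la + col)) +
        dbinom(sub$a[x], sub$depth[x], q, log = TRUE)
    }
    total <- total + lse(la)
  }
  total / log(10)
}

# default single-contig study design used by the end-to-end tests
study_config <- function(seed, length_bp = 1e6, n_progeny = 228,
                         depth = 100) {
  sim_config(seed = seed, n_progeny = n_progeny,
             contigs = data.frame(contig = "Sc_chrI", length = length_bp,
                                  sub_genome = "Sc"),
             founders = list(Sc = c("OS104", "OS253")),
             marker_spacing_bp = 500, read_depth = depth)
}

# one full pipeline run with a single planted QTL (or none); returns the
# called QTL table
study_run <- function(seed, effect, qtl_pos = 5e5, pool_size = 20,
                      ...) {
  cfg <- study_config(seed, ...)
  tr <- if (effect > 0)
    trait_model(qtls = data.frame(contig = "Sc_chrI", pos = qtl_pos,
                                  effect = effect, founder = "OS253"),
                baseline = 100, noise_sd = 5)
  else trait_model(baseline = 100, noise_sd = 5)
  out <- tempfile("hqtl_run")
  rc <- run_config(cfg, list(drug = tr), out_dir = out,
                   pool_size = pool_size)
  m <- run_all(rc)
  unlink(out, recursive = TRUE)
  m$qtl
}
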