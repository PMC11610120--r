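test_that("binning assigns markers by the 1-based boundary convention and conserves counts", {
  tr <- data.frame(contig = "c", pos = c(50, 90, 100, 101),
                   a = c(3, 2, 5, 7), depth = c(10, 4, 9, 11))
  b <- bin_counts(tr, res_bp = 100)
  expect_equal(b$a[1], 3 + 2 + 5)      # position 100 is in the first bin
  expect_equal(b$a[2], 7)
  expect_equal(sum(b$depth), sum(tr$depth))
  expect_equal(sum(b$a), sum(tr$a))
  # empty bins are carried
  b2 <- bin_counts(data.frame(contig = "c", pos = 950, a = 1, depth = 2),
                   res_bp = 100)
  expect_equal(nrow(b2), 10)
  expect_true(all(b2$depth[1:9] == 0))
})

test_that("the transition kernel follows the per-lineage resampling model", {
  p <- lod_params(N = 2, res_bp = 100, bp_per_cM = 2500)
  expect_equal(transition_matrix(0, p), diag(3))
  # r saturates at 1/2: row j=2 is Binomial(2, 3/4) = (1,6,9)/16
  far <- transition_matrix(1e15, p)
  expect_equal(far[3, ], c(1, 6, 9) / 16)
  # rows are stochastic for arbitrary N and distance
  p20 <- lod_params(N = 20)
  Tm <- transition_matrix(351, p20)
  expect_equal(rowSums(Tm), rep(1, 21))
  expect_true(all(Tm >= 0))
  # Binomial(N, 1/2) is stationary
  expect_equal(as.numeric(p20$prior %*% Tm), p20$prior)
  expect_error(transition_matrix(-1, p20), "non-negative")
})

test_that("emission is the binomial read-sampling likelihood", {
  p <- lod_params(N = 4, eps = 0)
  expect_equal(emission(5, 5, 4, p), 1)       # fixed state, all reads agree
  expect_equal(emission(2, 5, 0, p), 0)       # impossible under eps = 0
  # j/N = 1/2 is symmetric in a <-> depth - a
  p2 <- lod_params(N = 4, eps = 0.01)
  expect_equal(emission(1, 7, 2, p2), emission(6, 7, 2, p2))
  expect_error(emission(3, 2, 1, p2), "exceed")
  expect_equal(emission(0, 0, 3, p2), 1)      # empty bin
})

test_that("forward-backward matches hand-enumerable micro-cases", {
  p <- lod_params(N = 1, res_bp = 100, eps = 0)
  fb0 <- forward_backward(make_binned(0, 0), p)
  expect_equal(fb0$log10_lik, 0)                       # L = 1
  expect_equal(fb0$contigs[[1]]$gamma[1, ], c(0.5, 0.5))
  fb1 <- forward_backward(make_binned(1, 1), p)
  expect_equal(10^fb1$log10_lik, 0.5)
  expect_equal(fb1$contigs[[1]]$gamma[1, ] * 10^fb1$log10_lik, c(0, 0.5))
})

test_that("forward-backward and the tied contrast match exhaustive path enumeration", {
  set.seed(20)
  worst <- 0
  for (i in 1:40) {
    N <- sample(1:3, 1); B <- sample(2:4, 1)
    p <- lod_params(N = N, res_bp = sample(c(50, 100, 400), 1),
                    bp_per_cM = 500, eps = runif(1, 0, 0.05))
    dH <- rpois(B, 5); aH <- rbinom(B, dH, runif(1))
    dL <- rpois(B, 5); aL <- rbinom(B, dL, runif(1))
    fbH <- forward_backward(make_binned(aH, dH, p$res_bp), p)
    fbL <- forward_backward(make_binned(aL, dL, p$res_bp), p)
    eH <- enum_chain(aH, dH, p)
    worst <- max(worst, abs(10^fbH$log10_lik - eH$L) / eH$L)
    lt <- contrast_lod(make_binned(aH, dH, p$res_bp),
                       make_binned(aL, dL, p$res_bp), p)
    for (x in seq_len(B)) {
      tied <- enum_tied(aH, dH, aL, dL, x, p)
      got <- 10^(fbH$log10_lik + fbL$log10_lik - lt$lod[x])
      worst <- max(worst, abs(got - tied) / tied)
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("single-bin analytic LOD values are exact", {
  p <- lod_params(N = 1, res_bp = 100, eps = 0)
  agree <- contrast_lod(make_binned(1, 1), make_binned(1, 1), p)
  expect_equal(agree$lod, -log10(2))
  contra <- contrast_lod(make_binned(1, 1), make_binned(0, 1), p)
  expect_identical(contra$lod, Inf)
  expect_error(contrast_lod(make_binned(1, 1),
                            make_binned(c(0, 1), c(1, 1)), p),
               "grid")
})

test_that("identical pool data never yields positive LOD and eps keeps LOD finite", {
  set.seed(8)
  for (i in 1:10) {
    B <- sample(2:3, 1)
    p <- lod_params(N = 2, res_bp = 100, bp_per_cM = 300,
                    eps = runif(1, 0.001, 0.01))
    d <- rpois(B, 8); a <- rbinom(B, d, runif(1))
    lt <- contrast_lod(make_binned(a, d), make_binned(a, d), p)
    expect_true(all(lt$lod <= 1e-12))
    expect_true(all(is.finite(lt$lod)))
  }
})

test_that("peak LOD grows monotonically with the planted pool frequency gap", {
  set.seed(30)
  N <- 20; B <- 200
  p <- lod_params(N = N, res_bp = 100, bp_per_cM = 100)
  gaps <- seq(0.1, 0.9, by = 0.2)
  peaks <- vapply(gaps, function(g) {
    fH <- 0.5 + g / 2; fL <- 0.5 - g / 2
    d <- rep(50, B)
    aH <- rbinom(B, d, fH); aL <- rbinom(B, d, fL)
    max(contrast_lod(make_binned(aH, d), make_binned(aL, d), p)$lod)
  }, numeric(1))
  expect_true(all(diff(peaks) >= 0))
})

test_that("scaled-arithmetic log-likelihood agrees with log-space computation on long tracks", {
  set.seed(4)
  B <- 10000
  p <- lod_params(N = 5, res_bp = 100, bp_per_cM = 400, eps = 0.002)
  d <- rpois(B, 3)
  a <- rbinom(B, d, 0.5)
  fb <- forward_backward(make_binned(a, d), p)
  expect_equal(fb$log10_lik, logspace_loglik(make_binned(a, d), p),
               tolerance = 1e-9)
})
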