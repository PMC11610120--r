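#' Fit a logistic growth curve to one well's time series
#'
#' Least-squares fit of `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` with
#' carrying capacity `K`, intrinsic rate `r` (per hour) and initial
#' density `N0`, as used to summarise plate-reader growth of
#' reciprocal-hemizygote allele variants. Initial values are `K0 = max
#' density`, `N0` the first positive density, and `r0` from the log-linear
#' early slope; optimisation is Levenberg-Marquardt with a 1e-10 tolerance
#' so exact model data are recovered to machine-level precision.
#'
#' Derived metrics use the closed forms
#' `Tmid = log((K - N0)/N0) / r` (time of half capacity, `N(Tmid) = K/2`)
#' and `auc_l = (K/r) log((K + N0 (exp(rT) - 1)) / K)` (integral of the
#' fitted curve over `[0, T]`, `T` the last time point). `auc_e` is the
#' trapezoidal integral of the raw data.
#'
#' @param times Hours, strictly increasing, at least 5 points.
#' @param densities Optical densities, non-negative.
#' @return An object of class `growth_fit`: `K, r, N0, sigma, tmid, auc_l,
#'   auc_e, T, converged`.
#' @export
fit_logistic <- function(times, densities) {
  if (length(times) < 5L) stop("need at least 5 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(densities < 0)) stop("densities must be non-negative")
  if (all(densities <= 0)) stop("no positive densities to fit")
  if (all(densities == densities[1]))
    stop("densities are constant; logistic fit undefined")
  K0 <- max(densities)
  N00 <- densities[densities > 0][1]
  early <- which(densities > 0 & densities < 0.8 * K0)
  r0 <- if (length(early) >= 2L) {
    sl <- coef(stats::lm(log(densities[early]) ~ times[early]))[2]
    max(sl, 1e-3)
  } else 0.1
  df <- data.frame(t = times, y = densities)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)), data = df,
      start = list(K = K0, r = r0, N0 = max(N00, K0 * 1e-4)),
      lower = c(K = 1e-12, r = 1e-12, N0 = 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(K = NA_real_, r = NA_real_, N0 = NA_real_,
                sigma = NA_real_, tmid = NA_real_, auc_l = NA_real_,
                auc_e = trapz_auc(times, densities), T = max(times),
                converged = FALSE)
    class(out) <- "growth_fit"
    return(out)
  }
  p <- coef(fit)
  K <- p[["K"]]; r <- p[["r"]]; N0 <- p[["N0"]]
  Tend <- max(times)
  out <- list(
    K = K, r = r, N0 = N0,
    sigma = sqrt(sum(stats::residuals(fit)^2) /
                   max(1, length(times) - 3)),
    tmid = log((K - N0) / N0) / r,
    auc_l = (K / r) * log((K + N0 * (exp(r * Tend) - 1)) / K),
    auc_e = trapz_auc(times, densities),
    T = Tend, converged = TRUE)
  class(out) <- "growth_fit"
  out
}

trapz_auc <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf(
    "growth_fit: K=%.4g r=%.4g/h N0=%.4g  Tmid=%.3g h  auc_l=%.4g\n",
    x$K, x$r, x$N0, x$tmid, x$auc_l))
  invisible(x)
}

#' Fit all wells of a long-format growth table
#'
#' @param curves `data.frame(well, group, time_h, od)`.
#' @return `data.frame(well, group, K, r, N0, sigma, tmid, auc_l, auc_e,
#'   converged)`, one row per well.
#' @export
fit_growth_table <- function(curves) {
  stopifnot(all(c("well", "group", "time_h", "od") %in% names(curves)))
  rows <- lapply(unique(curves$well), function(w) {
    sub <- curves[curves$well == w, , drop = FALSE]
    sub <- sub[order(sub$time_h), , drop = FALSE]
    f <- fit_logistic(sub$time_h, sub$od)
    data.frame(well = w, group = sub$group[1], K = f$K, r = f$r,
               N0 = f$N0, sigma = f$sigma, tmid = f$tmid,
               auc_l = f$auc_l, auc_e = f$auc_e,
               converged = f$converged, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Compare a growth metric between two allele groups
#'
#' Two-sample Student's t-test (pooled variance, two-sided) on a fitted
#' growth metric, as in reciprocal-hemizygosity comparisons of the two
#' parental alleles. When comparing `auc_l` across groups the integrals
#' should be computed over a common horizon (see [fit_logistic()]).
#'
#' @param fits_a,fits_b Fit tables ([fit_growth_table()]) or numeric
#'   vectors of the metric itself.
#' @param metric One of `"K"`, `"r"`, `"tmid"`, `"auc_l"` (ignored for
#'   numeric input).
#' @return `list(t, df, p, mean_a, mean_b, degenerate)`; identical
#'   zero-variance groups give `t = 0, p = 1`, unequal zero-variance
#'   groups are flagged `degenerate`.
#' @export
compare_alleles <- function(fits_a, fits_b, metric = "auc_l") {
  pick <- function(f) {
    if (is.numeric(f)) return(f)
    stopifnot(metric %in% names(f))
    f[[metric]][is.finite(f[[metric]])]
  }
  a <- pick(fits_a); b <- pick(fits_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 fits per group")
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b), degenerate = FALSE))
    return(list(t = NA_real_, df = length(a) + length(b) - 2,
                p = NA_real_, mean_a = mean(a), mean_b = mean(b),
                degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       degenerate = FALSE)
}
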