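#' Exclude outlier replicates by the 1.25 x IQR fence
#'
#' Colony sizes of the four technical replicates are compared against
#' Tukey-style fences computed from the original replicate set: values
#' above `Q3 + k * IQR` or below `Q1 - k * IQR` are excluded, with
#' `k = 1.25` and quartiles by linear interpolation (type 7).
#'
#' @param values 2--4 finite, non-negative replicate sizes.
#' @param k Fence multiplier (default 1.25).
#' @param type Quantile type passed to [stats::quantile()] (default 7).
#' @return The kept values, original order preserved (possibly empty).
#' @export
filter_replicates <- function(values, k = 1.25, type = 7) {
  if (length(values) < 2L)
    stop("at least 2 replicate values are required to compute quartiles")
  if (any(!is.finite(values)) || any(values < 0))
    stop("replicate values must be finite and non-negative")
  q <- quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  values[values >= q[1] - k * iqr & values <= q[2] + k * iqr]
}

#' Summarise a replicate phenotype table
#'
#' Applies [filter_replicates()] per strain x condition, takes the median
#' of the kept replicates, and normalises each condition median by the
#' strain's control-condition median.
#'
#' @param pheno `data.frame(strain, condition, rep1..rep4)` (replicate
#'   columns are all columns matching `^rep`); NA replicates are ignored.
#' @param control Control condition label used for normalisation
#'   (default `"YPD"`).
#' @param k,type Passed to [filter_replicates()].
#' @return A `data.frame(strain, condition, n_kept, median, normalized)`.
#'   Strains whose replicates were all excluded get `n_kept = 0` and an NA
#'   median (and are ineligible for pool selection); strains lacking the
#'   control condition get an NA `normalized` with a warning.
#' @export
summarize_phenotypes <- function(pheno, control = "YPD", k = 1.25,
                                 type = 7) {
  stopifnot(all(c("strain", "condition") %in% names(pheno)))
  rep_cols <- grep("^rep", names(pheno), value = TRUE)
  if (!length(rep_cols)) stop("no replicate columns (rep*) found")
  out <- do.call(rbind, lapply(seq_len(nrow(pheno)), function(i) {
    v <- as.numeric(pheno[i, rep_cols])
    v <- v[!is.na(v)]
    kept <- if (length(v) >= 2L) filter_replicates(v, k = k, type = type)
    else v
    data.frame(strain = pheno$strain[i], condition = pheno$condition[i],
               n_kept = length(kept),
               median = if (length(kept)) median(kept) else NA_real_)
  }))
  ctrl <- out[out$condition == control, c("strain", "median")]
  cmed <- ctrl$median[match(out$strain, ctrl$strain)]
  out$normalized <- out$median / cmed
  no_ctrl <- unique(out$strain[is.na(cmed) & out$condition != control])
  if (length(no_ctrl))
    warning("no ", control, " control for strain(s): ",
            paste(head(no_ctrl, 5), collapse = ", "),
            if (length(no_ctrl) > 5) " ...")
  rownames(out) <- NULL
  out
}

#' Quartile coefficient of dispersion
#'
#' `(Q3 - Q1) / (Q3 + Q1)`, a scale-free spread measure used to compare
#' the phenotypic dispersion of per-strain medians across conditions.
#'
#' @param values Numeric vector (typically per-strain medians).
#' @param type Quantile type (default 7).
#' @return The QCD; `NaN` with a warning when `Q3 + Q1 == 0`.
#' @export
dispersion_qcd <- function(values, type = 7) {
  q <- quantile(values, c(0.25, 0.75), type = type, names = FALSE,
                na.rm = TRUE)
  if (q[1] + q[2] == 0) {
    warning("Q1 + Q3 is zero; quartile coefficient of dispersion undefined")
    return(NaN)
  }
  (q[2] - q[1]) / (q[2] + q[1])
}

#' Fraction of strains sustaining growth
#'
#' @param values Per-strain medians.
#' @param threshold Minimum median size counting as growth (default 0,
#'   i.e. any measurable colony).
#' @return Fraction in `[0, 1]` of strains with `median > threshold`.
#' @export
viability <- function(values, threshold = 0) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values supplied")
  mean(values > threshold)
}

#' Select the two-tailed high/low fitness pools
#'
#' Ranks strains by their (raw) median colony size in one condition and
#' takes the `n` largest as the high-fitness pool and the `n` smallest as
#' the low-fitness pool, from one consistent (median, strain id) ranking;
#' ties are therefore broken by strain id, selection is deterministic,
#' invariant to input row order, and the two pools are always disjoint.
#'
#' @param pheno_table Output of [summarize_phenotypes()].
#' @param condition Condition to select on.
#' @param n Pool size (default 20).
#' @return A list of class `pool_assignment` with `condition`, `high`
#'   and `low` (character vectors of strain ids, each length `n`).
#' @export
select_pools <- function(pheno_table, condition, n = 20) {
  sub <- pheno_table[pheno_table$condition == condition &
                       !is.na(pheno_table$median) &
                       pheno_table$n_kept > 0, , drop = FALSE]
  if (nrow(sub) < 2 * n)
    stop("need at least ", 2 * n, " strains with a median in ", condition,
         "; have ", nrow(sub))
  # one consistent ranking guarantees disjoint pools even when a tie
  # group straddles both boundaries
  asc <- sub$strain[order(sub$median, sub$strain)]
  lo <- asc[seq_len(n)]
  hi <- rev(asc)[seq_len(n)]
  structure(list(condition = condition, high = hi, low = lo),
            class = "pool_assignment")
}

#' @export
print.pool_assignment <- function(x, ...) {
  cat("pool_assignment (", x$condition, "): ", length(x$high),
      " high / ", length(x$low), " low\n", sep = "")
  invisible(x)
}
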