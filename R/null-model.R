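#' Log event-rate ratio between two samples
#'
#' The per-nucleotide log-ratio (natural log) of event rates, the basic
#' comparison statistic of the pipeline: large positive values mean the
#' first sample has proportionally more drop-offs/mutations than the second.
#' The ratio is missing wherever either rate is missing *or zero* — a
#' position must show a non-zero rate on both sides to contribute, so that
#' log-ratios stay finite and uninformative zero counts are excluded rather
#' than mapped to infinities.
#'
#' @param rates_t,rates_c Aligned `rate_track`s (numerator and denominator,
#'   typically treatment and control).
#' @return Numeric vector of log-ratios, `NA` where undefined.
#' @examples
#' # ln(0.02 / 0.01) = ln 2
#' @export
compute_ldr <- function(rates_t, rates_c) {
  check_aligned(rates_t, rates_c)
  rt <- rates_t$rate
  rc <- rates_c$rate
  out <- ifelse(!is.na(rt) & !is.na(rc) & rt > 0 & rc > 0,
                log(rt) - log(rc), NA_real_)
  as.numeric(out)
}

#' Log-ratio matrix over a set of sample comparisons
#'
#' Builds the positions-by-comparisons matrix of log event-rate ratios
#' together with the paired coverage of each cell, which the variance model
#' uses as its predictor. The paired coverage is the harmonic mean of the
#' two samples' coverages: the sampling variance of a log rate-ratio is
#' additive in the reciprocal coverages, `1/n_a + 1/n_b = 2/n_harmonic`, so
#' with this pairing the variance family `k1 + k2/n` is exact for binomial
#' noise even when the two coverages are very unequal.
#'
#' @param rates Named list of `rate_track`s (one per sample involved).
#' @param pairs Two-column character matrix or data frame; each row is one
#'   (numerator, denominator) comparison by sample name.
#' @return An `ldr_matrix`: list with `ldr` and `n` matrices (one column per
#'   comparison, named "num/den"), and the `info` position table.
#' @export
ldr_matrix <- function(rates, pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L, nrow(pairs) >= 1L)
  if (!all(pairs %in% names(rates))) {
    stop("comparison names sample(s) absent from the rate list",
         call. = FALSE)
  }
  ref <- rates[[pairs[1L, 1L]]]
  ldr <- matrix(NA_real_, nrow(ref), nrow(pairs))
  n <- matrix(NA_real_, nrow(ref), nrow(pairs))
  colnames(ldr) <- colnames(n) <- paste(pairs[, 1L], pairs[, 2L], sep = "/")
  for (j in seq_len(nrow(pairs))) {
    a <- rates[[pairs[j, 1L]]]
    b <- rates[[pairs[j, 2L]]]
    ldr[, j] <- compute_ldr(a, b)
    n[, j] <- ifelse(a$coverage > 0 & b$coverage > 0,
                     2 / (1 / a$coverage + 1 / b$coverage), NA_real_)
  }
  structure(list(ldr = ldr, n = n,
                 info = ref[, c("transcript", "position")]),
            class = "ldr_matrix")
}

#' All treatment-control and control-control comparisons of a condition
#'
#' Treatment-control comparisons are the full cross product of treatments
#' and controls in the condition (2 treatments x 2 controls gives 4); null
#' comparisons are all ordered pairs of distinct controls (k controls give
#' k(k-1)), making the pooled null exactly sign-symmetric since
#' log(a/b) = -log(b/a).
#'
#' @param treatments,controls Character vectors of sample ids.
#' @return List with `tc` and `null` two-column comparison matrices.
#' @export
condition_comparisons <- function(treatments, controls) {
  stopifnot(length(treatments) >= 1L)
  if (length(controls) < 2L) {
    stop("insufficient controls: at least 2 are required to form a null",
         call. = FALSE)
  }
  tc <- as.matrix(expand.grid(num = treatments, den = controls,
                              stringsAsFactors = FALSE))
  cc <- expand.grid(num = controls, den = controls,
                    stringsAsFactors = FALSE)
  cc <- as.matrix(cc[cc$num != cc$den, , drop = FALSE])
  list(tc = tc, null = cc)
}

#' Fit the coverage-dependent variance model
#'
#' Log-ratios of binomial rates are noisier at low coverage. The null
#' (control-control) log-ratios are binned by paired coverage into quantile
#' bins, and the model `sd(n) = sqrt(k1 + k2 / n)` — a constant
#' (biological/overdispersion) floor plus binomial sampling noise decaying
#' as 1/n — is least-squares fitted to the per-bin variances, with both
#' coefficients constrained non-negative. Dividing every log-ratio by
#' `sd(n)` then removes the coverage dependence of the null spread.
#'
#' @param null_ldrs Numeric vector (or matrix) of null log-ratios.
#' @param coverages Paired coverages of the same cells.
#' @param n_bins Number of quantile bins (default 10; at least 2).
#' @param min_per_bin Minimum values per bin (default 10).
#' @return A `variance_model` with elements `k1`, `k2` and the per-bin
#'   summary used for the fit.
#' @export
fit_variance_model <- function(null_ldrs, coverages, n_bins = 10,
                               min_per_bin = 10) {
  if (n_bins < 2L) stop("n_bins must be at least 2", call. = FALSE)
  x <- as.numeric(null_ldrs)
  n <- as.numeric(coverages)
  keep <- !is.na(x) & !is.na(n) & n > 0
  x <- x[keep]
  n <- n[keep]
  if (length(x) == 0L) stop("all null log-ratios are missing", call. = FALSE)
  qs <- unique(stats::quantile(n, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE))
  bin <- cut(n, breaks = qs, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = length(qs) - 1L)
  used <- which(counts >= min_per_bin)
  if (length(used) < 2L) {
    stop("too few usable coverage bins (need >= 2 with >= ", min_per_bin,
         " values)", call. = FALSE)
  }
  # per-bin spread about 0 (the null is sign-symmetric by construction)
  v <- vapply(used, function(b) mean(x[bin == b]^2), numeric(1L))
  inv_n <- vapply(used, function(b) mean(1 / n[bin == b]), numeric(1L))
  nbar <- vapply(used, function(b) mean(n[bin == b]), numeric(1L))

  fit <- stats::lm.fit(cbind(1, inv_n), v)
  k <- fit$coefficients
  if (k[2L] < 0) {                       # homoscedastic: no 1/n component
    k <- c(mean(v), 0)
  } else if (k[1L] < 0) {                # pure sampling noise
    k <- c(0, sum(v * inv_n) / sum(inv_n^2))
  }
  if (k[1L] <= 0 && k[2L] <= 0) {
    stop("degenerate variance fit: predicted sd is zero", call. = FALSE)
  }
  structure(list(k1 = unname(k[1L]), k2 = unname(k[2L]),
                 n_bins = length(used),
                 bins = data.frame(n_mean = nbar, inv_n_mean = inv_n,
                                   var = v, count = counts[used])),
            class = "variance_model")
}

#' @export
print.variance_model <- function(x, ...) {
  cat(sprintf("Variance model: sd(n) = sqrt(%.4g + %.4g / n)  [%d bins]\n",
              x$k1, x$k2, x$n_bins))
  invisible(x)
}

#' Predicted null standard deviation at a given paired coverage
#' @param model A `variance_model`.
#' @param n Paired coverage (vector or matrix).
#' @return `sqrt(k1 + k2 / n)`, same shape as `n`.
#' @export
predict_sd <- function(model, n) {
  stopifnot(inherits(model, "variance_model"))
  sqrt(model$k1 + model$k2 / n)
}

#' Variance-stabilize a log-ratio matrix
#'
#' Divides every cell by the model's predicted null standard deviation at
#' that cell's paired coverage, so the null spread is approximately 1 at
#' every coverage. Missing cells stay missing.
#'
#' @param x An [ldr_matrix()].
#' @param model A [fit_variance_model()] result fitted on the same run's
#'   null comparisons.
#' @return An `ldr_matrix` with stabilized values.
#' @export
stabilize <- function(x, model) {
  stopifnot(inherits(x, "ldr_matrix"))
  x$ldr <- x$ldr / predict_sd(model, x$n)
  x
}

#' Build the pooled null distribution
#'
#' Pools stabilized control-control log-ratios over all positions,
#' transcripts and ordered control pairs; missing values are dropped and
#' the pool is sorted for fast tail counting.
#'
#' @param x An `ldr_matrix` of stabilized null comparisons, or a numeric
#'   vector/matrix of stabilized values.
#' @param min_size Minimum pool size for acceptable P-value resolution
#'   (default 100).
#' @return A `null_distribution` with sorted `values` and size `N`.
#' @export
build_null <- function(x, min_size = 100) {
  vals <- if (inherits(x, "ldr_matrix")) x$ldr else x
  vals <- as.numeric(vals)
  vals <- sort(vals[!is.na(vals)])
  if (length(vals) < min_size) {
    stop("null distribution too small (", length(vals), " < ", min_size,
         " values); add controls or positions", call. = FALSE)
  }
  structure(list(values = vals, N = length(vals)), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution: %d values, median %.3g, 95%% quantile %.3g\n",
              x$N, stats::median(x$values),
              stats::quantile(x$values, 0.95, names = FALSE)))
  invisible(x)
}

#' Empirical P-values against the null distribution
#'
#' Upper-tail add-one estimator: `p = (1 + #\{null >= obs\}) / (N + 1)`, with
#' ties counted in the tail. The add-one form keeps every P-value strictly
#' positive, so Beta log-densities downstream stay finite; P-values of null
#' draws are (slightly super-) uniform by construction.
#'
#' @param obs Stabilized observed log-ratios (vector or matrix, `NA`
#'   propagated), or an `ldr_matrix`.
#' @param null A [build_null()] result.
#' @return P-values in `(0, 1]`, same shape as `obs`.
#' @export
empirical_pvalues <- function(obs, null) {
  stopifnot(inherits(null, "null_distribution"))
  x <- if (inherits(obs, "ldr_matrix")) obs$ldr else obs
  if (null$N == 0L) stop("empty null distribution", call. = FALSE)
  v <- as.numeric(x)
  p <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  # count of null values strictly below obs; ties land in the upper tail
  below <- findInterval(v[ok], null$values, left.open = TRUE)
  p[ok] <- (1 + null$N - below) / (null$N + 1)
  if (is.matrix(x)) {
    p <- matrix(p, nrow(x), ncol(x), dimnames = dimnames(x))
  }
  p
}
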