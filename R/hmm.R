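#' Four-state transition model for the differential HMM
#'
#' Each condition contributes a two-state (unmodified U / modified M) Markov
#' chain whose self-transition probabilities encode the expected run lengths
#' of double-stranded (unmodified) and single-stranded (modified) nucleotide
#' stretches: a geometric run of expected length L has self-transition
#' probability 1 - 1/L. The joint four-state chain over (condition 1,
#' condition 2) states UU, UM, MU, MM is the Kronecker product of the
#' per-condition chain with itself, i.e. the two conditions evolve
#' independently a priori; only the observed P-values couple them.
#'
#' @param l_ss Expected modified (single-stranded) run length in nucleotides
#'   (default 5).
#' @param l_ds Expected unmodified (double-stranded) run length (default 20).
#' @param initial Initial state distribution: `"stationary"` (default; the
#'   stationary distribution of the joint chain, the natural choice deep
#'   inside long segments) or `"uniform"`.
#' @return A `transition_model`: list with the 2x2 per-condition matrix `A`
#'   (states U, M), the 4x4 joint matrix `Q` (states UU, UM, MU, MM), and
#'   the initial distribution `pi`.
#' @examples
#' tm <- build_transition_matrix()
#' tm$A      # [[0.95, 0.05], [0.20, 0.80]]
#' tm$pi     # (0.64, 0.16, 0.16, 0.04)
#' @export
build_transition_matrix <- function(l_ss = 5, l_ds = 20,
                                    initial = c("stationary", "uniform")) {
  initial <- match.arg(initial)
  if (l_ss < 1 || l_ds < 1) {
    stop("expected run lengths must be >= 1 nucleotide", call. = FALSE)
  }
  a <- 1 / l_ds  # U -> M
  b <- 1 / l_ss  # M -> U
  A <- matrix(c(1 - a, a,
                b, 1 - b), nrow = 2L, byrow = TRUE,
              dimnames = list(c("U", "M"), c("U", "M")))
  Q <- kronecker(A, A)
  states <- c("UU", "UM", "MU", "MM")
  dimnames(Q) <- list(states, states)
  pi2 <- c(U = b, M = a) / (a + b)        # stationary of the 2-state chain
  pi4 <- switch(initial,
                stationary = as.numeric(kronecker(pi2, pi2)),
                uniform = rep(0.25, 4L))
  names(pi4) <- states
  structure(list(A = A, Q = Q, pi = pi4, l_ss = l_ss, l_ds = l_ds,
                 initial = initial),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf(
    "4-state transition model (run lengths: modified %g nt, unmodified %g nt; %s start)\n",
    x$l_ss, x$l_ds, x$initial))
  print(round(x$Q, 4))
  invisible(x)
}

#' Beta-uniform emission model
#'
#' Empirical P-values of unmodified nucleotides are uniform on (0, 1);
#' modified nucleotides produce small P-values, modelled as Beta(alpha,
#' beta) with a density decreasing in p (alpha <= 1 <= beta). The defaults
#' alpha = 1, beta = 10 place the Beta/uniform crossover near p = 0.23, so
#' P-values of roughly 0.2 or smaller favour the modified component.
#'
#' @param alpha Beta shape 1, in `(0, 1]` (default 1).
#' @param beta Beta shape 2, `>= 1` (default 10).
#' @return An `emission_model`.
#' @export
emission_model <- function(alpha = 1, beta = 10) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]",
                                       call. = FALSE)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, beta = beta), class = "emission_model")
}

#' @export
print.emission_model <- function(x, ...) {
  cat(sprintf("Beta-uniform emission model: Beta(%g, %g) vs Uniform(0,1)\n",
              x$alpha, x$beta))
  cat(sprintf("  crossover (Beta density = 1) at p = %.4f\n",
              emission_crossover(x)))
  invisible(x)
}

#' P-value at which the Beta density crosses the uniform density
#'
#' Below this P-value the modified (Beta) component is more likely than the
#' unmodified (uniform) one. For Beta(1, beta) the crossover is
#' `1 - (1/beta)^(1/(beta-1))` (about 0.2257 at beta = 10); in general it
#' is found by root solving.
#'
#' @param model An [emission_model()].
#' @return The crossover P-value in (0, 1), or `NA` if the densities never
#'   cross (uniform emission, alpha = beta = 1).
#' @export
emission_crossover <- function(model = emission_model()) {
  stopifnot(inherits(model, "emission_model"))
  f <- function(p) stats::dbeta(p, model$alpha, model$beta) - 1
  if (model$beta == 1 && model$alpha == 1) return(NA_real_)
  lo <- 1e-12
  if (f(lo) < 0) return(NA_real_)
  stats::uniroot(f, c(lo, 1 - 1e-12), tol = 1e-12)$root
}

# Summed Beta log-density of the non-missing P-values in each row.
# Missing entries contribute log 1 = 0 (factor skipped); p = 1 with
# beta > 1 contributes -Inf, handled downstream (never NaN).
beta_logsum <- function(p, alpha, beta) {
  p <- as.matrix(p)
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  ld <- stats::dbeta(p, alpha, beta, log = TRUE)
  ld[is.na(p)] <- 0
  rowSums(ld)
}

# T x 4 matrix of per-position log emission densities, state order
# UU, UM, MU, MM. m1/m2 are the condition-wise modified-component sums;
# the unmodified (uniform) component is log 1 = 0.
emission_logmatrix <- function(pvals_c1, pvals_c2, model) {
  p1 <- as.matrix(pvals_c1)
  p2 <- as.matrix(pvals_c2)
  if (nrow(p1) != nrow(p2)) {
    stop("the two conditions' P-value sets must cover the same positions",
         call. = FALSE)
  }
  m1 <- beta_logsum(p1, model$alpha, model$beta)
  m2 <- beta_logsum(p2, model$alpha, model$beta)
  cbind(UU = 0, UM = m2, MU = m1, MM = m1 + m2)
}

#' Log emission densities of the four joint states at one position
#'
#' Each condition contributes one factor per non-missing P-value: the
#' uniform density (log 1 = 0) under its U component and the Beta density
#' under its M component; missing entries are skipped. The joint state
#' (s1, s2) density is the sum of the two conditions' component sums.
#'
#' @param pvals_c1,pvals_c2 Numeric vectors of P-values in `(0, 1]`
#'   (`NA` allowed) for condition 1 and condition 2 at one position.
#' @param model An [emission_model()].
#' @return Named log-density 4-vector over (UU, UM, MU, MM); `-Inf` is a
#'   legitimate value (e.g. p = 1 with beta > 1 under an M component).
#' @export
emission_logdensity <- function(pvals_c1, pvals_c2,
                                model = emission_model()) {
  if (all(is.na(pvals_c1)) && all(is.na(pvals_c2))) {
    stop("both conditions' P-value sets are entirely missing",
         call. = FALSE)
  }
  e <- emission_logmatrix(matrix(pvals_c1, nrow = 1L),
                          matrix(pvals_c2, nrow = 1L), model)
  stats::setNames(as.numeric(e), colnames(e))
}

#' Split positions into decodable segments
#'
#' The HMM decodes maximal contiguous runs of positions that (a) meet the
#' coverage threshold in every sample, and (b) carry at least one
#' non-missing P-value in each condition. Excluded positions break the
#' chain; each segment is decoded independently. Transcript boundaries and
#' gaps in the position numbering also break segments.
#'
#' @param counts A [count_table()] (row-aligned with the P-value matrices).
#' @param pvalues List with elements `cond1` and `cond2`: positions x
#'   comparisons P-value matrices.
#' @param coverage_threshold Minimum coverage required of every sample
#'   (default 0, i.e. no coverage filter beyond P-value availability).
#' @return List of `segment` objects: each has `transcript`, `start`, `end`,
#'   `rows` (row indices into `counts`), and the per-condition P-value
#'   submatrices `pvals_c1`, `pvals_c2`.
#' @export
segment_positions <- function(counts, pvalues, coverage_threshold = 0) {
  stopifnot(inherits(counts, "count_table"),
            all(c("cond1", "cond2") %in% names(pvalues)))
  p1 <- as.matrix(pvalues$cond1)
  p2 <- as.matrix(pvalues$cond2)
  n <- nrow(counts$info)
  stopifnot(nrow(p1) == n, nrow(p2) == n)
  cov_ok <- rowSums(counts$coverage < coverage_threshold) == 0L
  ok <- cov_ok & rowSums(!is.na(p1)) > 0L & rowSums(!is.na(p2)) > 0L

  tr <- counts$info$transcript
  pos <- counts$info$position
  new_run <- c(TRUE, tr[-1L] != tr[-n] | pos[-1L] != pos[-n] + 1L)
  run_id <- cumsum(new_run | !ok)          # breaks at every excluded position
  segs <- list()
  for (g in split(which(ok), run_id[ok])) {
    segs[[length(segs) + 1L]] <- structure(
      list(transcript = tr[g[1L]], start = pos[g[1L]],
           end = pos[g[length(g)]], rows = g,
           pvals_c1 = p1[g, , drop = FALSE],
           pvals_c2 = p2[g, , drop = FALSE]),
      class = "segment")
  }
  segs
}

# Scaled forward-backward over a T x 4 log-emission matrix.
# Per-row max subtraction before exponentiation keeps the scaled densities
# in range for arbitrarily many comparisons; the UU column is always 0, so
# every row has a strictly positive scaled density and the scaling constants
# never vanish.
fb_scaled <- function(logE, Q, pi0) {
  TT <- nrow(logE)
  mx <- apply(logE, 1L, max)
  B <- exp(logE - mx)
  alpha <- matrix(0, TT, 4L)
  cc <- numeric(TT)
  a <- pi0 * B[1L, ]
  cc[1L] <- sum(a)
  alpha[1L, ] <- a / cc[1L]
  if (TT > 1L) {
    for (t in 2:TT) {
      a <- as.numeric(alpha[t - 1L, ] %*% Q) * B[t, ]
      cc[t] <- sum(a)
      alpha[t, ] <- a / cc[t]
    }
  }
  beta <- matrix(0, TT, 4L)
  beta[TT, ] <- 1
  if (TT > 1L) {
    for (t in (TT - 1L):1L) {
      beta[t, ] <- as.numeric(Q %*% (B[t + 1L, ] * beta[t + 1L, ])) /
        cc[t + 1L]
    }
  }
  g <- alpha * beta
  g <- g / rowSums(g)
  list(gamma = g, loglik = sum(log(cc)) + sum(mx))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Log-space forward-backward; numerically independent route used to
# cross-check the scaled recursion.
fb_logspace <- function(logE, Q, pi0) {
  TT <- nrow(logE)
  lQ <- log(Q)
  la <- matrix(-Inf, TT, 4L)
  lb <- matrix(0, TT, 4L)
  la[1L, ] <- log(pi0) + logE[1L, ]
  if (TT > 1L) {
    for (t in 2:TT) {
      for (s in 1:4) {
        la[t, s] <- logsumexp(la[t - 1L, ] + lQ[, s]) + logE[t, s]
      }
    }
    for (t in (TT - 1L):1L) {
      for (s in 1:4) {
        lb[t, s] <- logsumexp(lQ[s, ] + logE[t + 1L, ] + lb[t + 1L, ])
      }
    }
  }
  lg <- la + lb
  g <- t(apply(lg, 1L, function(r) {
    r <- r - max(r[is.finite(r)])
    e <- exp(r)
    e / sum(e)
  }))
  list(gamma = g, loglik = logsumexp(la[TT, ]))
}

#' Posterior decoding of a segment
#'
#' Runs the forward-backward algorithm over the four joint states and
#' returns the exact posterior marginal of every position. The default
#' scaled recursion is numerically stable for segments of 1e5+ positions;
#' the log-space route is retained as an independent cross-check.
#'
#' @param x A `segment` from [segment_positions()], or a matrix/vector of
#'   condition-1 P-values for a contiguous stretch (rows = positions).
#' @param pvals_c2 Condition-2 P-values (required when `x` is not a
#'   segment).
#' @param trans A [build_transition_matrix()] model.
#' @param emis An [emission_model()].
#' @param method `"scaled"` (default) or `"log"`.
#' @return A `posterior_track` data frame: `transcript`, `position`,
#'   `P_UU`, `P_UM`, `P_MU`, `P_MM`, `P_diff = P_UM + P_MU`; the
#'   log-likelihood of the segment is attached as attribute `"loglik"`.
#' @export
forward_backward <- function(x, pvals_c2 = NULL,
                             trans = build_transition_matrix(),
                             emis = emission_model(),
                             method = c("scaled", "log")) {
  method <- match.arg(method)
  if (inherits(x, "segment")) {
    p1 <- x$pvals_c1
    p2 <- x$pvals_c2
    tr_id <- x$transcript
    pos <- seq(x$start, x$end)
  } else {
    if (is.null(pvals_c2)) stop("pvals_c2 is required", call. = FALSE)
    p1 <- as.matrix(x)
    p2 <- as.matrix(pvals_c2)
    tr_id <- NA_character_
    pos <- seq_len(nrow(p1))
  }
  logE <- emission_logmatrix(p1, p2, emis)
  res <- switch(method,
                scaled = fb_scaled(logE, trans$Q, trans$pi),
                log = fb_logspace(logE, trans$Q, trans$pi))
  g <- res$gamma
  out <- data.frame(transcript = tr_id, position = pos,
                    P_UU = g[, 1L], P_UM = g[, 2L], P_MU = g[, 3L],
                    P_MM = g[, 4L], stringsAsFactors = FALSE)
  out$P_diff <- out$P_UM + out$P_MU
  attr(out, "loglik") <- res$loglik
  class(out) <- c("posterior_track", "data.frame")
  out
}

#' Call differentially reactive nucleotides from a posterior track
#'
#' Labels each position with its maximum-a-posteriori state (ties broken
#' towards the lowest state index, UU first) and flags positions whose
#' posterior probability of differential modification
#' `P_diff = P(UM) + P(MU)` reaches the threshold. The direction reports
#' which condition is the more reactive one: condition 1 when
#' `P_MU >= P_UM` (modified in condition 1 only is the likelier
#' differential state), condition 2 otherwise.
#'
#' @param track A `posterior_track` (rows with missing posteriors are
#'   left uncalled).
#' @param threshold P_diff threshold for a DRN call, in (0, 1)
#'   (default 0.95).
#' @return The track with added columns `call` (state label or `NA`),
#'   `drn` (logical) and `direction` (`"condition1"` / `"condition2"`,
#'   `NA` where uncalled).
#' @export
call_drns <- function(track, threshold = 0.95) {
  stopifnot(threshold > 0, threshold < 1)
  states <- c("UU", "UM", "MU", "MM")
  P <- as.matrix(track[, c("P_UU", "P_UM", "P_MU", "P_MM")])
  ok <- stats::complete.cases(P)
  call <- rep(NA_character_, nrow(P))
  call[ok] <- states[apply(P[ok, , drop = FALSE], 1L, which.max)]
  pdiff <- P[, "P_UM"] + P[, "P_MU"]
  drn <- !is.na(pdiff) & pdiff >= threshold
  direction <- rep(NA_character_, nrow(P))
  direction[ok] <- ifelse(P[ok, "P_MU"] >= P[ok, "P_UM"],
                          "condition1", "condition2")
  track$P_diff <- pdiff
  track$call <- call
  track$drn <- drn
  track$direction <- direction
  track
}
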