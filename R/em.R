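# Weighted maximum-likelihood fit of Beta(alpha, beta) by projected Newton
# ascent with backtracking, constrained to alpha in (0, 1], beta >= 1 (the
# box on which the emission density is non-increasing in p). Observations
# at p = 1 have log(1 - p) = -Inf; their modified-component posterior
# weight is exactly 0 there, so the 0 * -Inf product is dropped.
beta_mle_weighted <- function(p, w, alpha0, beta0,
                              max_newton = 50L, gtol = 1e-9) {
  keep <- p < 1 & w > 0
  p <- p[keep]
  w <- w[keep]
  W <- sum(w)
  if (W < 1e-8) {
    stop("degenerate weights: no posterior mass on the modified component",
         call. = FALSE)
  }
  slp <- sum(w * log(p))
  sl1p <- sum(w * log1p(-p))
  lo <- c(1e-6, 1)
  hi <- c(1, 1e6)
  obj <- function(th) {
    (th[1L] - 1) * slp + (th[2L] - 1) * sl1p - W * lbeta(th[1L], th[2L])
  }
  th <- pmin(pmax(c(alpha0, beta0), lo), hi)
  f <- obj(th)
  for (it in seq_len(max_newton)) {
    a <- th[1L]; b <- th[2L]
    g <- c(slp - W * (digamma(a) - digamma(a + b)),
           sl1p - W * (digamma(b) - digamma(a + b)))
    # active-set gradient test: stop when no admissible ascent remains
    g_act <- g
    g_act[(th <= lo & g < 0) | (th >= hi & g > 0)] <- 0
    if (max(abs(g_act)) < gtol * max(1, W)) break
    H <- -W * matrix(c(trigamma(a) - trigamma(a + b), -trigamma(a + b),
                       -trigamma(a + b), trigamma(b) - trigamma(a + b)),
                     2L, 2L)
    step <- tryCatch(solve(H, g), error = function(e) g / W)
    lam <- 1
    repeat {
      cand <- pmin(pmax(th - lam * step, lo), hi)
      fc <- obj(cand)
      if (fc >= f || lam < 1e-10) break
      lam <- lam / 2
    }
    if (fc < f || max(abs(cand - th)) < 1e-12) break
    th <- cand
    f <- fc
  }
  list(alpha = th[1L], beta = th[2L], objective = f)
}

#' Refine the Beta emission parameters by expectation-maximization
#'
#' The heuristic defaults Beta(1, 10) work well across datasets, but the
#' emission parameters can also be fitted to the data at hand. The E-step
#' computes, for every position and condition, the posterior probability of
#' the modified component from forward-backward decoding under the current
#' parameters; the M-step maximizes the resulting posterior-weighted Beta
#' log-likelihood of all P-values by Newton's method, constrained to
#' `alpha` in (0, 1] and `beta >= 1`. The observed-data log-likelihood is
#' non-decreasing across iterations.
#'
#' @param segments List of segments from [segment_positions()].
#' @param trans A [build_transition_matrix()] model (held fixed).
#' @param alpha_init,beta_init Starting values (defaults 1 and 10).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Stop when the log-likelihood improves by less than this
#'   (default 1e-6).
#' @return List with `alpha`, `beta`, `loglik` (the per-iteration trace),
#'   `iterations` and `converged`.
#' @export
fit_beta_em <- function(segments, trans = build_transition_matrix(),
                        alpha_init = 1, beta_init = 10,
                        max_iter = 100L, tol = 1e-6) {
  if (inherits(segments, "segment")) segments <- list(segments)
  stopifnot(length(segments) >= 1L)
  alpha <- alpha_init
  beta <- beta_init
  emission_model(alpha, beta)  # validates the starting box
  trace <- numeric(0L)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    emis <- emission_model(alpha, beta)
    ll <- 0
    ps <- list()
    ws <- list()
    for (seg in segments) {
      post <- forward_backward(seg, trans = trans, emis = emis)
      ll <- ll + attr(post, "loglik")
      w1 <- post$P_MU + post$P_MM          # P(modified in condition 1)
      w2 <- post$P_UM + post$P_MM
      for (j in seq_len(ncol(seg$pvals_c1))) {
        ps[[length(ps) + 1L]] <- seg$pvals_c1[, j]
        ws[[length(ws) + 1L]] <- w1
      }
      for (j in seq_len(ncol(seg$pvals_c2))) {
        ps[[length(ps) + 1L]] <- seg$pvals_c2[, j]
        ws[[length(ws) + 1L]] <- w2
      }
    }
    p <- unlist(ps)
    w <- unlist(ws)
    ok <- !is.na(p)
    fit <- beta_mle_weighted(p[ok], w[ok], alpha, beta)
    trace <- c(trace, ll)
    if (it > 1L && abs(ll - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    alpha <- fit$alpha
    beta <- fit$beta
  }
  if (!converged) {
    warning("EM did not converge within ", max_iter,
            " iterations; returning the last parameters", call. = FALSE)
  }
  list(alpha = alpha, beta = beta, loglik = trace,
       iterations = length(trace), converged = converged)
}
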