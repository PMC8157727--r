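# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-derivations: exhaustive enumeration, brute-force
# counting and a from-scratch 2-state decoder, sharing no code with the
# package internals they verify.

# Exact posterior marginals by summing over all 4^T hidden paths.
enumerate_posteriors <- function(logE, Q, pi0) {
  TT <- nrow(logE)
  paths <- as.matrix(expand.grid(rep(list(1:4), TT)))
  lw <- log(pi0)[paths[, 1L]] + logE[cbind(1L, paths[, 1L])]
  if (TT > 1L) {
    lQ <- log(Q)
    for (t in 2:TT) {
      lw <- lw + lQ[cbind(paths[, t - 1L], paths[, t])] +
        logE[cbind(t, paths[, t])]
    }
  }
  w <- exp(lw - max(lw))
  post <- matrix(0, TT, 4L)
  for (t in seq_len(TT)) {
    for (s in 1:4) post[t, s] <- sum(w[paths[, t] == s])
  }
  post / rowSums(post)
}

# From-scratch 2-state (U/M) beta-uniform HMM posterior, log-space.
# Used for the independence-limit check: marginalizing the 4-state joint
# chain over an uninformative condition must reproduce this.
bum2_posterior <- function(pvals, l_ss = 5, l_ds = 20, alpha = 1,
                           beta = 10) {
  p <- as.matrix(pvals)
  TT <- nrow(p)
  A <- matrix(c(1 - 1 / l_ds, 1 / l_ds, 1 / l_ss, 1 - 1 / l_ss), 2L,
              byrow = TRUE)
  pi0 <- c(1 / l_ss, 1 / l_ds) / (1 / l_ss + 1 / l_ds)
  lm_ <- dbeta(p, alpha, beta, log = TRUE)
  lm_[is.na(p)] <- 0
  logE <- cbind(0, rowSums(lm_))
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  la <- matrix(-Inf, TT, 2L)
  lb <- matrix(0, TT, 2L)
  la[1L, ] <- log(pi0) + logE[1L, ]
  if (TT > 1L) {
    for (t in 2:TT) {
      for (s in 1:2) la[t, s] <- lse(la[t - 1L, ] + log(A[, s])) + logE[t, s]
    }
    for (t in (TT - 1L):1L) {
      for (s in 1:2) lb[t, s] <- lse(log(A[s, ]) + logE[t + 1L, ] +
                                       lb[t + 1L, ])
    }
  }
  g <- exp(la + lb - apply(la + lb, 1L, max))
  g / rowSums(g)
}

# Random P-value matrices for a segment: mixes moderate values, near-0/1
# extremes and missing entries while keeping >= 1 observed value per
# condition per position.
random_segment_pvals <- function(TT, k = 2L) {
  p <- matrix(runif(TT * k), TT, k)
  extreme <- matrix(runif(TT * k) < 0.15, TT, k)
  p[extreme] <- sample(c(1e-6, 1e-3, 0.999, 1), sum(extreme),
                       replace = TRUE)
  drop_ <- matrix(runif(TT * k) < 0.2, TT, k)
  if (k > 1L) {
    keep_one <- cbind(seq_len(TT), sample.int(k, TT, replace = TRUE))
    drop_[keep_one] <- FALSE
  } else {
    drop_[] <- FALSE
  }
  p[drop_] <- NA_real_
  p
}

# Minimal valid 2x2 + 2x2 design sheet as a plain data frame.
toy_sheet_df <- function() {
  data.frame(
    sample_id = c("c1_t1", "c1_t2", "c1_c1", "c1_c2",
                  "c2_t1", "c2_t2", "c2_c1", "c2_c2"),
    condition = rep(1:2, each = 4L),
    role = rep(c("treatment", "treatment", "control", "control"), 2L),
    replicate = rep(c(1L, 2L, 1L, 2L), 2L),
    path = NA_character_,
    stringsAsFactors = FALSE)
}

# Tiny deterministic count table: n positions, given samples, counts
# filled from a seeded draw with coverage around 1000.
toy_counts <- function(n = 20L, samples = toy_sheet_df()$sample_id,
                       seed = 1L) {
  set.seed(seed)
  cov <- matrix(1000L + sample.int(200L, n * length(samples),
                                   replace = TRUE),
                n, length(samples), dimnames = list(NULL, samples))
  ev <- matrix(rbinom(n * length(samples), as.integer(cov), 0.01),
               n, length(samples), dimnames = list(NULL, samples))
  count_table(data.frame(transcript = "tx1", position = seq_len(n),
                         base = "A", stringsAsFactors = FALSE),
              cov, ev)
}

# Plant a dataset from the generating model (states from the default
# chain, p | M ~ Beta(alpha, beta), p | U ~ Uniform) as one segment with
# one P-value track per condition.
plant_segment <- function(TT, alpha = 1, beta = 10, seed = 71) {
  set.seed(seed)
  tm <- build_transition_matrix()
  draw_track <- function() {
    s <- integer(TT)
    s[1L] <- sample(1:2, 1L, prob = c(0.8, 0.2))
    for (t in 2:TT) s[t] <- sample(1:2, 1L, prob = tm$A[s[t - 1L], ])
    ifelse(s == 2L, rbeta(TT, alpha, beta), runif(TT))
  }
  p1 <- matrix(draw_track(), ncol = 1L)
  p2 <- matrix(draw_track(), ncol = 1L)
  structure(list(transcript = "sim", start = 1L, end = TT,
                 rows = seq_len(TT), pvals_c1 = p1, pvals_c2 = p2),
            class = "segment")
}
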