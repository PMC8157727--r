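test_that("transition model matches the run-length construction", {
  tm <- build_transition_matrix()
  expect_equal(unname(tm$A), matrix(c(0.95, 0.05, 0.2, 0.8), 2,
                                    byrow = TRUE))
  expect_equal(unname(tm$Q["UU", ]), c(0.9025, 0.0475, 0.0475, 0.0025))
  expect_equal(unname(tm$Q["MM", ]), c(0.04, 0.16, 0.16, 0.64))
  expect_equal(unname(tm$pi), c(0.64, 0.16, 0.16, 0.04))
  # stationarity: pi Q = pi
  expect_equal(as.numeric(tm$pi %*% tm$Q), unname(tm$pi))

  # rows sum to 1 for arbitrary run lengths
  for (l in list(c(1, 1), c(2, 7), c(5.5, 33), c(100, 3))) {
    Q <- build_transition_matrix(l[1], l[2])$Q
    expect_equal(unname(rowSums(Q)), rep(1, 4))
  }
  expect_error(build_transition_matrix(0.5, 20), ">= 1")

  tu <- build_transition_matrix(initial = "uniform")
  expect_equal(unname(tu$pi), rep(0.25, 4))
})

test_that("emission log-densities follow the beta-uniform closed form", {
  em <- emission_model()
  f <- 10 * 0.5^9  # Beta(1,10) density at 0.5
  e <- emission_logdensity(0.5, 0.5, em)
  expect_equal(unname(e), c(0, log(f), log(f), 2 * log(f)))
  expect_equal(f, 0.01953125)

  # missing condition-2 set: UU == UM and MU == MM contributions
  e2 <- emission_logdensity(c(0.1, 0.3), c(NA, NA), em)
  expect_equal(e2[["UU"]], e2[["UM"]])
  expect_equal(e2[["MU"]], e2[["MM"]])
  expect_equal(e2[["MU"]],
               sum(dbeta(c(0.1, 0.3), 1, 10, log = TRUE)))

  # p = 1 with beta > 1: -Inf for M components, never NaN
  e3 <- emission_logdensity(1, 0.5, em)
  expect_identical(e3[["MU"]], -Inf)
  expect_false(any(is.nan(e3)))

  expect_error(emission_logdensity(NA, NA, em), "entirely missing")
  expect_error(emission_logdensity(0, 0.5, em), "\\(0, 1\\]")
  expect_error(emission_model(alpha = 1.5), "alpha")
  expect_error(emission_model(beta = 0.5), "beta")
})

test_that("Beta/uniform crossover sits at 1 - 0.1^(1/9) for the defaults", {
  cross <- emission_crossover(emission_model())
  expect_equal(cross, 1 - 0.1^(1 / 9), tolerance = 1e-9)
  expect_equal(cross, 0.2257, tolerance = 1e-3)
  # the modified component wins below, loses above
  expect_gt(dbeta(cross - 0.01, 1, 10), 1)
  expect_lt(dbeta(cross + 0.01, 1, 10), 1)
})

test_that("segmentation breaks at missing data, thresholds and gaps", {
  tab <- toy_counts(n = 10L, samples = c("s1", "s2"))
  p1 <- matrix(runif(20), 10, 2)
  p2 <- matrix(runif(20), 10, 2)
  p1[5L, ] <- NA  # all-missing in condition 1 breaks the chain
  segs <- segment_positions(tab, list(cond1 = p1, cond2 = p2))
  expect_equal(length(segs), 2L)
  expect_equal(c(segs[[1L]]$start, segs[[1L]]$end), c(1L, 4L))
  expect_equal(c(segs[[2L]]$start, segs[[2L]]$end), c(6L, 10L))

  # threshold above the maximum coverage: nothing decodable
  expect_equal(length(segment_positions(tab, list(cond1 = p1, cond2 = p2),
                                        coverage_threshold = 1e6)), 0L)

  # no missing data: a single segment
  p1[5L, ] <- 0.5
  expect_equal(length(segment_positions(tab, list(cond1 = p1, cond2 = p2))),
               1L)

  # a gap in position numbering breaks the segment
  tab2 <- toy_counts(n = 10L, samples = c("s1", "s2"))
  tab2$info$position <- c(1:5, 7:11)
  segs2 <- segment_positions(tab2, list(cond1 = p1, cond2 = p2))
  expect_equal(length(segs2), 2L)
})

test_that("single-position posterior matches the Bayes hand calculation", {
  tm <- build_transition_matrix(initial = "uniform")
  post <- forward_backward(matrix(0.5), matrix(0.5), tm, emission_model())
  f <- 0.01953125
  z <- 1 + 2 * f + f^2
  expect_equal(post$P_UU, 1 / z, tolerance = 1e-9)
  expect_equal(post$P_UM, f / z, tolerance = 1e-9)
  expect_equal(post$P_MU, f / z, tolerance = 1e-9)
  expect_equal(post$P_MM, f^2 / z, tolerance = 1e-9)
  expect_equal(post$P_UU, 0.96205, tolerance = 1e-4)
  expect_equal(post$P_MM, 3.67e-4, tolerance = 1e-2)
})

test_that("forward-backward equals exhaustive path enumeration (T <= 6)", {
  set.seed(17)
  tm <- build_transition_matrix()
  em <- emission_model()
  worst <- 0
  for (rep in 1:50) {
    TT <- sample(1:6, 1L)
    p1 <- random_segment_pvals(TT)
    p2 <- random_segment_pvals(TT)
    post <- forward_backward(p1, p2, tm, em)
    logE <- diffprobe:::emission_logmatrix(p1, p2, em)
    oracle <- enumerate_posteriors(logE, tm$Q, tm$pi)
    worst <- max(worst, max(abs(as.matrix(
      post[, c("P_UU", "P_UM", "P_MU", "P_MM")]) - oracle)))
  }
  expect_lt(worst, 1e-10)
})

test_that("scaled and log-space recursions agree and stay stable when long", {
  set.seed(19)
  TT <- 3000L
  p1 <- random_segment_pvals(TT, 3L)
  p2 <- random_segment_pvals(TT, 3L)
  a <- forward_backward(p1, p2, method = "scaled")
  b <- forward_backward(p1, p2, method = "log")
  cols <- c("P_UU", "P_UM", "P_MU", "P_MM")
  expect_lt(max(abs(as.matrix(a[, cols]) - as.matrix(b[, cols]))), 1e-10)
  expect_true(all(abs(rowSums(as.matrix(a[, cols])) - 1) < 1e-9))
  expect_true(all(is.finite(as.matrix(a[, cols]))))
})

test_that("swapping the conditions swaps P_UM and P_MU exactly", {
  set.seed(29)
  p1 <- random_segment_pvals(40L)
  p2 <- random_segment_pvals(40L)
  a <- forward_backward(p1, p2)
  b <- forward_backward(p2, p1)
  # exact symmetry of Q = A (x) A and pi, up to summation order in the
  # recursions (relative differences at machine epsilon)
  expect_equal(a$P_UU, b$P_UU, tolerance = 1e-12)
  expect_equal(a$P_MM, b$P_MM, tolerance = 1e-12)
  expect_equal(a$P_UM, b$P_MU, tolerance = 1e-12)
  expect_equal(a$P_MU, b$P_UM, tolerance = 1e-12)
})

test_that("an uninformative condition reduces to the 2-state model", {
  set.seed(37)
  TT <- 60L
  p1 <- matrix(runif(TT * 2), TT, 2)
  p1[sample(TT, 10L), 1L] <- NA
  p2 <- matrix(NA_real_, TT, 2)  # condition 2 contributes nothing
  post <- forward_backward(p1, p2)
  marg_m1 <- post$P_MU + post$P_MM  # P(modified in condition 1)
  oracle <- bum2_posterior(p1)
  expect_lt(max(abs(marg_m1 - oracle[, 2L])), 1e-10)
})

test_that("single-position modification posterior is monotone in the P-value", {
  tm <- build_transition_matrix()
  em <- emission_model()
  ps <- seq(0.01, 1, by = 0.01)
  m1 <- vapply(ps, function(p) {
    post <- forward_backward(matrix(p), matrix(0.3), tm, em)
    post$P_MU + post$P_MM
  }, numeric(1))
  expect_true(all(diff(m1) <= 1e-12))
})

test_that("DRN calls apply the threshold, tie-break and direction rules", {
  mk <- function(v) {
    d <- data.frame(transcript = "t", position = seq_len(nrow(v)),
                    P_UU = v[, 1], P_UM = v[, 2], P_MU = v[, 3],
                    P_MM = v[, 4])
    d$P_diff <- d$P_UM + d$P_MU
    class(d) <- c("posterior_track", "data.frame")
    d
  }
  v <- rbind(c(0.01, 0.02, 0.95, 0.02),
             c(0.25, 0.25, 0.25, 0.25),
             c(0.02, 0.48, 0.48, 0.02),
             c(0.90, 0.05, 0.03, 0.02))
  out <- call_drns(mk(v), threshold = 0.95)
  expect_equal(out$call, c("MU", "UU", "UM", "UU"))
  expect_equal(out$drn, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction[1L], "condition1")
  expect_equal(out$direction[3L], "condition1")  # tie -> condition 1
  expect_error(call_drns(mk(v), threshold = 1.2), "threshold")
})

test_that("transition perturbations barely move strong-signal DRN calls", {
  set.seed(43)
  d <- simulate_dataset(sim_config(n_transcripts = 2, length = 500,
                                   seed = 301))
  run <- run_pipeline(d$samples, d$counts)
  base_calls <- which(run$posteriors$drn)
  expect_gt(length(base_calls), 50L)
  for (fac in c(0.5, 2)) {
    tm <- build_transition_matrix()
    A <- tm$A
    A[1, 2] <- min(A[1, 2] * fac, 0.9)
    A[2, 1] <- min(A[2, 1] * fac, 0.9)
    diag(A) <- 1 - c(A[1, 2], A[2, 1])
    Q <- kronecker(A, A)
    pi2 <- c(A[2, 1], A[1, 2]) / (A[1, 2] + A[2, 1])
    tm$Q <- Q
    tm$pi <- as.numeric(kronecker(pi2, pi2))
    post <- run$posteriors
    for (seg in run$segments) {
      dec <- forward_backward(seg, trans = tm, emis = run$emission)
      post[seg$rows, c("P_UU", "P_UM", "P_MU", "P_MM")] <-
        dec[, c("P_UU", "P_UM", "P_MU", "P_MM")]
    }
    post$P_diff <- post$P_UM + post$P_MU
    pert_calls <- which(!is.na(post$P_diff) & post$P_diff >= 0.95)
    jac <- length(union(base_calls, pert_calls))
    mismatch <- length(setdiff(union(base_calls, pert_calls),
                               intersect(base_calls, pert_calls))) / jac
    expect_lt(mismatch, 0.05)
  }
})
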