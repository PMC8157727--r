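mk_track <- function(r, cov = 1000L) {
  structure(
    data.frame(transcript = "t", position = seq_along(r), rate = r,
               coverage = cov),
    class = c("rate_track", "data.frame"))
}

test_that("log rate-ratios are natural-log and missing at zero rates", {
  rt <- mk_track(c(0.02, 0, 0.05, 0.01, NA))
  rc <- mk_track(c(0.01, 0.01, 0.05, 0, 0.01))
  ldr <- compute_ldr(rt, rc)
  expect_equal(ldr[1L], log(2))
  expect_true(is.na(ldr[2L]))  # zero numerator rate
  expect_equal(ldr[3L], 0)
  expect_true(is.na(ldr[4L]))  # zero denominator rate
  expect_true(is.na(ldr[5L]))
})

test_that("comparison sets are the cross product and ordered control pairs", {
  cmp <- condition_comparisons(c("t1", "t2"), c("c1", "c2"))
  expect_equal(nrow(cmp$tc), 4L)
  expect_equal(nrow(cmp$null), 2L)
  cmp3 <- condition_comparisons("t1", c("c1", "c2", "c3"))
  expect_equal(nrow(cmp3$null), 6L)
  expect_error(condition_comparisons("t1", "c1"), "insufficient controls")
})

test_that("the ordered-pair null is exactly sign-symmetric", {
  set.seed(5)
  rates <- list(c1 = mk_track(runif(50, 0.005, 0.05)),
                c2 = mk_track(runif(50, 0.005, 0.05)))
  cmp <- condition_comparisons("x", c("c1", "c2"))
  nul <- ldr_matrix(rates, cmp$null)
  expect_equal(nul$ldr[, 1L], -nul$ldr[, 2L])
  nd <- build_null(nul, min_size = 50)
  expect_equal(sort(nd$values), sort(-nd$values))
  expect_error(build_null(nul, min_size = 1000), "too small")
})

test_that("variance model recovers generating (k1, k2) and degenerates cleanly", {
  set.seed(101)
  n <- sample(100:10000, 50000, replace = TRUE)
  ldr <- rnorm(50000, 0, sqrt(0.01 + 50 / n))
  vm <- fit_variance_model(ldr, n)
  expect_lt(abs(vm$k1 - 0.01) / 0.01, 0.2)
  expect_lt(abs(vm$k2 - 50) / 50, 0.2)

  # homoscedastic input: no coverage-dependent component
  ldr0 <- rnorm(50000, 0, 0.3)
  vm0 <- fit_variance_model(ldr0, n)
  expect_lt(vm0$k2 * (1 / min(n)), 0.05 * vm0$k1)
  expect_equal(predict_sd(vm0, c(100, 10000)), c(0.3, 0.3),
               tolerance = 0.05)

  expect_error(fit_variance_model(ldr, n, n_bins = 1), "at least 2")
  expect_error(fit_variance_model(rep(NA_real_, 10), rep(100, 10)),
               "missing")
})

test_that("stabilization scales by predicted sd and equalizes null spread", {
  # direct scaling check: sd(n) = 0.25 at the cell's coverage gives ldr/0.25
  vm <- structure(list(k1 = 0.0625, k2 = 0), class = "variance_model")
  x <- structure(list(ldr = matrix(c(0.5, NA), 2, 1),
                      n = matrix(c(400, 400), 2, 1),
                      info = NULL), class = "ldr_matrix")
  s <- stabilize(x, vm)
  expect_equal(s$ldr[1L, 1L], 2.0)
  expect_true(is.na(s$ldr[2L, 1L]))

  # empirical: after stabilizing heteroscedastic null, per-bin sd is ~1
  set.seed(7)
  n <- sample(100:10000, 40000, replace = TRUE)
  ldr <- rnorm(40000, 0, sqrt(0.01 + 50 / n))
  vmf <- fit_variance_model(ldr, n)
  z <- ldr / predict_sd(vmf, n)
  bins <- cut(n, stats::quantile(n, seq(0, 1, 0.1)), include.lowest = TRUE)
  sds <- tapply(z, bins, sd)
  expect_true(all(sds > 0.75 & sds < 1.25))
})

test_that("empirical P-values match brute-force tail counting", {
  nd <- build_null(c(-1, -0.5, 0, 0.5, 1), min_size = 5)
  expect_equal(empirical_pvalues(0.6, nd), 2 / 6)
  expect_equal(empirical_pvalues(2.0, nd), 1 / 6)
  expect_equal(empirical_pvalues(-2.0, nd), 1.0)
  expect_equal(empirical_pvalues(0.5, nd), 3 / 6)  # tie counted in tail

  # randomized brute-force comparison, including ties
  set.seed(13)
  null_vals <- round(rnorm(200), 1)
  nd2 <- build_null(null_vals, min_size = 100)
  obs <- c(round(rnorm(50), 1), sample(null_vals, 20))
  brute <- vapply(obs, function(o) (1 + sum(null_vals >= o)) / 201,
                  numeric(1))
  expect_equal(as.numeric(empirical_pvalues(obs, nd2)), brute)

  # NA propagation and shape preservation
  m <- matrix(c(0.6, NA, -2, 2), 2, 2)
  pm <- empirical_pvalues(m, nd)
  expect_true(is.na(pm[2, 1]))
  expect_equal(dim(pm), c(2L, 2L))
})

test_that("null-drawn P-values are super-uniform and the map is monotone", {
  set.seed(23)
  null_vals <- rnorm(2000)
  nd <- build_null(null_vals, min_size = 100)
  obs <- rnorm(5000)
  p <- as.numeric(empirical_pvalues(obs, nd))
  slack <- 2 / (nd$N + 1)
  for (q in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(p <= q), q + slack + 3 * sqrt(q / 5000))
  }
  # monotone non-increasing in the observed statistic
  o <- sort(rnorm(100))
  expect_true(all(diff(as.numeric(empirical_pvalues(o, nd))) <= 0))
})

test_that("permuting position order permutes P-values identically", {
  set.seed(31)
  nd <- build_null(rnorm(500), min_size = 100)
  obs <- matrix(rnorm(200), 50, 4)
  perm <- sample(50)
  expect_equal(empirical_pvalues(obs, nd)[perm, ],
               empirical_pvalues(obs[perm, ], nd))
})
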