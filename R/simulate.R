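#' Configuration of a synthetic two-condition probing experiment
#'
#' The generator emulates the structure of real probing data at a
#' desk-friendly scale: per-condition modification states follow the
#' two-state geometric run-length chain (modified stretches of expected
#' length `l_ss`, unmodified of `l_ds`); read coverage is negative binomial
#' (high-coverage regime, mean 5000, moderate overdispersion); event counts
#' are binomial draws at a baseline rate elevated `modified_multiplier`-fold
#' at modified sites of probe-treated samples; replicate variability enters
#' as log-normal jitter on the rates. Setting `modified_multiplier = 1`
#' produces the identically-treated null regime in which treatments and
#' controls are exchangeable.
#'
#' @param n_transcripts Number of transcripts (default 10).
#' @param length Positions per transcript (default 1000).
#' @param l_ss,l_ds Expected modified / unmodified run lengths in the truth
#'   chain (defaults 5 and 20 nt).
#' @param differential_fraction Probability that a truth run of condition 1
#'   is flipped in condition 2, creating UM/MU stretches (default 0.5).
#' @param baseline_rate Unmodified event rate `r0` (default 0.002).
#' @param modified_multiplier Fold elevation `m >= 1` of the event rate at
#'   modified sites in treated samples (default 10).
#' @param coverage_mean,coverage_dispersion Negative binomial coverage law
#'   (defaults mean 5000, size 5).
#' @param n_treatment,n_control,n_denatured Replicates per condition
#'   (defaults 2, 2, 0).
#' @param replicate_noise_sd Standard deviation of the log-normal
#'   per-replicate, per-position rate jitter (default 0.1).
#' @param seed Mandatory integer seed; every draw of the generator is
#'   reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_transcripts = 10, length = 1000, l_ss = 5,
                       l_ds = 20, differential_fraction = 0.5,
                       baseline_rate = 0.002, modified_multiplier = 10,
                       coverage_mean = 5000, coverage_dispersion = 5,
                       n_treatment = 2, n_control = 2, n_denatured = 0,
                       replicate_noise_sd = 0.1, seed) {
  if (missing(seed) || is.na(seed)) {
    stop("a seed is mandatory for reproducible simulation", call. = FALSE)
  }
  stopifnot(n_transcripts >= 1, length >= 1, l_ss >= 1, l_ds >= 1,
            differential_fraction >= 0, differential_fraction <= 1,
            baseline_rate > 0, baseline_rate <= 1, modified_multiplier >= 1,
            coverage_mean > 0, coverage_dispersion > 0, n_treatment >= 1,
            n_control >= 2, n_denatured >= 0, replicate_noise_sd >= 0)
  if (baseline_rate * modified_multiplier > 1) {
    warning("modified rate exceeds 1 and will be clipped", call. = FALSE)
  }
  structure(list(n_transcripts = n_transcripts, length = length,
                 l_ss = l_ss, l_ds = l_ds,
                 differential_fraction = differential_fraction,
                 baseline_rate = baseline_rate,
                 modified_multiplier = modified_multiplier,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 n_treatment = n_treatment, n_control = n_control,
                 n_denatured = n_denatured,
                 replicate_noise_sd = replicate_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one condition-1 state sequence from the 2-state chain (1 = U, 2 = M)
sample_chain <- function(n, l_ss, l_ds) {
  a <- 1 / l_ds
  b <- 1 / l_ss
  pi_m <- a / (a + b)
  s <- integer(n)
  s[1L] <- 1L + (stats::runif(1L) < pi_m)
  if (n > 1L) {
    u <- stats::runif(n)
    for (i in 2:n) {
      s[i] <- if (s[i - 1L] == 1L) {
        if (u[i] < a) 2L else 1L
      } else {
        if (u[i] < b) 1L else 2L
      }
    }
  }
  s
}

#' Simulate the ground-truth modification states
#'
#' Condition-1 states are sampled from the two-state geometric run-length
#' chain. Condition-2 states start as a copy; each maximal run of the
#' condition-1 track is then flipped in condition 2 with probability
#' `differential_fraction`, so that differential (UM/MU) sites come in
#' runs, as the transition model assumes of real structural changes.
#'
#' @param config A [sim_config()].
#' @return A `truth_track` data frame: `transcript`, `position`, `state`
#'   (one of UU, UM, MU, MM).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  letters2 <- c("U", "M")
  out <- vector("list", config$n_transcripts)
  for (i in seq_len(config$n_transcripts)) {
    s1 <- sample_chain(config$length, config$l_ss, config$l_ds)
    r <- rle(s1)
    flip <- stats::runif(length(r$lengths)) < config$differential_fraction
    r2 <- r
    r2$values <- ifelse(flip, 3L - r$values, r$values)
    s2 <- inverse.rle(r2)
    out[[i]] <- data.frame(
      transcript = sprintf("tx%03d", i),
      position = seq_len(config$length),
      state = paste0(letters2[s1], letters2[s2]),
      stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("truth_track", "data.frame"))
}

#' Simulate per-sample count tables for a truth track
#'
#' For each sample, coverage is drawn from the negative binomial coverage
#' law and events from a binomial at the sample's per-position rate:
#' baseline for controls and for unmodified positions, baseline times
#' `modified_multiplier` at positions modified in the sample's condition
#' for treated samples, and the fully modified rate everywhere for
#' denatured samples. Rates receive independent log-normal jitter per
#' sample and position and are clipped to `[0, 1]`.
#'
#' @param truth A [simulate_truth()] track.
#' @param config The same [sim_config()].
#' @return List with `counts` (a [count_table()]), `samples` (a
#'   [as_sample_sheet()] sheet) and `truth`.
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- nrow(truth)
  sheet <- list()
  for (k in 1:2) {
    for (r in seq_len(config$n_treatment)) {
      sheet[[length(sheet) + 1L]] <-
        data.frame(sample_id = sprintf("c%d_t%d", k, r), condition = k,
                   role = "treatment", replicate = r, path = NA_character_)
    }
    for (r in seq_len(config$n_control)) {
      sheet[[length(sheet) + 1L]] <-
        data.frame(sample_id = sprintf("c%d_c%d", k, r), condition = k,
                   role = "control", replicate = r, path = NA_character_)
    }
    for (r in seq_len(config$n_denatured)) {
      sheet[[length(sheet) + 1L]] <-
        data.frame(sample_id = sprintf("c%d_d%d", k, r), condition = k,
                   role = "denatured", replicate = r, path = NA_character_)
    }
  }
  sheet <- as_sample_sheet(do.call(rbind, sheet))

  modified <- cbind(substr(truth$state, 1L, 1L) == "M",
                    substr(truth$state, 2L, 2L) == "M")
  r0 <- config$baseline_rate
  m <- config$modified_multiplier
  cov <- matrix(0L, n, nrow(sheet))
  ev <- matrix(0L, n, nrow(sheet))
  colnames(cov) <- colnames(ev) <- sheet$sample_id
  for (j in seq_len(nrow(sheet))) {
    base <- switch(sheet$role[j],
                   treatment = ifelse(modified[, sheet$condition[j]],
                                      r0 * m, r0),
                   control = rep(r0, n),
                   denatured = rep(r0 * m, n))
    rate <- base * exp(stats::rnorm(n, 0, config$replicate_noise_sd))
    rate <- pmin(pmax(rate, 0), 1)
    cv <- stats::rnbinom(n, size = config$coverage_dispersion,
                         mu = config$coverage_mean)
    cov[, j] <- cv
    ev[, j] <- stats::rbinom(n, cv, rate)
  }
  info <- data.frame(transcript = truth$transcript,
                     position = truth$position,
                     base = sample(c("A", "C", "G", "U"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
  list(counts = count_table(info, cov, ev), samples = sheet, truth = truth)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: [simulate_truth()] followed by [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return List with `counts`, `samples`, `truth`.
#' @export
simulate_dataset <- function(config) {
  simulate_counts(simulate_truth(config), config)
}

#' Write / read a ground-truth track
#'
#' Plain TSV with columns `transcript`, `position`, `state`; round-trips
#' exactly.
#'
#' @param truth A `truth_track`.
#' @param path Output path.
#' @return `path` invisibly (`write_truth`); the track (`read_truth`).
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("transcript", "position", "state") %in% names(truth)))
  if (!all(truth$state %in% c("UU", "UM", "MU", "MM"))) {
    stop("truth states must be UU, UM, MU or MM", call. = FALSE)
  }
  utils::write.table(truth[, c("transcript", "position", "state")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character"))
  if (nrow(df) > 0L && !all(df$state %in% c("UU", "UM", "MU", "MM"))) {
    stop("truth states must be UU, UM, MU or MM", call. = FALSE)
  }
  structure(df, class = c("truth_track", "data.frame"))
}
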