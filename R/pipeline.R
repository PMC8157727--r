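#' Default pipeline configuration
#'
#' Fills the tunable parameters of the full analysis with their defaults.
#' Any subset can be overridden via the `config` argument of
#' [run_pipeline()].
#'
#' @param ... Named overrides of the defaults: `l_ss` (5), `l_ds` (20),
#'   `alpha` (1), `beta` (10), `initial_dist` ("stationary" or "uniform"),
#'   `coverage_threshold` (0), `call_threshold` (0.95), `em` (FALSE),
#'   `denatured_normalize` (FALSE), `den_floor` (1e-3), `den_cap` (10),
#'   `n_bins` (10), `null_min_size` (100), `seed` (1).
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(...) {
  defaults <- list(l_ss = 5, l_ds = 20, alpha = 1, beta = 10,
                   initial_dist = "stationary", coverage_threshold = 0,
                   call_threshold = 0.95, em = FALSE,
                   denatured_normalize = FALSE, den_floor = 1e-3,
                   den_cap = 10, n_bins = 10, null_min_size = 100,
                   seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]])) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  defaults$initial_dist <- match.arg(defaults$initial_dist,
                                     c("stationary", "uniform"))
  stopifnot(defaults$coverage_threshold >= 0,
            defaults$call_threshold > 0, defaults$call_threshold < 1)
  defaults
}

# P-value matrix for one condition: rates -> (denatured normalization) ->
# observed and null log-ratio matrices -> variance stabilization ->
# pooled null -> empirical P-values.
condition_pvalues <- function(tab, sheet, condition, cfg) {
  treatments <- samples_for(sheet, condition, "treatment")
  controls <- samples_for(sheet, condition, "control")
  min_cov <- max(1, cfg$coverage_threshold)
  rates <- lapply(c(treatments, controls), function(id) {
    compute_event_rate(tab, id, min_coverage = min_cov)
  })
  names(rates) <- c(treatments, controls)
  if (isTRUE(cfg$denatured_normalize)) {
    den_ids <- samples_for(sheet, condition, "denatured")
    if (length(den_ids) == 0L) {
      stop("denatured samples required: condition ", condition,
           " has none in the sample sheet", call. = FALSE)
    }
    den_tracks <- lapply(den_ids, function(id) {
      compute_event_rate(tab, id, min_coverage = min_cov)
    })
    den <- den_tracks[[1L]]
    den$rate <- rowMeans(do.call(cbind, lapply(den_tracks, `[[`, "rate")),
                         na.rm = TRUE)
    den$rate[is.nan(den$rate)] <- NA_real_
    rates <- lapply(rates, denatured_normalize, denatured_rates = den,
                    floor = cfg$den_floor, cap = cfg$den_cap)
  }
  cmp <- condition_comparisons(treatments, controls)
  obs <- ldr_matrix(rates, cmp$tc)
  nul <- ldr_matrix(rates, cmp$null)
  vm <- fit_variance_model(nul$ldr, nul$n, n_bins = cfg$n_bins)
  obs_s <- stabilize(obs, vm)
  nul_s <- stabilize(nul, vm)
  nd <- build_null(nul_s, min_size = cfg$null_min_size)
  list(pvalues = empirical_pvalues(obs_s, nd), null = nd,
       variance_model = vm, observed = obs_s)
}

#' Run the full differential reactivity pipeline
#'
#' Executes every stage in order: event rates (with optional denatured
#' normalization), log rate-ratios for all treatment-control and
#' control-control comparisons, coverage-dependent variance stabilization,
#' empirical P-values against the pooled control-control null, segmentation
#' into decodable stretches, forward-backward posterior decoding under the
#' four-state beta-uniform mixture HMM, and DRN calling. The pipeline is
#' deterministic given fixed inputs and configuration.
#'
#' @param samples A `sample_sheet` or the path of one.
#' @param counts A [count_table()] or the path(s) of count table TSVs.
#'   When omitted (`NULL`) the tables named in the sheet's `path` column
#'   are read and combined.
#' @param config Named list of overrides, see [pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `posteriors.tsv`, `pvalues_cond1.tsv`, `pvalues_cond2.tsv`,
#'   `null_cond1.tsv`, `null_cond2.tsv` and `manifest.tsv`.
#' @return A `diffprobe_run`: list with `posteriors` (full-length track,
#'   `NA` outside decodable segments, with calls), `pvalues`, `nulls`,
#'   `variance_models`, `segments`, `emission`, `config`.
#' @export
run_pipeline <- function(samples, counts = NULL, config = list(),
                         out_dir = NULL) {
  cfg <- pipeline_config(config)
  sheet <- if (is.character(samples)) read_sample_sheet(samples) else
    as_sample_sheet(as.data.frame(samples))
  tab <- if (is.null(counts)) {
    paths <- unique(sheet$path[!is.na(sheet$path)])
    if (length(paths) == 0L) {
      stop("no count tables: pass `counts` or fill the sheet's path column",
           call. = FALSE)
    }
    read_count_table(paths, samples = sheet)
  } else if (is.character(counts)) {
    read_count_table(counts, samples = sheet)
  } else {
    counts
  }
  stopifnot(inherits(tab, "count_table"))
  if (!all(sheet$sample_id %in% table_samples(tab))) {
    stop("unknown sample column: ",
         paste(setdiff(sheet$sample_id, table_samples(tab)), collapse = ", "),
         " absent from count table", call. = FALSE)
  }
  if (isTRUE(cfg$denatured_normalize) &&
      !any(sheet$role == "denatured")) {
    stop("denatured samples required for denatured normalization",
         call. = FALSE)
  }

  conds <- lapply(1:2, function(k) condition_pvalues(tab, sheet, k, cfg))
  pvals <- list(cond1 = conds[[1L]]$pvalues, cond2 = conds[[2L]]$pvalues)
  segs <- segment_positions(tab, pvals, cfg$coverage_threshold)
  trans <- build_transition_matrix(cfg$l_ss, cfg$l_ds,
                                   initial = cfg$initial_dist)
  emis <- emission_model(cfg$alpha, cfg$beta)
  em_fit <- NULL
  if (isTRUE(cfg$em) && length(segs) > 0L) {
    em_fit <- fit_beta_em(segs, trans, alpha_init = cfg$alpha,
                          beta_init = cfg$beta)
    emis <- emission_model(em_fit$alpha, em_fit$beta)
  }

  n <- nrow(tab$info)
  post <- data.frame(transcript = tab$info$transcript,
                     position = tab$info$position,
                     base = tab$info$base,
                     P_UU = NA_real_, P_UM = NA_real_, P_MU = NA_real_,
                     P_MM = NA_real_, stringsAsFactors = FALSE)
  for (seg in segs) {
    dec <- forward_backward(seg, trans = trans, emis = emis)
    post[seg$rows, c("P_UU", "P_UM", "P_MU", "P_MM")] <-
      dec[, c("P_UU", "P_UM", "P_MU", "P_MM")]
  }
  post$P_diff <- post$P_UM + post$P_MU
  class(post) <- c("posterior_track", "data.frame")
  post <- call_drns(post, cfg$call_threshold)

  run <- structure(list(posteriors = post, pvalues = pvals,
                        nulls = lapply(conds, `[[`, "null"),
                        variance_models = lapply(conds, `[[`,
                                                 "variance_model"),
                        segments = segs, emission = emis, em_fit = em_fit,
                        config = cfg),
                   class = "diffprobe_run")
  if (!is.null(out_dir)) write_run(run, tab, out_dir)
  run
}

#' @export
print.diffprobe_run <- function(x, ...) {
  p <- x$posteriors
  ok <- !is.na(p$P_diff)
  cat("Differential reactivity run\n")
  cat(sprintf("  %d positions, %d decoded in %d segment(s)\n",
              nrow(p), sum(ok), length(x$segments)))
  cat(sprintf("  DRNs (P_diff >= %.2f): %d\n", x$config$call_threshold,
              sum(p$drn)))
  if (sum(ok) > 0L) {
    cat(sprintf("  max P_diff: %.4f\n", max(p$P_diff[ok])))
  }
  invisible(x)
}

write_run <- function(run, tab, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_posteriors(run$posteriors, file.path(out_dir, "posteriors.tsv"))
  for (k in 1:2) {
    pv <- as.data.frame(run$pvalues[[k]])
    pv <- cbind(tab$info[, c("transcript", "position")], pv)
    utils::write.table(pv, file.path(out_dir,
                                     sprintf("pvalues_cond%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(stabilized_null_ldr = run$nulls[[k]]$values),
      file.path(out_dir, sprintf("null_cond%d.tsv", k)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- run$config
  manifest <- data.frame(
    key = c("package", "version", names(cfg)),
    value = c("diffprobe",
              as.character(utils::packageVersion("diffprobe")),
              vapply(cfg, function(v) paste(as.character(v), collapse = ","),
                     character(1L))))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

hist_table <- function(x, breaks) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  data.frame(bin_lo = h$breaks[-length(h$breaks)],
             bin_hi = h$breaks[-1L], count = h$counts)
}

#' Diagnostic summaries of a completed run
#'
#' Writes histogram tables of the stabilized null log-ratios and of the
#' observed P-values per condition, plus a summary flagging the saturation
#' signature — a secondary peak of P-values near 1, which arises when the
#' treated sample is so heavily modified that unmodified positions show
#' abnormally few events. Saturated positions are assigned low modification
#' probability by the emission model, so the flag is informational.
#'
#' @param run A [run_pipeline()] result.
#' @param out_dir Directory for the diagnostic TSVs.
#' @param n_bins Histogram bins for the P-value tables (default 20).
#' @return Invisibly, a list with the histogram tables and the summary.
#' @export
diagnostics <- function(run, out_dir, n_bins = 20) {
  if (!inherits(run, "diffprobe_run")) {
    stop("diagnostics needs a completed run object", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(pvalue_hist = list(), null_hist = list())
  summary <- data.frame()
  for (k in 1:2) {
    p <- as.numeric(run$pvalues[[paste0("cond", k)]])
    p <- p[!is.na(p)]
    ph <- hist_table(p, breaks = seq(0, 1, length.out = n_bins + 1L))
    utils::write.table(ph, file.path(out_dir,
                                     sprintf("pvalue_hist_cond%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    nh <- hist_table(run$nulls[[k]]$values, breaks = 30)
    utils::write.table(nh, file.path(out_dir,
                                     sprintf("null_ldr_hist_cond%d.tsv", k)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- mean(p > 1 - 1 / n_bins)
    bottom <- mean(p <= 1 / n_bins)
    summary <- rbind(summary, data.frame(
      condition = k, n_pvalues = length(p),
      frac_low_bin = bottom, frac_high_bin = top,
      saturation_flag = top > 2 / n_bins))
    out$pvalue_hist[[k]] <- ph
    out$null_hist[[k]] <- nh
  }
  utils::write.table(summary, file.path(out_dir, "diagnostics_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out$summary <- summary
  invisible(out)
}
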