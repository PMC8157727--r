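#' Per-nucleotide count tables
#'
#' A count table holds, for every transcript position, the read coverage and
#' the event count (reverse-transcription drop-offs for stop-based protocols,
#' mutations for mutational-profiling protocols) of every sample. It is the
#' raw input of the whole pipeline: no reactivity normalization is applied
#' upstream, the model consumes counts directly.
#'
#' @param info Data frame with columns `transcript` (character), `position`
#'   (1-based integer, strictly increasing within each transcript) and
#'   optionally `base` (`A`, `C`, `G`, `U`, `T` or `N`).
#' @param coverage,events Integer matrices, one row per row of `info`, one
#'   column per sample (column names are the sample ids), with
#'   `0 <= events <= coverage` everywhere.
#'
#' @return A `count_table` object.
#' @export
count_table <- function(info, coverage, events) {
  stopifnot(is.data.frame(info),
            all(c("transcript", "position") %in% names(info)))
  if (!"base" %in% names(info)) info$base <- NA_character_
  info <- info[, c("transcript", "position", "base")]
  info$transcript <- as.character(info$transcript)
  info$position <- as.integer(info$position)
  coverage <- as.matrix(coverage)
  events <- as.matrix(events)
  storage.mode(coverage) <- "integer"
  storage.mode(events) <- "integer"
  if (nrow(info) == 0L) stop("count table has no records", call. = FALSE)
  if (nrow(coverage) != nrow(info) || nrow(events) != nrow(info) ||
      ncol(coverage) != ncol(events)) {
    stop("coverage/events dimensions do not match the position table",
         call. = FALSE)
  }
  if (is.null(colnames(coverage)) ||
      !identical(colnames(coverage), colnames(events))) {
    stop("coverage and events must carry identical sample column names",
         call. = FALSE)
  }
  ord <- order(info$transcript, info$position)
  info <- info[ord, , drop = FALSE]
  coverage <- coverage[ord, , drop = FALSE]
  events <- events[ord, , drop = FALSE]
  rownames(info) <- NULL

  if (anyNA(coverage) || anyNA(events)) {
    stop("counts must be non-missing integers", call. = FALSE)
  }
  if (any(coverage < 0L) || any(events < 0L)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bad <- which(events > coverage)
  if (length(bad) > 0L) {
    i <- ((bad[1L] - 1L) %% nrow(info)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(info)) + 1L
    stop(sprintf(
      "events exceed coverage at transcript %s position %d (sample %s)",
      info$transcript[i], info$position[i], colnames(coverage)[j]),
      call. = FALSE)
  }
  dup <- duplicated(paste(info$transcript, info$position))
  if (any(dup)) {
    stop("duplicate position within transcript ",
         info$transcript[dup][1L], call. = FALSE)
  }
  structure(list(info = info, coverage = coverage, events = events),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$info), "positions,",
      length(unique(x$info$transcript)), "transcript(s),",
      ncol(x$coverage), "sample(s)\n")
  cat("  samples:", paste(colnames(x$coverage), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) c(nrow(x$info), ncol(x$coverage))

#' Sample ids present in a count table
#' @param x A `count_table`.
#' @return Character vector of sample ids.
#' @export
table_samples <- function(x) colnames(x$coverage)

#' Read a per-nucleotide count table from TSV
#'
#' Expected layout: a header row with `transcript`, `position`, optionally
#' `base`, followed by one `<sample_id>_cov` / `<sample_id>_events` column
#' pair per sample. Any other column is rejected.
#'
#' @param path Path to a tab-separated file. A character vector of paths is
#'   allowed; the tables are concatenated row-wise (they must carry the same
#'   samples and disjoint transcript/position sets).
#' @param samples Optional character vector (or a `sample_sheet`): every
#'   listed sample must be present in the table.
#' @return A [count_table()].
#' @export
read_count_table <- function(path, samples = NULL) {
  if (inherits(samples, "sample_sheet")) samples <- samples$sample_id
  if (length(path) > 1L) {
    parts <- lapply(path, read_count_table, samples = samples)
    return(do.call(rbind_count_tables, parts))
  }
  if (!file.exists(path)) stop("count table not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("no records in count table: ", path,
                             call. = FALSE))
  if (nrow(df) == 0L) stop("no records in count table: ", path, call. = FALSE)
  if (!all(c("transcript", "position") %in% names(df))) {
    stop("count table must have 'transcript' and 'position' columns",
         call. = FALSE)
  }
  meta <- intersect(c("transcript", "position", "base"), names(df))
  rest <- setdiff(names(df), meta)
  is_cov <- grepl("_cov$", rest)
  is_ev <- grepl("_events$", rest)
  if (!all(is_cov | is_ev)) {
    stop("unknown sample column(s): ",
         paste(rest[!(is_cov | is_ev)], collapse = ", "), call. = FALSE)
  }
  ids_cov <- sub("_cov$", "", rest[is_cov])
  ids_ev <- sub("_events$", "", rest[is_ev])
  if (!setequal(ids_cov, ids_ev)) {
    stop("unpaired sample columns: every sample needs both _cov and _events",
         call. = FALSE)
  }
  ids <- ids_cov
  if (!is.null(samples) && !all(samples %in% ids)) {
    stop("unknown sample column: sheet sample(s) ",
         paste(setdiff(samples, ids), collapse = ", "),
         " absent from count table", call. = FALSE)
  }
  num <- df[, c(paste0(ids, "_cov"), paste0(ids, "_events")), drop = FALSE]
  if (!all(vapply(num, is.numeric, logical(1L))) ||
      any(vapply(num, function(v) any(v != floor(v), na.rm = TRUE),
                 logical(1L)))) {
    stop("counts must be integers", call. = FALSE)
  }
  cov <- as.matrix(df[, paste0(ids, "_cov"), drop = FALSE])
  ev <- as.matrix(df[, paste0(ids, "_events"), drop = FALSE])
  colnames(cov) <- colnames(ev) <- ids
  info <- df[, meta, drop = FALSE]
  count_table(info, cov, ev)
}

#' Write a count table to TSV
#'
#' Inverse of [read_count_table()]: `read_count_table(write_count_table(x))`
#' reproduces `x` exactly (counts are integers).
#'
#' @param x A `count_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  ids <- table_samples(x)
  out <- x$info
  for (id in ids) {
    out[[paste0(id, "_cov")]] <- x$coverage[, id]
    out[[paste0(id, "_events")]] <- x$events[, id]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

rbind_count_tables <- function(...) {
  parts <- list(...)
  ids <- table_samples(parts[[1L]])
  for (p in parts) {
    if (!identical(table_samples(p), ids)) {
      stop("count tables carry different samples; cannot combine",
           call. = FALSE)
    }
  }
  count_table(do.call(rbind, lapply(parts, `[[`, "info")),
              do.call(rbind, lapply(parts, `[[`, "coverage")),
              do.call(rbind, lapply(parts, `[[`, "events")))
}
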