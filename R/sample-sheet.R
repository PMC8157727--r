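#' Read and validate a sample sheet
#'
#' The sample sheet describes the experimental design of a two-condition
#' structure probing experiment: which sequencing samples belong to which
#' probing condition, whether each is a probe-treated sample, an untreated
#' control, or a chemically denatured control (used for SHAPE-MaP
#' normalization), and the replicate number.
#'
#' At least two control replicates per condition are required, because the
#' null distribution that calibrates the empirical P-values is built from
#' control-control comparisons; with a single control no such comparison
#' exists.
#'
#' @param path Path to a CSV or TSV file with header columns
#'   `sample_id`, `condition`, `role`, `replicate`, `path`. The separator is
#'   sniffed from the header line. `condition` must be 1 or 2; `role` one of
#'   `treatment`, `control`, `denatured`; `replicate` a positive integer.
#'   `path` may be empty when all counts live in a single count table.
#'
#' @return A `sample_sheet`, a validated data frame with the five columns
#'   above (roles lower-cased, condition and replicate integer).
#'
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,condition,role,replicate,path",
#'              "c1_t1,1,treatment,1,", "c1_t2,1,treatment,2,",
#'              "c1_c1,1,control,1,",   "c1_c2,1,control,2,",
#'              "c2_t1,2,treatment,1,", "c2_t2,2,treatment,2,",
#'              "c2_c1,2,control,1,",   "c2_c2,2,control,2,"), tf)
#' read_sample_sheet(tf)
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    stop("sample sheet not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE,
                          colClasses = "character")
  as_sample_sheet(df)
}

#' Coerce a data frame to a validated sample sheet
#'
#' @param df A data frame with columns `sample_id`, `condition`, `role`,
#'   `replicate` and optionally `path`.
#' @return A `sample_sheet` data frame.
#' @export
as_sample_sheet <- function(df) {
  required <- c("sample_id", "condition", "role", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"path" %in% names(df)) df$path <- NA_character_
  df <- df[, c(required, "path")]

  df$sample_id <- as.character(df$sample_id)
  df$condition <- suppressWarnings(as.integer(df$condition))
  df$role <- tolower(trimws(as.character(df$role)))
  df$replicate <- suppressWarnings(as.integer(df$replicate))
  df$path[!is.na(df$path) & !nzchar(df$path)] <- NA_character_

  if (nrow(df) == 0L) stop("sample sheet has no samples", call. = FALSE)
  if (anyNA(df$condition) || !all(df$condition %in% c(1L, 2L))) {
    stop("condition must be 1 or 2 for every sample", call. = FALSE)
  }
  roles <- c("treatment", "control", "denatured")
  if (!all(df$role %in% roles)) {
    stop("role must be one of ", paste(roles, collapse = ", "), call. = FALSE)
  }
  if (anyNA(df$replicate) || any(df$replicate < 1L)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  key <- paste(df$condition, df$role, df$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, role, replicate) triple: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  for (k in 1:2) {
    n_treat <- sum(df$condition == k & df$role == "treatment")
    n_ctrl <- sum(df$condition == k & df$role == "control")
    if (n_treat < 1L) {
      stop("condition ", k, " has no treatment samples", call. = FALSE)
    }
    if (n_ctrl < 2L) {
      stop("insufficient controls: condition ", k, " has ", n_ctrl,
           " control sample(s); at least 2 are required to form a null ",
           "distribution", call. = FALSE)
    }
  }
  structure(df, class = c("sample_sheet", "data.frame"))
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat("Sample sheet:", nrow(x), "samples\n")
  for (k in 1:2) {
    cat(sprintf("  condition %d: %d treatment, %d control, %d denatured\n", k,
                sum(x$condition == k & x$role == "treatment"),
                sum(x$condition == k & x$role == "control"),
                sum(x$condition == k & x$role == "denatured")))
  }
  print.data.frame(x, ...)
  invisible(x)
}

samples_for <- function(sheet, condition, role) {
  sheet$sample_id[sheet$condition == condition & sheet$role == role]
}
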