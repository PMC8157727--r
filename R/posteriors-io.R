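#' Write posterior tracks to TSV or bedGraph
#'
#' The TSV format carries one row per position with all four state
#' posteriors, the differential posterior and the call label, at full
#' double precision (round-trips through [read_posteriors()] to 1e-12).
#' The bedGraph format emits one file per requested posterior channel,
#' converting the 1-based inclusive transcript positions to 0-based
#' half-open intervals; rows with missing posteriors are omitted.
#'
#' @param track A `posterior_track` (typically after [call_drns()]). A
#'   `base` column is included in the TSV when present.
#' @param path Output path. For bedGraph, used as a prefix:
#'   `<path>.<channel>.bedgraph`.
#' @param format `"tsv"` (default) or `"bedgraph"`.
#' @param channels Posterior channels for bedGraph output
#'   (default `"P_diff"`).
#' @return The path(s) written, invisibly.
#' @export
write_posteriors <- function(track, path, format = c("tsv", "bedgraph"),
                             channels = "P_diff") {
  format <- match.arg(format)
  pcols <- c("P_UU", "P_UM", "P_MU", "P_MM")
  stopifnot(all(pcols %in% names(track)))
  if (!"P_diff" %in% names(track)) {
    track$P_diff <- track$P_UM + track$P_MU
  }
  if (format == "tsv") {
    if (!"base" %in% names(track)) track$base <- NA_character_
    if (!"call" %in% names(track)) track$call <- NA_character_
    cols <- c("transcript", "position", "base", pcols, "P_diff", "call")
    extra <- intersect(c("drn", "direction"), names(track))
    out <- as.data.frame(track)[, c(cols, extra)]
    for (cc in c(pcols, "P_diff")) {
      out[[cc]] <- sprintf("%.17g", out[[cc]])
      out[[cc]][out[[cc]] == "NA"] <- NA
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  stopifnot(all(channels %in% names(track)))
  written <- character(0L)
  for (ch in channels) {
    f <- paste0(path, ".", ch, ".bedgraph")
    keep <- !is.na(track[[ch]])
    df <- data.frame(track$transcript[keep],
                     track$position[keep] - 1L,   # 0-based half-open
                     track$position[keep],
                     sprintf("%.17g", track[[ch]][keep]))
    con <- file(f, "w")
    writeLines(sprintf("track type=bedGraph name=%s", ch), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    written <- c(written, f)
  }
  invisible(written)
}

#' @rdname write_posteriors
#' @param path_tsv Path of a TSV written by `write_posteriors()`.
#' @export
read_posteriors <- function(path_tsv) {
  df <- utils::read.table(path_tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA")
  class(df) <- c("posterior_track", "data.frame")
  df
}
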