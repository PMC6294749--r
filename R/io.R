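# Plain-text track and table I/O. BedGraph and BED coordinates are 0-based
# half-open throughout, matching the formats' definitions.

#' Write a depth track as BedGraph
#'
#' Runs of equal depth are collapsed into single records; zero-depth runs
#' are written too, so the track round-trips exactly.
#'
#' @param track a depth track (named list of integer vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in names(track)) {
    r <- rle(track[[sc]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%d", sc, start, end,
                       as.integer(r$values)), con)
  }
  invisible(path)
}

#' Read a BedGraph into a depth track
#'
#' @param path BedGraph path.
#' @param scaffold_lengths optional named lengths; defaults to the largest
#'   end coordinate seen per scaffold. Uncovered positions get depth 0.
#' @return a depth track.
#' @export
read_bedgraph <- function(path, scaffold_lengths = NULL) {
  df <- utils::read.table(path, sep = "\t", col.names = c("scaffold",
                                                          "start", "end",
                                                          "depth"))
  if (is.null(scaffold_lengths))
    scaffold_lengths <- vapply(split(df$end, df$scaffold), max, numeric(1))
  out <- lapply(scaffold_lengths, function(n) integer(n))
  for (i in seq_len(nrow(df))) {
    sc <- df$scaffold[i]
    out[[sc]][(df$start[i] + 1L):df$end[i]] <- df$depth[i]
  }
  out
}

#' Write candidate intervals as BED
#'
#' Columns: scaffold, start, end, name, score (the enrichment score,
#' rounded to 4 decimals).
#'
#' @param intervals a scored interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_candidate_bed <- function(intervals, path) {
  lines <- sprintf("%s\t%d\t%d\tinterval_%d\t%.4f",
                   intervals$scaffold, intervals$start, intervals$end,
                   seq_len(nrow(intervals)), intervals$score)
  writeLines(lines, path)
  invisible(path)
}

#' Write a profile summary TSV
#'
#' One-row table: modal depths, limits and adjustment factor of a profile.
#'
#' @param profile a `sex_coverage_profile`.
#' @param limits a `coverage_limits`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, limits, path) {
  df <- data.frame(n_females = profile$n_females, n_males = profile$n_males,
                   modal_f = profile$modal_f, modal_m = profile$modal_m,
                   min_f = limits$min_f, max_f = limits$max_f,
                   min_m = limits$min_m, max_m = limits$max_m,
                   adjustment = profile$adjustment)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
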