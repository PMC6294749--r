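# The W-discovery interval scan: valid-base masking, fixed-valid-base
# interval construction, log2 enrichment scoring with the zero-male
# substitution, filtering and candidate aggregation.

#' Valid-base mask from pooled coverage and limits
#'
#' A base is *valid* iff, writing `Cf`/`Cm` for the pooled female/male depth,
#' both upper conditions hold and at least one lower condition holds:
#' `(Cf < max_f AND Cm < max_m) AND (Cf > min_f OR Cm > min_m)`. All four
#' inequalities are strict. The upper limits skip collapsed repeats (depth
#' far above single copy in both sexes); the lower limits drop bases too
#' thinly sampled in both sexes for the ratio to be informative.
#'
#' @param profile a `sex_coverage_profile`.
#' @param limits a `coverage_limits` from [derive_limits()].
#' @return named list of logical vectors (TRUE = valid), one per scaffold.
#' @export
valid_mask <- function(profile, limits) {
  stopifnot(inherits(profile, "sex_coverage_profile"),
            inherits(limits, "coverage_limits"))
  out <- lapply(names(profile$female_track), function(sc) {
    cf <- profile$female_track[[sc]]
    cm <- profile$male_track[[sc]]
    (cf < limits$max_f & cm < limits$max_m) &
      (cf > limits$min_f | cm > limits$min_m)
  })
  names(out) <- names(profile$female_track)
  out
}

#' Partition each scaffold into intervals of ~V valid bases
#'
#' Scanning left to right within a scaffold, an interval closes as soon as it
#' has accumulated `V` valid bases; the final interval of a scaffold may
#' close at the scaffold end with fewer. Intervals never span scaffolds,
#' never overlap, and jointly cover every valid base exactly once. Reported
#' boundaries are trimmed to the first/last valid base each interval
#' contains, so `span` reflects assayable sequence. Mean female and (raw,
#' unadjusted) male depths are computed over the valid bases only.
#'
#' @param profile a `sex_coverage_profile`.
#' @param mask a valid-base mask from [valid_mask()].
#' @param V target number of valid bases per interval (>= 1).
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open, trimmed), `span`, `n_valid`, `mean_f`, `mean_m` (raw male
#'   mean), plus placeholder columns `mean_m_adj`, `score`, `zero_male`
#'   filled by [score_intervals()].
#' @export
scan_intervals <- function(profile, mask, V = 1000) {
  stopifnot(V >= 1)
  res <- lapply(names(mask), function(sc) {
    m <- mask[[sc]]
    vidx <- which(m)
    if (length(vidx) == 0) return(NULL)
    grp <- (seq_along(vidx) - 1L) %/% as.integer(V)
    first <- vidx[!duplicated(grp)]
    last <- vidx[!duplicated(grp, fromLast = TRUE)]
    n_valid <- tabulate(grp + 1L)
    f <- as.numeric(profile$female_track[[sc]][vidx])
    mm <- as.numeric(profile$male_track[[sc]][vidx])
    data.frame(scaffold = sc,
               start = first - 1L,
               end = last,
               span = last - first + 1L,
               n_valid = n_valid,
               mean_f = as.vector(rowsum(f, grp)) / n_valid,
               mean_m = as.vector(rowsum(mm, grp)) / n_valid)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), span = integer(), n_valid = integer(),
                      mean_f = numeric(), mean_m = numeric())
  res$mean_m_adj <- rep(NA_real_, nrow(res))
  res$score <- rep(NA_real_, nrow(res))
  res$zero_male <- rep(NA, nrow(res))
  rownames(res) <- NULL
  res
}

#' Enrichment scores for scanned intervals
#'
#' The enrichment score of an interval is
#' `log2(mean_f / (adjustment x mean_m))`, with the male mean first scaled
#' onto the female depth scale by `adjustment` (see [adjustment_factor()]).
#' When an interval's raw male mean is exactly zero the log ratio is
#' undefined; the male coverage estimate is then replaced by the depth
#' contribution of half of one aligned read, `(read_length / 2) / span`,
#' and the interval's `zero_male` flag is set. A valid interval cannot have
#' both means zero (every valid base exceeds one of the lower limits).
#'
#' @param intervals data.frame from [scan_intervals()].
#' @param adjustment male-coverage scaling factor (> 0).
#' @param read_length read length in bp used for the zero-male substitution.
#' @return the intervals with `mean_m_adj`, `score` and `zero_male` filled.
#' @export
score_intervals <- function(intervals, adjustment, read_length = 125) {
  stopifnot(adjustment > 0, read_length >= 1)
  if (nrow(intervals) == 0) return(intervals)
  if (any(intervals$mean_f == 0 & intervals$mean_m == 0))
    stop("interval with zero coverage in both sexes: not a valid interval")
  zero <- intervals$mean_m == 0
  mm <- ifelse(zero, (read_length / 2) / intervals$span, intervals$mean_m)
  intervals$mean_m_adj <- adjustment * mm
  intervals$score <- log2(intervals$mean_f / intervals$mean_m_adj)
  intervals$zero_male <- zero
  intervals
}

#' Drop short or valid-base-poor intervals
#'
#' Keeps intervals with `span >= min_span` and `n_valid >= min_valid`
#' (both boundaries inclusive); order is preserved. Short intervals arise at
#' scaffold ends or on short scaffolds, where the valid-base target cannot
#' be met and the mean estimates are unstable.
#'
#' @param intervals scored intervals.
#' @param min_span minimum interval span in bp.
#' @param min_valid minimum valid-base count.
#' @return the surviving subset, a data.frame.
#' @export
filter_intervals <- function(intervals, min_span = 500, min_valid = 200) {
  intervals[intervals$span >= min_span & intervals$n_valid >= min_valid, ,
            drop = FALSE]
}

#' Call candidate female-specific intervals and aggregate a report
#'
#' Candidates are intervals whose enrichment score strictly exceeds
#' `threshold`. The report aggregates per-scaffold counts, the total
#' candidate span, the number of scaffolds carrying two or more candidate
#' intervals, and the number of candidates with zero male reads.
#'
#' @param intervals filtered, scored intervals.
#' @param threshold minimum (exclusive) enrichment score.
#' @return a `candidate_report`: list with `intervals` (the candidates),
#'   `per_scaffold` (data.frame scaffold/n), `n_intervals`, `n_scaffolds`,
#'   `total_span`, `n_scaffolds_multi`, `n_zero_male`.
#' @export
call_candidates <- function(intervals, threshold = 2) {
  cand <- intervals[!is.na(intervals$score) & intervals$score > threshold, ,
                    drop = FALSE]
  per <- as.data.frame(table(scaffold = cand$scaffold),
                       stringsAsFactors = FALSE)
  names(per) <- c("scaffold", "n")
  per <- per[per$n > 0, , drop = FALSE]
  structure(list(intervals = cand,
                 per_scaffold = per,
                 n_intervals = nrow(cand),
                 n_scaffolds = nrow(per),
                 total_span = sum(cand$span),
                 n_scaffolds_multi = sum(per$n >= 2),
                 n_zero_male = sum(cand$zero_male)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf(paste0("candidate_report: %d candidate intervals on %d ",
                     "scaffolds (%d with >= 2), %d bp total, ",
                     "%d with zero male reads\n"),
              x$n_intervals, x$n_scaffolds, x$n_scaffolds_multi,
              x$total_span, x$n_zero_male))
  invisible(x)
}

#' Run the full W-discovery scan on a sex coverage profile
#'
#' Convenience wrapper chaining [derive_limits()], [valid_mask()],
#' [scan_intervals()], [score_intervals()], [filter_intervals()] and
#' [call_candidates()] at the standard settings.
#'
#' @param profile a `sex_coverage_profile`.
#' @param V valid bases per interval.
#' @param threshold candidate score threshold (exclusive).
#' @param min_span,min_valid interval filters.
#' @param read_length read length for the zero-male substitution.
#' @return list with `limits`, `intervals` (all filtered, scored intervals)
#'   and `report` (the `candidate_report`).
#' @export
scan_w_candidates <- function(profile, V = 1000, threshold = 2,
                              min_span = 500, min_valid = 200,
                              read_length = 125) {
  limits <- derive_limits(profile$modal_f, profile$modal_m)
  mask <- valid_mask(profile, limits)
  iv <- scan_intervals(profile, mask, V = V)
  iv <- score_intervals(iv, profile$adjustment, read_length = read_length)
  iv <- filter_intervals(iv, min_span = min_span, min_valid = min_valid)
  list(limits = limits, intervals = iv,
       report = call_candidates(iv, threshold = threshold))
}
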