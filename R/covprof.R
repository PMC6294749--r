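# Per-base depth from alignments, sex pooling, modal coverage and limits.

#' Per-base read depth from a coordinate-sorted SAM/BAM file
#'
#' Computes depth over every reference base. With `apply_filters = TRUE`
#' (the default) records that are unmapped, secondary (0x100) or
#' supplementary (0x800) are excluded — jointly the flag mask 2308 — as are
#' records soft- or hard-clipped at *both* ends of the read. Depth counts
#' aligned reference-consuming positions (CIGAR M/=/X/D); inserted and
#' clipped bases never contribute.
#'
#' @param path a SAM (`.sam`) or BAM file with a header; must be
#'   coordinate-sorted.
#' @param apply_filters logical; disable to count every mapped record.
#' @return a depth track: named list of integer vectors, one per header
#'   reference sequence, one entry per base.
#' @export
depth_from_alignments <- function(path, apply_filters = TRUE) {
  bam <- as_bam(path)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  targets <- hdr$targets
  if (length(targets) == 0)
    stop("alignment file has no @SQ header lines")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = if (apply_filters)
                                   FALSE else NA,
                                 isSupplementaryAlignment = if (apply_filters)
                                   FALSE else NA)
  param <- Rsamtools::ScanBamParam(flag = flag, what = character(0))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (apply_filters) {
    cig <- GenomicAlignments::cigar(aln)
    both <- grepl("^[0-9]+[SH]", cig) & grepl("[0-9]+[SH]$", cig)
    aln <- aln[!both]
  }
  cov <- GenomicAlignments::coverage(aln)
  out <- lapply(names(targets), function(sc) {
    if (sc %in% names(cov)) as.integer(cov[[sc]])[seq_len(targets[[sc]])]
    else integer(targets[[sc]])
  })
  names(out) <- names(targets)
  out
}

# Convert SAM input to an (indexed) BAM; verify header and coordinate order.
as_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    lines <- readLines(path, n = 50L)
    if (!any(startsWith(lines, "@SQ")))
      stop("headerless SAM input: no @SQ lines found")
    hd <- grep("^@HD", lines, value = TRUE)
    if (length(hd) && grepl("SO:", hd[1]) && !grepl("SO:coordinate", hd[1]))
      stop("alignment file is not coordinate-sorted (header SO is '",
           sub(".*SO:(\\S+).*", "\\1", hd[1]), "')")
    dest <- tempfile(fileext = ".bam")
    bam <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                            overwrite = TRUE, indexDestination = TRUE)
    check_sorted(bam)
    bam
  } else {
    check_sorted(path)
    path
  }
}

check_sorted <- function(bam) {
  p <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    what = c("rname", "pos"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  pos <- split(x$pos, x$rname)
  if (any(vapply(pos, is.unsorted, logical(1), na.rm = TRUE)))
    stop("alignment records are not coordinate-sorted")
  invisible(TRUE)
}

#' Pool per-individual depth tracks by sex
#'
#' Sums depth per base across all individuals of each sex and returns a
#' sex coverage profile holding the two pooled tracks, the modal nonzero
#' depth of each, and the male-coverage adjustment factor.
#'
#' @param tracks list of depth tracks (as returned by [simulate_depth()] or
#'   [depth_from_alignments()]); all must cover identical scaffolds.
#' @param sexes character vector, one of `"female"`/`"male"` per track.
#' @param adjustment_method `"modal"` (default): adjustment is
#'   `modal_f / modal_m`; `"mean"`: ratio of genome-wide mean depths.
#' @return an object of class `sex_coverage_profile` with elements
#'   `female_track`, `male_track`, `n_females`, `n_males`, `modal_f`,
#'   `modal_m`, `adjustment`.
#' @export
merge_by_sex <- function(tracks, sexes, adjustment_method = "modal") {
  stopifnot(length(tracks) == length(sexes))
  sexes <- match.arg(sexes, c("female", "male"), several.ok = TRUE)
  if (!any(sexes == "female") || !any(sexes == "male"))
    stop("need at least one individual of each sex to form a coverage ratio")
  ref <- lapply(tracks[[1]], length)
  for (t in tracks) {
    if (!identical(names(t), names(ref)) ||
        !identical(lapply(t, length), ref))
      stop("tracks cover mismatched scaffold sets or lengths")
  }
  pool <- function(sub) {
    out <- lapply(ref, function(n) integer(n))
    for (t in sub) for (sc in names(out)) out[[sc]] <- out[[sc]] + t[[sc]]
    out
  }
  sex_coverage_profile(pool(tracks[sexes == "female"]),
                       pool(tracks[sexes == "male"]),
                       n_females = sum(sexes == "female"),
                       n_males = sum(sexes == "male"),
                       adjustment_method = adjustment_method)
}

#' Construct a sex coverage profile from pooled tracks
#'
#' @param female_track,male_track pooled depth tracks (per-base sums over
#'   all individuals of the sex); identical scaffold sets and lengths.
#' @param n_females,n_males individual counts behind each pool.
#' @inheritParams merge_by_sex
#' @return a `sex_coverage_profile`; see [merge_by_sex()].
#' @export
sex_coverage_profile <- function(female_track, male_track,
                                 n_females, n_males,
                                 adjustment_method = "modal") {
  if (!identical(names(female_track), names(male_track)) ||
      !identical(lapply(female_track, length), lapply(male_track, length)))
    stop("female and male tracks cover mismatched scaffolds")
  adjustment_method <- match.arg(adjustment_method, c("modal", "mean"))
  prof <- structure(list(female_track = female_track,
                         male_track = male_track,
                         n_females = n_females, n_males = n_males,
                         modal_f = modal_coverage(female_track),
                         modal_m = modal_coverage(male_track),
                         adjustment = NA_real_,
                         adjustment_method = adjustment_method),
                    class = "sex_coverage_profile")
  prof$adjustment <- adjustment_factor(prof, method = adjustment_method)
  prof
}

#' @export
print.sex_coverage_profile <- function(x, ...) {
  cat(sprintf(paste0("sex_coverage_profile: %d scaffolds, %d females ",
                     "(modal %d) / %d males (modal %d), adjustment %.4f\n"),
              length(x$female_track), x$n_females, x$modal_f,
              x$n_males, x$modal_m, x$adjustment))
  invisible(x)
}

#' Modal nonzero depth of a track
#'
#' The depth value (excluding depth 0) covering the most bases; ties are
#' broken toward the smaller depth. Zero depth is excluded because the bulk
#' of an incomplete or repeat-masked reference sits at 0 and would swamp the
#' single-copy peak that limits and normalization are anchored to.
#'
#' @param track a depth track.
#' @return positive integer modal depth.
#' @export
modal_coverage <- function(track) {
  if (is.numeric(track)) track <- list(track)
  mx <- max(vapply(track, function(v) if (length(v)) max(v) else 0L,
                   numeric(1)))
  if (mx < 1) stop("track has no base with nonzero depth")
  counts <- numeric(mx)
  for (v in track) {
    v <- v[v > 0]
    if (length(v)) {
      tb <- tabulate(v, nbins = mx)
      counts <- counts + tb
    }
  }
  which.max(counts)  # first maximum = smallest depth on ties
}

#' Validity limits from modal coverages
#'
#' Lower limits are `floor(lower_frac x modal)` and upper limits
#' `upper_mult x modal`, per sex. With the defaults (1/3 and 3), modal
#' coverages of 25 and 29 give limits (8, 75) and (9, 87).
#'
#' @param modal_f,modal_m modal pooled depths (>= 1).
#' @param lower_frac,upper_mult limit parameters.
#' @return a `coverage_limits` list: `min_f`, `min_m`, `max_f`, `max_m`.
#' @export
derive_limits <- function(modal_f, modal_m, lower_frac = 1 / 3,
                          upper_mult = 3) {
  stopifnot(modal_f >= 1, modal_m >= 1)
  lim <- list(min_f = as.integer(floor(lower_frac * modal_f)),
              min_m = as.integer(floor(lower_frac * modal_m)),
              max_f = as.integer(upper_mult * modal_f),
              max_m = as.integer(upper_mult * modal_m))
  if (lim$min_f >= lim$max_f || lim$min_m >= lim$max_m)
    stop("degenerate limits: lower limit not below upper limit")
  structure(lim, class = "coverage_limits")
}

#' Male-coverage adjustment factor
#'
#' Factor applied to male mean coverages before ratio formation so that the
#' two sexes are compared on the same scale. The default is the modal-depth
#' ratio `modal_f / modal_m`; `method = "mean"` uses the ratio of genome-wide
#' mean depths (total throughput) instead.
#'
#' @param profile a `sex_coverage_profile`.
#' @param method `"modal"` or `"mean"`.
#' @return positive scaling factor.
#' @export
adjustment_factor <- function(profile, method = c("modal", "mean")) {
  method <- match.arg(method)
  if (method == "modal") {
    profile$modal_f / profile$modal_m
  } else {
    tot <- function(tr) sum(vapply(tr, function(v) sum(as.numeric(v)),
                                   numeric(1)))
    n <- sum(vapply(profile$female_track, length, numeric(1)))
    (tot(profile$female_track) / n) / (tot(profile$male_track) / n)
  }
}
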