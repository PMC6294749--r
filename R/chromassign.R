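# Scaffold-to-chromosome assignment by physical coverage of perfect read
# pairs from a laser-captured chromosome library, plus marker-representation
# QC of such a library.

#' Perfect concordant pairs as physical fragments
#'
#' Reads a paired-end SAM/BAM and keeps only properly-paired records whose
#' edit distance to the reference (`NM` tag) is 0 for *both* mates and whose
#' mates map to the same scaffold. Each surviving pair contributes one
#' fragment spanning the pair's outermost aligned coordinates (physical
#' coverage semantics). Records without an `NM` tag are excluded
#' (conservative: mismatch status unknown).
#'
#' @param path SAM/BAM file with mate-pairing flags set.
#' @return a fragment set: named list (scaffold -> data.frame with 0-based
#'   half-open `start`, `end`), with attribute `scaffold_lengths` taken from
#'   the header.
#' @export
filter_perfect_pairs <- function(path) {
  bam <- as_bam(path)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE),
    what = c("qname", "flag", "rname", "pos", "cigar"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(x$flag) == 0 || !any(bitwAnd(x$flag, 1L) > 0))
    stop("no paired records: input lacks mate-pairing flags")
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(x$flag))
  proper <- bitwAnd(x$flag, 2L) > 0
  keep <- proper & !is.na(nm) & nm == 0L
  end <- x$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar) - 1L
  df <- data.frame(qname = x$qname, rname = as.character(x$rname),
                   start = x$pos, end = end)[keep, , drop = FALSE]
  frags <- list()
  if (nrow(df) > 0) {
    sp <- split(df, df$qname)
    sp <- Filter(function(d) nrow(d) == 2 && d$rname[1] == d$rname[2], sp)
    if (length(sp) > 0) {
      fr <- data.frame(
        rname = vapply(sp, function(d) d$rname[1], character(1)),
        start = vapply(sp, function(d) min(d$start) - 1L, numeric(1)),
        end = vapply(sp, function(d) max(d$end), numeric(1)))
      frags <- lapply(split(fr[c("start", "end")], fr$rname), function(d) {
        rownames(d) <- NULL
        d
      })
    }
  }
  structure(frags, scaffold_lengths = targets, class = "fragment_set")
}

#' Fraction of a scaffold under physical coverage
#'
#' Union length of the fragment spans divided by the scaffold length.
#'
#' @param frags data.frame of 0-based half-open `start`, `end` spans (one
#'   scaffold's entry of a fragment set), or NULL for none.
#' @param scaffold_length scaffold length in bp.
#' @return fraction in \[0, 1\].
#' @export
physical_fraction <- function(frags, scaffold_length) {
  stopifnot(scaffold_length >= 1)
  if (is.null(frags) || nrow(frags) == 0) return(0)
  if (any(frags$start < 0) || any(frags$end > scaffold_length) ||
      any(frags$start >= frags$end))
    stop("fragment outside scaffold bounds")
  ir <- IRanges::reduce(IRanges::IRanges(start = frags$start + 1L,
                                         end = frags$end))
  sum(IRanges::width(ir)) / scaffold_length
}

#' Assign scaffolds to the captured chromosome
#'
#' A scaffold is assigned when at least `threshold` of its bases (default
#' 5%) lie under physical coverage by perfect pairs from the chromosome
#' library; the boundary is inclusive.
#'
#' @param frag_set a `fragment_set` from [filter_perfect_pairs()], or a
#'   named numeric vector of precomputed fractions.
#' @param threshold minimum covered fraction (inclusive).
#' @return data.frame: `scaffold`, `length` (NA for precomputed fractions),
#'   `fraction`, `assigned`.
#' @export
assign_scaffolds <- function(frag_set, threshold = 0.05) {
  if (is.numeric(frag_set)) {
    if (any(frag_set < 0 | frag_set > 1)) stop("fractions must be in [0,1]")
    return(data.frame(scaffold = names(frag_set), length = NA_integer_,
                      fraction = unname(frag_set),
                      assigned = unname(frag_set) >= threshold))
  }
  stopifnot(inherits(frag_set, "fragment_set"))
  lens <- attr(frag_set, "scaffold_lengths")
  frac <- vapply(names(lens), function(sc)
    physical_fraction(frag_set[[sc]], lens[[sc]]), numeric(1))
  data.frame(scaffold = names(lens), length = as.integer(lens),
             fraction = unname(frac), assigned = unname(frac) >= threshold,
             row.names = NULL)
}

#' Marker representation of a chromosome library
#'
#' QC for a single-chromosome sequencing library: the fraction of known
#' linkage-group markers hit by at least one mapped read. A library that
#' samples a large share of a linkage group's markers very likely derives
#' from that chromosome.
#'
#' @param hit_counts named integer vector: mapped-read count per marker
#'   (markers with zero reads may be present or absent).
#' @param markers character vector of all known markers on the linkage
#'   group; must be non-empty.
#' @return list with `fraction` (markers hit / markers known), `n_hit`,
#'   `n_markers`, and `per_marker` (data.frame marker/reads, zero-filled,
#'   in marker-list order, for plotting).
#' @export
marker_representation <- function(hit_counts, markers) {
  if (length(markers) == 0) stop("marker list is empty")
  unknown <- setdiff(names(hit_counts), markers)
  if (length(unknown))
    warning(length(unknown), " hit marker(s) not in the marker list; ignored")
  counts <- stats::setNames(integer(length(markers)), markers)
  shared <- intersect(names(hit_counts), markers)
  counts[shared] <- as.integer(hit_counts[shared])
  hit <- sum(counts > 0)
  list(fraction = hit / length(markers), n_hit = hit,
       n_markers = length(markers),
       per_marker = data.frame(marker = markers, reads = unname(counts)))
}
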