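# Outgroup-parsimony attribution of derived substitutions between two
# recent paralogs, and pairwise identity over a nucleotide alignment.

#' Attribute derived substitutions to each member of a gene duplication
#'
#' Works on a codon alignment containing the two paralogs and one or more
#' outgroups. Alignment columns where either paralog has a gap are
#' excluded. At each remaining column the ancestral state is taken as the
#' strict-majority consensus of the ungapped outgroup states; columns with
#' no majority are unresolvable. A substitution is attributed to paralog X
#' when X differs from the ancestral state while the *other* paralog
#' matches it; columns where both paralogs differ from the ancestral state
#' (including shared changes, which predate the duplication) are not
#' attributed. Amino-acid impact is counted per codon: a codon counts as
#' changed for X when translating it with X's attributed sites reverted to
#' the ancestral state yields a different residue than X's observed codon.
#'
#' @param aln named character vector of aligned nucleotide sequences (same
#'   length, gaps as `-`), or a `Biostrings::DNAStringSet`; aligned length
#'   must be divisible by 3 and codon-register.
#' @param a,b names of the two paralogs in `aln`.
#' @param outgroups names of the outgroup sequences (>= 1).
#' @return list of class `branch_counts`: per paralog the attributed
#'   nucleotide substitutions (`nt_a`, `nt_b`) and amino-acid changes
#'   (`aa_a`, `aa_b`); `n_excluded` (focal-gap columns), `n_unresolvable`
#'   (no outgroup majority, or both paralogs off-consensus), and
#'   `n_columns` (aligned length).
#' @export
attribute_derived <- function(aln, a, b, outgroups) {
  aln <- as_aligned_strings(aln)
  if (length(outgroups) < 1) stop("at least one outgroup is required")
  missing <- setdiff(c(a, b, outgroups), names(aln))
  if (length(missing))
    stop("sequences not in alignment: ", paste(missing, collapse = ", "))
  len <- unique(nchar(aln))
  if (length(len) != 1) stop("sequences have unequal aligned lengths")
  if (len %% 3 != 0) stop("aligned length not divisible by 3")

  mat <- do.call(rbind, strsplit(toupper(aln[c(a, b, outgroups)]), ""))
  rownames(mat) <- c(a, b, outgroups)
  focal_gap <- mat[a, ] == "-" | mat[b, ] == "-"

  anc <- rep(NA_character_, len)
  for (j in which(!focal_gap)) {
    og <- mat[outgroups, j]
    og <- og[og %in% c("A", "C", "G", "T")]
    if (length(og) == 0) next
    tb <- sort(table(og), decreasing = TRUE)
    if (length(tb) == 1 || tb[1] > tb[2]) anc[j] <- names(tb)[1]
  }

  usable <- !focal_gap & !is.na(anc)
  der_a <- usable & mat[a, ] != anc & mat[b, ] == anc
  der_b <- usable & mat[b, ] != anc & mat[a, ] == anc
  both_off <- usable & mat[a, ] != anc & mat[b, ] != anc

  aa_changes <- function(focal, derived) {
    obs <- mat[focal, ]
    rev <- obs
    rev[derived] <- anc[derived]
    codon <- (seq_len(len) - 1L) %/% 3L
    n <- 0L
    for (cd in unique(codon[derived])) {
      idx <- which(codon == cd)
      t_obs <- translate_codon(obs[idx])
      t_rev <- translate_codon(rev[idx])
      if (!is.na(t_obs) && !is.na(t_rev) && t_obs != t_rev) n <- n + 1L
    }
    n
  }

  structure(list(nt_a = sum(der_a), nt_b = sum(der_b),
                 aa_a = aa_changes(a, der_a), aa_b = aa_changes(b, der_b),
                 n_excluded = sum(focal_gap),
                 n_unresolvable = sum((!focal_gap & is.na(anc)) | both_off),
                 n_columns = len),
            class = "branch_counts")
}

#' @export
print.branch_counts <- function(x, ...) {
  cat(sprintf(paste0("branch_counts: paralog A %d nt / %d aa, paralog B ",
                     "%d nt / %d aa (%d columns; %d excluded, ",
                     "%d unresolvable)\n"),
              x$nt_a, x$aa_a, x$nt_b, x$aa_b, x$n_columns, x$n_excluded,
              x$n_unresolvable))
  invisible(x)
}

translate_codon <- function(chars) {
  codon <- paste(chars, collapse = "")
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

#' Pairwise identity over an alignment
#'
#' Percent identity between two aligned nucleotide sequences over the
#' comparable columns — those where neither sequence has a gap. Symmetric
#' in its arguments.
#'
#' @param a,b aligned nucleotide strings of equal length (gaps as `-`).
#' @return list with `identity` (percent) and `n_aligned` (comparable
#'   column count).
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(toupper(as.character(a)), "")[[1]]
  cb <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(ca) != length(cb)) stop("sequences have unequal aligned lengths")
  comp <- ca != "-" & cb != "-"
  if (!any(comp)) stop("no comparable (dual-ungapped) columns")
  list(identity = 100 * sum(ca[comp] == cb[comp]) / sum(comp),
       n_aligned = sum(comp))
}

#' Read an aligned FASTA into named strings
#'
#' @param path aligned FASTA path.
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  dss <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

as_aligned_strings <- function(aln) {
  if (inherits(aln, "XStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  if (!is.character(aln) || is.null(names(aln)))
    stop("alignment must be a named character vector or DNAStringSet")
  aln
}
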