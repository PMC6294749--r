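# Homolog calling from tabular protein alignments and per-chromosome
# synteny enrichment of a focal gene set.

#' Read a 12-column tabular alignment file
#'
#' Standard blast outfmt-6 layout: query, target, percent identity,
#' alignment length, mismatches, gap opens, qstart, qend, tstart, tend,
#' evalue, bitscore. Malformed rows (wrong field count or non-numeric
#' identity/length) are skipped with a warning; a file with no usable rows
#' is an error.
#'
#' @param path path to the tabular alignment file.
#' @return data.frame with columns `query`, `target`, `identity`, `length`.
#' @export
read_alignment_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty alignment table")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 12
  df <- NULL
  if (any(ok)) {
    m <- do.call(rbind, parts[ok])
    ident <- suppressWarnings(as.numeric(m[, 3]))
    len <- suppressWarnings(as.numeric(m[, 4]))
    good <- !is.na(ident) & !is.na(len)
    ok[ok] <- good
    df <- data.frame(query = m[good, 1], target = m[good, 2],
                     identity = ident[good], length = len[good])
  }
  n_bad <- sum(!ok)
  if (is.null(df) || nrow(df) == 0)
    stop("no well-formed rows in alignment table")
  if (n_bad > 0)
    warning(n_bad, " malformed row(s) skipped in ", path)
  df
}

#' Call homologs from alignment records
#'
#' Keeps alignments with length `>= min_len` amino acids and percent
#' identity `>= min_ident` (both inclusive), then retains one best target
#' per query: highest identity, ties broken by longer alignment, remaining
#' ties by input order. Set `best_per_query = FALSE` to keep every passing
#' alignment.
#'
#' @param records data.frame with columns `query`, `target`, `identity`
#'   (percent scale: 60 means 60%), `length` (amino acids), and optionally
#'   `chromosome` of the target.
#' @param min_len,min_ident inclusive thresholds.
#' @param best_per_query keep only the best target per query (default).
#' @return the surviving calls, a data.frame.
#' @export
call_homologs <- function(records, min_len = 50, min_ident = 60,
                          best_per_query = TRUE) {
  need <- c("query", "target", "identity", "length")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$identity < 0 | records$identity > 100))
    stop("identity must be on the percent scale in [0, 100]")
  keep <- records[records$length >= min_len & records$identity >= min_ident,
                  , drop = FALSE]
  if (best_per_query && nrow(keep) > 0) {
    ord <- order(keep$query, -keep$identity, -keep$length,
                 seq_len(nrow(keep)))
    keep <- keep[ord, , drop = FALSE]
    keep <- keep[!duplicated(keep$query), , drop = FALSE]
  }
  rownames(keep) <- NULL
  keep
}

#' Per-chromosome synteny enrichment of homolog calls
#'
#' For each chromosome, the enrichment score is the observed number of
#' homolog calls landing on it divided by the total number of genes
#' annotated to it. A focal gene set drawn from a single ancestral
#' chromosome shows scores far above the genome-wide background on its
#' conserved-synteny partners.
#'
#' @param calls homolog calls with a `chromosome` column (target
#'   chromosome per call).
#' @param annotation named numeric vector or two-column data.frame
#'   (`chromosome`, `n_genes`): total annotated genes per chromosome.
#' @return data.frame: `chromosome`, `observed`, `total`, `score`, ordered
#'   as the annotation table.
#' @export
enrichment <- function(calls, annotation) {
  if (is.data.frame(annotation))
    annotation <- stats::setNames(annotation[[2]], annotation[[1]])
  if (any(annotation <= 0))
    stop("chromosome with zero annotated genes: ",
         paste(names(annotation)[annotation <= 0], collapse = ", "))
  if (!"chromosome" %in% names(calls))
    stop("calls need a 'chromosome' column")
  missing <- setdiff(unique(calls$chromosome), names(annotation))
  if (length(missing))
    stop("calls on chromosomes absent from the annotation table: ",
         paste(missing, collapse = ", "))
  obs <- table(factor(calls$chromosome, levels = names(annotation)))
  data.frame(chromosome = names(annotation),
             observed = as.integer(obs),
             total = as.integer(annotation),
             score = as.integer(obs) / as.numeric(annotation),
             row.names = NULL)
}
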