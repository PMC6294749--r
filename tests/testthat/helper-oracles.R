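# Independent oracles and fixture builders used across the suite.

# Naive single-pass interval scanner over a boolean mask: walks base by base,
# closes an interval once V valid bases have accumulated (or at the end),
# trims boundaries to the first/last valid base. Deliberately unvectorised
# and independent of scan_intervals().
oracle_scan <- function(mask, V) {
  out <- list()
  count <- 0L
  first <- last <- NA_integer_
  for (i in seq_along(mask)) {
    if (mask[i]) {
      count <- count + 1L
      if (count == 1L) first <- i
      last <- i
      if (count == V) {
        out[[length(out) + 1L]] <- c(start = first - 1L, end = last,
                                     n_valid = count)
        count <- 0L
      }
    }
  }
  if (count > 0L)
    out[[length(out) + 1L]] <- c(start = first - 1L, end = last,
                                 n_valid = count)
  do.call(rbind, out)
}

# Per-base boolean oracle for the union length of fragment spans.
oracle_union_length <- function(frags, scaffold_length) {
  covered <- logical(scaffold_length)
  for (i in seq_len(nrow(frags)))
    covered[(frags$start[i] + 1L):frags$end[i]] <- TRUE
  sum(covered)
}

# Build a profile directly from given pooled per-base depth vectors on one
# scaffold (bypasses simulation; for hand-constructed scan cases).
toy_profile <- function(cf, cm, n_f = 2, n_m = 2) {
  sex_coverage_profile(list(s = as.integer(cf)), list(s = as.integer(cm)),
                       n_females = n_f, n_males = n_m)
}

# Write a minimal coordinate-sorted single-end SAM file from a record table
# (data.frame: qname, flag, rname, pos [1-based], cigar, and optionally nm).
write_sam <- function(records, scaffold_lengths,
                      path = tempfile(fileext = ".sam"), sort_order = TRUE) {
  hdr <- c(if (sort_order) "@HD\tVN:1.6\tSO:coordinate" else
             "@HD\tVN:1.6\tSO:queryname",
           sprintf("@SQ\tSN:%s\tLN:%d", names(scaffold_lengths),
                   as.integer(scaffold_lengths)))
  opt <- if (!is.null(records$nm)) sprintf("\tNM:i:%d", records$nm) else ""
  rnext <- if (!is.null(records$rnext)) records$rnext else "*"
  pnext <- if (!is.null(records$pnext)) records$pnext else 0L
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t*\t*%s",
                  records$qname, records$flag, records$rname, records$pos,
                  records$cigar, rnext, pnext, opt)
  writeLines(c(hdr, body), path)
  path
}

# Pool simulated tracks for a full synthetic panel; returns the profile.
simulate_panel_profile <- function(model, n_f = 22, n_m = 26,
                                   target_depth = 1, master_seed = 1) {
  add <- function(a, b) if (is.null(a)) b else mapply(`+`, a, b,
                                                      SIMPLIFY = FALSE)
  fem <- mal <- NULL
  for (i in seq_len(n_f))
    fem <- add(fem, simulate_depth(model, "female", target_depth,
                                   individual_seed(master_seed, i)))
  for (i in seq_len(n_m))
    mal <- add(mal, simulate_depth(model, "male", target_depth,
                                   individual_seed(master_seed, n_f + i)))
  sex_coverage_profile(fem, mal, n_females = n_f, n_males = n_m)
}

# Truth-vs-candidate overlap: which truth segments overlap any candidate?
segments_recovered <- function(truth, candidates) {
  vapply(seq_len(nrow(truth)), function(i)
    any(candidates$scaffold == truth$scaffold[i] &
          candidates$start < truth$end[i] &
          candidates$end > truth$start[i]),
    logical(1))
}
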