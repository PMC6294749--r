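# Synthetic genomes and sexed depth tracks with known copy-number structure.
#
# The generator emulates the coverage structure that the W-discovery scan
# assumes: a diploid (2/2 copy) background, hemizygous female-specific
# segments (1 copy in ZW females, 0 in ZZ males), Z-hemizygous segments
# (1 copy in females, 2 in males), collapsed high-copy repeats that inflate
# depth in both sexes, and segregating deletion polymorphisms that are not
# correlated with sex. All coordinates are 0-based half-open.

#' Segment copy-number classes
#'
#' Canonical per-sex copy numbers for the five segment classes used by the
#' simulator. `w_specific` is 1 copy in females / 0 in males, `z_hemizygous`
#' 1/2, `autosomal` and `shared_sex` (pseudoautosomal) 2/2, and `repeat`
#' 2/2 with a depth multiplier >= 1 representing collapsed high-copy
#' sequence on the reference.
#'
#' @param label one of `"autosomal"`, `"shared_sex"`, `"w_specific"`,
#'   `"z_hemizygous"`, `"repeat"`.
#' @param repeat_multiplier depth multiplier, must be >= 1 and is only
#'   meaningful (> 1) for the `repeat` class.
#' @return a list with elements `label`, `copy_female`, `copy_male`,
#'   `repeat_multiplier`.
#' @export
segment_class <- function(label, repeat_multiplier = 1) {
  label <- match.arg(label,
                     c("autosomal", "shared_sex", "w_specific",
                       "z_hemizygous", "repeat"))
  if (!is.numeric(repeat_multiplier) || repeat_multiplier < 1)
    stop("repeat_multiplier must be >= 1")
  if (label != "repeat" && repeat_multiplier != 1)
    stop("repeat_multiplier > 1 is only valid for the 'repeat' class")
  copies <- switch(label,
                   autosomal    = c(2L, 2L),
                   shared_sex   = c(2L, 2L),
                   w_specific   = c(1L, 0L),
                   z_hemizygous = c(1L, 2L),
                   `repeat`     = c(2L, 2L))
  structure(list(label = label,
                 copy_female = copies[1],
                 copy_male = copies[2],
                 repeat_multiplier = repeat_multiplier),
            class = "segment_class")
}

#' Build a synthetic genome model with planted sex-linked segments
#'
#' Lays out `n_scaffolds` scaffolds of `scaffold_length` bp and plants
#' non-overlapping segments of the requested classes at random positions
#' (uniformly over scaffolds and offsets, rejection-sampled to avoid
#' overlap). Everything not planted is `autosomal`. Deletion polymorphisms
#' are sex-independent: each listed locus segregates at frequency
#' `indel_freq` in both sexes and individuals draw 0/1/2 deleted copies
#' under Hardy-Weinberg proportions when depth is simulated.
#'
#' Defaults reproduce the scale used throughout the package's recovery
#' tests: a 10-Mb genome carrying 20 x 2-kb female-specific segments.
#'
#' @param n_scaffolds,scaffold_length scaffold count and common length (bp).
#' @param n_w,w_length number and length of `w_specific` segments.
#' @param n_z,z_length number and length of `z_hemizygous` segments.
#' @param n_repeat,repeat_length,repeat_multiplier collapsed-repeat segments
#'   and their depth multiplier.
#' @param n_indel,indel_length,indel_freq segregating deletion polymorphisms
#'   (sex-independent; `indel_freq` is the population frequency of the
#'   deleted allele).
#' @param seed integer seed; the model is deterministic given the seed.
#' @return a `genome_model`: list with `scaffolds` (named integer lengths),
#'   `segments` (data.frame: scaffold, start, end, label, copy_female,
#'   copy_male, repeat_multiplier) tiling every scaffold exactly, and
#'   `indels` (data.frame: scaffold, start, end, freq).
#' @export
build_genome_model <- function(n_scaffolds = 10, scaffold_length = 1e6,
                               n_w = 20, w_length = 2000,
                               n_z = 10, z_length = 2000,
                               n_repeat = 5, repeat_length = 5000,
                               repeat_multiplier = 50,
                               n_indel = 10, indel_length = 2000,
                               indel_freq = 0.3,
                               seed = 1) {
  if (n_scaffolds < 1 || scaffold_length < 1)
    stop("need at least one scaffold of positive length")
  planted_total <- n_w * w_length + n_z * z_length + n_repeat * repeat_length
  if (planted_total > n_scaffolds * scaffold_length)
    stop("total planted length exceeds total scaffold length")
  scaffolds <- stats::setNames(rep(as.integer(scaffold_length), n_scaffolds),
                               sprintf("scaffold_%02d", seq_len(n_scaffolds)))

  withr_seed(seed, {
    want <- rbind(
      if (n_w > 0) data.frame(label = "w_specific", len = rep(w_length, n_w)),
      if (n_z > 0) data.frame(label = "z_hemizygous", len = rep(z_length, n_z)),
      if (n_repeat > 0) data.frame(label = "repeat",
                                   len = rep(repeat_length, n_repeat)))
    placed <- place_segments(scaffolds, want)
    indels <- place_segments(scaffolds,
                             if (n_indel > 0)
                               data.frame(label = "indel",
                                          len = rep(indel_length, n_indel))
                             else NULL,
                             avoid = placed)
  })

  segments <- tile_with_background(scaffolds, placed, repeat_multiplier)
  indels <- if (is.null(indels) || nrow(indels) == 0) {
    data.frame(scaffold = character(), start = integer(), end = integer(),
               freq = numeric())
  } else {
    data.frame(scaffold = indels$scaffold, start = indels$start,
               end = indels$end, freq = indel_freq)
  }
  structure(list(scaffolds = scaffolds, segments = segments, indels = indels),
            class = "genome_model")
}

# Rejection-sample non-overlapping placements, uniform over scaffold x offset.
place_segments <- function(scaffolds, want, avoid = NULL, max_tries = 10000L) {
  if (is.null(want) || nrow(want) == 0) return(NULL)
  taken <- lapply(scaffolds, function(...) cbind(start = integer(),
                                                 end = integer()))
  if (!is.null(avoid))
    for (i in seq_len(nrow(avoid)))
      taken[[avoid$scaffold[i]]] <-
        rbind(taken[[avoid$scaffold[i]]],
              c(avoid$start[i], avoid$end[i]))
  out <- vector("list", nrow(want))
  for (i in seq_len(nrow(want))) {
    len <- want$len[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      sc <- sample(names(scaffolds), 1)
      maxs <- scaffolds[[sc]] - len
      if (maxs < 0) next
      start <- sample.int(maxs + 1L, 1L) - 1L
      end <- start + len
      tk <- taken[[sc]]
      if (nrow(tk) == 0 || all(end <= tk[, 1] | start >= tk[, 2])) {
        taken[[sc]] <- rbind(tk, c(start, end))
        out[[i]] <- data.frame(scaffold = sc, start = start, end = end,
                               label = want$label[i])
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place segment without overlap; genome too full")
  }
  do.call(rbind, out)
}

# Fill the gaps between planted segments with autosomal background so that
# segments tile each scaffold exactly.
tile_with_background <- function(scaffolds, placed, repeat_multiplier) {
  rows <- list()
  for (sc in names(scaffolds)) {
    len <- scaffolds[[sc]]
    here <- if (is.null(placed)) NULL else placed[placed$scaffold == sc, ]
    if (!is.null(here) && nrow(here) > 0) here <- here[order(here$start), ]
    pos <- 0L
    if (!is.null(here) && nrow(here) > 0) {
      for (i in seq_len(nrow(here))) {
        if (here$start[i] > pos)
          rows[[length(rows) + 1L]] <-
            data.frame(scaffold = sc, start = pos, end = here$start[i],
                       label = "autosomal")
        rows[[length(rows) + 1L]] <- here[i, c("scaffold", "start", "end",
                                               "label")]
        pos <- here$end[i]
      }
    }
    if (pos < len)
      rows[[length(rows) + 1L]] <-
        data.frame(scaffold = sc, start = pos, end = len, label = "autosomal")
  }
  seg <- do.call(rbind, rows)
  rownames(seg) <- NULL
  cls <- lapply(seg$label, function(l)
    segment_class(l, if (l == "repeat") repeat_multiplier else 1))
  seg$copy_female <- vapply(cls, `[[`, integer(1), "copy_female")
  seg$copy_male <- vapply(cls, `[[`, integer(1), "copy_male")
  seg$repeat_multiplier <- vapply(cls, `[[`, numeric(1), "repeat_multiplier")
  seg
}

#' Expand a master seed into per-individual seeds
#'
#' Deterministic schedule: individual `i` (1-based) in a panel gets seed
#' `(master * 1009 + i) mod 2^31 - 1`, so partial re-runs of a panel
#' reproduce exactly the same tracks.
#'
#' @param master integer master seed.
#' @param i individual index (1-based), possibly vectorised.
#' @return integer seed(s).
#' @export
individual_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + i) %% (2^31 - 1))
}

#' Simulate a per-base depth track for one individual
#'
#' Per-base depth is an independent Poisson draw with mean
#' `target_depth * (copies for the individual's sex / 2) * repeat_multiplier`,
#' further scaled by `(2 - deleted copies)/2` over any deletion polymorphism
#' the individual happens to carry (genotype drawn once per locus under
#' Hardy-Weinberg at the locus frequency). `target_depth` is therefore the
#' expected depth on ordinary diploid sequence.
#'
#' @param model a `genome_model`.
#' @param sex `"female"` or `"male"`.
#' @param target_depth expected per-base depth on a 2-copy segment.
#' @param seed integer seed; the track is deterministic given the seed.
#' @return a depth track: named list of non-negative integer vectors, one
#'   per scaffold, one entry per base.
#' @export
simulate_depth <- function(model, sex = c("female", "male"),
                           target_depth = 1, seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  sex <- match.arg(sex)
  if (target_depth <= 0) stop("target_depth must be positive")
  copy_col <- if (sex == "female") "copy_female" else "copy_male"
  withr_seed(seed, {
    lam <- lapply(names(model$scaffolds), function(sc) {
      v <- numeric(model$scaffolds[[sc]])
      seg <- model$segments[model$segments$scaffold == sc, ]
      for (i in seq_len(nrow(seg)))
        v[(seg$start[i] + 1L):seg$end[i]] <-
          target_depth * seg[[copy_col]][i] / 2 * seg$repeat_multiplier[i]
      v
    })
    names(lam) <- names(model$scaffolds)
    # deletion genotypes: sex-independent HWE draw per locus
    if (nrow(model$indels) > 0) {
      q <- model$indels$freq
      lost <- stats::rbinom(length(q), 2L, q)  # deleted copies carried
      for (i in seq_len(nrow(model$indels))) {
        if (lost[i] == 0L) next
        sc <- model$indels$scaffold[i]
        idx <- (model$indels$start[i] + 1L):model$indels$end[i]
        lam[[sc]][idx] <- lam[[sc]][idx] * (2L - lost[i]) / 2
      }
    }
    track <- lapply(lam, function(v) stats::rpois(length(v), v))
  })
  track
}

#' Write placed reads for one individual as a SAM file
#'
#' Places single-end reads (not re-aligned) so that per-base depth recomputed
#' from the file with no filters has the same expectation as
#' [simulate_depth()]: the read count per segment is Poisson with mean
#' `expected depth x segment length / read_length`, with uniform start
#' positions. A configurable fraction of records is emitted flagged as
#' secondary, and a fraction soft-clipped on both ends (their aligned span
#' shrinks accordingly), to exercise downstream alignment filters. Records
#' are coordinate-sorted and the header declares `SO:coordinate`.
#'
#' @param model a `genome_model`.
#' @param sex,target_depth,seed as in [simulate_depth()].
#' @param read_length read length in bp (>= 1).
#' @param n_reads optional exact total read count, uniformly placed on the
#'   expected-depth profile; overrides the Poisson per-segment counts.
#' @param frac_secondary fraction of records flagged secondary (0x100).
#' @param frac_clipped fraction of records soft-clipped at both ends.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
emit_alignments <- function(model, sex = c("female", "male"),
                            target_depth = 1, read_length = 125,
                            n_reads = NULL, frac_secondary = 0,
                            frac_clipped = 0, seed = 1,
                            path = tempfile(fileext = ".sam")) {
  stopifnot(inherits(model, "genome_model"))
  sex <- match.arg(sex)
  if (read_length < 1) stop("read_length must be >= 1")
  copy_col <- if (sex == "female") "copy_female" else "copy_male"
  seg <- model$segments
  mean_depth <- target_depth * seg[[copy_col]] / 2 * seg$repeat_multiplier
  seg_len <- seg$end - seg$start
  withr_seed(seed, {
    if (is.null(n_reads)) {
      counts <- stats::rpois(nrow(seg), mean_depth * seg_len / read_length)
    } else {
      w <- mean_depth * seg_len
      if (sum(w) == 0) w <- seg_len  # place uniformly if profile is flat zero
      counts <- as.vector(stats::rmultinom(1, n_reads, w))
    }
    recs <- lapply(which(counts > 0), function(i) {
      k <- counts[i]
      maxstart <- model$scaffolds[[seg$scaffold[i]]] - read_length
      start0 <- pmin(seg$start[i] + sample.int(seg_len[i], k, replace = TRUE)
                     - 1L, max(maxstart, 0L))
      data.frame(scaffold = seg$scaffold[i], start = start0)
    })
    recs <- if (length(recs)) do.call(rbind, recs) else
      data.frame(scaffold = character(), start = integer())
    n <- nrow(recs)
    sec <- clip <- logical(n)
    if (n > 0) {
      sec <- stats::runif(n) < frac_secondary
      clip <- stats::runif(n) < frac_clipped
    }
  })
  ord <- order(match(recs$scaffold, names(model$scaffolds)), recs$start)
  recs <- recs[ord, , drop = FALSE]
  sec <- sec[ord]; clip <- clip[ord]

  clip_len <- max(1L, read_length %/% 10L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(model$scaffolds),
                   as.integer(model$scaffolds)))
  n <- nrow(recs)
  body <- character(0)
  if (n > 0) {
    flag <- ifelse(sec, 256L, 0L)
    m <- ifelse(clip, read_length - 2L * clip_len, read_length)
    cig <- ifelse(clip,
                  sprintf("%dS%dM%dS", clip_len, m, clip_len),
                  sprintf("%dM", read_length))
    body <- sprintf("read%06d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                    seq_len(n), flag, recs$scaffold, recs$start + 1L, cig,
                    strrep("A", read_length))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the truth BED for a genome model
#'
#' Emits the planted non-autosomal segments (0-based half-open, class label
#' in column 4) for recovery testing against scan output.
#'
#' @param model a `genome_model`.
#' @param path output BED path.
#' @param labels segment classes to include.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(model, path,
                            labels = c("w_specific", "z_hemizygous",
                                       "repeat")) {
  seg <- model$segments[model$segments$label %in% labels, ]
  utils::write.table(seg[, c("scaffold", "start", "end", "label")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a random reference FASTA for a genome model
#'
#' Sequence content is uniform random nucleotides; the analysis consumes
#' depth, so the FASTA exists only to make the output bundle self-contained.
#'
#' @param model a `genome_model`.
#' @param path output FASTA path.
#' @param seed integer seed.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(model, path, seed = 1) {
  withr_seed(seed, {
    seqs <- vapply(as.integer(model$scaffolds), function(n)
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
      character(1))
  })
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- names(model$scaffolds)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

# Run expr with a locally-set RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}
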