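test_that("genome model plants the requested structure and tiles exactly", {
  m <- build_genome_model(n_scaffolds = 10, scaffold_length = 1e5,
                          n_w = 5, w_length = 2000, n_z = 0, n_repeat = 0,
                          n_indel = 0, seed = 11)
  w <- m$segments[m$segments$label == "w_specific", ]
  expect_equal(nrow(w), 5)
  expect_equal(sum(w$end - w$start), 10000)
  # segments tile each scaffold: sorted, non-overlapping, gap-free
  for (sc in names(m$scaffolds)) {
    seg <- m$segments[m$segments$scaffold == sc, ]
    seg <- seg[order(seg$start), ]
    expect_equal(seg$start[1], 0)
    expect_equal(seg$end[nrow(seg)], unname(m$scaffolds[[sc]]))
    if (nrow(seg) > 1)
      expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  }
  # copy-number invariants per class
  expect_true(all(w$copy_female == 1 & w$copy_male == 0))
  auto <- m$segments[m$segments$label == "autosomal", ]
  expect_true(all(auto$copy_female == 2 & auto$copy_male == 2))
})

test_that("a config with no planted segments is all-autosomal", {
  m <- build_genome_model(n_scaffolds = 3, scaffold_length = 1e4,
                          n_w = 0, n_z = 0, n_repeat = 0, n_indel = 0,
                          seed = 1)
  expect_equal(nrow(m$segments), 3)
  expect_true(all(m$segments$label == "autosomal"))
})

test_that("planted fraction matches the requested fraction", {
  # study-like scale-down: W truth is a tiny fraction of the genome
  m <- build_genome_model(n_scaffolds = 10, scaffold_length = 1e6,
                          n_w = 20, w_length = 2000, n_z = 10,
                          z_length = 2000, n_repeat = 0, n_indel = 0,
                          seed = 2)
  bed <- tempfile(fileext = ".bed")
  write_truth_bed(m, bed, labels = "w_specific")
  tb <- read.table(bed, sep = "\t",
                   col.names = c("scaffold", "start", "end", "label"))
  frac <- sum(tb$end - tb$start) / sum(as.numeric(m$scaffolds))
  expect_equal(frac, 20 * 2000 / 1e7)
})

test_that("overfull configs and invalid classes are rejected", {
  expect_error(build_genome_model(n_scaffolds = 1, scaffold_length = 1000,
                                  n_w = 2, w_length = 600, seed = 1),
               "exceeds")
  expect_error(build_genome_model(n_scaffolds = 0, scaffold_length = 1000),
               "at least one scaffold")
  expect_error(segment_class("autosomal", repeat_multiplier = 2),
               "repeat")
  expect_error(segment_class("repeat", repeat_multiplier = 0.5), ">= 1")
})

test_that("simulated depth matches the copy-number expectation per class", {
  m <- build_genome_model(n_scaffolds = 1, scaffold_length = 3e5,
                          n_w = 1, w_length = 1e5, n_z = 1, z_length = 1e5,
                          n_repeat = 0, n_indel = 0, seed = 5)
  trk <- simulate_depth(m, "female", target_depth = 1, seed = 9)
  seg <- m$segments
  mean_over <- function(lab) {
    s <- seg[seg$label == lab, ][1, ]
    mean(trk[[s$scaffold]][(s$start + 1):s$end])
  }
  # +/- 3 standard errors of the Poisson mean at n = 1e5
  expect_lt(abs(mean_over("autosomal") - 1.0), 3 * sqrt(1 / 1e5))
  expect_lt(abs(mean_over("w_specific") - 0.5), 3 * sqrt(0.5 / 1e5))
  expect_lt(abs(mean_over("z_hemizygous") - 0.5), 3 * sqrt(0.5 / 1e5))
  # a male carries no W sequence at all
  trk_m <- simulate_depth(m, "male", target_depth = 1, seed = 9)
  s <- seg[seg$label == "w_specific", ][1, ]
  expect_true(all(trk_m[[s$scaffold]][(s$start + 1):s$end] == 0))
})

test_that("simulation is deterministic and sex-symmetric in distribution", {
  m <- build_genome_model(n_scaffolds = 2, scaffold_length = 1e4,
                          n_w = 1, w_length = 1000, n_z = 1, z_length = 500,
                          n_repeat = 0, n_indel = 2, indel_length = 500,
                          seed = 3)
  expect_identical(simulate_depth(m, "female", 1, seed = 4),
                   simulate_depth(m, "female", 1, seed = 4))
  expect_identical(build_genome_model(seed = 8, n_scaffolds = 2,
                                      scaffold_length = 1e4, n_w = 2,
                                      n_z = 1, n_repeat = 1,
                                      repeat_length = 1000, n_indel = 1),
                   build_genome_model(seed = 8, n_scaffolds = 2,
                                      scaffold_length = 1e4, n_w = 2,
                                      n_z = 1, n_repeat = 1,
                                      repeat_length = 1000, n_indel = 1))
  # swapping per-sex copies is the same as swapping the sex label: a male
  # over a z_hemizygous segment equals a female over it with copies swapped
  m2 <- m
  m2$segments[c("copy_female", "copy_male")] <-
    m$segments[c("copy_male", "copy_female")]
  expect_identical(simulate_depth(m, "female", 1, seed = 21),
                   simulate_depth(m2, "male", 1, seed = 21))
})

test_that("indel polymorphisms thin depth sex-independently", {
  m <- build_genome_model(n_scaffolds = 1, scaffold_length = 1e5,
                          n_w = 0, n_z = 0, n_repeat = 0,
                          n_indel = 1, indel_length = 5e4, indel_freq = 1,
                          seed = 6)
  # freq 1: every individual is homozygous deleted -> depth 0 on the locus
  trk <- simulate_depth(m, "female", 1, seed = 2)
  idx <- (m$indels$start[1] + 1):m$indels$end[1]
  expect_true(all(trk[[m$indels$scaffold[1]]][idx] == 0))
})

test_that("emitted alignments conserve depth and honour flag fractions", {
  m <- build_genome_model(n_scaffolds = 2, scaffold_length = 5000,
                          n_w = 0, n_z = 0, n_repeat = 0, n_indel = 0,
                          seed = 1)
  # exact read count, no clipping: unfiltered depth sum = reads x length
  sam <- emit_alignments(m, "female", read_length = 100, n_reads = 100,
                         seed = 2)
  d <- depth_from_alignments(sam, apply_filters = FALSE)
  expect_equal(sum(unlist(lapply(d, as.numeric))), 100 * 100)

  # conservation against the file itself: sum(depth) = sum(aligned length)
  sam2 <- emit_alignments(m, "male", read_length = 50, n_reads = 77,
                          frac_clipped = 0.3, seed = 3)
  d2 <- depth_from_alignments(sam2, apply_filters = FALSE)
  recs <- readLines(sam2)
  recs <- recs[!startsWith(recs, "@")]
  cig <- vapply(strsplit(recs, "\t"), `[[`, character(1), 6)
  aligned <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  expect_equal(sum(unlist(lapply(d2, as.numeric))), sum(aligned))

  # flagged-secondary records are exactly what the filter removes
  sam3 <- emit_alignments(m, "female", read_length = 100, n_reads = 200,
                          frac_secondary = 0.1, seed = 4)
  recs3 <- readLines(sam3)
  recs3 <- recs3[!startsWith(recs3, "@")]
  flags <- as.integer(vapply(strsplit(recs3, "\t"), `[[`, character(1), 2))
  n_sec <- sum(bitwAnd(flags, 256L) > 0)
  d_all <- sum(unlist(lapply(depth_from_alignments(sam3, FALSE), as.numeric)))
  d_fil <- sum(unlist(lapply(depth_from_alignments(sam3, TRUE), as.numeric)))
  expect_equal(d_all - d_fil, n_sec * 100)

  # 0 reads: valid empty file with header
  sam0 <- emit_alignments(m, "female", n_reads = 0, seed = 5)
  d0 <- depth_from_alignments(sam0, FALSE)
  expect_equal(sum(unlist(lapply(d0, as.numeric))), 0)
  expect_named(d0, names(m$scaffolds))
})

test_that("per-individual seeds are deterministic and distinct", {
  expect_identical(individual_seed(42, 1:5), individual_seed(42, 1:5))
  expect_equal(length(unique(individual_seed(42, 1:100))), 100)
  expect_true(all(individual_seed(1e6, 1:10) < 2^31))
})
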