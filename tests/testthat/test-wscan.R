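test_that("valid-base rule applies both conditions with strict inequalities", {
  lim <- derive_limits(25, 29)  # (8, 75) / (9, 87)
  prof <- toy_profile(c(30L, 0L, 80L, 8L, 9L, 74L),
                      c(30L, 0L, 10L, 9L, 8L, 87L))
  mask <- valid_mask(prof, lim)$s
  expect_equal(mask,
               c(TRUE,    # 30/30: inside all limits
                 FALSE,   # 0/0: fails both lower conditions
                 FALSE,   # 80 >= max_f: repeat exclusion
                 FALSE,   # 8/9: neither strictly exceeds its lower limit
                 TRUE,    # Cf 9 > min_f = 8
                 FALSE))  # Cm 87 = max_m: upper bound is strict
})

test_that("scan partitions valid bases into ~V-base intervals", {
  cf <- rep(20L, 3000)
  prof <- toy_profile(cf, cf)
  mask <- list(s = c(rep(TRUE, 2500), rep(FALSE, 500)))
  iv <- scan_intervals(prof, mask, V = 1000)
  expect_equal(iv$n_valid, c(1000, 1000, 500))
  expect_equal(iv$start, c(0, 1000, 2000))
  expect_equal(iv$end, c(1000, 2000, 2500))
  # empty mask: no intervals
  iv0 <- scan_intervals(prof, list(s = rep(FALSE, 3000)), V = 1000)
  expect_equal(nrow(iv0), 0)
  # partition property: valid bases are covered exactly once
  expect_equal(sum(iv$n_valid), 2500)
})

test_that("scan boundaries are trimmed to the first/last valid base", {
  prof <- toy_profile(rep(20L, 100), rep(20L, 100))
  mask <- list(s = rep(FALSE, 100))
  mask$s[c(11, 50, 90)] <- TRUE
  iv <- scan_intervals(prof, mask, V = 10)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 10)   # 0-based first valid base
  expect_equal(iv$end, 90)     # half-open end at last valid base
  expect_equal(iv$n_valid, 3)
  expect_equal(iv$span, 80)
})

test_that("scan matches a brute-force oracle on many random masks", {
  set.seed(101)
  for (rep in 1:300) {
    n <- sample(20:400, 1)
    V <- sample(1:60, 1)
    mask <- runif(n) < runif(1)
    prof <- toy_profile(rpois(n, 20) + 1L, rpois(n, 20) + 1L)
    iv <- scan_intervals(prof, list(s = mask), V = V)
    orc <- oracle_scan(mask, V)
    if (is.null(orc)) {
      expect_equal(nrow(iv), 0)
    } else {
      expect_equal(iv$start, unname(orc[, "start"]))
      expect_equal(iv$end, unname(orc[, "end"]))
      expect_equal(iv$n_valid, unname(orc[, "n_valid"]))
    }
    expect_equal(sum(iv$n_valid), sum(mask))  # partition invariant
  }
})

test_that("interval means are over valid bases only", {
  cf <- c(rep(10L, 50), rep(100L, 50))
  cm <- c(rep(20L, 50), rep(0L, 50))
  prof <- toy_profile(cf, cm)
  mask <- list(s = c(rep(TRUE, 50), rep(FALSE, 50)))
  iv <- scan_intervals(prof, mask, V = 1000)
  expect_equal(iv$mean_f, 10)
  expect_equal(iv$mean_m, 20)
})

test_that("scoring applies log2 ratio, adjustment and zero-male rule", {
  iv <- data.frame(scaffold = "s", start = 0L, end = 1000L, span = 1000L,
                   n_valid = 800L, mean_f = c(4, 3, 10), mean_m = c(1, 3, 0))
  sc <- score_intervals(iv, adjustment = 1, read_length = 100)
  expect_equal(sc$score[1], 2)    # log2(4/1)
  expect_equal(sc$score[2], 0)    # equal means
  # zero male: substitute (read_length/2)/span = 0.05
  expect_equal(sc$mean_m_adj[3], 0.05)
  expect_equal(sc$score[3], log2(10 / 0.05))
  expect_equal(sc$zero_male, c(FALSE, FALSE, TRUE))
  # both-zero intervals cannot be valid
  bad <- iv; bad$mean_f[1] <- 0; bad$mean_m[1] <- 0
  expect_error(score_intervals(bad, 1), "zero coverage in both")
})

test_that("antisymmetry: swapping sexes negates scores without substitution", {
  set.seed(7)
  iv <- data.frame(scaffold = "s", start = 0L, end = 500L, span = 500L,
                   n_valid = 400L, mean_f = runif(20, 1, 40),
                   mean_m = runif(20, 1, 40))
  adj <- 0.85
  fwd <- score_intervals(iv, adjustment = adj)
  swp <- iv
  swp$mean_f <- iv$mean_m
  swp$mean_m <- iv$mean_f
  rev <- score_intervals(swp, adjustment = 1 / adj)
  expect_equal(rev$score, -fwd$score)
})

test_that("interval filters are inclusive at the stated minima", {
  iv <- data.frame(scaffold = "s", start = 0L, end = 1L,
                   span = c(499L, 10000L, 500L),
                   n_valid = c(400L, 199L, 200L),
                   mean_f = 1, mean_m = 1, mean_m_adj = 1,
                   score = 1, zero_male = FALSE)
  kept <- filter_intervals(iv)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$span, 500L)  # span 500 AND n_valid 200 survive
})

test_that("candidate calling is strict at the threshold and aggregates", {
  iv <- data.frame(scaffold = c("a", "a", "a", "b", "c"),
                   start = c(0L, 2000L, 4000L, 0L, 0L),
                   end = c(1000L, 3000L, 5000L, 1000L, 1000L),
                   span = 1000L, n_valid = 900L, mean_f = 1, mean_m = 1,
                   mean_m_adj = 1,
                   score = c(2.0, 2.5, 3.1, 4.0, 1.9),
                   zero_male = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  rep <- call_candidates(iv, threshold = 2)
  expect_equal(rep$n_intervals, 3)        # score exactly 2.0 is excluded
  expect_equal(rep$n_scaffolds, 2)
  expect_equal(rep$n_scaffolds_multi, 1)  # only "a" has >= 2
  expect_equal(rep$n_zero_male, 2)
  expect_equal(rep$total_span, 3000)
})

test_that("planted W segments are recovered and z segments never called", {
  model <- build_genome_model(n_scaffolds = 4, scaffold_length = 5e5,
                              n_w = 8, w_length = 2000,
                              n_z = 4, z_length = 2000,
                              n_repeat = 2, repeat_length = 3000,
                              n_indel = 4, indel_length = 1000, seed = 19)
  prof <- simulate_panel_profile(model, master_seed = 19)
  res <- scan_w_candidates(prof)
  truth_w <- model$segments[model$segments$label == "w_specific", ]
  truth_z <- model$segments[model$segments$label == "z_hemizygous", ]
  hit <- segments_recovered(truth_w, res$report$intervals)
  expect_gte(mean(hit), 0.95)
  # no candidate overlaps a z_hemizygous or repeat segment
  other <- model$segments[model$segments$label %in%
                            c("z_hemizygous", "repeat"), ]
  expect_false(any(segments_recovered(other, res$report$intervals)))
  # z-hemizygous intervals sit near score -1 (half female copy number)
  zin <- unlist(lapply(seq_len(nrow(truth_z)), function(i) {
    iv <- res$intervals
    iv$score[iv$scaffold == truth_z$scaffold[i] &
               iv$start >= truth_z$start[i] & iv$end <= truth_z$end[i]]
  }))
  expect_gt(length(zin), 0)
  expect_true(median(zin) > -1.5 && median(zin) < -0.5)
})
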