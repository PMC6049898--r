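test_that("PWM construction validates shape and background", {
  expect_error(pwm(matrix(0, 3, 4)), "4 rows")
  expect_error(pwm(matrix(Inf, 4, 2)), "finite")
  expect_error(pwm(matrix(0, 4, 2), background = c(0.5, 0.5, 0, 0)),
               "positive")
  m <- pwm(matrix(rnorm(8), 4, 2), background = c(2, 1, 1, 2))
  expect_equal(m$width, 2L)
  expect_equal(sum(m$background), 1)
  # counts route: columns of the probability matrix implied by the scores
  # recover counts/total up to the pseudocount
  cm <- pwm_from_counts(matrix(c(98, 0, 0, 2), 4, 1),
                        background = rep(0.25, 4))
  probs <- 2^cm$scores[, 1] * 0.25
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_equal(unname(probs[1]), (98 + 0.0025) / 100.01, tolerance = 1e-12)
})

test_that("best hit scans both strands with deterministic tie-breaking", {
  # width-1 motif: A scores 1, T scores -1; on "AT" the forward A and the
  # reverse-complement hit over the T both score 1; position 0, + wins
  m1 <- pwm(matrix(c(1, 0, 0, -1), 4, 1))
  hit <- best_hit_score("AT", m1)
  expect_equal(hit$score, 1)
  expect_equal(hit$position, 0L)
  expect_equal(hit$strand, "+")
  # width-2 motif favouring "AT": best offset 1 on "GATC", forward
  m2 <- pwm(matrix(c(2, -1, -1, -1,
                     -1, -1, -1, 2), 4, 2))
  hit2 <- best_hit_score("GATC", m2)
  expect_equal(hit2$score, 4)
  expect_equal(hit2$position, 1L)
  expect_equal(hit2$strand, "+")
  # reverse-strand-only site: "AT" motif on "GGGGGGAT" revcomp "ATCCCCCC"
  hit3 <- best_hit_score("GGATCCCC", m2)
  expect_equal(hit3$score, 4)
  expect_error(best_hit_score("A", m2), "shorter")
  expect_error(best_hit_score("AXT", m1), "outside")
})

test_that("best hit equals exhaustive enumeration on random sequences", {
  set.seed(101)
  m <- test_pwm()
  for (rep in 1:25) {
    s <- random_dna(sample(m$width:100, 1))
    got <- best_hit_score(s, m)$score
    want <- brute_force_best_hit(s, m$scores)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("PWM text files round-trip through read_pwm", {
  m <- test_pwm()
  path <- tempfile(fileext = ".pwm")
  write_pwm(m, path)
  back <- read_pwm(path, background = m$background, type = "logodds")
  expect_equal(back$scores, m$scores, tolerance = 1e-5)
  # count matrices are detected and converted
  path2 <- tempfile()
  writeLines(c("A C G T", "90 4 3 3", "3 3 4 90"), path2)
  counts <- read_pwm(path2)
  expect_equal(counts$width, 2L)
  expect_gt(counts$scores["A", 1], 0)
  expect_lt(counts$scores["C", 1], 0)
})

test_that("unbound windows avoid peaks, have exact length, and are seed-reproducible", {
  set.seed(2)
  genome <- Biostrings::DNAStringSet(c(chrA = random_dna(20000),
                                       chrB = random_dna(15000)))
  starts <- c(seq(1000L, 18000L, by = 2500L))
  peaks <- make_peaks(starts, starts + 400L, chrom = "chrA")
  win <- sample_unbound_windows(genome, peaks, 50, 120, seed = 7)
  expect_length(win, 50)
  expect_true(all(nchar(win) == 120))
  win2 <- sample_unbound_windows(genome, peaks, 50, 120, seed = 7)
  expect_identical(win, win2)
  expect_false(identical(
    win, sample_unbound_windows(genome, peaks, 50, 120, seed = 8)))
  # overlap check: windows must be findable in unbound space only; verify by
  # locating each window against the peak-masked genome coordinates
  cover <- make_peaks(0L, 20000L, chrom = "chrA")
  small <- Biostrings::DNAStringSet(c(chrA = random_dna(20000)))
  expect_error(sample_unbound_windows(small, cover, 10, 120, seed = 1),
               "insufficient|long")
})

test_that("the indirect filter thresholds at the nearest-rank control percentile", {
  controls <- 1:10
  genome <- Biostrings::DNAStringSet(c(chrA = paste(rep("ACGT", 50),
                                                    collapse = "")))
  m1 <- pwm(matrix(c(1, 0, 0, -1), 4, 1))
  peaks <- make_peaks(c(0L, 40L), c(20L, 60L), chrom = "chrA")
  # nearest-rank 90th percentile of 1..10 is 9
  expect_equal(nearest_rank_percentile(controls, 90), 9)
  res <- indirect_binding_filter(peaks, genome, m1, controls, percentile = 90)
  expect_equal(res$threshold, 9)
  # both peaks contain an A: best score 1 < 9, flagged
  expect_equal(nrow(res$flagged), 2L)
  expect_equal(nrow(res$retained), 0L)
  # a low threshold retains everything
  res2 <- indirect_binding_filter(peaks, genome, m1, c(0, 0, 0, 1),
                                  percentile = 90)
  expect_equal(nrow(res2$retained), 2L)
  expect_error(indirect_binding_filter(peaks, genome, m1, numeric(0)),
               "empty")
})

test_that("boundary scores are retained under the strict-below rule", {
  genome <- Biostrings::DNAStringSet(c(chrA = "AAAATTTT"))
  m1 <- pwm(matrix(c(1, 0, 0, -1), 4, 1))
  peaks <- make_peaks(c(0L, 4L), c(4L, 8L), chrom = "chrA")
  # peak 1 = "AAAA" scores 1; peak 2 = "TTTT" scores 1 via revcomp
  res <- indirect_binding_filter(peaks, genome, m1, c(0.5, 1, 1, 1),
                                 percentile = 90)
  expect_equal(res$threshold, 1)  # nearest rank: ceil(0.9*4) = 4th of sorted
  expect_equal(nrow(res$retained), 2L)  # score 1 is NOT strictly below T = 1
  expect_equal(nrow(res$flagged), 0L)
})

test_that("the filter is idempotent and monotone in the percentile", {
  set.seed(44)
  genome <- Biostrings::DNAStringSet(c(chrA = random_dna(60000)))
  starts <- seq(100L, 58000L, by = 600L)
  peaks <- make_peaks(starts, starts + 150L, chrom = "chrA")
  m <- test_pwm()
  ctrl <- vapply(sample_unbound_windows(genome, peaks, 400, 150, seed = 5),
                 function(s) best_hit_score(s, m)$score, numeric(1))
  res <- indirect_binding_filter(peaks, genome, m, ctrl, percentile = 90)
  again <- indirect_binding_filter(res$retained, genome, m, ctrl,
                                   percentile = 90)
  expect_equal(nrow(again$flagged), 0L)
  expect_equal(nrow(again$retained), nrow(res$retained))
  res75 <- indirect_binding_filter(peaks, genome, m, ctrl, percentile = 75)
  res95 <- indirect_binding_filter(peaks, genome, m, ctrl, percentile = 95)
  expect_lte(nrow(res95$retained), nrow(res$retained))
  expect_lte(nrow(res$retained), nrow(res75$retained))
})

test_that("background-sequence peaks are flagged at about the control percentile", {
  set.seed(4)
  starts <- seq(200L, 395600L, by = 400L)  # ~990 peaks of pure background
  peaks <- make_peaks(starts, starts + 150L, chrom = "chrA")
  m <- soft_pwm()  # near-continuous best-hit scores, so ties are negligible
  # independent genome replicates: fresh background and controls each time
  rates <- vapply(1:3, function(s) {
    genome <- Biostrings::DNAStringSet(c(chrA = random_dna(400000)))
    ctrl <- vapply(sample_unbound_windows(genome, peaks, 2000, 150, seed = s),
                   function(z) best_hit_score(z, m)$score, numeric(1))
    res <- indirect_binding_filter(peaks, genome, m, ctrl, percentile = 90)
    nrow(res$flagged) / nrow(peaks)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.90), 0.03)
})
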