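test_that("frequencies follow the pseudocount formula (hand computations)", {
  # one site, uniform background: N = 1, P = 1, p_b = 0.25
  p <- build_pwm("ACGT")
  expect_equal(unname(p$freq["A", 1]), (1 + 0.25) / 2)
  expect_equal(unname(p$freq["C", 1]), 0.25 / 2)
  expect_equal(unname(p$freq["C", 2]), (1 + 0.25) / 2)

  # four identical sites: N = 4, P = 2, p_b = 0.5
  p2 <- build_pwm(rep("AAAA", 4))
  expect_equal(unname(p2$freq["A", ]), rep(0.75, 4))
  expect_equal(unname(p2$logodds["A", ]), rep(log2(3), 4))

  # column sums are 1 for arbitrary input
  set.seed(1)
  sites <- replicate(7, random_dna(9))
  bg <- c(0.3, 0.2, 0.2, 0.3)
  p3 <- build_pwm(sites, background = bg)
  expect_equal(unname(colSums(p3$freq)), rep(1, 9), tolerance = 1e-9)
  expect_true(all(p3$freq > 0))
  expect_lt(p3$s_min, p3$s_max)
})

test_that("malformed site sets are rejected with context", {
  expect_error(build_pwm(c("ACGT", "ACG")), "equal length")
  expect_error(build_pwm(c("ACGT", "ACNT")), "site 2 at position 3")
  expect_error(build_pwm(character(0)))
  expect_error(build_pwm("ACGT", background = c(0.5, 0.5, 0.25, -0.25)))
})

test_that("subsequence scores hit the scale anchors", {
  set.seed(2)
  p <- build_pwm(replicate(10, random_dna(8)))
  cons <- pwm_consensus(p)
  expect_equal(score_subsequence(p, cons), p$s_max)
  worst <- paste(c("A", "C", "G", "T")[apply(p$logodds, 2, which.min)],
                 collapse = "")
  expect_equal(score_subsequence(p, worst), p$s_min)
  expect_equal(scale_score(p, score_subsequence(p, cons)), 1)
  expect_equal(scale_score(p, score_subsequence(p, worst)), 0)
  expect_equal(scale_score(p, (p$s_min + p$s_max) / 2), 0.5)
  expect_true(is.na(score_subsequence(p, "ACGTNACG")))
  expect_error(score_subsequence(p, "ACGT"), "length")
})

test_that("scores on the 4-copy homopolymer PWM match hand computation", {
  p <- build_pwm(rep("AAAA", 4))
  expect_equal(score_subsequence(p, "AAAA"), 4 * log2(3))
})

test_that("the relative scale is invariant to the log base", {
  set.seed(3)
  p <- build_pwm(replicate(6, random_dna(7)))
  # natural-log matrix built independently from the stored frequencies
  m_ln <- log(p$freq / p$background)
  s_min_ln <- sum(apply(m_ln, 2, min))
  s_max_ln <- sum(apply(m_ln, 2, max))
  for (k in 1:20) {
    w <- random_dna(7)
    raw2 <- score_subsequence(p, w)
    ch <- chars_of(w)
    raw_ln <- sum(vapply(1:7, function(i) m_ln[ch[i], i], numeric(1)))
    expect_equal((raw_ln - s_min_ln) / (s_max_ln - s_min_ln),
                 scale_score(p, raw2), tolerance = 1e-12)
  }
})

test_that("raw score is monotone in per-column base improvement", {
  set.seed(4)
  p <- build_pwm(replicate(8, random_dna(6)))
  best <- c("A", "C", "G", "T")[apply(p$logodds, 2, which.max)]
  for (k in 1:20) {
    w <- chars_of(random_dna(6))
    raw <- score_subsequence(p, paste(w, collapse = ""))
    i <- sample.int(6, 1)
    w[i] <- best[i]
    expect_gte(score_subsequence(p, paste(w, collapse = "")), raw)
  }
})

test_that("interval scoring is strand-symmetric and handles ambiguity", {
  set.seed(5)
  p <- build_pwm(replicate(5, random_dna(6)))
  seq <- random_dna(300)
  expect_equal(score_interval(p, seq, 0, 300),
               score_interval(p, revcomp(seq), 0, 300), tolerance = 1e-12)

  cons <- pwm_consensus(p)
  expect_equal(score_interval(p, strrep(cons, 20), 0, 120), 1)

  # every window ambiguous -> 0
  expect_equal(score_interval(p, strrep("N", 50), 0, 50), 0)
  # ambiguous windows skipped, clean windows still scored
  mixed <- paste0(strrep("N", 10), cons, strrep("N", 10))
  expect_equal(score_interval(p, mixed, 0, nchar(mixed)), 1)
  expect_error(score_interval(p, seq, 0, 4), "shorter")
  expect_error(score_interval(p, seq, -1, 10), "bounds")
})

test_that("interval scores equal the brute-force double-strand scan", {
  set.seed(6)
  p <- build_pwm(replicate(5, random_dna(6)))
  for (k in 1:10) {
    n <- sample(60:150, 1)
    seq <- random_dna(n, p_n = 0.02)
    expect_equal(score_interval(p, seq, 0, n),
                 brute_interval_score(p, seq, 0, n), tolerance = 1e-12)
  }
})

test_that("bin scanning matches per-interval scoring", {
  set.seed(7)
  p <- build_pwm(replicate(5, random_dna(6)))
  seq <- random_dna(3500, p_n = 0.01)
  sb <- scan_bins(p, seq, chrom = "c", bin_size = 1000)
  expect_equal(nrow(sb), 3L)
  for (b in 1:3)
    expect_equal(sb$pwm_score[b],
                 score_interval(p, seq, sb$start[b], sb$end[b]),
                 tolerance = 1e-12)
})

test_that("PWM serialization round-trips scores exactly", {
  set.seed(8)
  p <- build_pwm(replicate(6, random_dna(7)), background = c(.3, .2, .2, .3))
  f <- withr::local_tempfile(fileext = ".json")
  write_pwm(p, f)
  p2 <- read_pwm(f)
  expect_equal(p2$freq, p$freq)
  expect_equal(p2$s_min, p$s_min)
  w <- random_dna(7)
  expect_identical(score_subsequence(p, w), score_subsequence(p2, w))

  fj <- withr::local_tempfile(fileext = ".pfm")
  write_pwm(p, fj, format = "jaspar")
  expect_true(file.exists(fj) && file.exists(paste0(fj, ".meta.json")))
  expect_length(readLines(fj), 4L)
})
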