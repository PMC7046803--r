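test_that("PWM probabilities and log-odds follow the pseudocount formula", {
  m <- pwm_from_counts(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 0)
  expect_equal(unname(m$log_odds["A", 1]), 2)   # log2(1 / 0.25)
  flat <- pwm_from_counts(matrix(1, 4, 3), pseudocount = 0.7)
  expect_true(all(abs(flat$log_odds) < 1e-12))
  withr::local_seed(421)
  for (rep in 1:20) {
    counts <- matrix(rpois(4 * 8, 4), 4)
    counts[1, colSums(counts) == 0] <- 1
    m <- pwm_from_counts(counts, pseudocount = runif(1, 0, 2))
    expect_equal(unname(colSums(m$prob)), rep(1, 8))
  }
  # explicit formula check on one column
  m2 <- pwm_from_counts(matrix(c(3, 1, 0, 0), 4, 1), pseudocount = 0.5)
  expect_equal(unname(m2$prob[, 1]), (c(3, 1, 0, 0) + 0.5) / 6)
})

test_that("degenerate count matrices are rejected", {
  expect_error(pwm_from_counts(matrix(0, 4, 1), pseudocount = 0), "all-zero")
  expect_error(pwm_from_counts(matrix(-1, 4, 2)), "non-negative")
  expect_error(pwm_from_counts(matrix(1, 3, 2)), "4 rows")
  expect_error(pwm_from_counts(matrix(1, 4, 2), background = c(1, 0, 0, 0)),
               "background")
})

test_that("IUPAC consensus applies dominance then degenerate-pair rules", {
  mk <- function(p) {
    # build counts realizing the wanted probabilities under pseudocount 0
    pwm_from_counts(matrix(p * 1000, 4, length(p) / 4), pseudocount = 0)
  }
  expect_equal(consensus_string(mk(c(.9, .05, .03, .02))), "A")
  expect_equal(consensus_string(mk(c(.45, .05, .45, .05))), "R")
  expect_equal(consensus_string(mk(c(.3, .3, .2, .2))), "N")
  expect_equal(consensus_string(mk(c(.05, .45, .45, .05))), "S")
  three <- pwm_from_counts(matrix(c(900, 50, 30, 20, 450, 50, 450, 50,
                                    300, 300, 200, 200), 4), pseudocount = 0)
  expect_equal(consensus_string(three), "ARN")
})

test_that("the maximum-likelihood word is the unique hit at threshold 1", {
  m <- pwm_from_counts(matrix(c(9, 1, 1, 1,
                                1, 9, 1, 1,
                                1, 1, 1, 9), 4), name = "ACT")
  seq <- "ACT"
  hits <- scan_sequence(seq, m, min_score_frac = 1, both_strands = FALSE)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$matched_sequence, "ACT")
})

test_that("palindromic motifs produce paired +/- hits at the same offset", {
  pal <- pwm_from_counts(matrix(c(9, 0, 0, 0,
                                  0, 0, 0, 9), 4), name = "AT", pseudocount = 0.5)
  hits <- scan_sequence("GGATGG", pal, min_score_frac = 0.95)
  expect_equal(hits$offset, c(2L, 2L))
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("scanning guards its inputs", {
  m <- random_motif(6)
  expect_error(scan_sequence("ACGTAA", m, min_score_frac = 0), "min_score_frac")
  expect_error(scan_sequence("ACGTAA", m, min_score_frac = 1.2), "min_score_frac")
  expect_error(scan_sequence("ACXTAA", m), "A, C, G, T, N")
  expect_message(h <- scan_sequence("ACg", m), "shorter")
  expect_equal(nrow(h), 0)
})

test_that("hit sets equal the exhaustive per-window rescoring oracle", {
  withr::local_seed(422)
  for (rep in 1:40) {
    m <- random_motif()
    seq <- random_seq(sample(50:200, 1))
    frac <- sample(c(0.6, 0.75, 0.9), 1)
    got <- scan_sequence(seq, m, min_score_frac = frac)
    want <- oracle_scan(seq, m, min_score_frac = frac)
    expect_identical(hit_key(got), hit_key(want))
  }
})

test_that("N bases contribute the background-expected zero score", {
  m <- pwm_from_counts(matrix(c(9, 1, 1, 1, 1, 9, 1, 1), 4), name = "AC")
  with_n <- scan_sequence("NC", m, min_score_frac = 1e-6, both_strands = FALSE)
  expect_equal(with_n$score[with_n$offset == 0],
               unname(m$log_odds["C", 2]))
})

test_that("scan of the reverse complement mirrors the original scan", {
  withr::local_seed(423)
  for (rep in 1:20) {
    m <- random_motif()
    seq <- random_seq(80)
    fwd <- scan_sequence(seq, m, min_score_frac = 0.7)
    rev <- scan_sequence(mirreg:::revcomp(seq), m, min_score_frac = 0.7)
    n <- nchar(seq); L <- m$width
    mirrored <- data.frame(offset = n - L - rev$offset,
                           strand = ifelse(rev$strand == "+", "-", "+"))
    expect_identical(hit_key(fwd), hit_key(mirrored))
  }
})

test_that("lowering the threshold never removes hits", {
  withr::local_seed(424)
  m <- random_motif(7)
  seq <- random_seq(300)
  prev <- character(0)
  for (frac in c(1, 0.9, 0.75, 0.6, 0.4)) {
    cur <- hit_key(scan_sequence(seq, m, min_score_frac = frac))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("planted occurrences are recovered from peak sequences", {
  sim <- simulate_regulatory_landscape(simulation_config(seed = 31))
  # the planted motif is information-rich (>= 1.5 bits/column on average)
  info <- mean(2 + colSums(sim$motif$prob * log2(sim$motif$prob)))
  expect_gte(info, 1.5)
  peaks <- sim$tf_peaks[sim$tf_peaks$label == sim$config$motif_tf, ]
  hits <- scan_peaks(peaks, sim$genome, sim$motif, min_score_frac = 0.9)
  key <- function(d) sort(paste(d$chrom, d$start, d$strand))
  expect_identical(key(hits), key(sim$truth$motifs))
})
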