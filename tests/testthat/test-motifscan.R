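test_that("make_pwm normalizes and validates; file round-trip", {
  m <- matrix(c(8, 1, 1, 0), nrow = 1)
  p <- make_pwm("x", m)
  expect_equal(sum(p$matrix), 1, tolerance = 1e-12)
  expect_true(all(p$matrix > 0))  # pseudocount applied
  expect_error(make_pwm("x", matrix(1, 1, 3)), "4 columns")
  expect_error(make_pwm("x", matrix(-1, 1, 4)), "non-negative")

  withr::local_seed(1)
  pwms <- list(a = make_pwm("a", matrix(stats::rgamma(20, 1), ncol = 4)),
               b = pwm_from_consensus("b", "ACGTAC"))
  f <- withr::local_tempfile()
  write_pwm(pwms, f)
  # stored matrices already carry the pseudocount; re-read without one
  rt <- read_pwm(f, pseudocount = 0)
  expect_equal(names(rt), c("a", "b"))
  expect_equal(rt$a$matrix, pwms$a$matrix, tolerance = 1e-5)
})

test_that("score_distribution: degenerate and analytic cases", {
  # 1-position uniform PWM, uniform background: all scores 0, P(S>=0)=1
  p <- make_pwm("u", matrix(1, 1, 4), pseudocount = 0)
  d <- score_distribution(p)
  expect_equal(prc2scan:::tail_at_bin(d, 0L), 1)
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)

  # tail at max score = product of background probs of the consensus word
  p2 <- pwm_from_consensus("c", "ACGT")
  bg <- c(0.4, 0.1, 0.2, 0.3)
  d2 <- score_distribution(p2, background = bg)
  expect_equal(d2$tail[length(d2$tail)], prod(bg[c(1, 2, 3, 4)]),
               tolerance = 1e-12)
  # tails monotone non-increasing
  expect_true(all(diff(d2$tail) <= 1e-15))
})

test_that("score_distribution equals full enumeration (length 2)", {
  withr::local_seed(2)
  p <- make_pwm("d", matrix(stats::rgamma(8, 1), ncol = 4))
  bg <- c(0.3, 0.2, 0.2, 0.3)
  d <- score_distribution(p, background = bg)
  or <- bf_pwm_oracle(p, bg)
  # every achievable score's tail matches enumeration
  lo <- log2(sweep(p$matrix, 2, bg, "/"))
  for (b1 in 1:4) for (b2 in 1:4) {
    s <- lo[1, b1] + lo[2, b2]
    bin <- round(lo[1, b1] / 0.001) + round(lo[2, b2] / 0.001)
    expect_equal(prc2scan:::tail_at_bin(d, bin), or$pvalue(s),
                 tolerance = 1e-9)
  }
})

test_that("scan_pwm equals brute-force scoring on a 2 kb fixture", {
  withr::local_seed(5)
  p <- make_pwm("r", matrix(stats::rgamma(24, 1), ncol = 4))
  bg <- c(0.3, 0.2, 0.2, 0.3)
  s <- random_seq(2000, gc = 0.4)
  for (alpha in c(2e-3, 5e-5)) {
    hits <- scan_pwm(c(c1 = s), p, alpha = alpha, background = bg)
    expect_equal(hits$start[hits$strand == "+"],
                 bf_scan_hits(s, p, bg, alpha))
    rcp <- prc2scan:::reverse_complement_pwm(p)
    expect_equal(hits$start[hits$strand == "-"],
                 bf_scan_hits(s, rcp, bg, alpha))
  }
})

test_that("scan_pwm recovers a planted near-deterministic 6-mer", {
  # at alpha = 5e-5 a 6-mer can only be significant when its letters are
  # rare under the background, so plant a GC-rich word in AT-rich sequence
  withr::local_seed(8)
  s <- random_seq(3000, gc = 0.3)
  substr(s, 1501, 1506) <- "GCCGCG"
  p <- pwm_from_consensus("m", "GCCGCG")
  hits <- scan_pwm(c(c1 = s), p, alpha = 5e-5)
  expect_true(any(hits$start <= 1500 & hits$end >= 1506))
  # AT-rich PWM finds nothing in an all-G sequence
  expect_equal(nrow(scan_pwm(c(c1 = strrep("G", 500)),
                             pwm_from_consensus("at", "ATATAT"),
                             alpha = 5e-5)), 0)
})

test_that("hit multiset is invariant under reverse complement", {
  withr::local_seed(9)
  g <- c(c1 = random_seq(4000, gc = 0.45))
  p <- pwm_from_consensus("m", "ACGCGT", p = 0.9)
  fwd <- scan_pwm(g, p, alpha = 1e-3)
  rc <- stats::setNames(reverse_complement(g), "c1")
  rev <- scan_pwm(rc, p, alpha = 1e-3)
  L <- nchar(g[[1]])
  key <- function(h) sort(paste(L - h$end, ifelse(h$strand == "+", "-",
                                                  "+")))
  expect_equal(sort(paste(rev$start, rev$strand)), key(fwd))
})

test_that("decreasing alpha never adds hits", {
  withr::local_seed(10)
  g <- c(c1 = random_seq(3000))
  p <- pwm_from_consensus("m", "CCAAT", p = 0.85)
  h1 <- scan_pwm(g, p, alpha = 1e-2)
  h2 <- scan_pwm(g, p, alpha = 1e-4)
  k <- function(h) paste(h$start, h$strand)
  expect_true(all(k(h2) %in% k(h1)))
})

test_that("count_hits matches the island/locus configuration", {
  z <- simulate_preset("zfpm2-like", seed = 4)
  hits <- scan_pwm(z$genome, z$pwms$YY1, alpha = 5e-5)
  whole <- genomic_intervals("zfpm2_bac", 0, 44000)
  expect_equal(count_hits(hits, whole), 11L)
  expect_equal(count_hits(hits, z$islands[1, ]), 0L)
  expect_equal(count_hits(hits[0, ], whole), 0L)
})

test_that("asymmetry_score closed forms", {
  island <- genomic_intervals("c1", 0, 1000)
  left10 <- genomic_intervals("c1", seq(10, 400, length.out = 10),
                              seq(20, 410, length.out = 10))
  a <- asymmetry_score(island, left10)
  expect_equal(a$left, 10L)
  expect_equal(a$right, 0L)
  expect_equal(a$p, 2 * 0.5^10, tolerance = 1e-12)

  both <- genomic_intervals("c1", c(seq(10, 400, 97), seq(600, 990, 97)),
                            c(seq(20, 410, 97), seq(610, 1000, 97)))
  b <- asymmetry_score(island, both)
  expect_equal(b$p, 1)

  none <- asymmetry_score(island, left10[0, ])
  expect_equal(none$left, 0L)
  expect_true(is.na(none$p))
  # middle-spanning hit goes left on exact tie
  mid <- genomic_intervals("c1", 490, 510)
  expect_equal(asymmetry_score(island, mid)$left, 1L)
})

test_that("depletion_flag thresholds and monotonicity", {
  iv <- genomic_intervals("c1", 0, 1000)
  h3 <- genomic_intervals("c1", c(10, 20, 30), c(19, 29, 39))
  expect_true(depletion_flag(iv, h3[0, ], 2))
  expect_false(depletion_flag(iv, h3, 2))
  for (k in 0:5) {
    if (depletion_flag(iv, h3, k)) expect_true(depletion_flag(iv, h3, k + 1))
  }
})
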