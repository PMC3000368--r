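test_that("build_density hand layouts", {
  gl <- c(c1 = 2000)
  # single + read at 0, extension 200, bin 25: bins 1..8 get value 1
  d <- build_density(make_reads("c1", 0, "+"), gl)
  expect_equal(d$tracks$c1[1:8], rep(1, 8))
  expect_equal(sum(d$tracks$c1), 200 / 25)
  # single - read at 1000 covers [800, 1000): bins 33..40
  d2 <- build_density(make_reads("c1", 1000, "-"), gl)
  expect_equal(which(d2$tracks$c1 > 0), 33:40)
  # empty read set: all-zero track
  d3 <- build_density(make_reads("c1", integer()), gl)
  expect_true(all(d3$tracks$c1 == 0))
  # read beyond the end is clipped with a warning
  expect_warning(build_density(make_reads("c1", 1950, "+"), gl), "clipped")
})

test_that("null model: determinism, expected mean, convergence", {
  gl <- c(c1 = 1e6)
  rs <- make_reads("c1", rep(0, 10000))  # positions irrelevant to the null
  n1 <- build_null(rs, gl, window_bp = 1000, n_rand = 5, seed = 42)
  n2 <- build_null(rs, gl, window_bp = 1000, n_rand = 5, seed = 42)
  expect_identical(n1$counts, n2$counts)
  expect_lt(abs(mean(n1$counts) - 10) / 10, 0.05)

  # pooling more randomizations shrinks the distance between independent
  # replicates of the null distribution
  tv <- function(a, b) {
    lev <- 0:max(a$counts, b$counts)
    pa <- tabulate(a$counts + 1, length(lev)) / a$n
    pb <- tabulate(b$counts + 1, length(lev)) / b$n
    sum(abs(pa - pb)) / 2
  }
  small <- tv(build_null(rs, gl, n_rand = 2, seed = 1),
              build_null(rs, gl, n_rand = 2, seed = 2))
  big <- tv(build_null(rs, gl, n_rand = 16, seed = 3),
            build_null(rs, gl, n_rand = 16, seed = 4))
  expect_lt(big, small)
})

test_that("window_pvalue matches a hand tally on a toy null", {
  null <- toy_null(c(rep(0, 20), rep(5, 20), rep(10, 10)))
  expect_equal(window_pvalue(0, null), 1)
  expect_equal(window_pvalue(5, null), (30 + 1) / 51)
  expect_equal(window_pvalue(6, null), (10 + 1) / 51)
  expect_equal(window_pvalue(11, null), 1 / 51)  # tail floor
  cnts <- 0:12
  expect_true(all(diff(window_pvalue(cnts, null)) <= 0))
})

test_that("call_enriched_windows: empty input and calibration example", {
  gl <- c(c1 = 1e6)
  empty <- call_enriched_windows(make_reads("c1", integer()), gl, seed = 1)
  expect_equal(nrow(empty), 0)

  rr <- generate_reads(chip_spec(10000), gl, seed = 31)
  cw <- call_enriched_windows(rr$reads, gl, step_bp = 1000, seed = 32)
  frac <- nrow(cw) / attr(cw, "n_windows")
  expect_gte(frac, 0)
  expect_lte(frac, 0.003)  # pure-null called fraction near 1e-3
})

test_that("merge_regions gap rule, transitivity, idempotence, order", {
  w <- data.frame(contig = "c1", start = c(0L, 1800L),
                  end = c(1000L, 2800L), count = c(5L, 7L),
                  p_value = c(1e-4, 5e-5))
  m <- merge_regions(w, gap_bp = 1000)
  expect_equal(nrow(m), 1)
  expect_equal(m$width_bp, 2800)
  expect_equal(m$p_value, 5e-5)
  expect_equal(m$summit, (1800 + 2800) %/% 2)

  w2 <- data.frame(contig = "c1", start = c(0L, 2500L),
                   end = c(1000L, 3500L))
  expect_equal(nrow(merge_regions(w2, gap_bp = 1000)), 2)

  # chain of 5 windows each 900 apart merges transitively into one region
  chain <- data.frame(contig = "c1", start = seq(0L, by = 1900L,
                                                 length.out = 5))
  chain$end <- chain$start + 1000L
  mc <- merge_regions(chain, gap_bp = 1000)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$n_windows, 5L)

  # input order must not matter
  shuf <- chain[c(3, 1, 5, 2, 4), ]
  expect_equal(merge_regions(shuf, gap_bp = 1000)[, 1:3], mc[, 1:3])
  # idempotent
  again <- merge_regions(mc[, c("contig", "start", "end")], gap_bp = 1000)
  expect_equal(again[, 1:3], mc[, 1:3])
})

test_that("identical read sets give identical promoter call columns", {
  gl <- c(c1 = 100000)
  rr <- generate_reads(chip_spec(2000), gl, seed = 8)
  prom <- data.frame(id = paste0("p", 1:5), contig = "c1",
                     tss = as.integer(seq(10000, 90000, length.out = 5)),
                     strand = "+")
  calls <- classify_promoters(prom, list(A = rr$reads, B = rr$reads), gl,
                              seed = 9)
  expect_identical(calls$A, calls$B)
})

test_that("signal_matrix partitions and orders rows", {
  regions <- data.frame(contig = "c1",
                        start = c(10000L, 40000L, 70000L),
                        end = c(15000L, 42000L, 71000L),
                        width_bp = c(5000L, 2000L, 1000L))
  islands <- genomic_intervals("c1", c(40500L, 70100L), c(41000L, 70500L))
  rs <- make_reads("c1", seq(0, 99000, by = 500))
  dens <- build_density(rs, c(c1 = 100000))
  sm <- signal_matrix(regions, dens, islands, span_bp = 20000)
  expect_equal(sm$rows$group, c("island", "island", "non_island"))
  # within the island group, width descending: 2 kb before 1 kb
  expect_equal(sm$rows$width_bp, c(2000L, 1000L, 5000L))
  expect_equal(ncol(sm$signal), 20000 / 25)
  # identical widths fall back to coordinate order
  regions$width_bp <- 1000L
  sm2 <- signal_matrix(regions, dens, islands[0, ], span_bp = 20000)
  expect_equal(sm2$rows$start, regions$start)
  # center column equals the density at the region midpoint
  mid <- (regions$start[1] + regions$end[1]) %/% 2
  expect_equal(sm2$signal[which(sm2$rows$start == regions$start[1]),
                          (20000 / 25) %/% 2 + 1],
               dens$tracks$c1[mid %/% 25 + 1])
  # rows near the contig edge are NA-padded
  edge <- data.frame(contig = "c1", start = 1000L, end = 2000L,
                     width_bp = 1000L)
  sm3 <- signal_matrix(edge, dens, islands[0, ], span_bp = 20000)
  expect_true(anyNA(sm3$signal[1, ]))
})

test_that("spreading_extent geometry and monotonicity", {
  dist <- c(500, 1500, 2500, 3500)
  val <- c(8, 5, 3, 1)
  expect_equal(spreading_extent(dist, val, 2), 2500)
  expect_equal(spreading_extent(dist, c(1, 1, 1, 1), 2), 0)
  # contiguity: a gap stops the scan even if a farther point is high
  expect_equal(spreading_extent(dist, c(8, 1, 9, 9), 2), 500)
  ext <- vapply(c(0.5, 2, 4, 6, 9), function(th) {
    spreading_extent(dist, val, th)
  }, 0)
  expect_true(all(diff(ext) <= 0))
})
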