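test_that("generate_genome hits GC and O/E targets and is seeded", {
  spec <- genome_spec(6000, gc = 0.40, cpg_oe = 0.20,
                      segments = data.frame(start = 2000L, end = 3000L,
                                            gc = 0.65, cpg_oe = 0.80))
  g1 <- generate_genome(spec, seed = 13)
  g2 <- generate_genome(spec, seed = 13)
  expect_identical(g1$genome, g2$genome)
  expect_false(identical(g1$genome, generate_genome(spec, seed = 14)$genome))

  seg <- substr(g1$genome[[1]], 2001, 3000)
  expect_lt(abs(gc_fraction(seg) - 0.65), 0.03)
  expect_lt(abs(cpg_observed_expected(seg) - 0.80), 0.1)
  bg <- substr(g1$genome[[1]], 1, 2000)
  expect_lt(abs(gc_fraction(bg) - 0.40), 0.03)
  expect_lt(abs(cpg_observed_expected(bg) - 0.20), 0.1)
})

test_that("genome spec validation and infeasible targets", {
  expect_error(genome_spec(1000, segments = data.frame(
    start = c(0L, 100L), end = c(200L, 300L),
    gc = 0.5, cpg_oe = 0.5)), "disjoint")
  expect_error(genome_spec(1000, segments = data.frame(
    start = 900L, end = 1200L, gc = 0.5, cpg_oe = 0.5)), "bounds")
  expect_error(generate_genome(genome_spec(500, gc = 0.02, cpg_oe = 100),
                               seed = 1), "infeasible")
  expect_error(genome_spec(1000, motifs = list(
    list(name = "m", consensus = "ACGT", positions = 999L))), "bounds")
})

test_that("motif plants are written verbatim", {
  spec <- genome_spec(2000, motifs = list(
    list(name = "m", consensus = "ACGTACGTA", positions = c(500L, 1200L))))
  g <- generate_genome(spec, seed = 2)
  expect_equal(substr(g$genome[[1]], 501, 509), "ACGTACGTA")
  expect_equal(substr(g$genome[[1]], 1201, 1209), "ACGTACGTA")
  expect_equal(g$truth$motifs$position, c(500L, 1200L))
})

test_that("truth records round-trip through JSON", {
  spec <- genome_spec(1000, segments = data.frame(
    start = 100L, end = 700L, gc = 0.6, cpg_oe = 0.7))
  tr <- generate_genome(spec, seed = 4)$truth
  f <- withr::local_tempfile(fileext = ".json")
  write_truth(tr, f)
  rt <- read_truth(f)
  expect_equal(rt$seed, tr$seed)
  expect_equal(rt$segments$start, tr$segments$start)
  expect_equal(rt$background$cpg_oe, tr$background$cpg_oe)
})

test_that("generate_reads: enrichment ratio and determinism", {
  gl <- c(c1 = 100000)
  reg <- data.frame(contig = "c1", start = 50000L, end = 52000L, fold = 8)
  r1 <- generate_reads(chip_spec(20000, regions = reg), gl, seed = 6)
  r2 <- generate_reads(chip_spec(20000, regions = reg), gl, seed = 6)
  expect_identical(r1$reads$reads, r2$reads$reads)
  pos <- r1$reads$reads$pos
  inside <- sum(pos >= 50000 & pos < 52000) / 2          # per kb
  outside <- sum(pos < 50000 | pos >= 52000) / 98        # per kb
  # fold 8 within 3 sd of the window count
  expect_lt(abs(inside / outside - 8), 3 * sqrt(inside / 2) / outside)
  expect_equal(r1$reads$total_count, 20000L)
})

test_that("generate_rnaseq: rates drive counts, reads stay exonic", {
  genes <- list(
    list(id = "off", rate = 0,
         exons = data.frame(contig = "c1", start = 0L, end = 1000L)),
    list(id = "lo", rate = 1,
         exons = data.frame(contig = "c1", start = 5000L, end = 6000L)),
    list(id = "hi", rate = 9,
         exons = data.frame(contig = "c1", start = 9000L, end = 9500L,
                            stringsAsFactors = FALSE)))
  r <- generate_rnaseq(genes, 5000, seed = 7)
  expect_equal(r$truth$counts[1], 0)
  ratio <- r$truth$counts[3] / r$truth$counts[2]
  expect_lt(abs(ratio - 9), 1)  # multinomial sampling error at n = 5000
  expect_true(all(r$reads$reads$pos >= 9000 & r$reads$reads$pos < 9500 |
                    r$reads$reads$pos < 6000))
  expect_identical(generate_rnaseq(genes, 5000, seed = 7)$reads$reads,
                   r$reads$reads)
})

test_that("generate_methylation: levels, binomial recovery, determinism", {
  pos <- data.frame(contig = "c1", pos = seq(0L, by = 37L,
                                             length.out = 200))
  z <- generate_methylation(pos, 0, 20, seed = 8)
  expect_true(all(z$calls$methylated == 0))
  m <- generate_methylation(pos, 0.8, 20, seed = 9)
  iv <- genomic_intervals("c1", 0, max(pos$pos) + 1)
  expect_lt(abs(interval_methylation(m$calls, iv)$mean_level - 0.8), 0.05)
  expect_identical(generate_methylation(pos, 0.8, 20, seed = 9)$calls,
                   m$calls)
  expect_error(generate_methylation(pos, 1.2, 20, seed = 1))
})

test_that("presets are deterministic and write their artifact bundle", {
  s1 <- simulate_preset("arl3-sfxn2-like", seed = 3)
  s2 <- simulate_preset("arl3-sfxn2-like", seed = 3)
  expect_identical(s1$genome, s2$genome)
  expect_equal(nchar(s1$genome[[1]]), 20000)

  d <- withr::local_tempdir()
  sim <- simulate_preset("gene-desert-like", seed = 2, outdir = d)
  expect_true(file.exists(file.path(d, "genome.fa")))
  expect_true(file.exists(file.path(d, "truth.json")))
  expect_identical(read_fasta(file.path(d, "genome.fa")), sim$genome)
})
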