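make_promoter_genome <- function(gc, oe, seed) {
  generate_genome(genome_spec(4000, gc = gc, cpg_oe = oe), seed)$genome
}

test_that("classify_promoter_cpg separates planted promoter classes", {
  # HCP: 65% GC / O/E 0.9 core under the promoter span
  hcp <- generate_genome(genome_spec(
    4000, gc = 0.30, cpg_oe = 0.20,
    segments = data.frame(start = 1500L, end = 2600L, gc = 0.65,
                          cpg_oe = 0.90)), seed = 21)$genome
  expect_equal(classify_promoter_cpg(hcp, names(hcp), 1600)[1], "HCP")
  # LCP: CpG-depleted 30% GC background everywhere (at bulk O/E 0.1-0.2 a
  # 500 bp sub-window clears O/E 0.4 by chance often enough that the
  # LCP/ICP boundary is stochastic; a true LCP exemplar is CpG-poor)
  lcp <- make_promoter_genome(0.30, 0.05, 22)
  expect_equal(classify_promoter_cpg(lcp, names(lcp), 1600)[1], "LCP")
  # ICP: O/E ~0.5 everywhere but GC below the HCP cutoff
  icp <- make_promoter_genome(0.50, 0.50, 23)
  expect_equal(classify_promoter_cpg(icp, names(icp), 1600)[1], "ICP")
})

test_that("classify_promoter_cpg is deterministic and threshold-monotone", {
  g <- make_promoter_genome(0.55, 0.55, 24)
  c1 <- classify_promoter_cpg(g, names(g), 1600)
  expect_identical(c1, classify_promoter_cpg(g, names(g), 1600))
  # raising the HCP O/E requirement can only demote, never promote to HCP
  rank <- c(LCP = 1, ICP = 2, HCP = 3)
  loose <- classify_promoter_cpg(g, names(g), 1600, hcp_min_oe = 0.4)
  strict <- classify_promoter_cpg(g, names(g), 1600, hcp_min_oe = 0.8)
  expect_lte(rank[strict[1]], rank[loose[1]])
})

test_that("expression_score hand layout and edge cases", {
  exons <- data.frame(contig = "c1", start = 1000L, end = 4000L)
  rs <- make_reads("c1", c(1100, 1200, 1300, 3500))
  # best 1 kb window holds 3 reads; library of 4 reads
  expect_equal(expression_score(exons, rs), 3 / 4 * 1e6)
  expect_equal(expression_score(exons, make_reads("c1", integer()),
                                total_reads = 10), 0)
  expect_error(expression_score(exons[0, ], rs), "no exons")
  # whole-span rule when exonic length < window
  short <- data.frame(contig = "c1", start = 1000L, end = 1500L)
  expect_equal(expression_score(short, rs), 3 / 4 * 1e6)
})

test_that("expression_score equals brute-force enumeration on 3 exons", {
  withr::local_seed(31)
  exons <- data.frame(contig = "c1", start = c(100L, 3000L, 7000L),
                      end = c(900L, 3700L, 8000L))
  pos <- unlist(lapply(seq_len(3), function(i) {
    sample(exons$start[i]:(exons$end[i] - 1), 40, replace = TRUE)
  }))
  rs <- make_reads("c1", pos)
  expect_equal(expression_score(exons, rs),
               bf_expression(exons, rs, 1000, rs$total_count))
})

test_that("interval_methylation weighting and degenerate cases", {
  calls <- data.frame(contig = "c1", pos = c(10L, 20L, 30L),
                      methylated = c(0L, 0L, 0L), total = c(10L, 10L, 10L))
  iv <- genomic_intervals("c1", 0, 100)
  expect_equal(interval_methylation(calls, iv)$mean_level, 0)

  calls2 <- data.frame(contig = "c1", pos = c(10L, 20L),
                       methylated = c(2L, 24L), total = c(10L, 30L))
  r <- interval_methylation(calls2, iv)
  expect_equal(r$mean_level, 0.65)  # coverage-weighted
  expect_equal(r$n_cpg, 2L)
  expect_true(is.na(interval_methylation(calls2,
                                         genomic_intervals("c1", 500,
                                                           600))$mean_level))
})

test_that("methylation composite: flat zero, strand mirror, gene order", {
  tss <- data.frame(contig = "c1", tss = 20000L, strand = "+")
  pos <- data.frame(contig = "c1", pos = seq(15100L, 24900L, by = 150L))
  zero <- generate_methylation(pos, 0, 10, seed = 5)$calls
  prof <- methylation_composite(zero, tss)
  expect_true(all(prof$mean_level[!is.na(prof$mean_level)] == 0))

  # a minus-strand gene over mirrored positions gives the mirrored profile
  lv <- function(p) ifelse(abs(p$pos - 20000) < 2000, 0.1, 0.9)
  calls <- generate_methylation(pos, lv, 50, seed = 6)$calls
  plus <- methylation_composite(calls, tss, step_bp = 200)
  mpos <- data.frame(contig = "c1", pos = 40000L - pos$pos)
  mcalls <- calls
  mcalls$pos <- 40000L - calls$pos
  minus <- methylation_composite(
    mcalls, data.frame(contig = "c1", tss = 20000L, strand = "-"),
    step_bp = 200)
  expect_equal(minus$mean_level, plus$mean_level, tolerance = 1e-12)

  # pooling is invariant to gene order
  two <- data.frame(contig = "c1", tss = c(20000L, 20000L),
                    strand = c("+", "+"))
  expect_equal(methylation_composite(calls, two)$mean_level,
               methylation_composite(calls, two[2:1, ])$mean_level)
})

test_that("stratify_inactive_hcps applies the single-island filter", {
  prom <- data.frame(
    id = c("one_island", "two_islands", "lcp"),
    cpg_class = c("HCP", "HCP", "LCP"),
    n_islands = c(1L, 2L, 0L),
    expression_score = c(0.1, 0.2, 5),
    ezh2_positive = c(TRUE, FALSE, FALSE),
    island_length_bp = c(800L, 400L, NA),
    island_gc = c(0.62, 0.55, NA))
  out <- stratify_inactive_hcps(prom)
  expect_equal(out$filtered$id, "one_island")
  expect_equal(out$inactive_threshold, 5)  # data-driven from the LCP
  expect_true(is.na(out$p_ranksum))        # only one group present
})
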