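# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately use naive enumeration, never the vectorized paths
# they check.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-window GC / CpG O/E by direct substring recomputation
bf_window_stats <- function(seq, window, step) {
  starts <- seq(0, nchar(seq) - window, by = step)
  data.frame(
    start = starts,
    gc = vapply(starts, function(a) {
      gc_fraction(substr(seq, a + 1, a + window))
    }, 0),
    oe = vapply(starts, function(a) {
      cpg_observed_expected(substr(seq, a + 1, a + window))
    }, 0)
  )
}

# exact PWM match p-values by full word enumeration (motif length <= 8);
# tails are precomputed over sorted word scores so lookups stay cheap
bf_pwm_oracle <- function(pwm, background) {
  m <- nrow(pwm$matrix)
  stopifnot(m <= 8)
  background <- background / sum(background)
  words <- as.matrix(expand.grid(rep(list(1:4), m)))
  lo <- log2(sweep(pwm$matrix, 2, background, "/"))
  sc <- apply(words, 1, function(w) sum(lo[cbind(seq_len(m), w)]))
  pr <- apply(words, 1, function(w) prod(background[w]))
  ord <- order(sc)
  sc_s <- sc[ord]
  tail_s <- rev(cumsum(rev(pr[ord])))  # P(S >= sc_s[i])
  list(
    score = function(codes) sum(lo[cbind(seq_len(m), codes)]),
    pvalue = function(s) {
      i <- findInterval(s - 1e-9, sc_s) + 1L
      if (i > length(tail_s)) 0 else tail_s[i]
    }
  )
}

# hit starts (0-based) on one strand by scoring every position naively
bf_scan_hits <- function(seq, pwm, background, alpha) {
  or <- bf_pwm_oracle(pwm, background)
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  m <- nrow(pwm$matrix)
  starts <- integer(0)
  for (i in seq_len(nchar(seq) - m + 1)) {
    cs <- codes[i:(i + m - 1)]
    if (anyNA(cs)) next
    if (or$pvalue(or$score(cs)) <= alpha) starts <- c(starts, i - 1L)
  }
  starts
}

# expression score by enumerating every window placement on the virtual
# exon concatenation
bf_expression <- function(exons, rs, window_bp, total_reads) {
  offs <- cumsum(c(0, exons$end - exons$start))
  virt <- numeric(0)
  for (i in seq_len(nrow(exons))) {
    sel <- rs$reads$contig == exons$contig[i] &
      rs$reads$pos >= exons$start[i] & rs$reads$pos < exons$end[i]
    virt <- c(virt, rs$reads$pos[sel] - exons$start[i] + offs[i])
  }
  L <- offs[length(offs)]
  if (L <= window_bp) return(length(virt) / total_reads * 1e6)
  mx <- 0
  for (a in 0:(L - window_bp)) {
    mx <- max(mx, sum(virt >= a & virt < a + window_bp))
  }
  mx / total_reads * 1e6
}

make_reads <- function(contig, pos, strand = "+", extension_bp = 200) {
  read_set(data.frame(contig = rep_len(contig, length(pos)),
                      pos = as.integer(pos),
                      strand = rep_len(strand, length(pos)),
                      stringsAsFactors = FALSE),
           extension_bp = extension_bp)
}

# a toy null model with known counts (for hand-tally p-value checks)
toy_null <- function(counts, window_bp = 1000) {
  structure(list(window_bp = window_bp, n_rand = 1L, seed = 0L,
                 counts = sort(counts), n = length(counts),
                 total_count = sum(counts), genome_bp = NA),
            class = "null_model")
}
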