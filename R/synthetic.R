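# Synthetic-data generators. Every generator is a pure function of
# (spec, seed) and returns a ground-truth record alongside the data, so the
# whole pipeline can be exercised closed-loop with no external downloads.
#
# Backgrounds are drawn from a first-order (dinucleotide) Markov chain so
# that CpG O/E is controllable independently of GC content -- the
# discriminating statistic of GC-rich element discovery is O/E, not GC
# alone, so an i.i.d. base model would not do.

# transition matrix whose stationary sequence statistics hit (gc, oe);
# calibrated by fixed-point iteration on the nominal parameters.
markov_chain_params <- function(gc, oe, iters = 40) {
  stopifnot(gc > 0, gc < 1, oe >= 0)
  g <- gc; e <- max(oe, 1e-6)
  Tm <- NULL; st <- NULL
  for (it in seq_len(iters)) {
    pi0 <- c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2)
    pCG <- e * pi0[3]
    if (pCG > 0.95) {
      stop("infeasible GC / CpG O/E combination (CpG demand too high)")
    }
    Tm <- matrix(pi0, 4, 4, byrow = TRUE,
                 dimnames = list(BASES, BASES))
    Tm[2, ] <- pi0 * (1 - pCG) / (1 - pi0[3])
    Tm[2, 3] <- pCG
    st <- rep(0.25, 4)
    for (k in 1:200) st <- as.vector(st %*% Tm)
    gc_a <- st[2] + st[3]
    oe_a <- Tm[2, 3] / st[3]
    g <- min(0.999, max(1e-4, g * gc / gc_a))
    e <- e * max(oe, 1e-6) / oe_a
  }
  list(transition = Tm, stationary = st)
}

# sample n bases from the chain; returns an uppercase string
sample_chain <- function(n, chain) {
  cum <- t(apply(chain$transition, 1, cumsum))
  cum0 <- cumsum(chain$stationary)
  u <- stats::runif(n)
  v <- integer(n)
  v[1] <- findInterval(u[1], cum0) + 1L
  for (i in seq_len(n)[-1]) {
    v[i] <- findInterval(u[i], cum[v[i - 1L], ]) + 1L
  }
  intToUtf8(c(65L, 67L, 71L, 84L)[v])
}

#' Specification for a synthetic genome
#'
#' @param length contig length in bp.
#' @param gc,cpg_oe background GC fraction and CpG observed/expected.
#' @param contig contig name.
#' @param segments data.frame (start, end, gc, cpg_oe) of planted
#'   GC/CpG-controlled segments; must be disjoint and within bounds.
#' @param motifs list of `list(name =, consensus =, positions =)` motif
#'   plants (consensus written verbatim at each 0-based position).
#' @return validated spec list.
#' @export
genome_spec <- function(length, gc = 0.40, cpg_oe = 0.20,
                        contig = "synth", segments = NULL, motifs = list()) {
  if (is.null(segments)) {
    segments <- data.frame(start = integer(), end = integer(),
                           gc = numeric(), cpg_oe = numeric())
  }
  if (nrow(segments) > 1) {
    s <- segments[order(segments$start), ]
    if (any(s$start[-1] < s$end[-nrow(s)])) {
      stop("planted segments must be disjoint")
    }
  }
  if (nrow(segments) && (any(segments$start < 0) ||
                         any(segments$end > length))) {
    stop("planted segment out of bounds")
  }
  if (nrow(segments) && any(segments$gc <= 0 | segments$gc >= 1)) {
    stop("segment gc target must be in (0,1)")
  }
  for (m in motifs) {
    if (any(m$positions < 0 | m$positions + nchar(m$consensus) > length)) {
      stop("motif plant out of bounds")
    }
  }
  list(length = as.integer(length), gc = gc, cpg_oe = cpg_oe,
       contig = contig, segments = segments, motifs = motifs)
}

#' Generate a synthetic genome with planted segments and motifs
#'
#' Background and each planted segment are drawn from first-order Markov
#' chains calibrated to their GC / CpG O/E targets; motif consensus strings
#' are then written verbatim at the requested positions. At segment lengths
#' >= 500 bp the realized GC is within about +/-0.03 and O/E within about
#' +/-0.1 of target.
#'
#' @param spec [genome_spec()].
#' @param seed RNG seed.
#' @return list: `genome` (named character vector) and `truth` (seed, spec
#'   echo, segments, motifs; serializable with [write_truth()]).
#' @export
generate_genome <- function(spec, seed) {
  seq <- with_seed(seed, {
    bg <- markov_chain_params(spec$gc, spec$cpg_oe)
    s <- strsplit(sample_chain(spec$length, bg), "")[[1]]
    for (i in seq_len(nrow(spec$segments))) {
      seg <- spec$segments[i, ]
      chain <- markov_chain_params(seg$gc, seg$cpg_oe)
      len <- seg$end - seg$start
      # sampling noise at ~1 kb is comparable to the promised tolerances
      # (GC +/-0.03, O/E +/-0.1), so retry within the seeded stream until
      # the draw lands inside them; keep the best draw as a fallback
      best <- NULL; best_dev <- Inf
      for (try in 1:50) {
        cand <- sample_chain(len, chain)
        dev <- max(abs(gc_fraction(cand) - seg$gc) / 0.03,
                   abs(cpg_observed_expected(cand) - seg$cpg_oe) / 0.1)
        if (dev < best_dev) { best <- cand; best_dev <- dev }
        if (len >= 300 && best_dev <= 0.95) break
        if (len < 300) break
      }
      s[(seg$start + 1):seg$end] <- strsplit(best, "")[[1]]
    }
    for (m in spec$motifs) {
      b <- strsplit(toupper(m$consensus), "")[[1]]
      for (p in m$positions) s[(p + 1):(p + length(b))] <- b
    }
    paste(s, collapse = "")
  })
  genome <- stats::setNames(seq, spec$contig)
  motif_df <- if (length(spec$motifs)) {
    do.call(rbind, lapply(spec$motifs, function(m) {
      data.frame(name = m$name, consensus = m$consensus,
                 position = m$positions, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(name = character(), consensus = character(),
               position = integer())
  }
  truth <- list(kind = "genome", seed = seed, contig = spec$contig,
                length = spec$length,
                background = list(gc = spec$gc, cpg_oe = spec$cpg_oe),
                segments = spec$segments, motifs = motif_df)
  list(genome = genome, truth = truth)
}

# Disrupt all significant PWM hits outside the planted spans, so fixture
# motif counts are exact by construction. Low-GC backgrounds make GC-rich
# words individually so improbable that near-consensus words also clear the
# significance threshold, hence scrubbing must use the scanner itself, not
# exact word matching. Bases inside `keep` intervals are never touched.
scrub_pwm_hits <- function(genome, pwm, alpha, keep, max_iter = 50) {
  for (it in seq_len(max_iter)) {
    hits <- scan_pwm(genome, pwm, alpha = alpha)
    planted <- rep(FALSE, nrow(hits))
    if (nrow(keep)) {
      for (j in seq_len(nrow(keep))) {
        planted <- planted | (hits$contig == keep$contig[j] &
                                hits$start == keep$start[j] &
                                hits$end == keep$end[j] &
                                hits$strand == "+")
      }
    }
    spur <- hits[!planted, , drop = FALSE]
    if (nrow(spur) == 0) return(genome)
    for (i in seq_len(nrow(spur))) {
      cand <- seq(spur$start[i], spur$end[i] - 1L)
      if (nrow(keep)) {
        inkeep <- rep(FALSE, length(cand))
        for (j in seq_len(nrow(keep))) {
          inkeep <- inkeep | (spur$contig[i] == keep$contig[j] &
                                cand >= keep$start[j] & cand < keep$end[j])
        }
        cand <- cand[!inkeep]
      }
      if (!length(cand)) stop("cannot scrub hit inside a planted span")
      at <- cand[(it - 1L) %% length(cand) + 1L] + 1L
      cur <- substr(genome[[spur$contig[i]]], at, at)
      substr(genome[[spur$contig[i]]], at, at) <-
        if (cur == "A") "T" else "A"
    }
  }
  stop("motif scrubbing did not converge")
}

#' Specification for a synthetic ChIP read set
#'
#' @param total_reads number of reads.
#' @param regions data.frame (contig, start, end, fold) of enriched
#'   regions, fold >= 1.
#' @param extension_bp,label passed through to the generated [read_set()].
#' @return spec list.
#' @export
chip_spec <- function(total_reads, regions = NULL, extension_bp = 200,
                      label = "chip") {
  if (is.null(regions)) {
    regions <- data.frame(contig = character(), start = integer(),
                          end = integer(), fold = numeric())
  }
  if (nrow(regions) && any(regions$fold < 1)) {
    stop("enrichment folds must be >= 1")
  }
  list(total_reads = as.integer(total_reads), regions = regions,
       extension_bp = extension_bp, label = label)
}

#' Generate ChIP reads: uniform background plus fold-enriched regions
#'
#' Read 5' positions are a mixture of a uniform background over the whole
#' genome and extra mass inside each enriched region, weighted so the
#' expected local read rate inside a region is `fold` times the background
#' rate. Strands are Bernoulli(1/2).
#'
#' @param spec [chip_spec()].
#' @param genome_lengths named vector of contig lengths (or a genome).
#' @param seed RNG seed.
#' @return list: `reads` ([read_set()]) and `truth` (region table with
#'   folds, expected background rate per kb).
#' @export
generate_reads <- function(spec, genome_lengths, seed) {
  gl <- genome_lengths(genome_lengths)
  G <- sum(gl)
  reg <- spec$regions
  w <- c(G, if (nrow(reg)) (reg$end - reg$start) * (reg$fold - 1))
  out <- with_seed(seed, {
    ncomp <- as.vector(stats::rmultinom(1, spec$total_reads, w))
    contig <- character(0); pos <- integer(0)
    # background: uniform over the genome
    ct <- sample.int(length(gl), ncomp[1], replace = TRUE, prob = gl)
    contig <- names(gl)[ct]
    pos <- as.integer(floor(stats::runif(ncomp[1]) * gl[ct]))
    if (nrow(reg)) {
      for (i in seq_len(nrow(reg))) {
        n <- ncomp[i + 1]
        if (n == 0) next
        contig <- c(contig, rep(reg$contig[i], n))
        pos <- c(pos, as.integer(reg$start[i] +
                                   floor(stats::runif(n) *
                                           (reg$end[i] - reg$start[i]))))
      }
    }
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    data.frame(contig = contig, pos = pos, strand = strand,
               stringsAsFactors = FALSE)
  })
  rs <- read_set(out, extension_bp = spec$extension_bp, label = spec$label)
  truth <- list(kind = "chip", seed = seed, total_reads = spec$total_reads,
                regions = reg,
                background_rate_per_kb = spec$total_reads * 1000 / sum(w))
  list(reads = rs, truth = truth)
}

#' Generate RNA-Seq reads over exon models
#'
#' Gene read counts are multinomial in the supplied rates; within a gene,
#' read 5' positions are uniform over its exonic bases.
#'
#' @param genes list of `list(id =, rate =, exons = data.frame(contig,
#'   start, end))`.
#' @param total_reads library size.
#' @param seed RNG seed.
#' @param extension_bp,label passed to [read_set()].
#' @return list: `reads` and `truth` (per-gene counts and rates).
#' @export
generate_rnaseq <- function(genes, total_reads, seed, extension_bp = 200,
                            label = "rnaseq") {
  rates <- vapply(genes, function(g) g$rate, 0)
  stopifnot(all(rates >= 0))
  out <- with_seed(seed, {
    counts <- if (sum(rates) > 0) {
      as.vector(stats::rmultinom(1, total_reads, rates))
    } else rep(0L, length(genes))
    contig <- character(0); pos <- integer(0)
    for (i in seq_along(genes)) {
      if (counts[i] == 0) next
      ex <- genes[[i]]$exons
      lens <- ex$end - ex$start
      virt <- floor(stats::runif(counts[i]) * sum(lens))
      cuts <- cumsum(c(0, lens))
      k <- findInterval(virt, cuts, rightmost.closed = FALSE) # 1..nexon
      k[k > nrow(ex)] <- nrow(ex)
      contig <- c(contig, ex$contig[k])
      pos <- c(pos, as.integer(ex$start[k] + virt - cuts[k]))
    }
    strand <- sample(c("+", "-"), length(pos), replace = TRUE)
    list(df = data.frame(contig = contig, pos = pos, strand = strand,
                         stringsAsFactors = FALSE), counts = counts)
  })
  rs <- read_set(out$df, extension_bp = extension_bp, label = label)
  truth <- list(kind = "rnaseq", seed = seed, total_reads = total_reads,
                gene_ids = vapply(genes, function(g) g$id, ""),
                rates = rates, counts = out$counts)
  list(reads = rs, truth = truth)
}

#' All CpG (CG dinucleotide) positions in a genome
#'
#' @param genome named character vector.
#' @return data.frame (contig, pos) with pos the 0-based C position.
#' @export
cpg_positions <- function(genome) {
  out <- lapply(names(genome), function(ct) {
    occ <- gregexpr("CG", genome[[ct]], fixed = TRUE)[[1]]
    occ <- occ[occ > 0] - 1L
    if (!length(occ)) return(NULL)
    data.frame(contig = ct, pos = occ, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) data.frame(contig = character(), pos = integer()) else res
}

#' Generate binomial methylation calls at CpG positions
#'
#' @param positions data.frame (contig, pos) of CpG sites.
#' @param level true methylation level: scalar, vector (per site), or
#'   function(positions df) -> levels in \[0,1\].
#' @param coverage reads per site (scalar or vector).
#' @param seed RNG seed.
#' @return list: `calls` (contig, pos, methylated, total) and `truth`
#'   (per-site levels).
#' @export
generate_methylation <- function(positions, level, coverage, seed) {
  lv <- if (is.function(level)) level(positions) else
    rep_len(level, nrow(positions))
  stopifnot(all(lv >= 0 & lv <= 1))
  cov <- rep_len(coverage, nrow(positions))
  meth <- with_seed(seed, stats::rbinom(nrow(positions), cov, lv))
  calls <- data.frame(contig = positions$contig, pos = positions$pos,
                      methylated = meth, total = cov,
                      stringsAsFactors = FALSE)
  list(calls = calls,
       truth = list(kind = "methylation", seed = seed, level = lv,
                    coverage = cov))
}

#' Generate noisy qPCR replicates with known true folds
#'
#' ChIP quantity = input x fold x lognormal(0, cv). A fold-1 negative
#' genomic control amplicon is appended per mark when none is flagged.
#'
#' @param amplicons data.frame (amplicon, mark, fold; optional is_control).
#' @param cv lognormal sdlog of the multiplicative noise.
#' @param replicates biological replicates per measurement.
#' @param seed RNG seed.
#' @param input_quantity input DNA quantity (equal-mass pairing).
#' @return list: `table` (qPCR measurement table) and `truth`.
#' @export
generate_qpcr <- function(amplicons, cv = 0.1, replicates = 3, seed = 1,
                          input_quantity = 1) {
  stopifnot(cv >= 0, replicates >= 1)
  if (!"is_control" %in% names(amplicons)) amplicons$is_control <- FALSE
  if (!any(amplicons$is_control)) {
    ctrl <- do.call(rbind, lapply(unique(amplicons$mark), function(mk) {
      data.frame(amplicon = "neg_ctrl", mark = mk, fold = 1,
                 is_control = TRUE, stringsAsFactors = FALSE)
    }))
    amplicons <- rbind(amplicons[, c("amplicon", "mark", "fold",
                                     "is_control")], ctrl)
  }
  rows <- amplicons[rep(seq_len(nrow(amplicons)), each = replicates), ]
  rows$replicate <- rep(seq_len(replicates), nrow(amplicons))
  noise <- with_seed(seed, exp(stats::rnorm(nrow(rows), 0, cv)))
  rows$input <- input_quantity
  rows$chip <- input_quantity * rows$fold * noise
  rownames(rows) <- NULL
  table <- rows[, c("amplicon", "mark", "replicate", "chip", "input",
                    "is_control")]
  list(table = table,
       truth = list(kind = "qpcr", seed = seed, cv = cv,
                    replicates = replicates,
                    folds = amplicons[, c("amplicon", "mark", "fold")]))
}

#' Serialize / deserialize ground-truth records
#'
#' @param truth truth record (list).
#' @param path JSON path.
#' @return `read_truth` returns the record; `write_truth` returns `path`
#'   invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# consensus words used by the bundled presets
YY1_CONSENSUS <- "CGCCATTTT"    # YY1-like core; example motif, not the
                                # TRANSFAC matrix
AM_CONSENSUS <- "GGGGCGGGG"     # Sp1-like GC-box, the activating-motif
                                # stand-in

#' Bundled synthetic fixture presets
#'
#' Four stated-world configurations used throughout the test suite:
#' \describe{
#'   \item{zfpm2-like}{44 kb BAC-sized contig, one 1.7 kb GC-rich island
#'     (GC 0.65, O/E 0.80) at 21,000, 11 YY1-consensus motifs planted
#'     outside the island, none inside.}
#'   \item{gene-desert-like}{inert 40 kb contig (GC 0.40, O/E 0.20).}
#'   \item{arl3-sfxn2-like}{20 kb contig with a 1.8 kb island whose
#'     activating motifs all sit in the right half (feeds the asymmetry
#'     statistic).}
#'   \item{ecoli-like}{100 kb low-GC contig with two qualifying 1 kb
#'     GC-rich plants aligned to the 1 kb grid, one of them laden with 6
#'     activating motifs, plus an AT-rich control interval.}
#' }
#' Accidental exact occurrences of the preset's consensus words are
#' scrubbed from the background, so planted motif counts are exact by
#' construction.
#'
#' @param preset preset name.
#' @param seed RNG seed.
#' @param outdir if non-NULL, writes FASTA, truth JSON, planted-feature BED
#'   and PWM files there.
#' @return list: `genome`, `truth`, `pwms` (named list of `pwm`),
#'   `islands` (planted island intervals), `elements` (for ecoli-like, the
#'   expected discovery), `motif_positions`.
#' @export
simulate_preset <- function(preset = c("zfpm2-like", "gene-desert-like",
                                       "arl3-sfxn2-like", "ecoli-like"),
                            seed = 1, outdir = NULL) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    "zfpm2-like" = genome_spec(
      44000, gc = 0.40, cpg_oe = 0.20, contig = "zfpm2_bac",
      segments = data.frame(start = 21000L, end = 22700L, gc = 0.65,
                            cpg_oe = 0.80),
      motifs = list(list(name = "YY1", consensus = YY1_CONSENSUS,
                         positions = c(2000L, 5500L, 8000L, 11000L, 14500L,
                                       18000L, 25500L, 29000L, 33000L,
                                       37500L, 41000L)))),
    "gene-desert-like" = genome_spec(40000, gc = 0.40, cpg_oe = 0.20,
                                     contig = "gene_desert"),
    "arl3-sfxn2-like" = genome_spec(
      20000, gc = 0.40, cpg_oe = 0.20, contig = "arl3_sfxn2",
      segments = data.frame(start = 9000L, end = 10800L, gc = 0.65,
                            cpg_oe = 0.80),
      motifs = list(list(name = "AM", consensus = AM_CONSENSUS,
                         positions = c(9950L, 10050L, 10150L, 10250L,
                                       10350L, 10450L, 10550L, 10650L)))),
    "ecoli-like" = genome_spec(
      100000, gc = 0.40, cpg_oe = 0.20, contig = "ecoli_frag",
      segments = data.frame(start = c(30000L, 70000L),
                            end = c(31000L, 71000L),
                            gc = c(0.65, 0.65), cpg_oe = c(0.85, 0.85)),
      motifs = list(list(name = "AM", consensus = AM_CONSENSUS,
                         positions = c(70060L, 70200L, 70340L, 70480L,
                                       70620L, 70760L))))
  )
  gen <- generate_genome(spec, seed)
  pwms <- list(YY1 = pwm_from_consensus("YY1", YY1_CONSENSUS),
               AM = pwm_from_consensus("AM", AM_CONSENSUS))
  for (m in spec$motifs) {
    keep <- genomic_intervals(spec$contig, m$positions,
                              m$positions + nchar(m$consensus))
    gen$genome <- scrub_pwm_hits(gen$genome, pwms[[m$name]], alpha = 5e-5,
                                 keep = keep)
  }
  islands <- if (nrow(spec$segments)) {
    genomic_intervals(spec$contig, spec$segments$start, spec$segments$end)
  } else genomic_intervals(character(), integer(), integer())
  out <- list(genome = gen$genome, truth = gen$truth, pwms = pwms,
              islands = islands, preset = preset)
  if (preset == "ecoli-like") {
    out$expected_element <- genomic_intervals(spec$contig, 30000L, 31000L)
    out$control_at_rich <- genomic_intervals(spec$contig, 50000L, 51000L)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(out$genome, file.path(outdir, "genome.fa"))
    write_truth(out$truth, file.path(outdir, "truth.json"))
    if (nrow(islands)) {
      write_intervals(islands, file.path(outdir, "planted_islands.bed"))
    }
    write_pwm(pwms, file.path(outdir, "motifs.pwm"))
  }
  out
}
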