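# PWM motif scanning with an exact (discretized-convolution) score
# distribution, the significance-thresholded scan, and motif clustering
# statistics (asymmetry within islands, depletion flags).

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Rows are motif positions, columns A/C/G/T. Input may be counts or
#' probabilities; a pseudocount is added and rows renormalized, so all
#' probabilities are strictly positive.
#'
#' @param name motif name.
#' @param matrix numeric matrix (positions x 4) of counts or probabilities.
#' @param background background base frequencies (A,C,G,T); default uniform.
#' @param pseudocount added to each cell before row normalization.
#' @return object of class `pwm`: list(name, matrix, background, pseudocount).
#' @export
make_pwm <- function(name, matrix, background = rep(0.25, 4),
                     pseudocount = 1e-3) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) stop("PWM must have 4 columns (A,C,G,T)")
  if (any(matrix < 0)) stop("PWM entries must be non-negative")
  m <- sweep(matrix, 1, rowSums(matrix), "/")
  m <- (m + pseudocount) / (1 + 4 * pseudocount)
  colnames(m) <- BASES
  background <- background / sum(background)
  if (any(background <= 0)) stop("background frequencies must be positive")
  structure(list(name = name, matrix = m, background = background,
                 pseudocount = pseudocount), class = "pwm")
}

#' Near-deterministic PWM from a consensus word
#'
#' @param name motif name.
#' @param consensus A/C/G/T string.
#' @param p probability placed on the consensus base at each position.
#' @return `pwm` object.
#' @export
pwm_from_consensus <- function(name, consensus, p = 0.97) {
  b <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(b %in% BASES))
  m <- matrix((1 - p) / 3, nrow = length(b), ncol = 4,
              dimnames = list(NULL, BASES))
  m[cbind(seq_along(b), match(b, BASES))] <- p
  make_pwm(name, m)
}

#' Read PWMs from a tabular file
#'
#' Format: `>name` header lines, then one row per motif position with 4
#' whitespace-separated numbers (A C G T order), counts or probabilities.
#'
#' @param path file path.
#' @param background,pseudocount passed to [make_pwm()].
#' @return named list of `pwm` objects.
#' @export
read_pwm <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop("no '>name' headers in PWM file ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    name <- sub("^>\\s*", "", lines[hdr[i]])
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (any(lengths(rows) != 4)) {
      stop("PWM '", name, "': every row needs 4 values")
    }
    out[[name]] <- make_pwm(name, do.call(rbind, rows),
                            background = background,
                            pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in the tabular format read by [read_pwm()]
#'
#' @param pwms a `pwm` or list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$name), con)
    utils::write.table(format(p$matrix, digits = 6), con, sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# binned per-position log-odds contributions (integer bins of bin_bits)
pwm_bins <- function(pwm, background, bin_bits) {
  lo <- log2(sweep(pwm$matrix, 2, background, "/"))
  list(lo = lo, bins = round(lo / bin_bits))
}

#' Exact score distribution of a PWM under a background model
#'
#' Computes the distribution of total log-odds scores (bits) of a random
#' background position by per-position convolution over scores discretized
#' to `bin_bits` bins (default 1/1000 bit). The discretization error of any
#' total score is at most `nrow * bin_bits / 2` bits, reported in the
#' result. Tail probabilities are monotone non-increasing in score.
#'
#' @param pwm `pwm` object (length <= 30).
#' @param background base frequencies to score against; defaults to the
#'   PWM's own stored background.
#' @param bin_bits discretization bin width in bits.
#' @return list: `score` (bits, bin centers), `prob`, `tail`
#'   (P(S >= score)), `bin` (integer bins), `bin_bits`, `max_abs_error`,
#'   plus the per-position binned contributions used by [scan_pwm()].
#' @export
score_distribution <- function(pwm, background = pwm$background,
                               bin_bits = 0.001) {
  if (!inherits(pwm, "pwm")) stop("need a 'pwm' object")
  m <- nrow(pwm$matrix)
  if (m > 30) stop("motif length > 30 not supported")
  if (any(abs(rowSums(pwm$matrix) - 1) > 1e-9)) {
    stop("PWM rows must sum to 1")
  }
  background <- background / sum(background)
  pb <- pwm_bins(pwm, background, bin_bits)
  lo_min <- sum(apply(pb$bins, 1, min))
  lo_max <- sum(apply(pb$bins, 1, max))
  width <- lo_max - lo_min + 1L
  # dist[k] = P(sum of first j contributions == lo_min_partial + k - 1)
  dist <- 1
  off <- 0L
  for (j in seq_len(m)) {
    bj <- pb$bins[j, ]
    newoff <- off + min(bj)
    new <- numeric(length(dist) + max(bj) - min(bj))
    for (b in 1:4) {
      sh <- off + bj[b] - newoff
      idx <- seq_along(dist) + sh
      new[idx] <- new[idx] + dist * background[b]
    }
    dist <- new
    off <- newoff
  }
  stopifnot(off == lo_min, length(dist) == width)
  tail <- rev(cumsum(rev(dist)))
  bins <- seq.int(lo_min, lo_max)
  list(score = bins * bin_bits, prob = dist, tail = tail, bin = bins,
       bin_bits = bin_bits, max_abs_error = m * bin_bits / 2,
       pos_bins = pb$bins, pos_lo = pb$lo, background = background)
}

# tail probability P(S >= s) for total binned scores (vectorized)
tail_at_bin <- function(dist, bin) {
  i <- bin - dist$bin[1] + 1L
  i[i < 1L] <- 1L
  out <- rep(0, length(bin))
  ok <- i <= length(dist$tail)
  out[ok] <- dist$tail[i[ok]]
  out
}

# PWM for the reverse-complement motif (scan forward sequence, report '-')
reverse_complement_pwm <- function(pwm) {
  m <- pwm$matrix[rev(seq_len(nrow(pwm$matrix))), c("T", "G", "C", "A"),
                  drop = FALSE]
  colnames(m) <- BASES
  structure(list(name = pwm$name, matrix = m,
                 background = pwm$background[c(4, 3, 2, 1)],
                 pseudocount = pwm$pseudocount), class = "pwm")
}

#' Scan sequences for significant PWM matches
#'
#' Reports every position/strand whose per-position match p-value --
#' P(random background position scores >= observed), from
#' [score_distribution()] -- is at most `alpha`. This is a per-position
#' p-value, not a sequence-level E-value. By default the background model is
#' the scanned sequence's own base composition (MAST-style); positions
#' containing N never match.
#'
#' @param genome named character vector, or a single unnamed sequence.
#' @param pwm `pwm` object.
#' @param alpha significance level (default 5e-5).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param background optional base frequencies (A,C,G,T) overriding the
#'   sequence-composition default.
#' @param bin_bits score discretization for the p-value computation.
#' @return interval table of hits: contig, start, end, strand, name,
#'   score (log-odds bits), p_value; sorted by coordinate.
#' @export
scan_pwm <- function(genome, pwm, alpha = 5e-5, strands = "both",
                     background = NULL, bin_bits = 0.001) {
  if (is.null(names(genome)) && length(genome) == 1) {
    names(genome) <- "seq"
  }
  m <- nrow(pwm$matrix)
  if (is.null(background)) {
    counts <- rep(0, 4)
    for (s in genome) {
      v <- seq_codes(s)
      counts <- counts + tabulate(v, 4)
    }
    background <- counts + 1  # floor: degenerate compositions stay scannable
    background <- background / sum(background)
  } else {
    background <- background / sum(background)
  }
  want <- list()
  if (strands %in% c("both", "+")) want[["+"]] <- pwm
  if (strands %in% c("both", "-")) want[["-"]] <- reverse_complement_pwm(pwm)
  hits <- list()
  for (ct in names(genome)) {
    v <- seq_codes(genome[[ct]])
    L <- length(v)
    if (L < m) next
    npos <- L - m + 1L
    for (std in names(want)) {
      dist <- score_distribution(want[[std]], background = background,
                                 bin_bits = bin_bits)
      sc <- numeric(npos)
      bn <- integer(npos)
      for (j in seq_len(m)) {
        vj <- v[j:(j + npos - 1L)]
        sc <- sc + dist$pos_lo[j, ][vj]
        bn <- bn + dist$pos_bins[j, ][vj]
      }
      p <- tail_at_bin(dist, bn)
      ok <- which(!is.na(sc) & p <= alpha)
      if (length(ok)) {
        hits[[length(hits) + 1]] <- data.frame(
          contig = ct, start = ok - 1L, end = ok - 1L + m, strand = std,
          name = pwm$name, score = sc[ok], p_value = p[ok],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      name = character(), score = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, hits)
  res <- res[order(res$contig, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Motif-clustering asymmetry within an island
#'
#' Splits the island at its midpoint, assigns each overlapping hit to the
#' half containing the hit's own midpoint (left on exact tie), and tests
#' left vs right counts against Binomial(n, 1/2), two-sided.
#'
#' @param island single-row interval (length >= 2).
#' @param hits motif hit table.
#' @return list: `left`, `right` (counts), `p` (two-sided binomial p-value,
#'   capped at 1; NA when there are no hits).
#' @export
asymmetry_score <- function(island, hits) {
  if (island$end[1] - island$start[1] < 2) stop("island length must be >= 2")
  mid <- (island$start[1] + island$end[1]) / 2
  ov <- hits[hits$contig == island$contig[1] & hits$start < island$end[1] &
               hits$end > island$start[1], , drop = FALSE]
  if (nrow(ov) == 0) return(list(left = 0L, right = 0L, p = NA_real_))
  hmid <- (ov$start + ov$end) / 2
  left <- sum(hmid <= mid)
  right <- nrow(ov) - left
  n <- left + right
  p <- min(1, 2 * stats::pbinom(min(left, right), n, 0.5))
  list(left = left, right = right, p = p)
}

#' Activating-motif depletion flag
#'
#' TRUE iff the interval contains at most `max_hits` motif hits.
#'
#' @param interval single-row interval table.
#' @param hits motif hit table.
#' @param max_hits depletion cutoff.
#' @return logical.
#' @export
depletion_flag <- function(interval, hits, max_hits) {
  count_hits(hits, interval) <= max_hits
}
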