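# Sequence scanning: windowed GC / CpG observed-expected statistics,
# CpG-island calling, and GC-rich element discovery.

# A/C/G/T -> 1..4, N -> NA; input must already be uppercase ACGTN.
seq_codes <- function(seq) {
  code <- integer(256)
  code[utf8ToInt("A")] <- 1L; code[utf8ToInt("C")] <- 2L
  code[utf8ToInt("G")] <- 3L; code[utf8ToInt("T")] <- 4L
  v <- code[utf8ToInt(seq)]
  v[v == 0L] <- NA_integer_
  v
}

#' GC fraction of a sequence
#'
#' (#G + #C) / (#non-N bases). N bases are excluded from the denominator.
#'
#' @param seq A/C/G/T/N string (uppercase).
#' @return fraction in \[0,1\], or NA if the sequence is all N.
#' @export
gc_fraction <- function(seq) {
  if (!nzchar(seq)) stop("gc_fraction: empty sequence")
  v <- seq_codes(seq)
  n_inf <- sum(!is.na(v))
  if (n_inf == 0) return(NA_real_)
  sum(v == 2L | v == 3L, na.rm = TRUE) / n_inf
}

#' CpG observed/expected ratio
#'
#' O/E = N_CpG * L / (N_C * N_G), where N_CpG counts literal "CG"
#' dinucleotides (both positions non-N), and L is the number of non-N
#' positions. Returns 0 when N_C or N_G is zero (degenerate rule).
#'
#' @param seq A/C/G/T/N string, length >= 2.
#' @return ratio >= 0.
#' @export
cpg_observed_expected <- function(seq) {
  if (nchar(seq) < 2) stop("cpg_observed_expected: need length >= 2")
  v <- seq_codes(seq)
  n_c <- sum(v == 2L, na.rm = TRUE)
  n_g <- sum(v == 3L, na.rm = TRUE)
  if (n_c == 0 || n_g == 0) return(0)
  n_cg <- sum(v[-length(v)] == 2L & v[-1] == 3L, na.rm = TRUE)
  L <- sum(!is.na(v))
  n_cg * L / (n_c * n_g)
}

#' Sliding-window GC and CpG O/E scan
#'
#' One record per window placement per contig. CpG dinucleotides are
#' counted within the window only (no wrap across edges). Windows with an N
#' fraction above `max_n_fraction` are masked (statistics set to NA).
#'
#' @param genome named character vector (see [read_fasta()]).
#' @param window_bp window size (default 1000).
#' @param step_bp step between window starts (default `window_bp`); a step
#'   larger than the window leaves gaps and triggers a warning.
#' @param max_n_fraction masking threshold for assembly gaps.
#' @return data.frame: contig, start, end, gc_fraction, cpg_oe, n_fraction;
#'   attributes `window_bp`, `step_bp`.
#' @export
scan_windows <- function(genome, window_bp = 1000, step_bp = window_bp,
                         max_n_fraction = 0.10) {
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  if (step_bp > window_bp) {
    warning("step_bp > window_bp leaves unscanned gaps")
  }
  out <- lapply(names(genome), function(ct) {
    len <- nchar(genome[[ct]])
    if (window_bp > len) stop("window_bp exceeds length of contig ", ct)
    v <- seq_codes(genome[[ct]])
    starts <- seq.int(0L, len - window_bp, by = step_bp)
    cs_c <- cumsum(c(0L, v == 2L & !is.na(v)))
    cs_g <- cumsum(c(0L, v == 3L & !is.na(v)))
    cs_n <- cumsum(c(0L, is.na(v)))
    di <- v[-len] == 2L & v[-1] == 3L
    di[is.na(di)] <- FALSE
    cs_cg <- cumsum(c(0L, di, 0L))  # cs_cg[i+1]: CG starts at pos <= i
    a <- starts; b <- starts + window_bp
    nC <- cs_c[b + 1L] - cs_c[a + 1L]
    nG <- cs_g[b + 1L] - cs_g[a + 1L]
    nN <- cs_n[b + 1L] - cs_n[a + 1L]
    # CG dinucleotide must lie fully inside the window: start in [a, b-2]
    nCG <- cs_cg[b] - cs_cg[a + 1L]
    Leff <- window_bp - nN
    gc <- ifelse(Leff > 0, (nC + nG) / Leff, NA_real_)
    oe <- ifelse(nC > 0 & nG > 0, nCG * Leff / (nC * nG), 0)
    oe[Leff == 0] <- NA_real_
    nf <- nN / window_bp
    mask <- nf > max_n_fraction
    gc[mask] <- NA_real_; oe[mask] <- NA_real_
    data.frame(contig = ct, start = a, end = b, gc_fraction = gc,
               cpg_oe = oe, n_fraction = nf, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "window_bp") <- window_bp
  attr(res, "step_bp") <- step_bp
  res
}

#' Call CpG islands
#'
#' Scans each contig with a small sliding window (default 200 bp, 1 bp
#' step), marks qualifying placements (GC >= min_gc, O/E >= min_oe), merges
#' runs of qualifying placements into maximal spans, trims non-G/C edge
#' bases, and keeps spans that satisfy the criteria when recomputed over
#' their full length. Calls are non-overlapping and sorted.
#'
#' @param genome named character vector.
#' @param min_gc,min_oe,min_len island criteria (defaults 0.50 / 0.60 /
#'   200 bp, the classical mammalian CpG-island convention).
#' @param window_bp,step_bp scan resolution.
#' @param max_n_fraction window masking threshold.
#' @return data.frame: contig, start, end, strand, gc_fraction, cpg_oe,
#'   length_bp.
#' @export
call_cpg_islands <- function(genome, min_gc = 0.50, min_oe = 0.60,
                             min_len = 200, window_bp = 200, step_bp = 1,
                             max_n_fraction = 0.10) {
  calls <- list()
  for (ct in names(genome)) {
    len <- nchar(genome[[ct]])
    if (len < min_len) next
    w <- min(window_bp, len)
    sw <- scan_windows(stats::setNames(genome[ct], ct), window_bp = w,
                       step_bp = step_bp, max_n_fraction = max_n_fraction)
    ok <- !is.na(sw$gc_fraction) & sw$gc_fraction >= min_gc &
      !is.na(sw$cpg_oe) & sw$cpg_oe >= min_oe
    if (!any(ok)) next
    r <- rle(ok)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    runs <- which(r$values)
    span <- data.frame(contig = ct,
                       start = sw$start[starts_idx[runs]],
                       end = sw$start[ends_idx[runs]] + w,
                       stringsAsFactors = FALSE)
    span <- merge_intervals(span, gap_bp = 0)
    for (i in seq_len(nrow(span))) {
      a <- span$start[i]; b <- span$end[i]
      s <- get_seq(genome, ct, a, b)
      v <- strsplit(s, "")[[1]]
      while (a < b - 1 && !v[1] %in% c("C", "G")) { a <- a + 1; v <- v[-1] }
      while (b - a > 1 && !v[length(v)] %in% c("C", "G")) {
        b <- b - 1; v <- v[-length(v)]
      }
      if (b - a < min_len) next
      s <- get_seq(genome, ct, a, b)
      gc <- gc_fraction(s); oe <- cpg_observed_expected(s)
      if (!is.na(gc) && gc >= min_gc && oe >= min_oe) {
        calls[[length(calls) + 1]] <- data.frame(
          contig = ct, start = a, end = b, strand = "*", gc_fraction = gc,
          cpg_oe = oe, length_bp = b - a, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(calls)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      gc_fraction = numeric(), cpg_oe = numeric(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, calls)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Discover GC-rich, activating-motif-depleted elements
#'
#' The prokaryote-selection procedure: tile the genome with 1 kb windows
#' (default step = window, so candidate elements are disjoint genome
#' segments; set `step_bp` smaller for a sliding variant), keep placements
#' that satisfy mammalian CpG-island criteria AND contain at most
#' `max_hits_per_window` activating-motif hits, then greedily retain a
#' non-overlapping set ranked by CpG O/E (descending), ties broken by GC
#' fraction then leftmost coordinate.
#'
#' @param genome named character vector.
#' @param motif_hits interval table of activating-motif hits on this genome
#'   (from [scan_pwm()]); may be empty.
#' @param window_bp element size (default 1000).
#' @param step_bp scan step (default `window_bp`: non-overlapping tiling).
#' @param min_gc,min_oe island criteria applied per window.
#' @param max_hits_per_window depletion cutoff (default 2).
#' @param max_n_fraction window masking threshold.
#' @return ranked data.frame: contig, start, end, strand, gc_fraction,
#'   cpg_oe, n_hits.
#' @export
find_gc_rich_elements <- function(genome, motif_hits, window_bp = 1000,
                                  step_bp = window_bp, min_gc = 0.50,
                                  min_oe = 0.60, max_hits_per_window = 2,
                                  max_n_fraction = 0.10) {
  sw <- scan_windows(genome, window_bp = window_bp, step_bp = step_bp,
                     max_n_fraction = max_n_fraction)
  ok <- !is.na(sw$gc_fraction) & sw$gc_fraction >= min_gc &
    !is.na(sw$cpg_oe) & sw$cpg_oe >= min_oe
  cand <- sw[ok, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      gc_fraction = numeric(), cpg_oe = numeric(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  }
  cand$n_hits <- vapply(seq_len(nrow(cand)), function(i) {
    count_hits(motif_hits, cand[i, ])
  }, 0L)
  cand <- cand[cand$n_hits <= max_hits_per_window, , drop = FALSE]
  # rank: O/E desc, GC desc, then coordinate
  cand <- cand[order(-cand$cpg_oe, -cand$gc_fraction, cand$contig,
                     cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  taken <- list()
  for (i in seq_len(nrow(cand))) {
    ov <- FALSE
    for (tk in taken) {
      if (tk$contig == cand$contig[i] && cand$start[i] < tk$end &&
          cand$end[i] > tk$start) { ov <- TRUE; break }
    }
    if (!ov) {
      keep[i] <- TRUE
      taken[[length(taken) + 1]] <- list(contig = cand$contig[i],
                                         start = cand$start[i],
                                         end = cand$end[i])
    }
  }
  res <- cand[keep, c("contig", "start", "end", "gc_fraction", "cpg_oe",
                      "n_hits")]
  res$strand <- "*"
  res <- res[, c("contig", "start", "end", "strand", "gc_fraction",
                 "cpg_oe", "n_hits")]
  rownames(res) <- NULL
  res
}

#' Self-consistency audit of island/element calls
#'
#' Recomputes GC and O/E from the sequence for every call and checks the
#' stated criteria. Used by the test suite; exported because it is a useful
#' sanity check on any imported call set.
#'
#' @param calls interval table of calls.
#' @param genome named character vector.
#' @param min_gc,min_oe,min_len criteria to audit against.
#' @return logical vector, one per call.
#' @export
audit_island_calls <- function(calls, genome, min_gc = 0.50, min_oe = 0.60,
                               min_len = 0) {
  vapply(seq_len(nrow(calls)), function(i) {
    s <- get_seq(genome, calls$contig[i], calls$start[i], calls$end[i])
    gc <- gc_fraction(s)
    !is.na(gc) && gc >= min_gc && cpg_observed_expected(s) >= min_oe &&
      (calls$end[i] - calls$start[i]) >= min_len
  }, TRUE)
}
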