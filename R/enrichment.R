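# ChIP-Seq enrichment: read sets, extended-read density tracks, the
# randomized-read empirical null, sliding-window calling, region merging,
# promoter mark classification, heat-map matrices and spreading extent.
#
# Window enrichment statistics (observed and null alike) count read 5'
# positions per window; the read extension is applied only when building
# density tracks. This keeps the null mean exactly
# total_count * window / genome and the two sides of every p-value
# comparison on identical footing.

#' Construct a ChIP read set
#'
#' @param reads data.frame with columns `contig`, `pos` (0-based 5' mapped
#'   position) and `strand` (`+`/`-`).
#' @param extension_bp fragment-length proxy used by [build_density()].
#' @param label dataset label (antibody/mark).
#' @return object of class `read_set`.
#' @export
read_set <- function(reads, extension_bp = 200, label = "") {
  stopifnot(all(c("contig", "pos", "strand") %in% names(reads)))
  stopifnot(all(reads$strand %in% c("+", "-")))
  structure(list(reads = reads[, c("contig", "pos", "strand")],
                 extension_bp = as.integer(extension_bp),
                 total_count = nrow(reads), label = label),
            class = "read_set")
}

#' Read mapped reads from a BED-like file
#'
#' Accepts 4-column (contig, start, end, strand) or standard BED6 lines;
#' the start column is taken as the 5' mapped position for both strands.
#'
#' @param path file path.
#' @param extension_bp,label passed to [read_set()].
#' @return `read_set`.
#' @export
read_reads <- function(path, extension_bp = 200, label = "") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(read_set(data.frame(contig = character(), pos = integer(),
                               strand = character()), extension_bp, label))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(f)
  if (any(nc < 4)) stop("reads BED needs >= 4 columns (line ",
                        which(nc < 4)[1], ")")
  strand <- ifelse(nc >= 6, vapply(f, function(x) x[min(6, length(x))], ""),
                   vapply(f, `[`, "", 4L))
  c4 <- vapply(f, `[`, "", 4L)
  strand <- ifelse(c4 %in% c("+", "-"), c4, strand)
  if (!all(strand %in% c("+", "-"))) stop("missing strand in reads BED")
  read_set(data.frame(contig = vapply(f, `[`, "", 1L),
                      pos = as.integer(vapply(f, `[`, "", 2L)),
                      strand = strand, stringsAsFactors = FALSE),
           extension_bp, label)
}

#' Write a read set as 4-column BED-like text
#'
#' @param rs `read_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads <- function(rs, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", rs$reads$contig, rs$reads$pos,
                     rs$reads$pos + 1L, rs$reads$strand), path)
  invisible(path)
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Extended-read density track
#'
#' Each read contributes coverage from its 5' position, extended
#' `extension_bp` in its strand direction (`+`: `[pos, pos+ext)`; `-`:
#' `[pos-ext, pos)`), truncated at contig ends. Per-bin values are covered
#' base pairs divided by `bin_bp`, so a fully interior read contributes
#' exactly `extension_bp / bin_bp` in total.
#'
#' @param rs `read_set`.
#' @param genome_lengths named vector of contig lengths (or a genome).
#' @param bin_bp bin size (default 25).
#' @return object of class `density_track`: list(bin_bp, extension_bp,
#'   tracks = named list of per-bin numeric vectors, n_clipped).
#' @export
build_density <- function(rs, genome_lengths, bin_bp = 25) {
  gl <- genome_lengths(genome_lengths)
  ext <- rs$extension_bp
  n_clipped <- 0L
  tracks <- list()
  for (ct in names(gl)) {
    len <- as.integer(gl[[ct]])
    nb <- ceiling(len / bin_bp)
    sel <- rs$reads$contig == ct
    if (!any(sel)) { tracks[[ct]] <- numeric(nb); next }
    pos <- rs$reads$pos[sel]
    plus <- rs$reads$strand[sel] == "+"
    s <- ifelse(plus, pos, pos - ext)
    e <- ifelse(plus, pos + ext, pos)
    n_clipped <- n_clipped + sum(s < 0 | e > len)
    s <- pmax(s, 0L); e <- pmin(e, len)
    keep <- e > s
    s <- s[keep]; e <- e[keep]
    delta <- tabulate(s + 1L, nbins = len + 1L) -
      tabulate(e + 1L, nbins = len + 1L)
    cov <- cumsum(delta)[seq_len(len)]
    pad <- nb * bin_bp - len
    if (pad > 0) cov <- c(cov, numeric(pad))
    tracks[[ct]] <- colSums(matrix(cov, nrow = bin_bp)) / bin_bp
  }
  if (n_clipped > 0) {
    warning(n_clipped, " extended read(s) clipped at contig boundaries")
  }
  structure(list(bin_bp = as.integer(bin_bp), extension_bp = ext,
                 tracks = tracks, n_clipped = n_clipped),
            class = "density_track")
}

# counts of read 5' positions falling in [start, end) windows of one contig
count_in_windows <- function(pos_sorted, starts, ends) {
  findInterval(ends - 0.5, pos_sorted) -
    findInterval(starts - 0.5, pos_sorted)
}

#' Randomized-read empirical null model
#'
#' Re-places all reads uniformly on the genome (contig chosen with
#' probability proportional to length, position uniform within contig),
#' `n_rand` times, and pools per-window read counts over non-overlapping
#' `window_bp` tilings into an empirical distribution. Built separately for
#' each dataset so that sequencing depth is matched.
#'
#' @param rs `read_set`.
#' @param genome_lengths named vector of contig lengths (or a genome).
#' @param window_bp window size the null is matched to.
#' @param n_rand number of randomizations pooled (default 10).
#' @param seed RNG seed (required for reproducibility).
#' @return object of class `null_model`: list(window_bp, n_rand, seed,
#'   counts (sorted), n (pooled window count), total_count, genome_bp).
#' @export
build_null <- function(rs, genome_lengths, window_bp = 1000, n_rand = 10,
                       seed = 1) {
  stopifnot(n_rand >= 1)
  gl <- genome_lengths(genome_lengths)
  window_bp <- as.integer(window_bp)
  nwin <- pmax(0L, floor(gl / window_bp))
  total <- rs$total_count
  counts <- with_seed(seed, {
    out <- vector("list", n_rand)
    for (r in seq_len(n_rand)) {
      ct <- sample.int(length(gl), total, replace = TRUE, prob = gl)
      pos <- floor(stats::runif(total) * gl[ct])
      percontig <- lapply(seq_along(gl), function(i) {
        p <- sort(pos[ct == i])
        if (nwin[i] == 0) return(integer(0))
        starts <- seq.int(0, by = window_bp, length.out = nwin[i])
        count_in_windows(p, starts, starts + window_bp)
      })
      out[[r]] <- unlist(percontig)
    }
    unlist(out)
  })
  structure(list(window_bp = window_bp, n_rand = as.integer(n_rand),
                 seed = seed, counts = sort(counts), n = length(counts),
                 total_count = total, genome_bp = sum(gl)),
            class = "null_model")
}

#' Empirical upper-tail p-value of a window count
#'
#' Add-one-smoothed: p = (#\{null windows >= count\} + 1) / (N + 1), so the
#' smallest attainable p is 1/(N+1). Monotone non-increasing in count.
#'
#' @param count integer vector of observed window counts.
#' @param null `null_model`.
#' @return numeric p-values.
#' @export
window_pvalue <- function(count, null) {
  ge <- null$n - findInterval(count - 0.5, null$counts)
  (ge + 1) / (null$n + 1)
}

#' Per-window enrichment statistics genome-wide
#'
#' Slides `window_bp` windows at `step_bp`, counts read 5' positions, and
#' assigns each window an empirical p-value against the randomized-read
#' null.
#'
#' @param rs `read_set`.
#' @param genome_lengths named vector of contig lengths (or a genome).
#' @param window_bp,step_bp window geometry (defaults 1000 / 200).
#' @param seed seed for the null randomizations.
#' @param n_rand randomizations pooled into the null.
#' @param null optionally, a prebuilt matching `null_model`.
#' @return data.frame: contig, start, end, count, p_value; attribute
#'   `null`.
#' @export
window_enrichment <- function(rs, genome_lengths, window_bp = 1000,
                              step_bp = 200, seed = 1, n_rand = 10,
                              null = NULL) {
  gl <- genome_lengths(genome_lengths)
  if (is.null(null)) {
    null <- build_null(rs, gl, window_bp = window_bp, n_rand = n_rand,
                       seed = seed)
  }
  stopifnot(null$window_bp == window_bp)
  out <- lapply(names(gl), function(ct) {
    len <- gl[[ct]]
    if (len < window_bp) return(NULL)
    starts <- seq.int(0, len - window_bp, by = step_bp)
    pos <- sort(rs$reads$pos[rs$reads$contig == ct])
    cnt <- count_in_windows(pos, starts, starts + window_bp)
    data.frame(contig = ct, start = as.integer(starts),
               end = as.integer(starts + window_bp), count = cnt,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(contig = character(), start = integer(),
                      end = integer(), count = integer())
  }
  res$p_value <- if (nrow(res)) window_pvalue(res$count, null) else numeric()
  attr(res, "null") <- null
  res
}

#' Call significantly enriched windows
#'
#' Windows with p < `p_threshold` (strict), per [window_enrichment()].
#' Under a pure-null read set the called fraction is approximately the
#' threshold.
#'
#' @inheritParams window_enrichment
#' @param p_threshold significance cutoff (default 1e-3).
#' @return qualifying windows (same columns as [window_enrichment()]);
#'   attributes `null` and `n_windows` (total windows tested).
#' @export
call_enriched_windows <- function(rs, genome_lengths, window_bp = 1000,
                                  step_bp = 200, p_threshold = 1e-3,
                                  seed = 1, n_rand = 10, null = NULL) {
  we <- window_enrichment(rs, genome_lengths, window_bp = window_bp,
                          step_bp = step_bp, seed = seed, n_rand = n_rand,
                          null = null)
  res <- we[we$p_value < p_threshold, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "null") <- attr(we, "null")
  attr(res, "n_windows") <- nrow(we)
  res
}

#' Merge enriched windows into regions
#'
#' Transitive closure of "separated by at most `gap_bp`": any chain of
#' windows whose consecutive gaps are within the limit becomes one region.
#' Region p-value is the minimum member p-value; the summit is the midpoint
#' of the highest-count member window.
#'
#' @param windows window table (from [call_enriched_windows()]); order does
#'   not matter.
#' @param gap_bp maximum merge gap (default 1000).
#' @return data.frame: contig, start, end, strand, p_value, width_bp,
#'   summit, n_windows.
#' @export
merge_regions <- function(windows, gap_bp = 1000) {
  if (nrow(windows) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      p_value = numeric(), width_bp = integer(),
                      summit = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE))
  }
  w <- windows[order(windows$contig, windows$start), , drop = FALSE]
  has_p <- "p_value" %in% names(w)
  has_c <- "count" %in% names(w)
  grp <- integer(nrow(w))
  g <- 1L
  grp[1] <- g
  cur_end <- w$end[1]
  for (i in seq_len(nrow(w))[-1]) {
    if (w$contig[i] != w$contig[i - 1] || w$start[i] - cur_end > gap_bp) {
      g <- g + 1L
      cur_end <- w$end[i]
    } else {
      cur_end <- max(cur_end, w$end[i])
    }
    grp[i] <- g
  }
  res <- do.call(rbind, lapply(split(seq_len(nrow(w)), grp), function(idx) {
    sub <- w[idx, , drop = FALSE]
    summit <- if (has_c) {
      top <- idx[which.max(sub$count)]
      as.integer((w$start[top] + w$end[top]) %/% 2)
    } else NA_integer_
    data.frame(contig = sub$contig[1], start = min(sub$start),
               end = max(sub$end), strand = "*",
               p_value = if (has_p) min(sub$p_value) else NA_real_,
               width_bp = max(sub$end) - min(sub$start), summit = summit,
               n_windows = nrow(sub), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Classify promoters by ChIP mark occupancy
#'
#' For each mark, counts reads in the TSS +/- `tss_flank_bp` window and
#' calls the promoter positive when the count is significantly enriched
#' (p < `p_threshold`) against that dataset's own randomized-read null
#' (each dataset gets its own null so that sequencing depth is matched).
#' When both `K4me3` and `K27me3` are among the marks, a `bivalent` column
#' (positive for both) is added. The cross-tabulation of all mark
#' combinations (Venn counts) is attached as attribute `overlap_counts`.
#'
#' @param promoters data.frame with `id`, `contig`, `tss` (0-based),
#'   `strand`.
#' @param readsets named list of `read_set`s, one per mark.
#' @param genome_lengths named vector of contig lengths (or a genome).
#' @param p_threshold significance cutoff (default 1e-3).
#' @param tss_flank_bp half-width of the promoter window (default 1000).
#' @param seed base seed; each mark's null uses `seed + mark index`.
#' @param n_rand randomizations per null.
#' @return data.frame of calls: id plus, per mark, `<mark>` (logical) and
#'   `<mark>_p`; attribute `overlap_counts`.
#' @export
classify_promoters <- function(promoters, readsets, genome_lengths,
                               p_threshold = 1e-3, tss_flank_bp = 1000,
                               seed = 1, n_rand = 10) {
  stopifnot(!is.null(names(readsets)), all(nzchar(names(readsets))))
  gl <- genome_lengths(genome_lengths)
  window_bp <- 2L * as.integer(tss_flank_bp)
  starts <- pmax(0, promoters$tss - tss_flank_bp)
  ends <- pmin(gl[promoters$contig], promoters$tss + tss_flank_bp)
  res <- data.frame(id = promoters$id, stringsAsFactors = FALSE)
  for (k in seq_along(readsets)) {
    mark <- names(readsets)[k]
    rs <- readsets[[k]]
    null <- build_null(rs, gl, window_bp = window_bp, n_rand = n_rand,
                       seed = seed + k)
    cnt <- integer(nrow(promoters))
    for (ct in unique(promoters$contig)) {
      sel <- promoters$contig == ct
      pos <- sort(rs$reads$pos[rs$reads$contig == ct])
      cnt[sel] <- count_in_windows(pos, starts[sel], ends[sel])
    }
    p <- window_pvalue(cnt, null)
    res[[mark]] <- p < p_threshold
    res[[paste0(mark, "_p")]] <- p
  }
  marks <- names(readsets)
  if (all(c("K4me3", "K27me3") %in% marks)) {
    res$bivalent <- res$K4me3 & res$K27me3
  }
  combo <- apply(res[, marks, drop = FALSE], 1, function(x) {
    pos <- marks[as.logical(x)]
    if (!length(pos)) "none" else paste(pos, collapse = "+")
  })
  attr(res, "overlap_counts") <- table(combo)
  res
}

#' Region-centered signal matrix (enrichment heat map)
#'
#' One row per enriched region, spanning `span_bp` centered on the region
#' midpoint, sampled from a density track. Rows are partitioned into
#' island-overlapping and non-overlapping groups (overlapping first) and,
#' within each group, sorted by enrichment width descending with ties
#' broken by genomic coordinate. Columns near contig edges are NA-padded.
#' If a genome is supplied, a companion matrix of per-column GC fraction is
#' included.
#'
#' @param regions merged-region table ([merge_regions()]); needs width_bp.
#' @param density `density_track` from [build_density()].
#' @param islands interval table of CpG islands (may be empty).
#' @param span_bp row span (default 20000).
#' @param genome optional named character vector for the GC companion.
#' @return list: `signal` (matrix), `rows` (region order/group metadata),
#'   and `gc` (matrix) when `genome` is given.
#' @export
signal_matrix <- function(regions, density, islands, span_bp = 20000,
                          genome = NULL) {
  bin <- density$bin_bp
  ncol <- floor(span_bp / bin)
  overlaps <- vapply(seq_len(nrow(regions)), function(i) {
    count_hits(islands, regions[i, ]) > 0
  }, TRUE)
  ord <- order(!overlaps, -regions$width_bp, regions$contig, regions$start)
  rows <- regions[ord, , drop = FALSE]
  rows$group <- ifelse(overlaps[ord], "island", "non_island")
  sig <- matrix(NA_real_, nrow = nrow(rows), ncol = ncol)
  gcm <- if (!is.null(genome)) sig else NULL
  for (i in seq_len(nrow(rows))) {
    ct <- rows$contig[i]
    center <- (rows$start[i] + rows$end[i]) %/% 2
    first_bp <- center - (ncol %/% 2) * bin
    bps <- first_bp + (seq_len(ncol) - 1L) * bin
    bidx <- bps %/% bin + 1L
    tr <- density$tracks[[ct]]
    ok <- bidx >= 1 & bidx <= length(tr)
    sig[i, ok] <- tr[bidx[ok]]
    if (!is.null(genome)) {
      len <- nchar(genome[[ct]])
      for (j in which(bps >= 0 & bps + bin <= len)) {
        gcm[i, j] <- gc_fraction(get_seq(genome, ct, bps[j], bps[j] + bin))
      }
    }
  }
  rownames(rows) <- NULL
  out <- list(signal = sig, rows = rows)
  if (!is.null(genome)) out$gc <- gcm
  out
}

#' Spreading extent of a chromatin signal away from an element
#'
#' Scans measurement points outward from an element boundary, in order of
#' increasing distance, and returns the largest distance at which the
#' signal is still at or above `threshold`; the first sub-threshold point
#' stops the scan (spreading is contiguous by definition).
#'
#' @param distance_bp distances of measurement points from the element edge.
#' @param value signal at each point (e.g. qPCR fold-enrichment).
#' @param threshold detection threshold.
#' @return extent in bp (0 if the nearest point is already below threshold).
#' @export
spreading_extent <- function(distance_bp, value, threshold) {
  stopifnot(length(distance_bp) == length(value))
  ord <- order(distance_bp)
  ext <- 0
  for (i in ord) {
    if (is.na(value[i]) || value[i] < threshold) break
    ext <- distance_bp[i]
  }
  ext
}
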