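# Promoter CpG-class stratification, RNA-Seq exonic activity scoring,
# Ezh2-vs-expression stratification of inactive HCPs, and bisulfite
# methylation summaries.

#' Classify a promoter by CpG content (HCP/ICP/LCP)
#'
#' Examines the strand-oriented span around the TSS (default -500..+2000)
#' with 500 bp sub-windows: HCP if any sub-window has GC >= `hcp_min_gc`
#' and CpG O/E >= `hcp_min_oe`; LCP if no sub-window reaches
#' `lcp_max_oe`; otherwise ICP. Spans running off the contig are clipped
#' (flagged via attribute `clipped`).
#'
#' @param genome named character vector.
#' @param contig,tss,strand promoter anchor (0-based TSS).
#' @param span two offsets relative to the TSS in transcript orientation.
#' @param subwindow_bp sub-window size (default 500).
#' @param step_bp sub-window step (default 50).
#' @param hcp_min_gc,hcp_min_oe,lcp_max_oe class thresholds.
#' @return `"HCP"`, `"ICP"` or `"LCP"`.
#' @export
classify_promoter_cpg <- function(genome, contig, tss, strand = "+",
                                  span = c(-500, 2000), subwindow_bp = 500,
                                  step_bp = 50, hcp_min_gc = 0.55,
                                  hcp_min_oe = 0.60, lcp_max_oe = 0.40) {
  len <- nchar(genome[[contig]])
  if (strand == "-") {
    a <- tss - span[2]; b <- tss - span[1]
  } else {
    a <- tss + span[1]; b <- tss + span[2]
  }
  clipped <- a < 0 || b > len
  a <- max(0, a); b <- min(len, b)
  if (b - a < 2) stop("promoter span off contig")
  s <- get_seq(genome, contig, a, b)
  w <- min(subwindow_bp, nchar(s))
  sw <- scan_windows(c(p = s), window_bp = w, step_bp = step_bp)
  gc <- sw$gc_fraction; oe <- sw$cpg_oe
  ok <- !is.na(gc)
  cls <- if (any(ok & gc >= hcp_min_gc & oe >= hcp_min_oe)) "HCP"
  else if (!any(ok & oe >= lcp_max_oe)) "LCP"
  else "ICP"
  attr(cls, "clipped") <- clipped
  cls
}

#' Maximum exonic 1 kb read density (expression score)
#'
#' Concatenates the exons (in the given transcript order) into a virtual
#' coordinate, finds the maximum number of read 5' positions in any
#' `window_bp` window of the concatenation (the whole span if shorter), and
#' normalizes per million mapped reads.
#'
#' @param exons data.frame of exon intervals (contig/start/end), in
#'   transcript order; must be non-empty.
#' @param rnaseq `read_set` of RNA-Seq reads.
#' @param window_bp window size (default 1000).
#' @param total_reads library size used for normalization (defaults to the
#'   read set's total count).
#' @return score in reads per million.
#' @export
expression_score <- function(exons, rnaseq, window_bp = 1000,
                             total_reads = rnaseq$total_count) {
  if (is.null(exons) || nrow(exons) == 0) stop("gene has no exons")
  if (total_reads < 1) stop("total_reads must be >= 1")
  offs <- cumsum(c(0, exons$end - exons$start))
  virt <- numeric(0)
  for (i in seq_len(nrow(exons))) {
    sel <- rnaseq$reads$contig == exons$contig[i] &
      rnaseq$reads$pos >= exons$start[i] & rnaseq$reads$pos < exons$end[i]
    virt <- c(virt, rnaseq$reads$pos[sel] - exons$start[i] + offs[i])
  }
  if (!length(virt)) return(0)
  total_len <- offs[length(offs)]
  if (total_len <= window_bp) {
    mx <- length(virt)
  } else {
    v <- sort(virt)
    # a maximizing window can always be anchored at a read position
    upto <- findInterval(v + window_bp - 0.5, v)
    mx <- max(upto - seq_along(v) + 1L)
  }
  mx / total_reads * 1e6
}

#' Stratify transcriptionally inactive HCPs by Ezh2 occupancy
#'
#' Restricts to HCP promoters containing exactly one CpG island, splits by
#' Ezh2 call, compares expression scores between groups with a two-sided
#' rank-sum (Wilcoxon) test, and returns island length / GC for the
#' transcriptionally inactive subset.
#'
#' @param promoters data.frame with columns `id`, `cpg_class`, `n_islands`,
#'   `expression_score`, `ezh2_positive` (logical), and optionally
#'   `island_length_bp`, `island_gc`.
#' @param inactive_threshold expression cutoff below which a promoter is
#'   "inactive"; if NULL (default) it is data-driven: the maximum score
#'   among LCPs in `promoters` (0 if there are none).
#' @return list: `filtered` (the single-island HCPs), `summary` (per-group
#'   n / mean / median score), `p_ranksum`, `inactive` (scatter table),
#'   `inactive_threshold`.
#' @export
stratify_inactive_hcps <- function(promoters, inactive_threshold = NULL) {
  if (is.null(inactive_threshold)) {
    lcp <- promoters$expression_score[promoters$cpg_class == "LCP"]
    inactive_threshold <- if (length(lcp)) max(lcp) else 0
  }
  keep <- promoters$cpg_class == "HCP" & promoters$n_islands == 1
  hc <- promoters[keep, , drop = FALSE]
  groups <- split(hc$expression_score, hc$ezh2_positive)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(group = if (g == "TRUE") "Ezh2+" else "Ezh2-",
               n = length(x), mean_score = mean(x),
               median_score = stats::median(x), stringsAsFactors = FALSE)
  }))
  p <- if (length(groups) == 2 && all(lengths(groups) > 0)) {
    stats::wilcox.test(groups[["TRUE"]], groups[["FALSE"]],
                       exact = FALSE)$p.value
  } else NA_real_
  inactive <- hc[hc$expression_score <= inactive_threshold, , drop = FALSE]
  cols <- intersect(c("id", "island_length_bp", "island_gc",
                      "expression_score", "ezh2_positive"), names(inactive))
  list(filtered = hc, summary = summ, p_ranksum = p,
       inactive = inactive[, cols, drop = FALSE],
       inactive_threshold = inactive_threshold)
}

#' Read per-CpG methylation calls
#'
#' TSV with header: contig, pos (0-based position of the CpG cytosine),
#' methylated, total.
#'
#' @param path file path.
#' @return data.frame of calls.
#' @export
read_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "methylated", "total") %in% names(df)))
  if (any(df$methylated < 0 | df$methylated > df$total)) {
    stop("methylated count outside [0, total]")
  }
  df
}

#' Write per-CpG methylation calls
#'
#' @param calls data.frame (contig, pos, methylated, total).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(calls, path) {
  utils::write.table(calls[, c("contig", "pos", "methylated", "total")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' TSS-centered methylation composite profile
#'
#' Mean per-CpG methylation level in sliding windows across the span
#' surrounding the TSSs of a gene set, pooled across genes. Offsets are
#' strand-oriented (minus-strand promoters are flipped). Windows with no
#' covered CpG are NA.
#'
#' @param calls methylation call table (contig, pos, methylated, total).
#' @param tss_table data.frame with `contig`, `tss`, `strand`.
#' @param window_bp sliding window (default 200).
#' @param span_bp total span centered on the TSS (default 10000).
#' @param step_bp window step (default 50).
#' @return data.frame: offset (window start relative to TSS), offset_mid,
#'   mean_level, n_cpg.
#' @export
methylation_composite <- function(calls, tss_table, window_bp = 200,
                                  span_bp = 10000, step_bp = 50) {
  half <- span_bp / 2
  rel <- numeric(0); lev <- numeric(0)
  for (i in seq_len(nrow(tss_table))) {
    sel <- calls$contig == tss_table$contig[i] &
      calls$pos >= tss_table$tss[i] - half &
      calls$pos < tss_table$tss[i] + half &
      calls$total > 0
    if (!any(sel)) next
    r <- calls$pos[sel] - tss_table$tss[i]
    if (tss_table$strand[i] == "-") r <- -r
    rel <- c(rel, r)
    lev <- c(lev, calls$methylated[sel] / calls$total[sel])
  }
  offsets <- seq(-half, half - window_bp, by = step_bp)
  mean_level <- rep(NA_real_, length(offsets))
  n_cpg <- integer(length(offsets))
  for (j in seq_along(offsets)) {
    inwin <- rel >= offsets[j] & rel < offsets[j] + window_bp
    n_cpg[j] <- sum(inwin)
    if (n_cpg[j] > 0) mean_level[j] <- mean(lev[inwin])
  }
  data.frame(offset = offsets, offset_mid = offsets + window_bp / 2,
             mean_level = mean_level, n_cpg = n_cpg)
}

#' Coverage-weighted mean methylation of an interval
#'
#' @param calls methylation call table.
#' @param interval single-row interval table.
#' @return list: `mean_level` (sum methylated / sum total; NA when no CpG
#'   is covered), `n_cpg` (covered CpGs).
#' @export
interval_methylation <- function(calls, interval) {
  sel <- calls$contig == interval$contig[1] &
    calls$pos >= interval$start[1] & calls$pos < interval$end[1] &
    calls$total > 0
  n <- sum(sel)
  if (n == 0) return(list(mean_level = NA_real_, n_cpg = 0L))
  list(mean_level = sum(calls$methylated[sel]) / sum(calls$total[sel]),
       n_cpg = n)
}
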