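#' Write a per-window value track
#'
#' Supports bedGraph (one line per window) and fixed-step WIG (requires an
#' equally stepped grid on each contig; WIG is 1-based at the file boundary).
#' Missing values (NA/NaN) are written as explicit `nan` rows, never
#' silently dropped, so round-trips are lossless.
#'
#' @param values numeric vector, one per grid row.
#' @param interval_grid `genomic_intervals` table (the window grid).
#' @param path output path.
#' @param dialect `"bedgraph"` (default) or `"wig-fixed"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(values, interval_grid, path,
                        dialect = c("bedgraph", "wig-fixed")) {
  dialect <- match.arg(dialect)
  if (length(values) != nrow(interval_grid)) {
    stop("need exactly one value per grid interval (", length(values),
         " values, ", nrow(interval_grid), " intervals)")
  }
  fmt <- function(v) ifelse(is.na(v), "nan", sprintf("%.6f", v))
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "bedgraph") {
    writeLines("track type=bedGraph", con)
    if (length(values)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", interval_grid$contig,
                         interval_grid$start, interval_grid$end, fmt(values)),
                 con)
    }
  } else {
    for (ct in unique(interval_grid$contig)) {
      idx <- which(interval_grid$contig == ct)
      st <- interval_grid$start[idx]
      span <- unique(interval_grid$end[idx] - st)
      step <- if (length(idx) > 1) unique(diff(st)) else span
      if (length(span) != 1 || length(step) != 1) {
        stop("wig-fixed requires an equally stepped, constant-span grid on ",
             "contig ", ct)
      }
      writeLines(sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                         ct, st[1] + 1L, step, span), con)
      writeLines(fmt(values[idx]), con)
    }
  }
  invisible(path)
}

#' Read a value track written by [write_track()]
#'
#' @param path file path.
#' @param dialect `"bedgraph"` or `"wig-fixed"`.
#' @return list with `grid` (`genomic_intervals`) and `values` (numeric,
#'   NA where the file says `nan`).
#' @export
read_track <- function(path, dialect = c("bedgraph", "wig-fixed")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "bedgraph") {
    lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
    if (!length(lines)) {
      return(list(grid = genomic_intervals(character(), integer(), integer()),
                  values = numeric()))
    }
    f <- strsplit(lines, "\t", fixed = TRUE)
    grid <- genomic_intervals(vapply(f, `[`, "", 1),
                              as.integer(vapply(f, `[`, "", 2)),
                              as.integer(vapply(f, `[`, "", 3)))
    vals <- suppressWarnings(as.numeric(vapply(f, `[`, "", 4)))
    list(grid = grid, values = vals)
  } else {
    contigs <- starts <- ends <- character(0)
    vals <- numeric(0)
    cs <- ce <- integer(0); cn <- character(0)
    hdr <- NULL
    pos <- 0L
    for (ln in lines) {
      if (startsWith(ln, "fixedStep")) {
        kv <- strsplit(strsplit(ln, "\\s+")[[1]][-1], "=")
        hdr <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
        pos <- as.integer(hdr[["start"]]) - 1L
      } else if (nzchar(ln)) {
        span <- as.integer(hdr[["span"]])
        cn <- c(cn, hdr[["chrom"]])
        cs <- c(cs, pos); ce <- c(ce, pos + span)
        vals <- c(vals, suppressWarnings(as.numeric(ln)))
        pos <- pos + as.integer(hdr[["step"]])
      }
    }
    list(grid = genomic_intervals(cn, cs, ce), values = vals)
  }
}
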