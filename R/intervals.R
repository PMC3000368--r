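#' Construct a table of genomic intervals
#'
#' Intervals are the universal coordinate currency of the package: plain
#' data frames with columns `contig`, `start`, `end`, `strand` (plus any
#' extra columns such as `name` or `score`). All coordinates are 0-based
#' half-open (`[start, end)`); conversion to/from 1-based formats happens
#' only at file boundaries.
#'
#' @param contig character vector of contig names (non-empty strings).
#' @param start,end integer vectors, 0-based half-open; `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded); recycled.
#' @param ... further equal-length columns (e.g. `name`, `score`).
#' @return data.frame with class `c("genomic_intervals", "data.frame")`.
#' @export
genomic_intervals <- function(contig, start, end, strand = "*", ...) {
  n <- length(start)
  df <- data.frame(
    contig = rep_len(as.character(contig), n),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Validate an interval table
#'
#' Checks the `genomic_intervals` invariants: non-empty contig names,
#' `0 <= start < end`, strand in `{+, -, *}`.
#'
#' @param df data.frame with columns contig/start/end (strand optional).
#' @return the input, invisibly; errors describe the first offending row.
#' @export
validate_intervals <- function(df) {
  stopifnot(all(c("contig", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$contig)) || anyNA(df$contig)) {
    stop("interval with empty contig name (row ",
         which(!nzchar(df$contig) | is.na(df$contig))[1], ")")
  }
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad)) {
    stop("invalid interval at row ", bad[1], ": start=", df$start[bad[1]],
         " end=", df$end[bad[1]], " (need 0 <= start < end)")
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  invisible(df)
}

#' Read intervals from a BED or TSV file
#'
#' BED is parsed natively as 0-based half-open with optional
#' name/score/strand columns 4-6. The `tsv` dialect expects a header line
#' with at least `contig`, `start`, `end` columns (same coordinate
#' convention) and keeps any additional columns.
#'
#' @param path file path.
#' @param dialect `"bed"` (default) or `"tsv"`.
#' @return `genomic_intervals` data.frame.
#' @export
read_intervals <- function(path, dialect = c("bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                     !startsWith(lines, "#")]
    if (length(lines) == 0) {
      return(genomic_intervals(character(), integer(), integer()))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 3)) {
      stop("BED line ", which(ncol < 3)[1], " has fewer than 3 columns")
    }
    contig <- vapply(fields, `[`, "", 1L)
    start <- as.integer(vapply(fields, `[`, "", 2L))
    end <- as.integer(vapply(fields, `[`, "", 3L))
    bad <- which(is.na(start) | is.na(end) | start >= end | start < 0)
    if (length(bad)) {
      stop("invalid BED interval on line ", bad[1], ": '", lines[bad[1]], "'")
    }
    name <- ifelse(ncol >= 4, vapply(fields, function(f) f[4], ""), NA_character_)
    score <- suppressWarnings(
      as.numeric(ifelse(ncol >= 5, vapply(fields, function(f) f[5], ""), NA)))
    strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[6], ""), "*")
    strand[!strand %in% c("+", "-")] <- "*"
    df <- genomic_intervals(contig, start, end, strand)
    if (any(ncol >= 4)) df$name <- name
    if (any(ncol >= 5)) df$score <- score
    df
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("contig", "start", "end") %in% names(df)))
    if (!"strand" %in% names(df)) df$strand <- "*"
    bad <- which(df$start >= df$end | df$start < 0)
    if (length(bad)) {
      stop("invalid interval on data line ", bad[1], " of ", path)
    }
    validate_intervals(df)
    class(df) <- c("genomic_intervals", "data.frame")
    df
  }
}

#' Write intervals as BED
#'
#' Columns beyond contig/start/end are emitted as BED name/score/strand when
#' present (score defaults to 0, name to ".").
#'
#' @param df interval table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(df, path) {
  validate_intervals(df)
  name <- if ("name" %in% names(df)) ifelse(is.na(df$name), ".", df$name) else
    rep(".", nrow(df))
  score <- if ("score" %in% names(df)) ifelse(is.na(df$score), 0, df$score) else
    rep(0, nrow(df))
  strand <- if ("strand" %in% names(df)) df$strand else rep("*", nrow(df))
  strand[strand == "*"] <- "."
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$contig, df$start, df$end,
                 name, format(score, trim = TRUE, scientific = FALSE), strand)
  writeLines(out, path)
  invisible(path)
}

#' Count hits overlapping an interval
#'
#' Overlap means at least 1 bp shared, on either strand.
#'
#' @param hits interval table (e.g. motif hits).
#' @param interval single-row interval table (or list with contig/start/end).
#' @return integer count.
#' @export
count_hits <- function(hits, interval) {
  if (is.null(hits) || nrow(hits) == 0) return(0L)
  sum(hits$contig == interval$contig[1] &
        hits$start < interval$end[1] &
        hits$end > interval$start[1])
}

#' Merge overlapping or near-adjacent intervals
#'
#' Transitive closure of the "gap <= gap_bp" relation per contig. Intervals
#' whose gap is exactly `gap_bp` are merged; output is disjoint and sorted.
#'
#' @param df interval table.
#' @param gap_bp maximum separating distance to merge across (default 0 =
#'   merge only overlapping/adjacent).
#' @return interval table, one row per merged cluster, with a `n_merged`
#'   column.
#' @keywords internal
merge_intervals <- function(df, gap_bp = 0) {
  if (nrow(df) == 0) return(df)
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  out <- vector("list", nrow(df))
  k <- 0
  cur <- df[1, , drop = FALSE]
  n_m <- 1L
  for (i in seq_len(nrow(df))[-1]) {
    if (df$contig[i] == cur$contig && df$start[i] - cur$end <= gap_bp) {
      cur$end <- max(cur$end, df$end[i])
      n_m <- n_m + 1L
    } else {
      cur$n_merged <- n_m
      k <- k + 1; out[[k]] <- cur
      cur <- df[i, , drop = FALSE]
      n_m <- 1L
    }
  }
  cur$n_merged <- n_m
  k <- k + 1; out[[k]] <- cur
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}
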