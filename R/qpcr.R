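# ChIP-qPCR fold-enrichment quantification: ChIP vs equal-mass input,
# negative-control normalization, replicate mean and SEM.

#' Fold enrichment of a single qPCR measurement
#'
#' Quantity mode: chip/input relative quantities. Ct mode:
#' `efficiency^(input_ct - chip_ct)` (efficiency 2 = perfect doubling per
#' cycle).
#'
#' @param chip,input relative quantities (> 0), or NULL in Ct mode.
#' @param chip_ct,input_ct cycle thresholds (Ct mode).
#' @param efficiency amplification efficiency in (1, 2].
#' @return fold enrichment (vectorized).
#' @export
fold_enrichment <- function(chip = NULL, input = NULL, chip_ct = NULL,
                            input_ct = NULL, efficiency = 2) {
  if (!is.null(chip)) {
    if (any(chip <= 0) || any(input <= 0)) {
      stop("qPCR quantities must be positive")
    }
    chip / input
  } else {
    if (is.null(chip_ct) || is.null(input_ct)) {
      stop("supply either chip/input quantities or chip_ct/input_ct")
    }
    if (any(efficiency <= 1) || any(efficiency > 2)) {
      stop("amplification efficiency must be in (1, 2]")
    }
    efficiency^(input_ct - chip_ct)
  }
}

#' Normalize enrichment over a negative genomic control
#'
#' Background removal by dividing by the negative-control amplicon's
#' enrichment (the control maps to 1.0), applied per mark and per
#' replicate. An arithmetic-subtraction mode is available behind
#' `mode = "subtract"`.
#'
#' @param enr fold enrichment(s).
#' @param control_enr the negative control's fold enrichment (> 0).
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return normalized enrichment.
#' @export
normalize_background <- function(enr, control_enr, mode = c("divide",
                                                            "subtract")) {
  mode <- match.arg(mode)
  if (any(control_enr <= 0)) stop("control enrichment must be positive")
  if (mode == "divide") enr / control_enr else enr - control_enr
}

#' Mean and SEM over biological replicates
#'
#' @param values replicate fold enrichments (n >= 1).
#' @return list: `mean`, `sem` (sample sd / sqrt(n); NA at n = 1), `n`.
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no replicate values")
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' Read a qPCR measurement table
#'
#' TSV with header; required columns: amplicon, mark, replicate, plus
#' chip/input (quantity mode) or chip_ct/input_ct (Ct mode). Optional:
#' is_control (logical marking the negative genomic control amplicon),
#' efficiency, position.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("amplicon", "mark", "replicate") %in% names(df)))
  if (!"is_control" %in% names(df)) df$is_control <- FALSE
  df$is_control <- as.logical(df$is_control)
  df
}

#' ChIP-qPCR analysis: fold enrichment, normalization, replicate summary
#'
#' Computes per-measurement fold enrichment, optionally normalizes the
#' listed marks over the negative-control amplicon (per mark, per
#' replicate), then summarizes replicates per amplicon x mark.
#'
#' @param table measurement table (see [read_qpcr()]).
#' @param mode `"quantity"` or `"ct"`.
#' @param normalize_marks character vector of marks to background-normalize
#'   (e.g. `c("K27me3", "Ezh2")`); requires an `is_control` amplicon for
#'   each mark/replicate.
#' @param normalize_mode passed to [normalize_background()].
#' @param efficiency default amplification efficiency for Ct mode
#'   (overridden by a per-row `efficiency` column when present).
#' @return data.frame: amplicon, mark, mean, sem, n, normalized.
#' @export
qpcr_analyze <- function(table, mode = c("quantity", "ct"),
                         normalize_marks = character(),
                         normalize_mode = "divide", efficiency = 2) {
  mode <- match.arg(mode)
  eff <- if ("efficiency" %in% names(table)) table$efficiency else efficiency
  table$fold <- if (mode == "quantity") {
    fold_enrichment(chip = table$chip, input = table$input)
  } else {
    fold_enrichment(chip_ct = table$chip_ct, input_ct = table$input_ct,
                    efficiency = eff)
  }
  if (!"is_control" %in% names(table)) table$is_control <- FALSE
  table$norm_fold <- table$fold
  table$normalized <- FALSE
  for (mk in normalize_marks) {
    for (rep in unique(table$replicate[table$mark == mk])) {
      sel <- table$mark == mk & table$replicate == rep
      ctrl <- table$fold[sel & table$is_control]
      if (length(ctrl) != 1) {
        stop("need exactly one control amplicon for mark ", mk,
             " replicate ", rep)
      }
      table$norm_fold[sel] <- normalize_background(table$fold[sel], ctrl,
                                                   mode = normalize_mode)
      table$normalized[sel] <- TRUE
    }
  }
  keys <- unique(table[, c("amplicon", "mark")])
  out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- table$amplicon == keys$amplicon[i] & table$mark == keys$mark[i]
    s <- summarize_replicates(table$norm_fold[sel])
    data.frame(amplicon = keys$amplicon[i], mark = keys$mark[i],
               mean = s$mean, sem = s$sem, n = s$n,
               normalized = any(table$normalized[sel]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
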