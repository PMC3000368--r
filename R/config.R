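#' Pipeline configuration
#'
#' Central defaults for every tunable threshold. Values mirror the
#' windowing and significance conventions the analyses are built around:
#' 1 kb enrichment windows at p < 1e-3, motif significance 5e-5, 1 kb merge
#' gap, 200 bp methylation windows over a 10 kb TSS span, 20 kb heat-map
#' rows. Overrides are supplied as name = value pairs or via a flat
#' key: value config file (see [read_config()]); precedence is
#' explicit argument > config file > default.
#'
#' @param ... overrides (must name existing keys).
#' @param file optional config file applied beneath the explicit overrides.
#' @return named list of settings.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- list(
    window_bp = 1000L,        # enrichment / element-discovery window
    step_bp = 200L,           # sliding step for genome-wide calling
    merge_gap_bp = 1000L,     # enriched windows within this gap are merged
    p_threshold = 1e-3,       # enrichment significance
    motif_alpha = 5e-5,       # per-position motif match significance
    read_extension_bp = 200L, # fragment-length proxy for density tracks
    density_bin_bp = 25L,
    n_randomizations = 10L,
    min_gc = 0.50,            # CpG-island criteria (Gardiner-Garden style)
    min_oe = 0.60,
    min_len = 200L,
    island_window_bp = 200L,
    island_step_bp = 1L,
    max_n_fraction = 0.10,    # windows with more N are masked
    meth_window_bp = 200L,
    tss_span_bp = 10000L,     # methylation composite span around TSS
    heatmap_span_bp = 20000L, # per-row span of enrichment heat maps
    tss_flank_bp = 1000L,     # promoter classification window = TSS +/- this
    promoter_span = c(-500L, 2000L), # CpG-class span relative to TSS
    hcp_min_gc = 0.55,        # promoter CpG-class thresholds
    hcp_min_oe = 0.60,
    lcp_max_oe = 0.40,
    max_hits_per_window = 2L, # activating-motif depletion cutoff
    seed = 1L
  )
  if (!is.null(file)) {
    fcfg <- read_config(file)
    cfg <- utils::modifyList(cfg, fcfg)
  }
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown)) stop("unknown config key(s): ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, dots)
  }
  num1 <- c("window_bp", "step_bp", "merge_gap_bp", "p_threshold",
            "motif_alpha", "read_extension_bp", "density_bin_bp",
            "min_gc", "min_oe", "min_len", "meth_window_bp", "tss_span_bp")
  for (k in num1) if (any(cfg[[k]] <= 0)) stop("config key ", k,
                                               " must be positive")
  cfg
}

#' Read a flat key: value config file
#'
#' A YAML subset: one `key: value` per line, `#` comments, numeric values
#' auto-converted, comma-separated values become vectors.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl(":", lines, fixed = TRUE)])
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(num)) num else parts
  }
  out
}

#' Write a reproducibility log for a run
#'
#' Records the seed(s), the full config snapshot, and md5 digests of the
#' input files, as JSON. Randomized-null analyses are only reproducible if
#' the seed is captured, so CLI entry points call this on every run.
#'
#' @param path output path for the JSON log.
#' @param config config list ([pipeline_config()]).
#' @param inputs character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, config, inputs = character()) {
  digests <- if (length(inputs)) {
    stats::setNames(as.character(tools::md5sum(inputs)), basename(inputs))
  } else NULL
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = config$seed, config = config, input_md5 = digests)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
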