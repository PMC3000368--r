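#' Read a genome from FASTA
#'
#' Sequences are uppercased on read and restricted to the A/C/G/T/N
#' alphabet; anything else (including IUPAC ambiguity codes) is rejected so
#' that downstream window statistics have unambiguous semantics. Parsing is
#' delegated to Biostrings; sequences are stored as a plain named character
#' vector, which is what the scanning code consumes.
#'
#' @param path FASTA file path.
#' @return named character vector of uppercase contig sequences
#'   (a "genome"), names in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop("duplicate contig name in ", path, ": ", nm[duplicated(nm)][1])
  }
  seqs <- toupper(as.character(ss))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("contig ", nm[bad][1], " contains characters outside {A,C,G,T,N}")
  }
  if (any(nchar(seqs) < 1)) stop("zero-length contig in ", path)
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Extract sequence for an interval
#'
#' @param genome named character vector.
#' @param contig contig name.
#' @param start,end 0-based half-open coordinates.
#' @return character scalar of length `end - start`.
#' @export
get_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- nchar(genome[[contig]])
  if (start < 0 || end > len || start >= end) {
    stop("interval [", start, ",", end, ") out of bounds for contig ",
         contig, " (length ", len, ")")
  }
  substr(genome[[contig]], start + 1, end)
}

#' Reverse complement
#'
#' @param seq character vector of A/C/G/T/N sequences.
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

#' Contig lengths of a genome
#'
#' @param genome named character vector or an already-named numeric vector of
#'   lengths (passed through).
#' @return named numeric vector of contig lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.numeric(genome)) {
    stopifnot(!is.null(names(genome)))
    return(genome)
  }
  stats::setNames(as.numeric(nchar(genome)), names(genome))
}
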