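#' Reference sequence window
#'
#' A reference chromosome is stored as a *window*: the nucleotide sequence of
#' a region together with the genomic offset of the base preceding its first
#' base.  Genomic position `offset + 1` is the first character of `seq`.  This
#' lets a fixture sit at its true chromosomal coordinates (e.g. around
#' 6:125,750,000) without materialising the whole chromosome.
#'
#' @param chrom Chromosome name.
#' @param seq Nucleotide sequence (character or [Biostrings::DNAString]).
#' @param offset Genomic coordinate of the base before `seq[1]` (0 for a
#'   sequence that starts at position 1).
#' @return An object of class `genome_window`.
#' @export
genome_window <- function(chrom, seq, offset = 0L) {
  seq <- toupper(as.character(seq))
  stopifnot(is.character(chrom), length(chrom) == 1L, nchar(seq) > 0L,
            offset >= 0)
  structure(
    list(chrom = chrom, seq = seq, offset = as.integer(offset),
         start = as.integer(offset) + 1L,
         end = as.integer(offset) + nchar(seq)),
    class = "genome_window"
  )
}

#' @export
print.genome_window <- function(x, ...) {
  cat(sprintf("<genome_window> %s:%d-%d (%d nt)\n",
              x$chrom, x$start, x$end, nchar(x$seq)))
  invisible(x)
}

# Extract [start, end] (1-based genomic, inclusive) from a named list of
# genome windows.  Fatal if the chromosome is absent or the range leaves the
# window.
ref_seq <- function(reference, chrom, start, end) {
  win <- reference[[chrom]]
  if (is.null(win)) {
    abort(paste0("reference sequence unavailable for chromosome '", chrom, "'"))
  }
  if (start < win$start || end > win$end || start > end) {
    abort(sprintf("range %s:%d-%d outside reference window %d-%d",
                  chrom, start, end, win$start, win$end))
  }
  substr(win$seq, start - win$offset, end - win$offset)
}

# Single-base accessor.
ref_base <- function(reference, chrom, pos) ref_seq(reference, chrom, pos, pos)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

comp <- function(s) {
  as.character(Biostrings::complement(Biostrings::DNAString(s)))
}

# Translate a coding-strand nucleotide string codon by codon; incomplete
# trailing codons are dropped.  Stop is "*".
translate_cds <- function(s) {
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  aas <- vapply(seq_len(n), function(i) {
    codon <- substr(s, 3L * i - 2L, 3L * i)
    unname(Biostrings::GENETIC_CODE[codon])
  }, character(1))
  paste(aas, collapse = "")
}

is_stop_codon <- function(codon) codon %in% c("TAA", "TAG", "TGA")

#' Read a reference FASTA of genome windows
#'
#' Reads a (plain-text) FASTA file with [Biostrings::readDNAStringSet].  A
#' record header may carry an `offset=<int>` token after the sequence name to
#' place the sequence at genomic coordinates `offset+1 ...`; without it the
#' sequence starts at position 1.
#'
#' @param path FASTA file path.
#' @return Named list of [genome_window] objects, keyed by chromosome.
#' @export
read_reference <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(set)) {
    header <- names(set)[i]
    parts <- strsplit(header, "\\s+")[[1]]
    chrom <- parts[1]
    offset <- 0L
    off_tok <- grep("^offset=", parts, value = TRUE)
    if (length(off_tok) == 1L) {
      offset <- as.integer(sub("^offset=", "", off_tok))
    }
    out[[chrom]] <- genome_window(chrom, as.character(set[[i]]), offset)
  }
  out
}

#' Write genome windows to a FASTA file
#'
#' Inverse of [read_reference()]: each window becomes one record whose header
#' carries its genomic offset.
#'
#' @param reference Named list of [genome_window] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  lines <- unlist(lapply(reference, function(win) {
    body <- substring(win$seq,
                      seq(1, nchar(win$seq), 70),
                      pmin(seq(1, nchar(win$seq), 70) + 69, nchar(win$seq)))
    c(sprintf(">%s offset=%d", win$chrom, win$offset), body)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}
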