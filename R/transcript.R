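#' Construct a transcript model
#'
#' A transcript is a strand-aware chain of exons.  Exons are supplied as
#' genomic `[start, end]` intervals (1-based, inclusive, `start <= end`); they
#' are stored 5' to 3' in transcript order, i.e. ascending genomic order on
#' the plus strand and descending on the minus strand.
#'
#' @param accession Transcript identifier.
#' @param gene Gene symbol.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end` (genomic, 1-based
#'   inclusive), any order.
#' @return An object of class `transcript`.
#' @export
new_transcript <- function(accession, gene, chrom, strand, exons) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons$start <= exons$end))
  exons <- as_tibble(exons[c("start", "end")])
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    abort(paste0("overlapping exons in transcript ", accession))
  }
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  widths <- exons$end - exons$start + 1L
  structure(
    list(accession = accession, gene = gene, chrom = chrom, strand = strand,
         exons = exons, widths = widths, cum = cumsum(widths),
         length = sum(widths),
         span_start = min(exons$start), span_end = max(exons$end)),
    class = "transcript"
  )
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s (%s) %s:%d-%d [%s], %d exon(s), %d nt\n",
              x$accession, x$gene, x$chrom, x$span_start, x$span_end,
              x$strand, nrow(x$exons), x$length))
  invisible(x)
}

#' Map a genomic position onto a transcript
#'
#' Classifies a genomic position relative to a transcript and, for exonic
#' positions, returns the 1-based transcript coordinate counted 5' to 3' on
#' the coding strand.  Every position is classifiable: intronic positions get
#' the intron index plus distances to the donor (5') and acceptor (3') ends
#' of the intron, and positions outside the transcript span get an
#' upstream/downstream tag with the distance in nucleotides.
#'
#' @param pos Genomic position (scalar).
#' @param tx A [new_transcript()] object.
#' @return A list with `$type` in `exon`, `intron`, `upstream`, `downstream`;
#'   `$tpos` for exons; `$intron`, `$dist_donor`, `$dist_acceptor` for
#'   introns; `$dist` for flanks.
#' @export
genomic_to_transcript <- function(pos, tx) {
  n <- nrow(tx$exons)
  for (i in seq_len(n)) {
    e <- tx$exons[i, ]
    if (pos >= e$start && pos <= e$end) {
      prev <- if (i == 1L) 0L else tx$cum[i - 1L]
      tpos <- if (tx$strand == "+") prev + (pos - e$start + 1L)
              else                  prev + (e$end - pos + 1L)
      return(list(type = "exon", tpos = as.integer(tpos), exon = i))
    }
  }
  # flanks, measured from the transcript span in strand orientation
  if (pos < tx$span_start) {
    side <- if (tx$strand == "+") "upstream" else "downstream"
    return(list(type = side, dist = tx$span_start - pos))
  }
  if (pos > tx$span_end) {
    side <- if (tx$strand == "+") "downstream" else "upstream"
    return(list(type = side, dist = pos - tx$span_end))
  }
  # intronic: find the flanking exons in transcript order
  for (i in seq_len(n - 1L)) {
    e5 <- tx$exons[i, ]; e3 <- tx$exons[i + 1L, ]
    if (tx$strand == "+") {
      if (pos > e5$end && pos < e3$start) {
        return(list(type = "intron", intron = i,
                    dist_donor = pos - e5$end,
                    dist_acceptor = e3$start - pos))
      }
    } else {
      if (pos < e5$start && pos > e3$end) {
        return(list(type = "intron", intron = i,
                    dist_donor = e5$start - pos,
                    dist_acceptor = pos - e3$end))
      }
    }
  }
  abort("unclassifiable position (corrupt transcript model?)")  # nocov
}

#' Map a transcript coordinate back to the genome
#'
#' Inverse of [genomic_to_transcript()] for exonic positions; the round trip
#' is the identity on both strands.
#'
#' @param tpos 1-based transcript coordinate.
#' @param tx A [new_transcript()] object.
#' @return Genomic position (integer).
#' @export
transcript_to_genomic <- function(tpos, tx) {
  stopifnot(tpos >= 1L, tpos <= tx$length)
  i <- findInterval(tpos - 1L, c(0L, tx$cum), rightmost.closed = FALSE)
  prev <- if (i == 1L) 0L else tx$cum[i - 1L]
  off <- tpos - prev  # 1-based offset within exon i (transcript order)
  e <- tx$exons[i, ]
  if (tx$strand == "+") as.integer(e$start + off - 1L)
  else                  as.integer(e$end - off + 1L)
}

# Spliced transcript sequence on the coding strand.
transcript_seq <- function(tx, reference) {
  pieces <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- ref_seq(reference, tx$chrom, tx$exons$start[i], tx$exons$end[i])
    if (tx$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

# Distance (nt) from an exonic transcript position to the nearest *internal*
# exon junction (an exon edge adjacent to an intron); Inf for single-exon
# transcripts.  1 means the junction-adjacent base itself.
dist_to_junction <- function(tpos, tx) {
  n <- nrow(tx$exons)
  if (n == 1L) return(Inf)
  # junctions sit between transcript positions cum[i] and cum[i]+1
  min(abs(tpos - tx$cum[-n]) + 1L, abs(tpos - (tx$cum[-n] + 1L)) + 1L)
}

#' Locate a transcript position within an ORF's codons
#'
#' @param tpos 1-based transcript coordinate; must fall inside the ORF's
#'   coding span (stop codon included).
#' @param orf An [new_orf()] model.
#' @return List with `cds_pos` (1-based position in the CDS), `codon_index`
#'   (1-based) and `offset` (1..3 within the codon).
#' @export
transcript_to_codon <- function(tpos, orf) {
  if (tpos < orf$cds_t_start || tpos > orf$cds_t_end) {
    abort("transcript position outside the ORF coding span")
  }
  cds_pos <- tpos - orf$cds_t_start + 1L
  list(cds_pos = as.integer(cds_pos),
       codon_index = as.integer(ceiling(cds_pos / 3)),
       offset = as.integer(((cds_pos - 1L) %% 3L) + 1L))
}
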