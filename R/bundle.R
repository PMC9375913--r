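#' Construct an ORF model
#'
#' An ORF is a coding span on a transcript, given in 1-based inclusive
#' transcript coordinates and *including* the stop codon (required to call
#' stop_lost / stop_retained).  A transcript may host several ORFs, possibly
#' overlapping in different reading frames.
#'
#' @param protein_accession Protein identifier (e.g. UniProt-style, or an
#'   OpenProt-style `IP_`/`II_` accession for a predicted alternative ORF).
#' @param transcript_accession Host transcript identifier.
#' @param cds_t_start,cds_t_end Coding span in transcript coordinates.
#' @param category `"canonical"` or `"alternative"`.
#' @return An object of class `orf_model`.  `$frame_ok` is FALSE when the
#'   span length is not divisible by 3; such ORFs are kept but excluded from
#'   coding-consequence calls.
#' @export
new_orf <- function(protein_accession, transcript_accession,
                    cds_t_start, cds_t_end,
                    category = c("canonical", "alternative")) {
  category <- match.arg(category)
  stopifnot(cds_t_start >= 1L, cds_t_start < cds_t_end)
  len <- cds_t_end - cds_t_start + 1L
  frame_ok <- (len %% 3L) == 0L
  if (!frame_ok) {
    warn(sprintf("ORF %s: coding span of %d nt is not divisible by 3; kept but excluded from coding-consequence calls",
                 protein_accession, len))
  }
  structure(
    list(protein_accession = protein_accession,
         transcript_accession = transcript_accession,
         cds_t_start = as.integer(cds_t_start),
         cds_t_end = as.integer(cds_t_end),
         n_codons = len %/% 3L,
         category = category, frame_ok = frame_ok),
    class = "orf_model"
  )
}

#' @export
print.orf_model <- function(x, ...) {
  cat(sprintf("<orf_model> %s on %s t%d-%d (%s, %d codons%s)\n",
              x$protein_accession, x$transcript_accession,
              x$cds_t_start, x$cds_t_end, x$category, x$n_codons,
              if (x$frame_ok) "" else ", OUT OF FRAME"))
  invisible(x)
}

#' Assemble an annotation bundle
#'
#' Binds a reference, transcript models and ORF models into the indexed
#' object that [annotate()] consumes.  Spliced transcript sequences are
#' precomputed, and every ORF must name a known transcript and fit inside it.
#'
#' @param reference Named list of [genome_window] objects.
#' @param transcripts List of [new_transcript()] objects (names taken from
#'   their accessions).
#' @param orfs List of [new_orf()] objects.
#' @param flank Up/downstream flank (nt) within which a variant is still
#'   reported against a transcript (default 5000, the common annotator
#'   convention).
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(reference, transcripts, orfs, flank = 5000L) {
  transcripts <- setNames(transcripts,
                          vapply(transcripts, `[[`, "", "accession"))
  keep <- vapply(orfs, function(o) {
    tx <- transcripts[[o$transcript_accession]]
    if (is.null(tx)) {
      warn(sprintf("ORF %s: unknown transcript %s; skipped",
                   o$protein_accession, o$transcript_accession))
      return(FALSE)
    }
    if (o$cds_t_end > tx$length) {
      warn(sprintf("ORF %s: coding span exceeds transcript length; skipped",
                   o$protein_accession))
      return(FALSE)
    }
    TRUE
  }, logical(1))
  orfs <- orfs[keep]
  orfs <- setNames(orfs, vapply(orfs, `[[`, "", "protein_accession"))
  tx_seqs <- lapply(transcripts, transcript_seq, reference = reference)
  orf_by_tx <- split(names(orfs),
                     vapply(orfs, `[[`, "", "transcript_accession"))
  structure(
    list(reference = reference, transcripts = transcripts, orfs = orfs,
         tx_seqs = tx_seqs, orf_by_tx = orf_by_tx,
         flank = as.integer(flank)),
    class = "annotation_bundle"
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  n_can <- sum(vapply(x$orfs, function(o) o$category == "canonical", logical(1)))
  cat(sprintf("<annotation_bundle> %d chromosome window(s), %d transcript(s), %d ORF(s) (%d canonical, %d alternative), flank %d nt\n",
              length(x$reference), length(x$transcripts), length(x$orfs),
              n_can, length(x$orfs) - n_can, x$flank))
  invisible(x)
}

# Accessions of transcripts whose span (+/- flank) contains pos on chrom.
transcripts_near <- function(bundle, chrom, pos) {
  hits <- vapply(bundle$transcripts, function(tx) {
    tx$chrom == chrom &&
      pos >= tx$span_start - bundle$flank &&
      pos <= tx$span_end + bundle$flank
  }, logical(1))
  names(bundle$transcripts)[hits]
}

#' Codon sequence of an ORF
#'
#' Returns the coding-strand bases of one codon, spliced across exon
#' junctions and reverse-complemented for minus-strand transcripts.
#'
#' @param orf An [new_orf()] model.
#' @param codon_index 1-based codon index (the stop codon is the last one).
#' @param bundle An [annotation_bundle()].
#' @return 3-character string.
#' @export
codon_sequence <- function(orf, codon_index, bundle) {
  stopifnot(codon_index >= 1L, codon_index <= orf$n_codons)
  seq <- bundle$tx_seqs[[orf$transcript_accession]]
  from <- orf$cds_t_start + 3L * (codon_index - 1L)
  substr(seq, from, from + 2L)
}

# Full CDS string (coding strand, stop included) of an ORF.
orf_cds_seq <- function(orf, bundle) {
  substr(bundle$tx_seqs[[orf$transcript_accession]],
         orf$cds_t_start, orf$cds_t_end)
}
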