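#' Build a variant table
#'
#' Variants are plain tibbles with one row per normalized (record x ALT
#' allele) pair: columns `chrom`, `pos` (1-based position of the first
#' affected or anchor base), `ref`, `alt`, `vclass` (SNV/MNP/INS/DEL) and
#' `id` (`chrom_pos_ref_alt`).
#'
#' @param chrom,pos,ref,alt Vectors of equal length describing the variants.
#' @return Tibble of variants.
#' @export
#' @examples
#' variant_table("6", 125759711, "C", "T")
variant_table <- function(chrom, pos, ref, alt) {
  tibble(chrom = as.character(chrom), pos = as.integer(pos),
         ref = toupper(ref), alt = toupper(alt)) |>
    mutate(vclass = variant_class(.data$ref, .data$alt),
           id = paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = "_"))
}

# Variant class from allele lengths.
variant_class <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == nchar(alt) & nchar(ref) == 1L ~ "SNV",
    nchar(ref) == nchar(alt)                    ~ "MNP",
    nchar(alt) > nchar(ref)                     ~ "INS",
    TRUE                                        ~ "DEL"
  )
}

# Minimal-trimming normalization: drop the shared suffix, then the shared
# prefix (advancing pos), always keeping at least one base on each side.
# Returns NULL for a null change (ref == alt after trimming).
normalize_alleles <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) return(NULL)
  list(pos = pos, ref = ref, alt = alt)
}

#' Read variants from a VCF file
#'
#' Parses a VCF (v4.x) with \pkg{vcfR}, splits multi-allelic records into
#' independent variants, applies minimal prefix/suffix trimming, and derives
#' the variant class from the allele lengths.  Symbolic or malformed alleles
#' are skipped; the skip messages are attached as `attr(x, "warnings")` (and
#' land in `warnings.txt` when run through [run_annotate()]).
#'
#' @param path VCF file path.
#' @return Tibble of variants as in [variant_table()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  warnings <- character()
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    chrom <- fix$CHROM[i]; pos <- suppressWarnings(as.integer(fix$POS[i]))
    ref <- toupper(fix$REF[i] %||% NA_character_)
    alts <- strsplit(toupper(fix$ALT[i] %||% ""), ",", fixed = TRUE)[[1]]
    if (is.na(pos) || is.na(ref) || !grepl("^[ACGTN]+$", ref) ||
        length(alts) == 0L) {
      warnings <- c(warnings,
                    sprintf("malformed VCF record at line %d (%s:%s); skipped",
                            i, chrom, fix$POS[i]))
      next
    }
    for (alt in alts) {
      if (!grepl("^[ACGTN]+$", alt)) {
        warnings <- c(warnings,
                      sprintf("symbolic/unsupported ALT '%s' at %s:%d; skipped",
                              alt, chrom, pos))
        next
      }
      norm <- normalize_alleles(pos, ref, alt)
      if (is.null(norm)) {
        warnings <- c(warnings,
                      sprintf("null change %s:%d %s>%s; skipped",
                              chrom, pos, ref, alt))
        next
      }
      rows[[length(rows) + 1L]] <-
        variant_table(chrom, norm$pos, norm$ref, norm$alt)
    }
  }
  out <- if (length(rows) > 0L) list_rbind(rows) else
    variant_table(character(), integer(), character(), character())
  attr(out, "warnings") <- warnings
  out
}

#' Read transcript models from a GTF file
#'
#' Imports exon features with [rtracklayer::import()] and groups them into
#' [new_transcript()] models by `transcript_id`; exons are stored 5' to 3'
#' on the transcript's strand.
#'
#' @param path GTF file path.
#' @return Named list of transcripts.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  meta <- S4Vectors::mcols(gr)
  tid <- as.character(meta$transcript_id)
  if (anyNA(tid)) {
    warn(sprintf("%d exon feature(s) without transcript_id skipped",
                 sum(is.na(tid))))
    gr <- gr[!is.na(tid)]; tid <- tid[!is.na(tid)]
  }
  gene <- if ("gene_name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$gene_name)
  } else rep(NA_character_, length(gr))
  out <- list()
  for (acc in unique(tid)) {
    sel <- tid == acc
    sub <- gr[sel]
    out[[acc]] <- new_transcript(
      accession = acc,
      gene = gene[sel][1] %||% acc,
      chrom = as.character(GenomeInfoDb::seqnames(sub))[1],
      strand = as.character(BiocGenerics::strand(sub))[1],
      exons = data.frame(start = BiocGenerics::start(sub),
                         end = BiocGenerics::end(sub))
    )
  }
  out
}

#' Read an ORF table
#'
#' Reads a tab-delimited ORF table with columns `protein_accession`,
#' `transcript_accession`, `coord_space` (`transcript` or `genomic`),
#' `start`, `end`, `category` (`canonical`/`alternative`).  Genomic-space
#' rows are converted to transcript coordinates through the exon map of the
#' named transcript; both span ends must be exonic.
#'
#' @param path TSV file path.
#' @param transcripts Named list of transcripts (from [read_transcripts()]),
#'   required to resolve genomic-space rows and to validate accessions.
#' @return Named list of [new_orf()] models (out-of-frame rows kept with a
#'   warning and flagged; rows on unknown transcripts skipped with a
#'   warning).
#' @export
read_orfs <- function(path, transcripts) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_accession", "transcript_accession", "coord_space",
            "start", "end", "category")
  if (!all(need %in% names(tab))) {
    abort(paste0("ORF table must have columns: ", paste(need, collapse = ", ")))
  }
  out <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    tx <- transcripts[[row$transcript_accession]]
    if (is.null(tx)) {
      warn(sprintf("ORF %s: unknown transcript %s; skipped",
                   row$protein_accession, row$transcript_accession))
      next
    }
    if (row$coord_space == "genomic") {
      a <- genomic_to_transcript(row$start, tx)
      b <- genomic_to_transcript(row$end, tx)
      if (a$type != "exon" || b$type != "exon") {
        warn(sprintf("ORF %s: genomic span end not exonic; skipped",
                     row$protein_accession))
        next
      }
      t1 <- min(a$tpos, b$tpos); t2 <- max(a$tpos, b$tpos)
    } else {
      t1 <- row$start; t2 <- row$end
    }
    out[[row$protein_accession]] <-
      new_orf(row$protein_accession, row$transcript_accession, t1, t2,
              category = row$category)
  }
  out
}
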