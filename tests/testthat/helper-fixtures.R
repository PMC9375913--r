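# Small in-code fixtures shared across test files.

# Two-exon plus-strand toy gene: exon1 1-100, exon2 201-300, canonical ORF
# t31-t150 (40 codons), genome built so the ORF translates cleanly.
toy_gene <- function(strand = "+") {
  tx_len <- 200L
  tseq <- rep("C", tx_len)  # C-rich background: no stop codons possible
  tseq[31:33] <- c("A", "T", "G")
  tseq[148:150] <- c("T", "A", "A")
  genome <- rep("G", 320L)
  if (strand == "+") {
    genome[1:100] <- tseq[1:100]
    genome[201:300] <- tseq[101:200]
    exons <- data.frame(start = c(1L, 201L), end = c(100L, 300L))
  } else {
    rc <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[tseq]))
    genome[21:120] <- rc[1:100]    # transcript 3' half, genomic left
    genome[221:320] <- rc[101:200] # transcript 5' half, genomic right
    exons <- data.frame(start = c(221L, 21L), end = c(320L, 120L))
  }
  ref <- list(chrT = genome_window("chrT", paste(genome, collapse = ""), 0L))
  tx <- new_transcript("TX1", "TOY", "chrT", strand, exons)
  orf <- new_orf("PROT1", "TX1", 31L, 150L, "canonical")
  annotation_bundle(ref, list(tx), list(orf), flank = 5000L)
}

# Engine records restricted to coding consequences, for oracle comparison.
coding_effects <- c("stop_gained", "stop_lost", "start_lost",
                    "frameshift_variant", "missense_variant",
                    "inframe_insertion", "inframe_deletion",
                    "synonymous_variant", "stop_retained_variant")

engine_vs_oracle <- function(sim) {
  recs <- annotate(sim$variants, sim$bundle)
  eng <- recs[recs$effect %in% coding_effects,
              c("id", "protein_accession", "effect")]
  tr <- sim$truth[, c("id", "protein_accession", "effect")]
  m <- merge(eng, tr, by = c("id", "protein_accession"), all = TRUE,
             suffixes = c(".engine", ".oracle"))
  m[is.na(m$effect.engine) | is.na(m$effect.oracle) |
      m$effect.engine != m$effect.oracle, , drop = FALSE]
}

write_minimal_vcf <- function(rows, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
  path
}
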