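# Brute-force re-translation oracle.
#
# Independent of the consequence engine: the variant is applied to the
# *genome* string, the transcript is rebuilt base-by-base from the mutated
# genome (position vectors, not interval arithmetic), and the coding
# consequence is read off the full reference-vs-mutant protein comparison.
# Used as the ground truth for the simulator's truth tables and for the
# oracle-equivalence property tests.

# Genomic positions of a transcript's bases in 5'->3' transcript order.
tx_position_vector <- function(tx) {
  pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
    tx$exons$start[i]:tx$exons$end[i]
  }))
  if (tx$strand == "-") {
    pos <- unlist(lapply(seq_len(nrow(tx$exons)), function(i) {
      tx$exons$end[i]:tx$exons$start[i]
    }))
  }
  pos
}

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Effect of one variant on one ORF, by whole-genome mutation and protein
# diff.  Returns a one-row tibble (effect, protein_change) or NULL when the
# variant does not produce a coding-comparison record for this ORF (the
# region-term cases are derived geometrically).
oracle_effect <- function(v, tx, orf, bundle) {
  win <- bundle$reference[[v$chrom]]
  genome <- strsplit(win$seq, "")[[1]]
  p1 <- v$pos - win$offset
  p2 <- p1 + nchar(v$ref) - 1L
  stopifnot(paste(genome[p1:p2], collapse = "") == v$ref)

  tpos_vec <- tx_position_vector(tx)            # genomic pos per t-index
  # transcript index of every changed genomic base (anchor excluded)
  anchored <- nchar(v$ref) != nchar(v$alt) &&
    substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  changed_g <- if (nchar(v$ref) == nchar(v$alt)) {
    v$pos:(v$pos + nchar(v$ref) - 1L)
  } else if (anchored && nchar(v$alt) == 1L && nchar(v$ref) > 1L) {
    (v$pos + 1L):(v$pos + nchar(v$ref) - 1L)    # deletion body
  } else if (anchored && nchar(v$ref) == 1L) {
    integer(0)                                   # pure insertion
  } else {
    v$pos:(v$pos + nchar(v$ref) - 1L)
  }
  changed_t <- match(changed_g, tpos_vec)
  ins_point_t <- if (nchar(v$alt) > nchar(v$ref) && anchored) {
    flanks <- match(c(v$pos, v$pos + 1L), tpos_vec)
    if (anyNA(flanks)) NA_integer_ else min(flanks)
  } else NA_integer_

  if (length(changed_t) > 0 && anyNA(changed_t)) return(NULL)   # not fully exonic
  net <- nchar(v$alt) - nchar(v$ref)

  coding <- if (!is.na(ins_point_t)) {
    ins_point_t >= orf$cds_t_start && ins_point_t < orf$cds_t_end
  } else {
    any(changed_t >= orf$cds_t_start & changed_t <= orf$cds_t_end)
  }
  if (!coding || !orf$frame_ok) return(NULL)

  # mutate the genome and rebuild the transcript base by base
  mut_genome <- c(genome[seq_len(p1 - 1L)],
                  strsplit(v$alt, "")[[1]],
                  genome[seq.int(p2 + 1L, length(genome))])
  # remap exon coordinates: starts shift when past the replaced span; ends
  # shift when at or past its last base (an edit inside an exon stretches
  # that exon; edits crossing an exon boundary were rejected above)
  g1 <- v$pos; g2 <- v$pos + nchar(v$ref) - 1L
  ex <- tx$exons
  ex2 <- data.frame(
    start = ifelse(ex$start > g2, ex$start + net, ex$start),
    end   = ifelse(ex$end >= g2, ex$end + net, ex$end)
  )
  ex2 <- ex2[order(ex2$start), , drop = FALSE]   # ascending genomic
  mut_tx <- unlist(lapply(seq_len(nrow(ex2)), function(i) {
    idx <- (ex2$start[i]:ex2$end[i]) - win$offset
    mut_genome[idx]
  }))
  if (tx$strand == "-") mut_tx <- rev(unname(COMP[mut_tx]))

  ref_tx <- strsplit(bundle$tx_seqs[[tx$accession]], "")[[1]]
  # sanity: unchanged length relationship
  stopifnot(length(mut_tx) == length(ref_tx) + net)

  cds_from <- orf$cds_t_start
  translate_vec <- function(x, from, max_codons) {
    n <- min(max_codons, (length(x) - from + 1L) %/% 3L)
    if (n <= 0L) return("")
    aas <- character(n)
    for (i in seq_len(n)) {
      codon <- paste(x[from + 3L * (i - 1L) + 0:2], collapse = "")
      aas[i] <- unname(Biostrings::GENETIC_CODE[codon])
      if (aas[i] == "*") return(paste(aas[1:i], collapse = ""))
    }
    paste(aas, collapse = "")
  }
  ref_prot <- translate_vec(ref_tx, cds_from, orf$n_codons)
  mut_prot <- translate_vec(mut_tx, cds_from, orf$n_codons + 50L)

  min_t <- if (length(changed_t) > 0) min(changed_t) else ins_point_t + 0.5
  max_t <- if (length(changed_t) > 0) max(changed_t) else ins_point_t + 0.5
  hits_start <- min_t <= orf$cds_t_start + 2L && max_t >= orf$cds_t_start
  hits_stop  <- min_t <= orf$cds_t_end && max_t >= orf$cds_t_end - 2L

  effect <- oracle_classify(ref_prot, mut_prot, net, hits_start, hits_stop,
                            mut_codon1 = paste(mut_tx[cds_from + 0:2],
                                               collapse = ""))
  pc <- ""
  if (effect %in% c("missense_variant", "stop_gained", "synonymous_variant",
                    "stop_lost", "stop_retained_variant") && net == 0L) {
    d <- which(strsplit(ref_prot, "")[[1]][seq_len(min(nchar(ref_prot),
                                                       nchar(mut_prot)))] !=
               strsplit(mut_prot, "")[[1]][seq_len(min(nchar(ref_prot),
                                                       nchar(mut_prot)))])
    if (length(d) > 0) {
      i <- d[1]
      pc <- sprintf("%s%d%s", substr(ref_prot, i, i), i,
                    substr(mut_prot, i, i))
    } else {
      i <- ceiling((min_t - orf$cds_t_start + 1L) / 3)
      pc <- sprintf("%s%d%s", substr(ref_prot, i, i), i,
                    substr(ref_prot, i, i))
    }
  }
  tibble(effect = effect, protein_change = pc)
}

# Shared decision rules, computed from the oracle's own quantities.
oracle_classify <- function(ref_prot, mut_prot, net, hits_start, hits_stop,
                            mut_codon1) {
  if (hits_start && (net < 0L || mut_codon1 != "ATG")) return("start_lost")
  if (net %% 3L != 0L) return("frameshift_variant")
  ref_stop <- if (grepl("*", ref_prot, fixed = TRUE))
    regexpr("*", ref_prot, fixed = TRUE)[1] else Inf
  mut_stop <- if (grepl("*", mut_prot, fixed = TRUE))
    regexpr("*", mut_prot, fixed = TRUE)[1] else Inf
  if (net == 0L) {
    if (mut_stop < ref_stop) return("stop_gained")
    if (hits_stop && mut_stop > ref_stop) return("stop_lost")
    if (hits_stop && mut_stop == ref_stop && mut_stop <= nchar(mut_prot) &&
        !identical(substr(ref_prot, 1L, ref_stop),
                   substr(mut_prot, 1L, mut_stop))) {
      # change inside the stop codon but still a stop, possibly with other
      # codons changed too: pick the dominant term
      if (identical(substr(ref_prot, 1L, ref_stop - 1L),
                    substr(mut_prot, 1L, mut_stop - 1L)))
        return("stop_retained_variant")
    }
    if (identical(ref_prot, mut_prot)) {
      if (hits_start) return("start_lost")   # unreachable; guard
      return(if (hits_stop) "stop_retained_variant" else "synonymous_variant")
    }
    return("missense_variant")
  }
  expected_stop <- ref_stop + net %/% 3L
  if (net < 0L && hits_stop && mut_stop != expected_stop) return("stop_lost")
  if (mut_stop < expected_stop) return("stop_gained")
  if (mut_stop > expected_stop) return("stop_lost")
  if (net > 0L) "inframe_insertion" else "inframe_deletion"
}

#' Brute-force truth table for a set of variants
#'
#' Runs the genome-level re-translation oracle for every (variant x ORF)
#' pair with a coding consequence.  This is the validation path for the
#' consequence engine: it never uses the engine's codon arithmetic.
#'
#' @param variants Variant tibble.
#' @param bundle An [annotation_bundle()].
#' @return Tibble with `id`, `protein_accession`, `effect`,
#'   `protein_change` (one-letter shorthand, SNV/MNP only).
#' @export
oracle_truth_table <- function(variants, bundle) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- as.list(variants[i, ])
    for (orf in bundle$orfs) {
      tx <- bundle$transcripts[[orf$transcript_accession]]
      if (tx$chrom != v$chrom) next
      res <- oracle_effect(v, tx, orf, bundle)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <-
        tibble(id = v$id, protein_accession = orf$protein_accession,
               effect = res$effect, protein_change = res$protein_change)
    }
  }
  if (length(rows) == 0L) {
    return(tibble(id = character(), protein_accession = character(),
                  effect = character(), protein_change = character()))
  }
  list_rbind(rows)
}
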