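# Seeded synthetic-gene simulator.  Generates a random gene with a canonical
# ORF and an overlapping (or upstream) alternative ORF in a shifted reading
# frame, plus random variants, and pairs them with the brute-force oracle's
# truth table.  Used as the engine's ground-truth test bed.

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Place ATG/stop constraints on a transcript-sequence character vector and
# clear in-frame internal stops in every listed ORF (setting a base to C is
# always safe: no stop codon contains C).
constrain_orfs <- function(tseq, orf_spans) {
  constrained <- integer()
  for (sp in orf_spans) {
    tseq[sp[1]:(sp[1] + 2L)] <- c("A", "T", "G")
    tseq[(sp[2] - 2L):sp[2]] <- c("T", "A", "A")
    constrained <- c(constrained, sp[1]:(sp[1] + 2L), (sp[2] - 2L):sp[2])
  }
  for (pass in 1:4) {
    dirty <- FALSE
    for (sp in orf_spans) {
      n_codons <- (sp[2] - sp[1] + 1L) %/% 3L
      for (ci in seq_len(n_codons - 1L)) {
        at <- sp[1] + 3L * (ci - 1L)
        if (is_stop_codon(paste(tseq[at:(at + 2L)], collapse = ""))) {
          free <- setdiff(at:(at + 2L), constrained)
          if (length(free) == 0L) return(NULL)  # infeasible layout
          tseq[free[1]] <- "C"
          dirty <- TRUE
        }
      }
    }
    if (!dirty) return(tseq)
  }
  tseq
}

#' Simulate a random two-ORF gene with variants and a truth table
#'
#' Builds a deterministic (per-seed) synthetic gene: a transcript with
#' `n_exons` exons on the requested strand, a canonical ORF, an alternative
#' ORF in a different reading frame (nested in the canonical CDS, spilling
#' past its 3' end, or upstream of it), and `n_variants` random variants
#' (SNVs, MNPs, 1-3 bp insertions and deletions).  The expected coding
#' consequence of every variant x ORF pair is computed by the genome-level
#' re-translation oracle ([oracle_truth_table()]), *not* by the annotation
#' engine, so the pair can serve as an engine test.
#'
#' @param seed Integer seed; a fixed seed reproduces the gene, the variants
#'   and the truth table exactly.
#' @param n_exons Number of exons (default 2).
#' @param strand `"+"` or `"-"`.
#' @param orf_layout `"overlap_3prime"` (HEY2-like), `"nested"` or
#'   `"upstream"`.
#' @param n_variants Number of random variants (default 12).
#' @return List with `$bundle`, `$variants`, `$truth`
#'   (the oracle truth table) and `$seed`.
#' @export
#' @examples
#' sim <- simulate_gene(seed = 1)
#' sim$truth
simulate_gene <- function(seed, n_exons = 2L, strand = "+",
                          orf_layout = c("overlap_3prime", "nested",
                                         "upstream"),
                          n_variants = 12L) {
  orf_layout <- match.arg(orf_layout)
  with_seed(seed, {
    for (attempt in 1:25) {
      tx_len <- sample(700:1100, 1L)
      n1 <- sample(60:110, 1L)                 # canonical codons incl. stop
      s1 <- sample(40:120, 1L)
      e1 <- s1 + 3L * n1 - 1L
      if (e1 > tx_len - 80L) next
      shift <- sample(1:2, 1L)
      if (orf_layout == "nested") {
        n2 <- sample(15:max(16L, (n1 %/% 2L)), 1L)
        s2 <- s1 + 3L * sample(5:12, 1L) + shift
        e2 <- s2 + 3L * n2 - 1L
        if (e2 > e1 - 6L) next
      } else if (orf_layout == "overlap_3prime") {
        n2 <- sample(25:60, 1L)
        s2 <- s1 + 3L * sample((n1 %/% 2L):(n1 - 10L), 1L) + shift
        e2 <- s2 + 3L * n2 - 1L
        if (e2 <= e1 + 9L || e2 > tx_len - 20L) next
      } else {
        n2 <- sample(8:15, 1L)
        e2 <- s1 - sample(4:10, 1L)
        s2 <- e2 - 3L * n2 + 1L
        if (s2 < 10L) next
      }
      tseq <- constrain_orfs(random_bases(tx_len),
                             list(c(s1, e1), c(s2, e2)))
      if (is.null(tseq)) next

      # exon layout: cut the transcript, join with random introns
      cuts <- if (n_exons > 1L) {
        sort(sample(seq(50L, tx_len - 50L, by = 1L), n_exons - 1L))
      } else integer()
      widths <- diff(c(0L, cuts, tx_len))
      if (any(widths < 20L)) next
      introns <- if (n_exons > 1L) sample(150:400, n_exons - 1L,
                                          replace = TRUE) else integer()
      # genomic slots left-to-right; on the minus strand transcript exon 1
      # occupies the rightmost slot, so slot widths are reversed
      gw <- if (strand == "+") widths else rev(widths)
      flank <- 800L
      starts <- integer(n_exons); g <- flank + 1L
      for (i in seq_len(n_exons)) {
        starts[i] <- g
        g <- g + gw[i] + (if (i < n_exons) introns[i] else 0L)
      }
      ends <- starts + gw - 1L
      genome_len <- ends[n_exons] + flank

      # genome on the plus strand; a minus-strand gene stores the reverse
      # complement of the transcript in its exons
      genome <- random_bases(genome_len)
      for (i in seq_len(n_exons)) {
        t_lo <- c(0L, cumsum(widths))[i] + 1L
        piece <- tseq[t_lo:(t_lo + widths[i] - 1L)]
        if (strand == "+") {
          genome[starts[i]:ends[i]] <- piece
        } else {
          # exon i (transcript order) is the i-th from the genomic right
          j <- n_exons - i + 1L
          genome[starts[j]:ends[j]] <-
            rev(unname(COMP[piece]))
        }
      }
      reference <- list(chrS = genome_window("chrS",
                                             paste(genome, collapse = ""),
                                             0L))
      tx <- new_transcript("TX_SIM_1", "SIMGENE", "chrS", strand,
                           data.frame(start = starts, end = ends))
      orfs <- list(
        new_orf("CANON_1", "TX_SIM_1", s1, e1, "canonical"),
        new_orf("ALT_1", "TX_SIM_1", s2, e2, "alternative")
      )
      bundle <- annotation_bundle(reference, list(tx), orfs)

      variants <- simulate_variants(n_variants, genome, tx)
      truth <- oracle_truth_table(variants, bundle)
      return(list(bundle = bundle, variants = variants, truth = truth,
                  seed = seed))
    }
    abort("could not find a feasible gene layout for this seed/params")
  })
}

simulate_variants <- function(n_variants, genome, tx) {
  if (n_variants == 0L) {
    return(variant_table(character(), integer(), character(), character()))
  }
  lo <- max(2L, tx$span_start - 100L)
  hi <- min(length(genome) - 5L, tx$span_end + 100L)
  rows <- list()
  for (i in seq_len(n_variants)) {
    pos <- sample(lo:hi, 1L)
    type <- sample(c("SNV", "DEL", "INS", "MNP"), 1L,
                   prob = c(0.6, 0.15, 0.15, 0.1))
    if (type == "SNV") {
      ref <- genome[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    } else if (type == "DEL") {
      l <- sample(1:3, 1L)
      ref <- paste(genome[pos:(pos + l)], collapse = "")
      alt <- genome[pos]
    } else if (type == "INS") {
      ref <- genome[pos]
      alt <- paste(c(ref, random_bases(sample(1:3, 1L))), collapse = "")
    } else {
      l <- sample(2:3, 1L)
      ref <- paste(genome[pos:(pos + l - 1L)], collapse = "")
      repeat {
        alt <- paste(random_bases(l), collapse = "")
        if (alt != ref && substr(alt, 1, 1) != substr(ref, 1, 1)) break
      }
    }
    rows[[i]] <- variant_table("chrS", pos, ref, alt)
  }
  distinct(list_rbind(rows), .data$id, .keep_all = TRUE)
}

#' Mirror a simulated gene onto the opposite strand
#'
#' Reverse-complements the genome window and flips all coordinates, yielding
#' a gene whose protein-level biology is identical but whose transcript runs
#' on the other strand.  Variants are mirrored too (alleles
#' reverse-complemented, positions reflected).  Engine classifications must
#' be invariant under this transformation.
#'
#' @param sim Result of [simulate_gene()].
#' @return A list like `sim`, mirrored (truth table recomputed by the
#'   oracle on the mirrored gene).
#' @export
mirror_gene <- function(sim) {
  bundle <- sim$bundle
  win <- bundle$reference[[1]]
  chrom <- win$chrom
  L <- nchar(win$seq)
  mirror <- function(p) (win$start + win$end) - p
  reference <- setNames(list(genome_window(chrom, revcomp(win$seq),
                                           win$offset)), chrom)
  tx0 <- bundle$transcripts[[1]]
  tx <- new_transcript(tx0$accession, tx0$gene, chrom,
                       if (tx0$strand == "+") "-" else "+",
                       data.frame(start = mirror(tx0$exons$end),
                                  end = mirror(tx0$exons$start)))
  orfs <- unname(lapply(bundle$orfs, function(o) {
    new_orf(o$protein_accession, o$transcript_accession,
            o$cds_t_start, o$cds_t_end, o$category)
  }))
  mb <- annotation_bundle(reference, list(tx), orfs, flank = bundle$flank)
  v <- sim$variants
  mv <- variant_table(
    chrom = v$chrom,
    pos = mirror(v$pos + nchar(v$ref) - 1L),
    ref = vapply(v$ref, revcomp, character(1)),
    alt = vapply(v$alt, revcomp, character(1))
  )
  list(bundle = mb, variants = mv, truth = oracle_truth_table(mv, mb),
       seed = sim$seed)
}
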