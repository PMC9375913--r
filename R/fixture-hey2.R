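# Synthetic HEY2 locus fixture.
#
# Rebuilds a two-exon plus-strand HEY2-like transcript on a synthetic chr6
# window from the coordinates the locus is known by: canonical ORF Q9UBP5
# spanning genomic 6:125,749,777-125,759,802 (1014 nt CDS incl. stop = 337
# residues), alternative ORF IP_145210 contiguous at 6:125,759,396-125,759,827
# (432 nt = 143 residues + stop, overlapping the canonical 3' end in a
# shifted reading frame).  Reference bases at documented variant sites are
# fixed so that the five test variants reproduce their published
# consequences; everything else is filled deterministically from a seed,
# with in-frame stops in either ORF cleared.

HEY2_OFFSET <- 125749500L
# exon 2 genomic position = transcript position + HEY2_E2_SHIFT
HEY2_E2_SHIFT <- 125758591L
HEY2_E1_SHIFT <- 125749579L   # exon 1 (t1-300)

hey2_t2g <- function(t) {
  ifelse(t <= 300L, t + HEY2_E1_SHIFT, t + HEY2_E2_SHIFT)
}

# run the expression with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build the synthetic HEY2 two-ORF fixture
#'
#' Constructs an [annotation_bundle()] holding a synthetic HEY2 locus (one
#' two-exon plus-strand transcript hosting the canonical ORF and an
#' overlapping alternative ORF in a shifted frame) plus the five documented
#' test variants: two canonical stop-gains (R127*, R239*), two variants that
#' are canonical missense but alternative-ORF stop-gains (S308L/Q106*,
#' G331V/G129*), and 6:125,759,806 T>G, which lies 4 nt past the canonical
#' stop codon yet is a missense change (p.Phe137Leu) for the alternative
#' ORF.
#'
#' @param seed Seed for the unconstrained filler bases (recorded in the
#'   returned object as `$seed`).
#' @return List with `$bundle`, `$variants` (tibble of the 5 variants) and
#'   `$seed`.
#' @export
#' @examples
#' fx <- build_fixture_hey2()
#' fx$bundle
build_fixture_hey2 <- function(seed = 145210L) {
  win_len <- 10900L
  seq <- with_seed(seed,
                   sample(c("A", "C", "G", "T"), win_len, replace = TRUE))

  setb <- function(gpos, bases) {
    chars <- strsplit(bases, "")[[1]]
    idx <- gpos - HEY2_OFFSET + seq_along(chars) - 1L
    stopifnot(all(idx >= 1L), all(idx <= win_len))
    seq[idx] <<- chars
  }
  g <- function(n) 125759000L + n   # shorthand for 6:125,759,xxx

  # hard-constrained bases (see header comment for the codon layout)
  setb(125749777L, "ATG")      # canonical initiator (exon 1, t198-200)
  setb(g(167L), "CGA")         # canonical codon 127: C>T -> R127*
  setb(g(500L), "AGC")         # canonical codon 238 / pads alt codon 36
  setb(g(503L), "CGA")         # canonical codon 239: C>T -> R239*
                               #   alt codon 36 = GCC: C>T synonymous
  setb(g(710L), "TCAA")        # canonical codon 308 TCA (S308L on C>T);
                               #   alt codon 106 CAA (Q106* on C>T)
  setb(g(779L), "GGGA")        # canonical codon 331 GGG (G331V on G>T);
                               #   alt codon 129 GGA (G129* on G>T)
  setb(g(395L), "CATG")        # alt initiator ATG at 396-398, C pad keeps
                               #   the overlapping canonical codon stop-free
  setb(g(800L), "TGA")         # canonical stop (t1209-1211)
  setb(g(804L), "TTT")         # alt codon 137 TTT (T>G at 806 -> F137L)
  setb(g(825L), "TAA")         # alt stop (t1234-1236)
  constrained <- c(125749777:125749779,
                   g(c(167:169, 500:505, 710:713, 779:782, 395:398,
                       800:802, 804:806, 825:827)))

  # clear accidental in-frame stops in both ORFs (setting a base to C can
  # never create a stop: no stop codon contains C)
  clear_stops <- function(cds_t_start, n_codons) {
    for (ci in seq_len(n_codons - 1L)) {
      t0 <- cds_t_start + 3L * (ci - 1L)
      gp <- hey2_t2g(t0:(t0 + 2L))
      codon <- paste(seq[gp - HEY2_OFFSET], collapse = "")
      if (is_stop_codon(codon)) {
        free <- gp[!(gp %in% constrained)]
        if (length(free) == 0L) abort("fixture bug: fully constrained stop codon")
        seq[free[1] - HEY2_OFFSET] <<- "C"
      }
    }
  }
  clear_stops(198L, 338L)   # canonical: codons 1-337 must be coding
  clear_stops(805L, 144L)   # alternative: codons 1-143 must be coding

  reference <- list(`6` = genome_window("6", paste(seq, collapse = ""),
                                        HEY2_OFFSET))
  tx <- new_transcript(
    accession = "ENST00000368364", gene = "HEY2", chrom = "6", strand = "+",
    exons = data.frame(start = c(125749580L, 125758892L),
                       end   = c(125749879L, 125759891L))
  )
  orfs <- list(
    new_orf("Q9UBP5", "ENST00000368364", 198L, 1211L, "canonical"),
    new_orf("IP_145210", "ENST00000368364", 805L, 1236L, "alternative")
  )
  bundle <- annotation_bundle(reference, list(tx), orfs)

  # internal consistency checks: a failure here is a fixture bug
  can_prot <- translate_cds(orf_cds_seq(bundle$orfs$Q9UBP5, bundle))
  alt_prot <- translate_cds(orf_cds_seq(bundle$orfs$IP_145210, bundle))
  ok <- nchar(can_prot) == 338L &&
    substr(can_prot, 338L, 338L) == "*" &&
    !grepl("*", substr(can_prot, 1L, 337L), fixed = TRUE) &&
    nchar(alt_prot) == 144L &&
    substr(alt_prot, 144L, 144L) == "*" &&
    !grepl("*", substr(alt_prot, 1L, 143L), fixed = TRUE) &&
    substr(can_prot, 1L, 1L) == "M" && substr(alt_prot, 1L, 1L) == "M"
  if (!ok) abort("HEY2 fixture failed its self-check")

  variants <- variant_table(
    chrom = "6",
    pos = c(125759167L, 125759503L, 125759711L, 125759780L, 125759806L),
    ref = c("C", "C", "C", "G", "T"),
    alt = c("T", "T", "T", "T", "G")
  )
  list(bundle = bundle, variants = variants, seed = seed)
}
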