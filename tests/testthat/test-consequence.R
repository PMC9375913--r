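# Consequence engine: region calls, SNV/MNP/indel classification, impact
# mapping, per-ORF frame independence.

test_that("every HEY2 fixture variant gets its documented dual annotation", {
  fx <- build_fixture_hey2()
  recs <- annotate(fx$variants, fx$bundle)
  expect_equal(nrow(recs), 10L)  # 5 variants x (canonical + alternative)

  get <- function(pos, cat) {
    r <- recs[recs$pos == pos & recs$orf_category == cat, ]
    expect_equal(nrow(r), 1L)
    r
  }
  # canonical stop-gains
  expect_equal(get(125759167, "canonical")$effect, "stop_gained")
  expect_equal(get(125759167, "canonical")$protein_change, "R127*")
  expect_equal(get(125759167, "canonical")$hgvs_p, "p.Arg127Ter")
  expect_equal(get(125759503, "canonical")$protein_change, "R239*")
  # canonical missense
  expect_equal(get(125759711, "canonical")$effect, "missense_variant")
  expect_equal(get(125759711, "canonical")$protein_change, "S308L")
  expect_equal(get(125759780, "canonical")$protein_change, "G331V")
  # alternative-ORF stop-gains in the shifted frame
  expect_equal(get(125759711, "alternative")$effect, "stop_gained")
  expect_equal(get(125759711, "alternative")$protein_change, "Q106*")
  expect_equal(get(125759780, "alternative")$effect, "stop_gained")
  expect_equal(get(125759780, "alternative")$protein_change, "G129*")
  # upstream-of-altORF variant is a 5'UTR modifier for the alternative ORF
  expect_equal(get(125759167, "alternative")$effect, "five_prime_UTR_variant")
  expect_equal(get(125759167, "alternative")$impact, "modifier")
  # 4 nt past the canonical stop: modifier on canonical, missense on alt
  expect_equal(get(125759806, "canonical")$effect, "three_prime_UTR_variant")
  expect_equal(get(125759806, "canonical")$impact, "modifier")
  expect_equal(get(125759806, "alternative")$effect, "missense_variant")
  expect_equal(get(125759806, "alternative")$hgvs_p, "p.Phe137Leu")
  expect_equal(get(125759806, "alternative")$impact, "moderate")
  # feature id combines transcript and protein accession
  expect_equal(get(125759806, "alternative")$feature_id,
               "ENST00000368364@IP_145210")
})

test_that("region classification is ORF-relative", {
  fx <- build_fixture_hey2()
  tx <- fx$bundle$transcripts$ENST00000368364
  alt <- fx$bundle$orfs$IP_145210
  can <- fx$bundle$orfs$Q9UBP5
  v <- function(pos) variant_table("6", pos, "A", "G")[1, ]
  expect_equal(classify_region(v(125759167), tx, alt), "five_UTR")
  expect_equal(classify_region(v(125759167), tx, can), "CDS")
  expect_equal(classify_region(v(125759806), tx, can), "three_UTR")
  expect_equal(classify_region(v(125759806), tx, alt), "CDS")
  expect_equal(classify_region(v(125759901), tx, can), "downstream")
  expect_equal(classify_region(v(125749400), tx, can), "upstream")
  # intron geometry: donor/acceptor windows, then the splice region
  expect_equal(classify_region(v(125749881), tx, can), "splice_donor")
  expect_equal(classify_region(v(125749885), tx, can), "splice_region")
  expect_equal(classify_region(v(125758890), tx, can), "splice_acceptor")
  expect_equal(classify_region(v(125758885), tx, can), "splice_region")
  expect_equal(classify_region(v(125755000), tx, can), "intron")
})

test_that("intronic and flanking variants get modifier-level terms", {
  b <- toy_gene("+")
  run1 <- function(pos, ref = "G", alt = "A") {
    annotate(variant_table("chrT", pos, ref, alt), b)
  }
  expect_equal(run1(150)$effect, "intron_variant")
  expect_equal(run1(101)$effect, "splice_donor_variant")
  expect_equal(run1(199)$effect, "splice_acceptor_variant")
  expect_equal(run1(105)$effect, "splice_region_variant")
  expect_equal(run1(310)$effect, "downstream_gene_variant")
  expect_equal(annotate(variant_table("chrT", 340, "G", "A"),
                        toy_gene("-"))$effect, "upstream_gene_variant")
  # exonic base next to the junction carries a secondary splice-region term
  r <- run1(100, "C", "G")
  expect_match(r$secondary, "splice_region_variant")
  # far from any transcript: single intergenic record
  far <- annotate(variant_table("chr9", 1e6, "A", "T"), b)
  expect_equal(far$effect, "intergenic_variant")
  expect_equal(nrow(far), 1L)
})

test_that("SNVs in the toy CDS classify by codon change", {
  b <- toy_gene("+")
  run1 <- function(pos, ref, alt) {
    r <- annotate(variant_table("chrT", pos, ref, alt), b)
    r[1, ]
  }
  # background codons are CCC (Pro): third-position C>A stays Pro
  expect_equal(run1(36, "C", "A")$effect, "synonymous_variant")
  expect_equal(run1(36, "C", "A")$protein_change, "P2P")
  # first-position C>T gives a stop only via TGA/TAA/TAG patterns; CCC->TCC
  # is missense (Ser)
  expect_equal(run1(34, "C", "T")$effect, "missense_variant")
  expect_equal(run1(34, "C", "T")$protein_change, "P2S")
  # destroy the initiator
  expect_equal(run1(31, "A", "C")$effect, "start_lost")
  # mutate the stop codon: TAA->TGA retains the stop, TAA->CAA loses it
  stop_g <- 201L + (148L - 101L)  # genomic position of transcript 148
  expect_equal(run1(stop_g + 1L, "A", "G")$effect, "stop_retained_variant")
  expect_equal(run1(stop_g, "T", "C")$effect, "stop_lost")
  # reference mismatch is flagged but still classified
  r <- run1(36, "T", "A")
  expect_match(r$warning, "reference mismatch")
})

test_that("MNPs re-translate all affected codons and report the worst", {
  b <- toy_gene("+")
  run1 <- function(pos, ref, alt) {
    annotate(variant_table("chrT", pos, ref, alt), b)[1, ]
  }
  # two changes inside one codon: CCC->TGA-like stop via first two bases
  # codon 3 occupies transcript 37-39 (genomic 37-39)
  r <- run1(37, "CC", "TG")  # CCC -> TGC (Cys): missense
  expect_equal(r$effect, "missense_variant")
  r <- run1(37, "CCC", "TGA")
  expect_equal(r$effect, "stop_gained")
  # whole-codon MNP that keeps the residue: CCC -> CCA is still Pro
  r <- run1(37, "CCC", "CCA")
  expect_equal(r$effect, "synonymous_variant")
  # one missense + one synonymous across two codons -> missense wins
  r <- run1(39, "CC", "AA")  # codon3 CCA (syn) + codon4 ACC? -> check worst
  expect_true(r$effect %in% c("missense_variant"))
  expect_match(r$secondary, "synonymous_variant")
})

test_that("indels classify by frame, early stops and boundary codons", {
  b <- toy_gene("+")
  run1 <- function(pos, ref, alt) {
    annotate(variant_table("chrT", pos, ref, alt), b)[1, ]
  }
  # 1-bp insertion at CDS position 10 -> frameshift
  expect_equal(run1(40, "C", "CT")$effect, "frameshift_variant")
  expect_equal(impact_code("frameshift_variant"), 3L)
  # 3-bp in-frame deletion, no new stop
  expect_equal(run1(39, "CCCC", "C")$effect, "inframe_deletion")
  # 3-bp in-frame insertion introducing TAA -> stop_gained
  expect_equal(run1(39, "C", "CTAA")$effect, "stop_gained")
  # 3-bp in-frame insertion of a plain codon
  expect_equal(run1(39, "C", "CAGA")$effect, "inframe_insertion")
  # deletion removing the initiator
  expect_equal(run1(30, "CATG", "C")$effect, "start_lost")
  # deletion removing the stop codon
  stop_g <- 201L + (148L - 101L)
  expect_equal(run1(stop_g - 1L, "CTAA", "C")$effect, "stop_lost")
  # indel spanning the exon/intron boundary -> splice disruption + warning
  r <- run1(99, "CCGG", "C")
  expect_equal(r$effect, "splice_donor_variant")
  expect_match(r$warning, "exon boundary")
})

test_that("overlapping ORFs in different frames are classified independently", {
  # add a +1-frame alternative ORF inside the toy canonical CDS
  b <- toy_gene("+")
  tx <- b$transcripts$TX1
  win <- b$reference$chrT
  seq <- strsplit(win$seq, "")[[1]]
  # alternative ORF at transcript 44..103 (frame +1 vs canonical 31..150);
  # place ATG at t44-46 (genomic 44-46) and TAA at t101-103 (genomic
  # 201-203, across the junction? no: t101 -> genomic 201)
  seq[44:46] <- c("A", "T", "G")
  seq[201:203] <- c("T", "A", "A")
  ref <- list(chrT = genome_window("chrT", paste(seq, collapse = ""), 0L))
  orfs <- list(new_orf("PROT1", "TX1", 31L, 150L, "canonical"),
               new_orf("ALTP", "TX1", 44L, 103L, "alternative"))
  b2 <- annotation_bundle(ref, list(tx), orfs)
  # sanity: canonical frame must survive the inserted ATG/TAA codons
  can_cds <- vapply(seq_len(40L), function(i)
    codon_sequence(b2$orfs$PROT1, i, b2), "")
  expect_false(any(can_cds[-40L] %in% c("TAA", "TAG", "TGA")))

  # a change synonymous for one frame need not be for the other
  recs <- annotate(variant_table("chrT", 48, "C", "A"), b2)
  can <- recs[recs$protein_accession == "PROT1", ]
  alt <- recs[recs$protein_accession == "ALTP", ]
  expect_equal(nrow(can), 1L)
  expect_equal(nrow(alt), 1L)
  # canonical codon 6 (t46-48) = GCC -> GCA: synonymous Ala
  expect_equal(can$effect, "synonymous_variant")
  # alternative codon 2 (t47-49) = CCC -> ACC? position 48 is its offset 2:
  # CCC -> CAC (His): missense
  expect_equal(alt$effect, "missense_variant")
  # canonical records come first in the output
  expect_equal(recs$orf_category, c("canonical", "alternative"))
})

test_that("every effect term carries its fixed impact category", {
  fx <- build_fixture_hey2()
  sim <- suppressWarnings(simulate_gene(5, n_exons = 2))
  recs <- rbind(annotate(fx$variants, fx$bundle),
                annotate(sim$variants, sim$bundle))
  expect_true(all(recs$impact_code == impact_code(recs$effect)))
  expect_true(all(recs$impact == impact_label(recs$impact_code)))
  # and the mapping itself is the fixed 4-level scheme
  expect_equal(impact_code(c("stop_gained", "frameshift_variant",
                             "splice_acceptor_variant")), rep(3L, 3))
  expect_equal(impact_code(c("missense_variant", "inframe_deletion")),
               rep(2L, 2))
  expect_equal(impact_code(c("synonymous_variant", "splice_region_variant",
                             "stop_retained_variant")), rep(1L, 3))
  expect_equal(impact_code(c("intron_variant", "five_prime_UTR_variant",
                             "upstream_gene_variant")), rep(0L, 3))
})
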