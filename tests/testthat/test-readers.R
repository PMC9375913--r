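# File readers: VCF normalization, GTF transcript assembly, ORF tables.

test_that("VCF records are split, trimmed and classified", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_minimal_vcf(c(
    "6\t125759711\t.\tC\tT\t.\t.\t.",
    "1\t100\t.\tAT\tAT\t.\t.\t.",          # null change after trimming
    "1\t100\t.\tCA\tCT,C\t.\t.\t.",         # multi-allelic: SNV + DEL
    "1\t200\t.\tA\t<DEL>\t.\t.\t."          # symbolic allele
  ), path)
  v <- suppressWarnings(read_vcf(path))
  expect_equal(nrow(v), 3L)
  expect_equal(v$vclass, c("SNV", "SNV", "DEL"))
  # first record passes through untouched
  expect_equal(v$pos[1], 125759711L)
  expect_equal(v$ref[1], "C")
  # shared prefix trimmed with position advanced
  expect_equal(v$pos[2], 101L)
  expect_equal(v$ref[2], "A"); expect_equal(v$alt[2], "T")
  # anchored deletion keeps its anchor base
  expect_equal(v$pos[3], 100L)
  expect_equal(v$ref[3], "CA"); expect_equal(v$alt[3], "C")
  # null change and symbolic allele produce warnings, not variants
  expect_length(attr(v, "warnings"), 2L)
  expect_match(attr(v, "warnings")[1], "null change")
})

test_that("variant ids follow the chrom_pos_ref_alt convention", {
  v <- variant_table("6", 125759711, "C", "T")
  expect_identical(v$id, "6_125759711_C_T")
})

test_that("GTF exons group into strand-ordered transcripts", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 1, 100, ".", "+", ".",
          'transcript_id "T1"; gene_name "GENEA";', sep = "\t"),
    paste("chr1", "src", "exon", 201, 300, ".", "+", ".",
          'transcript_id "T1"; gene_name "GENEA";', sep = "\t"),
    paste("chr1", "src", "exon", 50, 80, ".", "-", ".",
          'transcript_id "T2"; gene_name "GENEB";', sep = "\t"),
    paste("chr1", "src", "exon", 120, 160, ".", "-", ".",
          'transcript_id "T2"; gene_name "GENEB";', sep = "\t")
  ), path)
  txs <- read_transcripts(path)
  expect_setequal(names(txs), c("T1", "T2"))
  expect_equal(txs$T1$length, 200L)
  expect_equal(txs$T1$gene, "GENEA")
  # minus-strand exons stored 5'->3', i.e. descending genomic order
  expect_equal(txs$T2$exons$start, c(120L, 50L))
  expect_equal(genomic_to_transcript(160, txs$T2)$tpos, 1L)
})

test_that("ORF tables convert genomic rows and flag broken frames", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("6", "src", "exon", 125749580, 125749879, ".", "+", ".",
          'transcript_id "TXH"; gene_name "HEY2";', sep = "\t"),
    paste("6", "src", "exon", 125758892, 125759891, ".", "+", ".",
          'transcript_id "TXH"; gene_name "HEY2";', sep = "\t")
  ), gtf)
  txs <- read_transcripts(gtf)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "protein_accession\ttranscript_accession\tcoord_space\tstart\tend\tcategory",
    "IP_145210\tTXH\tgenomic\t125759396\t125759827\talternative",
    "BADFRAME\tTXH\ttranscript\t10\t442\tcanonical",
    "NOTX\tMISSING\ttranscript\t1\t9\tcanonical"
  ), tsv)
  orfs <- withCallingHandlers(
    read_orfs(tsv, txs),
    warning = function(w) invokeRestart("muffleWarning"))
  # the published alternative ORF interval is 432 nt = 144 codons
  expect_equal(orfs$IP_145210$cds_t_end - orfs$IP_145210$cds_t_start + 1L,
               432L)
  expect_equal(orfs$IP_145210$n_codons, 144L)
  expect_equal(orfs$IP_145210$cds_t_start, 805L)
  # 433-nt span: kept but flagged out of frame (and warned about)
  expect_false(orfs$BADFRAME$frame_ok)
  w <- capture_warnings(read_orfs(tsv, txs))
  expect_true(any(grepl("not divisible by 3", w)))
  expect_true(any(grepl("unknown transcript", w)))
  # unknown transcript skipped
  expect_false("NOTX" %in% names(orfs))
})

test_that("reference FASTA round-trips genome windows with offsets", {
  win <- genome_window("6", "ACGTACGTACGT", offset = 1000L)
  path <- withr::local_tempfile(fileext = ".fa")
  write_reference(list(`6` = win), path)
  back <- read_reference(path)
  expect_equal(back$`6`$offset, 1000L)
  expect_equal(back$`6`$seq, win$seq)
})
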