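# Output contracts: annOnePerLine, max_impact, annotated VCF, summary.

test_that("annOnePerLine has the exact column contract and one row per effect", {
  fx <- build_fixture_hey2()
  recs <- annotate(fx$variants, fx$bundle)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ann_one_per_line(recs, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(names(tab),
               c("CHROM", "POS", "REF", "ALT", "ANN[*].EFFECT",
                 "ANN[*].IMPACT", "ANN[*].HGVS_C", "ANN[*].HGVS_P",
                 "ANN[*].FEATUREID", "ANN[*].GENE"))
  expect_equal(nrow(tab), nrow(recs))   # 5 variants x 2 ORFs = 10
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("stop_gained", "missense_variant",
                    "five_prime_UTR_variant") %in% tab$`ANN[*].EFFECT`))

  # empty input -> header-only file
  write_ann_one_per_line(recs[0, ], path)
  expect_equal(nrow(read.delim(path, check.names = FALSE)), 0L)
})

test_that("max_impact applies the greater-or-equal reporting rule", {
  fx <- build_fixture_hey2()
  recs <- annotate(fx$variants, fx$bundle)
  mi <- max_impact_table(recs)
  expect_equal(nrow(mi), 5L)   # one row per variant
  row <- function(pos) mi[grepl(paste0("_", pos, "_"), mi$hg38_name), ]

  # canonical missense (2) vs alternative stop-gain (3): alt fields shown
  r <- row(125759711)
  expect_true(r$in_ref && r$in_alt)
  expect_equal(r$ref_max_impact, 2L)
  expect_equal(r$alt_max_impact, 3L)
  expect_equal(r$alt_protein, "IP_145210")

  # canonical stop-gain (3) vs alternative modifier (0): alt suppressed
  r <- row(125759167)
  expect_equal(r$ref_max_impact, 3L)
  expect_equal(r$alt_max_impact, 0L)
  expect_true(is.na(r$alt_protein))

  # modifier on canonical (0) vs moderate on alternative (2): shown
  r <- row(125759806)
  expect_equal(r$ref_max_impact, 0L)
  expect_equal(r$alt_max_impact, 2L)
  expect_equal(r$alt_hgvs_p, "p.Phe137Leu")

  # intergenic-only variant: both flags false, both maxima 0
  lone <- annotate(variant_table("chr9", 1e6, "A", "T"), fx$bundle)
  mi2 <- max_impact_table(lone)
  expect_false(mi2$in_ref); expect_false(mi2$in_alt)
  expect_equal(mi2$ref_max_impact, 0L)
  expect_equal(mi2$alt_max_impact, 0L)

  # canonical effects are visible in every output
  expect_true(all(!is.na(mi$ref_protein)))
})

test_that("annotated VCF gains a well-formed ANN field and keeps INFO", {
  fx <- build_fixture_hey2()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_minimal_vcf(c("6\t125759711\t.\tC\tT\t.\t.\tDP=10",
                      "6\t125759806\t.\tT\tG\t.\t.\t."), vcf)
  variants <- read_vcf(vcf)
  recs <- annotate(variants, fx$bundle)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_annotated_vcf(recs, vcf, out)
  lines <- readLines(out)
  expect_true(any(grepl("^##INFO=<ID=ANN", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2L)   # record count preserved
  # one comma-separated ANN entry per effect record (2 ORFs here)
  ann1 <- sub(".*ANN=", "", body[1])
  expect_length(strsplit(ann1, ",")[[1]], 2L)
  # pre-existing INFO keys pass through
  expect_match(body[1], "DP=10;ANN=")
  # canonical entry precedes the alternative one
  expect_match(strsplit(ann1, ",")[[1]][1], "Q9UBP5")
})

test_that("the impact summary counts each variant once at its overall max", {
  fx <- build_fixture_hey2()
  recs <- annotate(fx$variants, fx$bundle)
  s <- impact_summary(recs)
  expect_equal(s$n[s$impact == "high"], 4L)
  expect_equal(s$n[s$impact == "moderate"], 1L)
  expect_equal(sum(s$proportion), 1)

  # all-intergenic input: modifier proportion 1
  lone <- annotate(variant_table("chr9", c(1e6, 2e6), c("A", "C"),
                                 c("T", "G")), fx$bundle)
  s2 <- impact_summary(lone)
  expect_equal(s2$proportion[s2$impact == "modifier"], 1)

  # structured summary file round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_summary(recs, path)
  js <- jsonlite::read_json(path)
  expect_equal(js$n_variants, 5L)
  expect_equal(js$impact_counts$high, 4L)
})
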