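# Output tables mirroring the tool's contract: annOnePerLine.tsv (one row
# per effect), max_impact.tsv (one row per variant), the annotated VCF and
# the machine-readable summary.

ann_effect_string <- function(effect, secondary) {
  ifelse(secondary == "" | is.na(secondary), effect,
         paste(effect, secondary, sep = "&"))
}

#' Write the one-effect-per-line table
#'
#' Writes `annOnePerLine.tsv`: one row for each effect of each variant with
#' the exact columns `CHROM`, `POS`, `REF`, `ALT`, `ANN[*].EFFECT`,
#' `ANN[*].IMPACT`, `ANN[*].HGVS_C`, `ANN[*].HGVS_P`, `ANN[*].FEATUREID`,
#' `ANN[*].GENE`.
#'
#' @param records Effect-record tibble from [annotate()].
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_ann_one_per_line <- function(records, path) {
  out <- tibble(
    CHROM = records$chrom, POS = records$pos,
    REF = records$ref, ALT = records$alt,
    `ANN[*].EFFECT` = ann_effect_string(records$effect, records$secondary),
    `ANN[*].IMPACT` = records$impact,
    `ANN[*].HGVS_C` = records$hgvs_c,
    `ANN[*].HGVS_P` = records$hgvs_p,
    `ANN[*].FEATUREID` = records$feature_id,
    `ANN[*].GENE` = records$gene
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(out)
}

#' Per-variant maximal-impact table
#'
#' Collapses effect records to one row per variant: the maximal impact over
#' canonical-ORF records (`ref_max_impact`) and over non-canonical ones
#' (`alt_max_impact`), with the accessions and changes of the maximal
#' records.  Ties within an impact level break by effect severity, then by
#' accession.  Following the reporting rule, alternative-ORF fields are only
#' populated when the variant's impact on the alternative ORF is greater
#' than or equal to its impact on a canonical ORF.
#'
#' @param records Effect-record tibble from [annotate()].
#' @return Tibble with one row per variant: `hg38_name`, `in_ref`,
#'   `in_alt`, `ref_max_impact`, `alt_max_impact` (0-3), and the
#'   transcript/protein accessions and DNA/protein changes of the maximal
#'   canonical and alternative records.
#' @export
max_impact_table <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(hg38_name = character(), in_ref = logical(),
                  in_alt = logical(), ref_max_impact = integer(),
                  alt_max_impact = integer(), ref_transcript = character(),
                  ref_protein = character(), ref_hgvs_c = character(),
                  ref_hgvs_p = character(), alt_transcript = character(),
                  alt_protein = character(), alt_hgvs_c = character(),
                  alt_hgvs_p = character()))
  }
  one_side <- function(df) {
    if (nrow(df) == 0L) {
      return(list(max = 0L, tx = NA_character_, prot = NA_character_,
                  hgvs_c = NA_character_, hgvs_p = NA_character_))
    }
    df <- df[order(-df$impact_code, severity_rank(df$effect),
                   df$protein_accession), , drop = FALSE]
    list(max = df$impact_code[1], tx = df$transcript_accession[1],
         prot = df$protein_accession[1], hgvs_c = df$hgvs_c[1],
         hgvs_p = df$hgvs_p[1])
  }
  records |>
    group_by(.data$id) |>
    group_map(function(df, key) {
      can <- df[!is.na(df$orf_category) & df$orf_category == "canonical", ]
      alt <- df[!is.na(df$orf_category) & df$orf_category == "alternative", ]
      r <- one_side(can); a <- one_side(alt)
      show_alt <- nrow(alt) > 0L && a$max >= r$max
      tibble(
        hg38_name = key$id,
        in_ref = nrow(can) > 0L, in_alt = nrow(alt) > 0L,
        ref_max_impact = r$max, alt_max_impact = a$max,
        ref_transcript = r$tx, ref_protein = r$prot,
        ref_hgvs_c = r$hgvs_c, ref_hgvs_p = r$hgvs_p,
        alt_transcript = if (show_alt) a$tx else NA_character_,
        alt_protein = if (show_alt) a$prot else NA_character_,
        alt_hgvs_c = if (show_alt) a$hgvs_c else NA_character_,
        alt_hgvs_p = if (show_alt) a$hgvs_p else NA_character_
      )
    }) |>
    list_rbind() |>
    (\(x) x[match(unique(records$id), x$hg38_name), , drop = FALSE])()
}

#' Write an annotated VCF
#'
#' Re-emits the input VCF with a SnpEff-dialect `ANN` INFO field added to
#' each record:
#' `Allele|EffectTerm|Impact|Gene|FeatureID|HGVS_c|HGVS_p`, one
#' comma-separated entry per effect record, canonical ORFs first, then by
#' severity.  Pre-existing INFO keys pass through unchanged and the header
#' gains an ANN description line.
#'
#' @param records Effect-record tibble from [annotate()].
#' @param input_vcf Path of the VCF that produced the records.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_annotated_vcf <- function(records, input_vcf, path) {
  lines <- readLines(input_vcf)
  is_header <- startsWith(lines, "#")
  header <- lines[is_header]
  body <- lines[!is_header]
  ann_line <- paste0(
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations:",
    " 'Allele | Effect | Impact | Gene | FeatureID | HGVS.c | HGVS.p'\">")
  chrom_line <- grepl("^#CHROM", header)
  header <- append(header, ann_line, after = max(which(!chrom_line)))

  by_key <- split(records, paste(records$chrom, records$pos, sep = ":"))
  out_body <- vapply(body, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    recs <- by_key[[paste(f[1], f[2], sep = ":")]]
    if (is.null(recs) || nrow(recs) == 0L) return(line)
    ann <- paste(vapply(seq_len(nrow(recs)), function(i) {
      r <- recs[i, ]
      paste(r$alt, ann_effect_string(r$effect, r$secondary), r$impact,
            r$gene %||% "", r$feature_id %||% "", r$hgvs_c, r$hgvs_p,
            sep = "|")
    }, character(1)), collapse = ",")
    info <- if (length(f) >= 8L && !(f[8] %in% c(".", ""))) {
      paste0(f[8], ";ANN=", ann)
    } else paste0("ANN=", ann)
    if (length(f) < 8L) f <- c(f, rep(".", 8L - length(f)))
    f[8] <- info
    paste(f, collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(header, out_body), path)
  invisible(path)
}

#' Summarize variants by their overall maximal impact
#'
#' Each variant is counted once, at the maximum impact across all its effect
#' records (so a 3'UTR modifier for the canonical protein that is a missense
#' change for an alternative ORF counts as moderate).
#'
#' @param records Effect-record tibble from [annotate()].
#' @return Tibble with one row per impact category (`modifier`, `low`,
#'   `moderate`, `high`): `n` variants and relative `proportion` (summing
#'   to 1 when any variant is present).
#' @export
impact_summary <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble(impact = IMPACT_LABELS, code = 0:3, n = rep(0L, 4),
                  proportion = rep(0, 4)))
  }
  per_variant <- records |>
    group_by(.data$id) |>
    summarise(max_impact = max(.data$impact_code), .groups = "drop")
  counts <- vapply(0:3, function(k) sum(per_variant$max_impact == k),
                   integer(1))
  tibble(impact = IMPACT_LABELS, code = 0:3, n = counts,
         proportion = if (sum(counts) > 0) counts / sum(counts) else
           rep(0, 4))
}

#' Write the run summary
#'
#' Serialises the impact summary (plus variant/record counts) as structured
#' JSON text.
#'
#' @param records Effect-record tibble from [annotate()].
#' @param path Output path.
#' @return The summary list, invisibly.
#' @export
write_summary <- function(records, path) {
  s <- impact_summary(records)
  obj <- list(
    n_variants = length(unique(records$id)),
    n_effect_records = nrow(records),
    impact_counts = setNames(as.list(s$n), s$impact),
    impact_proportions = setNames(as.list(s$proportion), s$impact)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(obj)
}

#' Bar chart of the impact-category distribution
#'
#' @param summary Tibble from [impact_summary()] (or a record tibble, which
#'   is summarised first).
#' @return A ggplot object.
#' @export
plot_impact_summary <- function(summary) {
  if ("effect" %in% names(summary)) summary <- impact_summary(summary)
  summary$impact <- factor(summary$impact, levels = IMPACT_LABELS)
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$impact, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#2e7d32") +
    ggplot2::labs(x = "impact category", y = "relative proportion") +
    ggplot2::theme_minimal()
}
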