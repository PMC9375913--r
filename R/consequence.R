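# Consequence engine: classify each variant's effect on every
# (transcript x ORF) pair, in transcript/codon space.  The brute-force
# genome-level re-translation oracle used to validate this code lives in
# oracle.R and shares none of the coordinate bookkeeping below.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

aa3 <- function(a) unname(AA3[strsplit(a, "")[[1]]]) |> paste(collapse = "")

codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# p.Arg127Ter / R127* pair for a substitution.
format_sub <- function(ref_aa, idx, mut_aa, synonymous = FALSE) {
  if (synonymous) {
    list(p3 = sprintf("p.%s%d=", aa3(ref_aa), idx),
         p1 = sprintf("%s%d%s", ref_aa, idx, ref_aa))
  } else {
    list(p3 = sprintf("p.%s%d%s", aa3(ref_aa), idx, aa3(mut_aa)),
         p1 = sprintf("%s%d%s", ref_aa, idx, mut_aa))
  }
}

# Genomic span replaced by the variant and the changed positions (anchor base
# of an anchored indel is not counted as changed).
variant_span <- function(v) {
  L <- nchar(v$ref)
  span <- c(v$pos, v$pos + L - 1L)
  anchored <- L != nchar(v$alt) &&
    substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  if (v$vclass == "INS" && anchored && L == 1L) {
    # pure insertion: no reference base changes; the classification looks at
    # both flanks of the insertion point (pos, pos + 1)
    return(list(span = c(v$pos, v$pos + 1L), changed = integer(),
                anchored = TRUE))
  }
  changed <- if (anchored && v$vclass == "DEL") {
    seq.int(span[1] + 1L, span[2])
  } else {
    seq.int(span[1], span[2])
  }
  list(span = span, changed = changed, anchored = anchored)
}

# Apply the variant to a spliced transcript sequence.  Assumes the replaced
# genomic span lies within exons of tx (caller has checked).  Returns the
# mutant sequence, the transcript coordinates of the edited span and the net
# length change.
apply_edit_tx <- function(tx_seq, tx, v) {
  L <- nchar(v$ref)
  t1 <- genomic_to_transcript(v$pos, tx)$tpos
  t2 <- if (L == 1L) t1 else genomic_to_transcript(v$pos + L - 1L, tx)$tpos
  lo <- min(t1, t2); hi <- max(t1, t2)
  repl <- if (tx$strand == "+") v$alt else revcomp(v$alt)
  mut <- paste0(substr(tx_seq, 1L, lo - 1L), repl,
                substr(tx_seq, hi + 1L, nchar(tx_seq)))
  list(seq = mut, t_start = lo, t_end = hi, net = nchar(v$alt) - L)
}

# --- SNV ---------------------------------------------------------------

classify_snv <- function(v, tx, orf, bundle, tpos) {
  loc <- transcript_to_codon(tpos, orf)
  ref_codon <- codon_sequence(orf, loc$codon_index, bundle)
  warning_msg <- NA_character_
  tx_ref <- substr(bundle$tx_seqs[[tx$accession]], tpos, tpos)
  want <- if (tx$strand == "+") v$ref else comp(v$ref)
  if (tx_ref != want) {
    warning_msg <- sprintf(
      "reference mismatch at %s:%d: annotation has %s, VCF REF implies %s",
      v$chrom, v$pos, tx_ref, want)
  }
  mut_base <- if (tx$strand == "+") v$alt else comp(v$alt)
  mut_codon <- ref_codon
  substr(mut_codon, loc$offset, loc$offset) <- mut_base
  ref_aa <- codon_aa(ref_codon); mut_aa <- codon_aa(mut_codon)

  if (loc$codon_index == 1L && mut_codon != "ATG") {
    effect <- "start_lost"
    pc <- list(p3 = "p.Met1?", p1 = "M1?")
  } else if (ref_aa == "*" && mut_aa == "*") {
    effect <- "stop_retained_variant"
    pc <- format_sub("*", loc$codon_index, "*", synonymous = TRUE)
  } else if (ref_aa == "*") {
    effect <- "stop_lost"
    pc <- format_sub("*", loc$codon_index, mut_aa)
  } else if (mut_aa == "*") {
    effect <- "stop_gained"
    pc <- format_sub(ref_aa, loc$codon_index, "*")
  } else if (ref_aa == mut_aa) {
    effect <- "synonymous_variant"
    pc <- format_sub(ref_aa, loc$codon_index, mut_aa, synonymous = TRUE)
  } else {
    effect <- "missense_variant"
    pc <- format_sub(ref_aa, loc$codon_index, mut_aa)
  }
  ref_c <- if (tx$strand == "+") v$ref else comp(v$ref)
  list(effect = effect,
       hgvs_c = sprintf("c.%d%s>%s", loc$cds_pos, ref_c, mut_base),
       hgvs_p = pc$p3, protein_change = pc$p1, warning = warning_msg)
}

# --- MNP / same-length delins ------------------------------------------

classify_mnp <- function(v, tx, orf, bundle, edit) {
  cds1 <- max(edit$t_start, orf$cds_t_start) - orf$cds_t_start + 1L
  cds2 <- min(edit$t_end, orf$cds_t_end) - orf$cds_t_start + 1L
  codons <- seq.int(ceiling(cds1 / 3), ceiling(cds2 / 3))
  mut_cds <- substr(edit$seq, orf$cds_t_start, orf$cds_t_end)
  terms <- character(); subs <- list()
  for (ci in codons) {
    rc <- codon_sequence(orf, ci, bundle)
    mc <- substr(mut_cds, 3L * ci - 2L, 3L * ci)
    if (rc == mc) next
    ra <- codon_aa(rc); ma <- codon_aa(mc)
    term <- if (ci == 1L && mc != "ATG") "start_lost"
      else if (ra == "*" && ma == "*") "stop_retained_variant"
      else if (ra == "*") "stop_lost"
      else if (ma == "*") "stop_gained"
      else if (ra == ma) "synonymous_variant"
      else "missense_variant"
    terms <- c(terms, term)
    subs[[length(subs) + 1L]] <- list(ci = ci, ra = ra, ma = ma, term = term)
  }
  if (length(terms) == 0L) {
    # all affected codons untouched on the coding strand (cannot happen for a
    # true MNP inside the CDS) -- fall back to synonymous
    terms <- "synonymous_variant"
    subs <- list(list(ci = codons[1],
                      ra = codon_aa(codon_sequence(orf, codons[1], bundle)),
                      ma = codon_aa(codon_sequence(orf, codons[1], bundle)),
                      term = "synonymous_variant"))
  }
  ord <- order(severity_rank(vapply(subs, `[[`, "", "term")))
  top <- subs[[ord[1]]]
  changed_aa <- Filter(function(s) s$ra != s$ma || s$term == "start_lost", subs)
  if (top$term == "start_lost") {
    pc <- list(p3 = "p.Met1?", p1 = "M1?")
  } else if (length(changed_aa) > 1L) {
    a <- changed_aa[[1]]; b <- changed_aa[[length(changed_aa)]]
    pc <- list(p3 = sprintf("p.%s%d_%s%ddelins%s", aa3(a$ra), a$ci,
                            aa3(b$ra), b$ci,
                            paste(vapply(changed_aa, function(s) aa3(s$ma),
                                         ""), collapse = "")),
               p1 = sprintf("%s%d%s", top$ra, top$ci, top$ma))
  } else {
    pc <- format_sub(top$ra, top$ci, top$ma,
                     synonymous = top$term %in% c("synonymous_variant",
                                                  "stop_retained_variant"))
  }
  sec <- setdiff(unique(vapply(subs, `[[`, "", "term")), top$term)
  list(effect = top$term, secondary = sec,
       hgvs_c = sprintf("c.%d_%d%s", cds1, cds2,
                        if (v$vclass == "MNP") "delins" else "delins"),
       hgvs_p = pc$p3, protein_change = pc$p1, warning = NA_character_)
}

# --- indels -------------------------------------------------------------

classify_indel <- function(v, tx, orf, bundle, edit) {
  net <- edit$net
  ref_cds <- orf_cds_seq(orf, bundle)
  ref_prot <- translate_cds(ref_cds)            # includes terminal "*"

  # transcript positions whose bases actually change (anchor excluded); for a
  # pure insertion, the two positions flanking the insertion point
  if (net > 0L && nchar(v$ref) == 1L) {
    lo <- min(edit$t_start, edit$t_end)
    changed_rng <- c(lo + 0.5, lo + 0.5)        # insertion point
  } else if (net < 0L && substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L) &&
             nchar(v$alt) == 1L) {
    # anchored deletion: drop the anchor base (strand decides which end)
    changed_rng <- if (tx$strand == "+") c(edit$t_start + 1L, edit$t_end)
                   else c(edit$t_start, edit$t_end - 1L)
  } else {
    changed_rng <- c(edit$t_start, edit$t_end)
  }
  hits <- function(a, b) changed_rng[1] <= b && changed_rng[2] >= a
  hits_start <- hits(orf$cds_t_start, orf$cds_t_start + 2L)
  hits_stop  <- hits(orf$cds_t_end - 2L, orf$cds_t_end)

  # ORF start in the mutant transcript shifts only when the whole edit is 5'
  # of the coding span (then the variant is not routed here anyway)
  mut_start <- orf$cds_t_start +
    if (edit$t_end < orf$cds_t_start) net else 0L
  # translate generously past the reference length to find the mutant stop
  max_nt <- (orf$n_codons + 50L) * 3L
  mut_cds <- substr(edit$seq, mut_start, mut_start + max_nt - 1L)
  mut_prot_full <- translate_cds(mut_cds)
  stop_at <- regexpr("*", mut_prot_full, fixed = TRUE)
  mut_prot <- if (stop_at > 0) substr(mut_prot_full, 1L, stop_at)
              else mut_prot_full

  # deletions clipping the initiator are start_lost outright; insertions only
  # when the mutant first codon is no longer ATG
  if (hits_start && (net < 0L || edit$t_start < orf$cds_t_start ||
                     substr(mut_cds, 1L, 3L) != "ATG")) {
    return(list(effect = "start_lost", hgvs_c = indel_hgvs_c(v, orf, edit),
                hgvs_p = "p.Met1?", protein_change = "M1?",
                warning = NA_character_))
  }

  first_diff <- first_divergence(ref_prot, mut_prot)
  if (net %% 3L != 0L) {
    idx <- min(first_diff, nchar(ref_prot))
    ra <- substr(ref_prot, idx, idx)
    return(list(effect = "frameshift_variant",
                hgvs_c = indel_hgvs_c(v, orf, edit),
                hgvs_p = sprintf("p.%s%dfs", aa3(ra), idx),
                protein_change = sprintf("%s%dfs", ra, idx),
                warning = NA_character_))
  }

  ref_stop_idx <- nchar(ref_prot)                # terminal "*"
  mut_stop_idx <- if (stop_at > 0) stop_at else Inf
  expected_stop <- ref_stop_idx + net %/% 3L
  if (net < 0L && hits_stop && mut_stop_idx != expected_stop) {
    return(list(effect = "stop_lost", hgvs_c = indel_hgvs_c(v, orf, edit),
                hgvs_p = sprintf("p.Ter%dext", ref_stop_idx),
                protein_change = sprintf("*%dext", ref_stop_idx),
                warning = NA_character_))
  }
  if (mut_stop_idx < expected_stop) {
    ra_idx <- min(first_diff, ref_stop_idx)
    ra <- substr(ref_prot, ra_idx, ra_idx)
    return(list(effect = "stop_gained", hgvs_c = indel_hgvs_c(v, orf, edit),
                hgvs_p = sprintf("p.%s%dTer", aa3(ra), ra_idx),
                protein_change = sprintf("%s%d*", ra, ra_idx),
                warning = NA_character_))
  }
  if (mut_stop_idx > expected_stop) {
    return(list(effect = "stop_lost", hgvs_c = indel_hgvs_c(v, orf, edit),
                hgvs_p = sprintf("p.Ter%dext", ref_stop_idx),
                protein_change = sprintf("*%dext", ref_stop_idx),
                warning = NA_character_))
  }
  idx <- min(first_diff, ref_stop_idx)
  ra <- substr(ref_prot, idx, idx)
  if (net > 0L) {
    list(effect = "inframe_insertion", hgvs_c = indel_hgvs_c(v, orf, edit),
         hgvs_p = sprintf("p.%s%dins", aa3(ra), idx),
         protein_change = sprintf("%s%dins", ra, idx),
         warning = NA_character_)
  } else {
    n_del <- (-net) %/% 3L
    list(effect = "inframe_deletion", hgvs_c = indel_hgvs_c(v, orf, edit),
         hgvs_p = if (n_del == 1L) sprintf("p.%s%ddel", aa3(ra), idx)
                  else sprintf("p.%s%d_%ddel", aa3(ra), idx, idx + n_del - 1L),
         protein_change = sprintf("%s%ddel", ra, idx),
         warning = NA_character_)
  }
}

first_divergence <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0L) {
    av <- strsplit(substr(a, 1L, n), "")[[1]]
    bv <- strsplit(substr(b, 1L, n), "")[[1]]
    d <- which(av != bv)
    if (length(d) > 0L) return(d[1])
  }
  n + 1L
}

indel_hgvs_c <- function(v, orf, edit) {
  a <- edit$t_start - orf$cds_t_start + 1L
  b <- edit$t_end - orf$cds_t_start + 1L
  if (edit$net > 0L) sprintf("c.%d_%dins", a, a + 1L)
  else if (edit$net < 0L) {
    if (a == b) sprintf("c.%ddel", a) else sprintf("c.%d_%ddel", a, b)
  } else sprintf("c.%d_%ddelins", a, b)
}

# --- region-level classification ---------------------------------------

utr_effect <- function(tpos, orf, tx, v, bundle) {
  five <- tpos < orf$cds_t_start
  effect <- if (five) "five_prime_UTR_variant" else "three_prime_UTR_variant"
  hgvs_c <- if (v$vclass == "SNV") {
    base_ref <- if (tx$strand == "+") v$ref else comp(v$ref)
    base_alt <- if (tx$strand == "+") v$alt else comp(v$alt)
    if (five) sprintf("c.-%d%s>%s", orf$cds_t_start - tpos, base_ref, base_alt)
    else sprintf("c.*%d%s>%s", tpos - orf$cds_t_end, base_ref, base_alt)
  } else ""
  list(effect = effect, hgvs_c = hgvs_c, hgvs_p = "", protein_change = "",
       warning = NA_character_)
}

# One (variant x transcript x ORF) classification.  Returns a list of fields
# or NULL when no record should be emitted (frame-broken ORF, in-span).
classify_effect <- function(v, tx, orf, bundle) {
  vs <- variant_span(v)
  locs <- lapply(unique(c(vs$span[1], vs$span[2], vs$changed)),
                 genomic_to_transcript, tx = tx)
  types <- vapply(locs, `[[`, "", "type")
  secondary <- character()

  if (all(types %in% c("upstream", "downstream"))) {
    effect <- paste0(types[1], "_gene_variant")
    res <- list(effect = effect, hgvs_c = "", hgvs_p = "",
                protein_change = "", warning = NA_character_)
  } else if (all(types == "intron")) {
    dd <- min(vapply(locs, `[[`, 0, "dist_donor"))
    da <- min(vapply(locs, `[[`, 0, "dist_acceptor"))
    if (dd <= 2L) {
      res <- list(effect = "splice_donor_variant", hgvs_c = "", hgvs_p = "",
                  protein_change = "", warning = NA_character_)
    } else if (da <= 2L) {
      res <- list(effect = "splice_acceptor_variant", hgvs_c = "",
                  hgvs_p = "", protein_change = "", warning = NA_character_)
    } else if (min(dd, da) <= 8L) {
      res <- list(effect = "splice_region_variant", hgvs_c = "", hgvs_p = "",
                  protein_change = "", warning = NA_character_)
    } else {
      res <- list(effect = "intron_variant", hgvs_c = "", hgvs_p = "",
                  protein_change = "", warning = NA_character_)
    }
  } else if (any(types == "intron") || any(types %in% c("upstream",
                                                        "downstream"))) {
    # edit spans an exon boundary: splice disruption, most severe applicable
    intr <- locs[types == "intron"]
    side <- if (length(intr) > 0L &&
                min(vapply(intr, `[[`, 0, "dist_donor")) <=
                min(vapply(intr, `[[`, 0, "dist_acceptor"))) {
      "splice_donor_variant"
    } else "splice_acceptor_variant"
    res <- list(effect = side, hgvs_c = "", hgvs_p = "", protein_change = "",
                warning = sprintf("variant %s spans an exon boundary of %s; classified as %s",
                                  v$id, tx$accession, side))
  } else {
    # fully exonic
    tpositions <- vapply(locs, `[[`, 0L, "tpos")
    changed_t <- if (length(vs$changed) > 0L) {
      vapply(vs$changed, function(g) genomic_to_transcript(g, tx)$tpos,
             integer(1))
    } else {
      # pure anchored insertion: the insertion point flanks
      tpositions
    }
    in_cds <- any(changed_t >= orf$cds_t_start & changed_t <= orf$cds_t_end)
    if (v$vclass == "INS" && vs$anchored) {
      # insertion point must lie strictly inside the coding span
      tp <- sort(tpositions)
      in_cds <- tp[1] >= orf$cds_t_start && tp[1] < orf$cds_t_end
    }
    if (!in_cds) {
      res <- utr_effect(changed_t[1], orf, tx, v, bundle)
    } else if (!orf$frame_ok) {
      return(NULL)
    } else if (v$vclass == "SNV") {
      res <- classify_snv(v, tx, orf, bundle, tpositions[1])
    } else {
      edit <- apply_edit_tx(bundle$tx_seqs[[tx$accession]], tx, v)
      if (v$vclass == "MNP") {
        res <- classify_mnp(v, tx, orf, bundle, edit)
        secondary <- res$secondary %||% character()
      } else {
        res <- classify_indel(v, tx, orf, bundle, edit)
      }
    }
    # exonic positions within 3 nt of an internal junction pick up a
    # secondary splice_region term
    if (!is.null(res) &&
        min(vapply(changed_t, dist_to_junction, 0, tx = tx)) <= 3) {
      secondary <- union(secondary, "splice_region_variant")
    }
  }
  if (is.null(res)) return(NULL)
  res$secondary <- setdiff(secondary, res$effect)
  res
}

#' Annotate variants against every transcript and ORF
#'
#' The core operation: every variant is classified once per (overlapping or
#' flanking transcript) x (hosted ORF) pair, so a single variant can be a
#' 3'UTR modifier for the canonical protein and a missense (or stop-gain)
#' change for an alternative ORF overlapping in another reading frame.
#' Canonical-ORF records are always present for transcripts that have one;
#' a variant with no transcript within the flank yields one
#' `intergenic_variant` record.
#'
#' @param variants Tibble of variants ([variant_table()] / [read_vcf()]).
#' @param bundle An [annotation_bundle()].
#' @return Tibble of effect records, one row per (variant x transcript x
#'   ORF): identifiers, `feature_id` (`transcript@protein`), `orf_category`,
#'   `effect` (plus `&`-joined `secondary` terms), four-level `impact` with
#'   numeric `impact_code`, HGVS-style `hgvs_c`/`hgvs_p`, Table-1-style
#'   one-letter `protein_change`, and a per-record `warning`.  Records for a
#'   variant are ordered canonical-first, then by effect severity, then by
#'   accession.
#' @export
#' @examples
#' fx <- build_fixture_hey2()
#' annotate(fx$variants[3, ], fx$bundle)
annotate <- function(variants, bundle) {
  if (nrow(variants) == 0L) return(empty_records())
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- as.list(variants[i, ])
    recs <- list()
    for (acc in transcripts_near(bundle, v$chrom, v$pos)) {
      tx <- bundle$transcripts[[acc]]
      for (orf_acc in bundle$orf_by_tx[[acc]] %||% character()) {
        orf <- bundle$orfs[[orf_acc]]
        res <- classify_effect(v, tx, orf, bundle)
        if (is.null(res)) next
        recs[[length(recs) + 1L]] <- tibble(
          chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, id = v$id,
          gene = tx$gene, transcript_accession = acc,
          protein_accession = orf$protein_accession,
          feature_id = paste0(acc, "@", orf$protein_accession),
          orf_category = orf$category,
          effect = res$effect,
          secondary = paste(res$secondary, collapse = "&"),
          impact_code = impact_code(res$effect),
          impact = impact_label(impact_code(res$effect)),
          hgvs_c = res$hgvs_c, hgvs_p = res$hgvs_p,
          protein_change = res$protein_change,
          warning = res$warning
        )
      }
    }
    if (length(recs) == 0L) {
      recs[[1L]] <- tibble(
        chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt, id = v$id,
        gene = NA_character_, transcript_accession = NA_character_,
        protein_accession = NA_character_, feature_id = NA_character_,
        orf_category = NA_character_, effect = "intergenic_variant",
        secondary = "", impact_code = 0L, impact = "modifier",
        hgvs_c = "", hgvs_p = "", protein_change = "",
        warning = NA_character_
      )
    }
    out <- list_rbind(recs)
    out <- out[order(out$orf_category != "canonical",
                     severity_rank(out$effect),
                     out$feature_id), , drop = FALSE]
    rows[[i]] <- out
  }
  list_rbind(rows)
}

empty_records <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), id = character(), gene = character(),
         transcript_accession = character(), protein_accession = character(),
         feature_id = character(), orf_category = character(),
         effect = character(), secondary = character(),
         impact_code = integer(), impact = character(), hgvs_c = character(),
         hgvs_p = character(), protein_change = character(),
         warning = character())
}

#' Classify a variant's region relative to one ORF
#'
#' Region classification is ORF-relative: an exonic position 5' of the ORF
#' is `five_UTR` for that ORF even when it sits inside another ORF's coding
#' span.  Intronic positions within 2 nt of a junction are
#' `splice_donor`/`splice_acceptor`, within 3-8 nt `splice_zone`
#' (splice-region); exonic positions get `CDS`, `five_UTR` or `three_UTR`.
#'
#' @param v One-row variant tibble (or list with `chrom`, `pos`, `ref`,
#'   `alt`, `vclass`).
#' @param tx Transcript.
#' @param orf ORF model.
#' @return Character scalar: `"CDS"`, `"five_UTR"`, `"three_UTR"`,
#'   `"intron"`, `"upstream"`, `"downstream"`, `"splice_donor"`,
#'   `"splice_acceptor"` or `"splice_region"`.
#' @export
classify_region <- function(v, tx, orf) {
  v <- as.list(v)
  loc <- genomic_to_transcript(v$pos, tx)
  switch(loc$type,
    upstream = "upstream",
    downstream = "downstream",
    intron = {
      if (loc$dist_donor <= 2L) "splice_donor"
      else if (loc$dist_acceptor <= 2L) "splice_acceptor"
      else if (min(loc$dist_donor, loc$dist_acceptor) <= 8L) "splice_region"
      else "intron"
    },
    exon = {
      if (loc$tpos < orf$cds_t_start) "five_UTR"
      else if (loc$tpos > orf$cds_t_end) "three_UTR"
      else "CDS"
    }
  )
}
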