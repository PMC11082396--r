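# three-letter amino acid codes, HGVS style ("*" -> Ter)
.AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Ter")

.CONSEQUENCE_IMPACT <- c(
  intergenic = "MODIFIER", intron = "MODIFIER",
  five_prime_UTR = "MODIFIER", three_prime_UTR = "MODIFIER",
  synonymous = "LOW", missense = "MODERATE",
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  splice_site = "HIGH"
)

.codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

# spliced CDS sequence of one transcript, 5'->3' of the mRNA
.cds_sequence <- function(models, transcript_id, genome) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  seg <- models$cds[models$cds$transcript_id == transcript_id, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  chunks <- substring(genome[[tx$chrom]], seg$start, seg$end)
  s <- paste(chunks, collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}

#' Annotate the functional consequences of SNPs
#'
#' Classifies each variant against every overlapping transcript (one
#' `intergenic` effect if none overlaps): `intron`, `splice_site` (within 2 bp
#' of an intron boundary, intron side), `five_prime_UTR` / `three_prime_UTR`,
#' and for coding positions `synonymous`, `missense`, `stop_gained`,
#' `stop_lost` or `start_lost` by substituting the variant base into its codon
#' (minus-strand alleles are complemented; codon and residue indices follow
#' transcription order, residue 1 being the initiator methionine). Impact
#' tiers follow the four-level MODIFIER/LOW/MODERATE/HIGH scheme of common
#' variant-effect annotators. Protein changes use three-letter notation, e.g.
#' `"Pro303Leu"`.
#'
#' @param variants A [variant_table()]. Each `ref` allele must match the
#'   reference genome at its position (hard error otherwise, guarding against
#'   FASTA/VCF coordinate drift).
#' @param models A [gene_models()] object.
#' @param genome Named character vector of chromosome sequences.
#' @return A `data.frame` with one row per variant x transcript (or per
#'   variant for intergenic): `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene_id`, `transcript_id`, `consequence`, `impact`, `protein_change`.
#' @export
annotate_variants <- function(variants, models, genome) {
  validate_variant_table(variants)
  n <- nrow(variants)
  if (n > 0) {
    obs <- substring(genome[variants$chrom], variants$pos, variants$pos)
    bad <- obs != variants$ref
    if (any(bad)) {
      i <- which(bad)[1]
      stop("reference mismatch at ", variants$chrom[i], ":", variants$pos[i],
           " (VCF says ", variants$ref[i], ", genome has ", obs[i], ")")
    }
  }

  tx <- models$transcripts
  keys <- variant_key(variants)

  if (nrow(tx) > 0 && n > 0) {
    tx_gr <- GenomicRanges::GRanges(tx$chrom,
                                    IRanges::IRanges(tx$start, tx$end))
    v_gr <- GenomicRanges::GRanges(variants$chrom,
                                   IRanges::IRanges(variants$pos, variants$pos))
    hits <- GenomicRanges::findOverlaps(v_gr, tx_gr)
    h_var <- S4Vectors::queryHits(hits)
    h_tx <- S4Vectors::subjectHits(hits)
  } else {
    h_var <- h_tx <- integer(0)
  }

  cds_cache <- new.env(parent = emptyenv())
  get_cds <- function(t_id) {
    if (is.null(cds_cache[[t_id]]))
      cds_cache[[t_id]] <- .cds_sequence(models, t_id, genome)
    cds_cache[[t_id]]
  }

  rows <- vector("list", length(h_var) + n)
  r <- 0L
  classify <- function(vi, ti) {
    pos <- variants$pos[vi]
    strand <- tx$strand[ti]
    t_id <- tx$transcript_id[ti]
    exons <- models$exons[models$exons$transcript_id == t_id, , drop = FALSE]
    cds <- models$cds[models$cds$transcript_id == t_id, , drop = FALSE]

    in_exon <- any(pos >= exons$start & pos <= exons$end)
    if (!in_exon) {
      # intron side: distance to the closest exon edge
      d <- min(abs(c(pos - exons$end, exons$start - pos)))
      cons <- if (d <= 2) "splice_site" else "intron"
      return(list(consequence = cons, protein_change = ""))
    }
    cds_hit <- which(pos >= cds$start & pos <= cds$end)
    if (length(cds_hit) == 0) {
      # exonic but non-coding: UTR side relative to the CDS in mRNA direction
      cds_min <- min(cds$start); cds_max <- max(cds$end)
      upstream <- pos < cds_min
      five <- (strand == "+" && upstream) || (strand == "-" && !upstream)
      return(list(consequence = if (five) "five_prime_UTR" else "three_prime_UTR",
                  protein_change = ""))
    }
    # offset into the spliced CDS, transcription order (cds rows already are)
    offset <- 0L
    for (k in seq_len(nrow(cds))) {
      s <- cds$start[k]; e <- cds$end[k]
      if (pos >= s && pos <= e) {
        offset <- offset + if (strand == "+") pos - s else e - pos
        break
      }
      offset <- offset + (e - s + 1L)
    }
    cds_seq <- get_cds(t_id)
    codon_idx <- offset %/% 3L
    within <- offset %% 3L
    wt_codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
    mut_base <- if (strand == "-") .COMPLEMENT[[variants$alt[vi]]]
                else variants$alt[vi]
    mut_codon <- wt_codon
    substr(mut_codon, within + 1L, within + 1L) <- mut_base
    aa_wt <- .codon_aa(wt_codon)
    aa_mut <- .codon_aa(mut_codon)
    residue <- codon_idx + 1L
    change <- paste0(.AA3[[aa_wt]], residue, .AA3[[aa_mut]])
    if (aa_wt == aa_mut)
      list(consequence = "synonymous", protein_change = "")
    else if (codon_idx == 0L)
      list(consequence = "start_lost", protein_change = change)
    else if (aa_mut == "*")
      list(consequence = "stop_gained", protein_change = change)
    else if (aa_wt == "*")
      list(consequence = "stop_lost", protein_change = change)
    else
      list(consequence = "missense", protein_change = change)
  }

  for (j in seq_along(h_var)) {
    vi <- h_var[j]; ti <- h_tx[j]
    cl <- classify(vi, ti)
    r <- r + 1L
    rows[[r]] <- data.frame(
      variant_id = keys[vi], chrom = variants$chrom[vi],
      pos = variants$pos[vi], ref = variants$ref[vi], alt = variants$alt[vi],
      gene_id = tx$gene_id[ti], transcript_id = tx$transcript_id[ti],
      consequence = cl$consequence,
      impact = .CONSEQUENCE_IMPACT[[cl$consequence]],
      protein_change = cl$protein_change, stringsAsFactors = FALSE)
  }
  hit_vars <- unique(h_var)
  for (vi in setdiff(seq_len(n), hit_vars)) {
    r <- r + 1L
    rows[[r]] <- data.frame(
      variant_id = keys[vi], chrom = variants$chrom[vi],
      pos = variants$pos[vi], ref = variants$ref[vi], alt = variants$alt[vi],
      gene_id = NA_character_, transcript_id = NA_character_,
      consequence = "intergenic", impact = "MODIFIER",
      protein_change = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(r)])
  if (is.null(out))
    out <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene_id = character(), transcript_id = character(),
                      consequence = character(), impact = character(),
                      protein_change = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Most severe impact per gene
#'
#' Aggregates annotated effects to one impact tier per gene: the most severe
#' impact over all of the gene's variants and transcripts
#' (HIGH > MODERATE > LOW > MODIFIER). Intergenic effects carry no gene and
#' are ignored.
#'
#' @param effects Output of [annotate_variants()].
#' @return A `data.frame` with columns `gene_id` and `impact`.
#' @export
gene_max_impact <- function(effects) {
  eff <- effects[!is.na(effects$gene_id), , drop = FALSE]
  if (nrow(eff) == 0)
    return(data.frame(gene_id = character(), impact = character(),
                      stringsAsFactors = FALSE))
  rank <- tapply(.impact_rank(eff$impact), eff$gene_id, max)
  out <- data.frame(gene_id = names(rank),
                    impact = .IMPACT_LEVELS[as.integer(rank)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}
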