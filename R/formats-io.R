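#' Construct a variant table
#'
#' The package-internal representation of biallelic SNP calls: one row per
#' variant with per-allele read depths (the VCF `AD` field). Coordinates are
#' 1-based, as in the VCF standard.
#'
#' @param chrom Chromosome identifiers.
#' @param pos 1-based positions (bp).
#' @param ref,alt Single-base reference and alternate alleles (A/C/G/T).
#' @param ad_ref,ad_alt Reference- and alternate-supporting read counts.
#' @param qual Optional call quality scores (`NA` allowed).
#' @return A `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          ad_ref = integer(), ad_alt = integer(),
                          qual = rep(NA_real_, length(chrom))) {
  vt <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    ad_ref = as.integer(ad_ref), ad_alt = as.integer(ad_alt),
    qual = as.numeric(qual), stringsAsFactors = FALSE
  )
  validate_variant_table(vt)
  class(vt) <- c("variant_table", "data.frame")
  vt
}

validate_variant_table <- function(vt) {
  if (nrow(vt) == 0) return(invisible(vt))
  stopifnot(
    all(vt$pos >= 1), all(vt$ad_ref >= 0), all(vt$ad_alt >= 0),
    all(vt$ref %in% .BASES), all(vt$alt %in% .BASES)
  )
  if (any(vt$ref == vt$alt))
    stop("ref and alt alleles must differ")
  invisible(vt)
}

variant_key <- function(vt) paste(vt$chrom, vt$pos, vt$ref, vt$alt, sep = ":")

#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file and returns one row per biallelic SNP record.
#' Indels, multi-allelic records and records with a missing `AD` value are
#' skipped; the skip counts are reported via `message()` and attached as the
#' `"skipped"` attribute. `AD` is summed across samples when the file holds
#' more than one.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @return A [variant_table()]. Attribute `"skipped"` holds a named vector of
#'   skip counts (`non_snp`, `multiallelic`, `missing_ad`).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (nrow(fix) == 0) {
    out <- variant_table()
    attr(out, "skipped") <- c(non_snp = 0L, multiallelic = 0L, missing_ad = 0L)
    return(out)
  }
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF has no sample columns; FORMAT field AD is required")
  fmt <- strsplit(gt[, 1], ":", fixed = TRUE)
  no_ad <- !vapply(fmt, function(f) "AD" %in% f, logical(1))
  if (any(no_ad)) {
    i <- which(no_ad)[1]
    stop("record ", fix[i, "CHROM"], ":", fix[i, "POS"],
         " has no AD entry in its FORMAT field")
  }

  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  snp <- fix[, "REF"] %in% .BASES & fix[, "ALT"] %in% .BASES
  keep <- !multi & snp

  ad <- vcfR::extract.gt(v, element = "AD")
  ad <- ad[keep, , drop = FALSE]
  fixk <- fix[keep, , drop = FALSE]

  ad_missing <- apply(is.na(ad) | ad == ".", 1, any)
  n_missing <- sum(ad_missing)
  ad <- ad[!ad_missing, , drop = FALSE]
  fixk <- fixk[!ad_missing, , drop = FALSE]

  sum_ad <- function(row, field) {
    sum(vapply(strsplit(row, ",", fixed = TRUE),
               function(x) as.integer(x[field]), integer(1)))
  }
  n <- nrow(fixk)
  ad_ref <- ad_alt <- integer(n)
  for (i in seq_len(n)) {
    ad_ref[i] <- sum_ad(ad[i, ], 1L)
    ad_alt[i] <- sum_ad(ad[i, ], 2L)
  }

  skipped <- c(
    non_snp = sum(!snp & !multi),
    multiallelic = sum(multi),
    missing_ad = n_missing
  )
  if (sum(skipped) > 0)
    message("read_vcf: skipped ", sum(skipped), " record(s) (",
            skipped[["non_snp"]], " non-SNP, ", skipped[["multiallelic"]],
            " multi-allelic, ", skipped[["missing_ad"]], " missing AD)")

  out <- variant_table(
    chrom = fixk[, "CHROM"], pos = as.integer(fixk[, "POS"]),
    ref = fixk[, "REF"], alt = fixk[, "ALT"],
    ad_ref = ad_ref, ad_alt = ad_alt,
    qual = suppressWarnings(as.numeric(fixk[, "QUAL"]))
  )
  attr(out, "skipped") <- skipped
  out
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal single-sample VCF 4.2 file carrying `GT:AD`. The output is
#' deterministic for a given input and round-trips through [read_vcf()]
#' (chrom/pos/alleles/AD/QUAL are preserved exactly).
#'
#' @param variants A [variant_table()].
#' @param path Output path.
#' @param sample_name Name of the single sample column.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_name = "POOL") {
  validate_variant_table(variants)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=oatmap",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants) > 0) {
    gt <- ifelse(variants$ad_ref == 0, "1/1", "0/1")
    qual <- ifelse(is.na(variants$qual), ".", as.character(variants$qual))
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  variants$alt, qual, ".", ".", "GT:AD",
                  paste0(gt, ":", variants$ad_ref, ",", variants$ad_alt),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Gene model container
#'
#' Holds transcript structures parsed from GFF3: per-transcript exon and CDS
#' intervals (1-based inclusive, as in the file) stored in transcription
#' order, i.e. reversed relative to genomic order on the minus strand.
#'
#' @param transcripts `data.frame` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (the transcript span).
#' @param exons,cds `data.frame`s with columns `transcript_id`, `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(transcripts, exons, cds) {
  obj <- list(transcripts = transcripts, exons = exons, cds = cds)
  class(obj) <- "gene_models"
  stopifnot(all(transcripts$strand %in% c("+", "-")))
  obj
}

empty_gene_models <- function() {
  tx <- data.frame(gene_id = character(), transcript_id = character(),
                   chrom = character(), strand = character(),
                   start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  iv <- data.frame(transcript_id = character(), start = integer(),
                   end = integer(), stringsAsFactors = FALSE)
  gene_models(tx, iv, iv)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$transcripts), "transcript(s),",
      nrow(x$cds), "CDS segment(s)\n")
  invisible(x)
}

# transcription-order sort of interval rows for one strand
.tx_order <- function(df, strand) {
  if (strand == "+") df[order(df$start), , drop = FALSE]
  else df[order(-df$start), , drop = FALSE]
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features linked by `ID`/`Parent`. All mRNAs of a
#' gene are retained. Minus-strand exon and CDS segments are stored in
#' transcription order.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gff <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  if (nrow(g) == 0) return(empty_gene_models())
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))
  g$type <- as.character(g$type)
  g$seqid <- as.character(g$seqid)

  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_ids <- mrna$ID
  seg <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  orphan <- seg$type == "CDS" & !(seg$Parent %in% tx_ids)
  if (any(orphan)) {
    i <- which(orphan)[1]
    stop("CDS feature at ", seg$seqid[i], ":", seg$start[i],
         " has no parent mRNA")
  }

  transcripts <- data.frame(
    gene_id = ifelse(is.na(mrna$Parent), mrna$ID, mrna$Parent),
    transcript_id = mrna$ID,
    chrom = mrna$seqid,
    strand = as.character(mrna$strand),
    start = mrna$start, end = mrna$end,
    stringsAsFactors = FALSE
  )

  gather <- function(type) {
    s <- seg[seg$type == type & seg$Parent %in% tx_ids, , drop = FALSE]
    out <- lapply(seq_len(nrow(transcripts)), function(i) {
      rows <- s[s$Parent == transcripts$transcript_id[i], , drop = FALSE]
      if (nrow(rows) == 0) return(NULL)
      df <- data.frame(transcript_id = rows$Parent, start = rows$start,
                       end = rows$end, stringsAsFactors = FALSE)
      .tx_order(df, transcripts$strand[i])
    })
    do.call(rbind, c(out, list(data.frame(transcript_id = character(),
                                          start = integer(), end = integer(),
                                          stringsAsFactors = FALSE))))
  }

  gene_models(transcripts, gather("exon"), gather("CDS"))
}

#' Write gene models to a GFF3 file
#'
#' Deterministic emission of gene/mRNA/exon/CDS features; segments are written
#' in genomic order so that [read_gff()] round-trips the models exactly.
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  tx <- models$transcripts
  for (g in unique(tx$gene_id)) {
    rows <- tx[tx$gene_id == g, , drop = FALSE]
    lines <- c(lines, paste(rows$chrom[1], "oatmap", "gene",
                            min(rows$start), max(rows$end), ".",
                            rows$strand[1], ".", paste0("ID=", g), sep = "\t"))
    for (i in seq_len(nrow(rows))) {
      t_id <- rows$transcript_id[i]
      lines <- c(lines, paste(rows$chrom[i], "oatmap", "mRNA", rows$start[i],
                              rows$end[i], ".", rows$strand[i], ".",
                              paste0("ID=", t_id, ";Parent=", g), sep = "\t"))
      for (type in c("exon", "CDS")) {
        seg <- if (type == "exon") models$exons else models$cds
        seg <- seg[seg$transcript_id == t_id, , drop = FALSE]
        seg <- seg[order(seg$start), , drop = FALSE]
        for (j in seq_len(nrow(seg))) {
          lines <- c(lines, paste(rows$chrom[i], "oatmap", type, seg$start[j],
                                  seg$end[j], ".", rows$strand[i],
                                  if (type == "CDS") "0" else ".",
                                  paste0("ID=", t_id, ".", tolower(type), j,
                                         ";Parent=", t_id), sep = "\t"))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased and validated against the `{A,C,G,T,N}` alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequence contains characters outside {A,C,G,T,N}")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80)
  invisible(path)
}

#' Expression matrix with tissue-group assignments
#'
#' @param tpm Numeric matrix of TPM values, genes in rows, samples in columns.
#' @param groups Named character vector mapping each sample (column) to a
#'   tissue group (e.g. `"seed"`, `"glume"`, `"spikelet"`).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(tpm, groups) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)), !is.null(colnames(tpm)))
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  missing <- setdiff(colnames(tpm), names(groups))
  if (length(missing) > 0)
    stop("sample(s) without a tissue group: ", paste(missing, collapse = ", "))
  obj <- list(tpm = tpm, groups = groups[colnames(tpm)])
  class(obj) <- "expression_matrix"
  obj
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$tpm), "gene(s) x", ncol(x$tpm),
      "sample(s);", "groups:",
      paste(names(table(x$groups)), table(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Read a TPM expression table
#'
#' @param path Tab-delimited file; first column `gene_id`, remaining columns
#'   one sample each.
#' @param group_map Named character vector mapping sample names to tissue
#'   groups; every sample in the file must be present.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, group_map) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, group_map)
}

#' Write an expression matrix to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  df <- data.frame(gene_id = rownames(em$tpm), em$tpm,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an orthogroup membership table
#'
#' @param path Tab-delimited file with columns `orthogroup_id`, `protein_id`,
#'   `species`. Each protein may belong to at most one orthogroup.
#' @return A `data.frame` of class `orthogroup_map`.
#' @export
read_orthogroups <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("orthogroup_id", "protein_id", "species") %in% names(df)))
  if (anyDuplicated(df$protein_id))
    stop("protein listed in more than one orthogroup: ",
         df$protein_id[duplicated(df$protein_id)][1])
  class(df) <- c("orthogroup_map", "data.frame")
  df
}

#' Read a known-gene (foreign seed-shape protein) list
#'
#' @param path Tab-delimited file with at least a `protein_id` column.
#' @return Character vector of protein ids.
#' @export
read_known_genes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot("protein_id" %in% names(df))
  df$protein_id
}
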