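#' Configuration for the synthetic mapping-by-sequencing experiment
#'
#' Defaults describe a desk-scale stand-in for a hexaploid-oat experiment:
#' 3 chromosomes of 5 Mb / 150 cM, 300 genes, 600 EMS mutations (99% canonical
#' C>T / G>A transitions), an F2 population of 150 from which 15
#' phenotype-positive (homozygous mutant) individuals are pooled, and pooled
#' sequencing at a Poisson mean depth of 30x with a per-read allele-flip error
#' of 0.01.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_bp Physical length of each chromosome (bp).
#' @param chrom_cM Genetic length of each chromosome (centiMorgan).
#' @param n_genes Number of simulated genes.
#' @param n_mutations Number of EMS SNPs (one of which is the causal mutation).
#' @param ems_fraction Probability that a mutation is a canonical EMS
#'   transition (C>T or G>A on the reference strand).
#' @param n_f2 Number of F2 individuals simulated.
#' @param pool_size Number of phenotype-positive F2s pooled (default 15).
#' @param mean_depth Poisson mean read depth per site (default 30).
#' @param seq_error Per-read probability that the observed allele is flipped
#'   (ref to alt or vice versa).
#' @param n_background Number of non-causal mutations also present in the
#'   background variant set (shared with sibling lines / parents).
#' @param n_samples Named integer vector of expression samples per tissue
#'   group.
#' @param tpm_meanlog,tpm_sdlog Log-normal parameters of the simulated TPM
#'   values.
#' @param low_expr_fraction Fraction of non-causal genes forced below the
#'   expression threshold in at least one sample.
#' @param n_known Number of foreign "known seed-shape" proteins emitted.
#' @param n_orthogroups Number of orthogroups genes are scattered over.
#' @param seed Random seed used by [simulate_experiment()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 3, chrom_bp = 5e6, chrom_cM = 150,
                       n_genes = 300, n_mutations = 600, ems_fraction = 0.99,
                       n_f2 = 150, pool_size = 15, mean_depth = 30,
                       seq_error = 0.01, n_background = 50,
                       n_samples = c(seed = 3, glume = 7, spikelet = 8),
                       tpm_meanlog = log(10), tpm_sdlog = 1,
                       low_expr_fraction = 0.2,
                       n_known = 10, n_orthogroups = 60, seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_bp = chrom_bp, chrom_cM = chrom_cM,
              n_genes = n_genes, n_mutations = n_mutations,
              ems_fraction = ems_fraction, n_f2 = n_f2, pool_size = pool_size,
              mean_depth = mean_depth, seq_error = seq_error,
              n_background = n_background, n_samples = n_samples,
              tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog,
              low_expr_fraction = low_expr_fraction, n_known = n_known,
              n_orthogroups = n_orthogroups, seed = seed)
  stopifnot(cfg$ems_fraction >= 0, cfg$ems_fraction <= 1, cfg$mean_depth > 0,
            cfg$seq_error >= 0, cfg$seq_error <= 0.5,
            cfg$pool_size >= 1, cfg$n_mutations >= 1,
            cfg$n_background < cfg$n_mutations)
  class(cfg) <- "sim_config"
  cfg
}

.chrom_names <- function(config) paste0("chr", seq_len(config$n_chrom))

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.ALL_CODONS <- apply(expand.grid(.BASES, .BASES, .BASES), 1, paste, collapse = "")
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

revcomp <- function(seq) {
  vapply(seq, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Simulate a reference genome with gene models
#'
#' Chromosomes are uniform random A/C/G/T sequences. Genes (1-3 exons, CDS
#' starting with ATG, internal codons free of stop codons, terminal stop
#' codon, random strand) are placed uniformly without overlap; exon intervals
#' coincide with CDS intervals (no UTRs are simulated).
#'
#' @param config A [sim_config()].
#' @return `list(genome = <named character vector>, models = <gene_models>)`.
#' @export
simulate_genome <- function(config) {
  chroms <- .chrom_names(config)
  base_vecs <- lapply(chroms, function(ch)
    sample(.BASES, config$chrom_bp, replace = TRUE))
  names(base_vecs) <- chroms

  tx_rows <- list(); seg_rows <- list()
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2))
  names(occupied) <- chroms

  for (i in seq_len(config$n_genes)) {
    n_codons <- sample(100:300, 1)          # 300-900 bp CDS incl. start & stop
    cds_seq <- paste0("ATG",
                      paste(sample(.SENSE_CODONS, n_codons - 2, replace = TRUE),
                            collapse = ""),
                      sample(.STOP_CODONS, 1))
    cds_len <- 3 * n_codons
    n_exons <- sample(1:3, 1)
    if (n_exons > 1) {
      cuts <- sort(sample(seq_len(cds_len - 1), n_exons - 1))
      exon_lens <- diff(c(0, cuts, cds_len))
    } else exon_lens <- cds_len
    intron_lens <- if (n_exons > 1) sample(50:200, n_exons - 1, replace = TRUE)
                   else integer(0)
    span <- sum(exon_lens) + sum(intron_lens)
    strand <- sample(c("+", "-"), 1)

    placed <- FALSE
    for (try in 1:200) {
      ch <- sample(chroms, 1)
      start <- sample.int(config$chrom_bp - span - 1, 1)
      occ <- occupied[[ch]]
      if (nrow(occ) == 0 ||
          all(start + span - 1 < occ[, 1] - 1 | start > occ[, 2] + 1)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place gene ", i, " without overlap; reduce n_genes ",
           "or enlarge chrom_bp")
    occupied[[ch]] <- rbind(occupied[[ch]], c(start, start + span - 1))

    # genomic exon intervals
    ex_start <- integer(n_exons); ex_end <- integer(n_exons)
    p <- start
    for (e in seq_len(n_exons)) {
      ex_start[e] <- p
      ex_end[e] <- p + exon_lens[e] - 1
      p <- ex_end[e] + 1 + if (e < n_exons) intron_lens[e] else 0
    }

    # write the CDS (or its reverse complement) across exons in genomic order
    gseq <- if (strand == "+") cds_seq else revcomp(cds_seq)
    gvec <- strsplit(gseq, "")[[1]]
    off <- 0
    for (e in seq_len(n_exons)) {
      len <- exon_lens[e]
      base_vecs[[ch]][ex_start[e]:ex_end[e]] <- gvec[(off + 1):(off + len)]
      off <- off + len
    }

    gene_id <- sprintf("g%04d", i)
    t_id <- paste0(gene_id, ".1")
    tx_rows[[i]] <- data.frame(
      gene_id = gene_id, transcript_id = t_id, chrom = ch, strand = strand,
      start = start, end = start + span - 1, stringsAsFactors = FALSE)
    seg <- data.frame(transcript_id = t_id, start = ex_start, end = ex_end,
                      stringsAsFactors = FALSE)
    seg_rows[[i]] <- .tx_order(seg, strand)
  }

  genome <- vapply(base_vecs, paste, character(1), collapse = "")
  segs <- do.call(rbind, seg_rows)
  models <- gene_models(do.call(rbind, tx_rows), segs, segs)
  list(genome = genome, models = models)
}

#' Simulate EMS mutations and the experiment's truth table
#'
#' Draws `n_mutations` distinct SNPs. With probability `ems_fraction` a
#' mutation is placed on a C or G site and mutated C>T / G>A (the canonical
#' EMS spectrum); otherwise a random site receives a random different base.
#' Exactly one mutation is the designated causal variant, redrawn until it is
#' a missense change inside a CDS. Genetic positions follow a uniform
#' physical-to-genetic map, `cM = pos * chrom_cM / chrom_bp`; the expected
#' pooled allele frequency at each marker is `1 - r` with `r` from the Haldane
#' map function relative to the causal locus (0.5 on unlinked chromosomes).
#'
#' @param genome Named character vector from [simulate_genome()].
#' @param models The matching [gene_models()].
#' @param config A [sim_config()].
#' @return A `data.frame` (class `truth_table`) with columns `chrom`, `pos`,
#'   `ref`, `alt`, `cm`, `is_causal`, `in_background`, `expected_af`;
#'   attributes `causal_gene` and `causal_transcript`.
#' @export
simulate_mutations <- function(genome, models, config) {
  chroms <- names(genome)
  chrom_len <- nchar(genome)

  draw_sites <- function(n, cg_only = FALSE) {
    ch <- sample(chroms, n, replace = TRUE, prob = chrom_len)
    pos <- vapply(ch, function(c) sample.int(chrom_len[[c]], 1), integer(1))
    ref <- substring(genome[ch], pos, pos)
    if (cg_only) {
      bad <- !(ref %in% c("C", "G"))
      while (any(bad)) {
        i <- which(bad)
        pos[i] <- vapply(ch[i], function(c) sample.int(chrom_len[[c]], 1),
                         integer(1))
        ref[i] <- substring(genome[ch[i]], pos[i], pos[i])
        bad <- !(ref %in% c("C", "G"))
      }
    }
    data.frame(chrom = ch, pos = pos, ref = ref, stringsAsFactors = FALSE,
               row.names = NULL)
  }

  n <- config$n_mutations - 1L
  is_ems <- runif(n) < config$ems_fraction
  sites <- draw_sites(n)
  redo <- is_ems & !(sites$ref %in% c("C", "G"))
  if (any(redo)) sites[redo, ] <- draw_sites(sum(redo), cg_only = TRUE)
  alt <- character(n)
  ems_map <- c(C = "T", G = "A")
  alt[is_ems] <- ems_map[sites$ref[is_ems]]
  alt[!is_ems] <- vapply(sites$ref[!is_ems],
                         function(r) sample(setdiff(.BASES, r), 1), character(1))

  # causal: EMS-type missense SNP inside a CDS, redrawn until satisfied
  causal <- NULL
  cds <- models$cds
  tx <- models$transcripts
  causal_ems <- runif(1) < config$ems_fraction
  for (try in 1:1000) {
    k <- sample.int(nrow(cds), 1)
    cpos <- sample(cds$start[k]:cds$end[k], 1)
    row <- tx[tx$transcript_id == cds$transcript_id[k], , drop = FALSE]
    cref <- substring(genome[row$chrom], cpos, cpos)
    if (causal_ems && !(cref %in% c("C", "G"))) next
    calt <- if (causal_ems) ems_map[[cref]]
            else sample(setdiff(.BASES, cref), 1)
    cand <- variant_table(chrom = row$chrom, pos = cpos, ref = cref,
                          alt = calt, ad_ref = 0L, ad_alt = 1L)
    eff <- annotate_variants(cand, models, genome)
    if (any(eff$consequence == "missense")) {
      causal <- list(chrom = row$chrom, pos = cpos, ref = cref, alt = calt,
                     gene = row$gene_id, transcript = row$transcript_id)
      break
    }
  }
  if (is.null(causal))
    stop("could not place a causal missense mutation after 1000 tries")

  truth <- data.frame(
    chrom = c(sites$chrom, causal$chrom),
    pos = c(sites$pos, causal$pos),
    ref = c(sites$ref, causal$ref),
    alt = c(alt, causal$alt),
    is_causal = c(rep(FALSE, n), TRUE),
    stringsAsFactors = FALSE
  )
  # keep positions distinct, preserving the EMS/non-EMS character of each draw;
  # the causal row is never redrawn (colliding non-causal rows are)
  row_ems <- c(is_ems, causal$ref %in% c("C", "G"))
  flag_dups <- function() {
    key <- paste(truth$chrom, truth$pos)
    dup <- duplicated(key)
    crow <- which(truth$is_causal)
    if (dup[crow]) {
      dup[crow] <- FALSE
      dup[which(key == key[crow] & !truth$is_causal)] <- TRUE
    }
    dup
  }
  dup <- flag_dups()
  while (any(dup)) {
    i <- which(dup)
    redraw <- draw_sites(length(i), cg_only = FALSE)
    ems_i <- row_ems[i]
    if (any(ems_i)) redraw[ems_i, ] <- draw_sites(sum(ems_i), cg_only = TRUE)
    truth$chrom[i] <- redraw$chrom
    truth$pos[i] <- redraw$pos
    truth$ref[i] <- redraw$ref
    truth$alt[i] <- ifelse(ems_i, ems_map[redraw$ref],
                           vapply(redraw$ref, function(r)
                             sample(setdiff(.BASES, r), 1), character(1)))
    dup <- flag_dups()
  }

  truth$cm <- truth$pos / config$chrom_bp * config$chrom_cM
  causal_row <- which(truth$is_causal)
  d <- ifelse(truth$chrom == truth$chrom[causal_row],
              abs(truth$cm - truth$cm[causal_row]) / 100, Inf)
  r <- ifelse(is.infinite(d), 0.5, 0.5 * (1 - exp(-2 * d)))
  truth$expected_af <- 1 - r

  truth$in_background <- FALSE
  truth$in_background[sample(which(!truth$is_causal), config$n_background)] <- TRUE

  truth <- truth[order(truth$chrom, truth$pos), ]
  rownames(truth) <- NULL
  truth <- truth[, c("chrom", "pos", "ref", "alt", "cm", "is_causal",
                     "in_background", "expected_af")]
  attr(truth, "causal_gene") <- causal$gene
  attr(truth, "causal_transcript") <- causal$transcript
  class(truth) <- c("truth_table", "data.frame")
  truth
}

# one gamete: mutant-haplotype indicator (0/1) at each marker of one chromosome
.gamete_chrom <- function(cm_sites, chrom_cM) {
  k <- rpois(1, chrom_cM / 100)
  start <- sample(0:1, 1)
  if (k == 0) return(rep(start, length(cm_sites)))
  breaks <- sort(runif(k, 0, chrom_cM))
  (start + findInterval(cm_sites, breaks)) %% 2
}

#' Simulate an F2 population and select the phenotype-positive pool
#'
#' Each F2 individual is the fusion of two independent gametes; each gamete is
#' a crossover mosaic of the two parental haplotypes with a Poisson crossover
#' count per chromosome (`chrom_cM / 100`), uniform breakpoints in genetic
#' position and no interference (Haldane model). An individual shows the
#' recessive phenotype iff it is homozygous for the mutant allele at the
#' causal locus; the first `pool_size` phenotype-positive individuals are
#' pooled.
#'
#' @param truth A truth table from [simulate_mutations()] (only `chrom`, `cm`
#'   and `is_causal` are used).
#' @param config A [sim_config()].
#' @return A list of class `f2_pool`: `genotypes` (mutant-allele counts,
#'   sites x pool members), `pool_af` (pooled mutant allele frequency per
#'   site), `n_f2`, `n_positive`.
#' @export
simulate_f2_pool <- function(truth, config) {
  stopifnot(sum(truth$is_causal) == 1)
  chroms <- unique(truth$chrom)
  idx <- lapply(chroms, function(ch) which(truth$chrom == ch))
  names(idx) <- chroms
  causal_row <- which(truth$is_causal)

  n_sites <- nrow(truth)
  genotypes <- matrix(NA_integer_, nrow = n_sites, ncol = config$pool_size)
  n_positive <- 0L
  n_selected <- 0L
  for (ind in seq_len(config$n_f2)) {
    geno <- integer(n_sites)
    for (ch in chroms) {
      cm <- truth$cm[idx[[ch]]]
      geno[idx[[ch]]] <- .gamete_chrom(cm, config$chrom_cM) +
        .gamete_chrom(cm, config$chrom_cM)
    }
    if (geno[causal_row] == 2L) {
      n_positive <- n_positive + 1L
      if (n_selected < config$pool_size) {
        n_selected <- n_selected + 1L
        genotypes[, n_selected] <- geno
      }
    }
  }
  if (n_selected < config$pool_size)
    stop("only ", n_positive, " phenotype-positive individuals among ",
         config$n_f2, " F2s; increase n_f2 to fill a pool of ",
         config$pool_size)
  out <- list(genotypes = genotypes,
              pool_af = rowSums(genotypes) / (2 * config$pool_size),
              n_f2 = config$n_f2, n_positive = n_positive)
  class(out) <- "f2_pool"
  out
}

#' Sample pooled sequencing reads over the mutation sites
#'
#' Per site, read depth is Poisson(`mean_depth`); each read carries the mutant
#' allele with probability equal to the pooled allele frequency and is flipped
#' to the other allele with probability `seq_error`. Sites may receive zero
#' reads (emitted with `AD 0,0`).
#'
#' @param pool An [simulate_f2_pool()] result.
#' @param truth The matching truth table.
#' @param config A [sim_config()].
#' @return A [variant_table()] in genome order.
#' @export
sample_pool_reads <- function(pool, truth, config) {
  n <- nrow(truth)
  depth <- rpois(n, config$mean_depth)
  f <- pool$pool_af
  p_alt <- f * (1 - config$seq_error) + (1 - f) * config$seq_error
  ad_alt <- rbinom(n, depth, p_alt)
  variant_table(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                alt = truth$alt, ad_ref = depth - ad_alt, ad_alt = ad_alt)
}

#' Emit the side tables of the simulated experiment
#'
#' Generates (i) a TPM expression matrix over the configured tissue-group
#' samples (log-normal noise; the causal gene is forced above 2 TPM in every
#' sample, a configurable fraction of other genes is forced below 0.5 TPM in
#' at least one sample), (ii) an orthogroup table scattering the simulated
#' proteins over orthogroups with the causal gene's orthogroup linked to at
#' least one foreign "known seed-shape" protein, (iii) the known-protein list,
#' and (iv) a background variant table holding the mutations shared with
#' sibling lines / parents.
#'
#' @param models The simulated [gene_models()].
#' @param truth The matching truth table.
#' @param config A [sim_config()].
#' @return `list(expression, orthogroups, known_genes, background, phenotypes)`.
#' @export
emit_side_tables <- function(models, truth, config) {
  genes <- unique(models$transcripts$gene_id)
  causal_gene <- attr(truth, "causal_gene")

  samples <- unlist(lapply(names(config$n_samples), function(g)
    paste0(g, "_", seq_len(config$n_samples[[g]]))))
  groups <- rep(names(config$n_samples), config$n_samples)
  names(groups) <- samples

  tpm <- matrix(rlnorm(length(genes) * length(samples),
                       config$tpm_meanlog, config$tpm_sdlog),
                nrow = length(genes), dimnames = list(genes, samples))
  tpm[causal_gene, ] <- pmax(tpm[causal_gene, ], 2)
  n_low <- floor(config$low_expr_fraction * length(genes))
  low_genes <- sample(setdiff(genes, causal_gene), n_low)
  for (g in low_genes) tpm[g, sample(length(samples), 1)] <- runif(1, 0, 0.4)
  expr <- expression_matrix(round(tpm, 3), groups)

  # orthogroups: oat proteins are <gene_id>.1; most genes assigned at random
  og_ids <- sprintf("OG%04d", seq_len(config$n_orthogroups))
  assigned <- genes[runif(length(genes)) < 0.8]
  if (!causal_gene %in% assigned) assigned <- c(assigned, causal_gene)
  og_of_gene <- sample(og_ids, length(assigned), replace = TRUE)
  names(og_of_gene) <- assigned
  oat <- data.frame(orthogroup_id = og_of_gene,
                    protein_id = paste0(assigned, ".1"),
                    species = "oat", stringsAsFactors = FALSE)

  foreign_species <- c("arabidopsis", "rice", "wheat", "maize")
  known <- sprintf("KSS%02d", seq_len(config$n_known))
  n_in_og <- max(1, floor(0.8 * config$n_known))
  in_og <- known[seq_len(n_in_og)]
  foreign_og <- sample(og_ids, n_in_og, replace = TRUE)
  foreign_og[1] <- og_of_gene[[causal_gene]]  # link causal orthogroup
  foreign <- data.frame(orthogroup_id = foreign_og, protein_id = in_og,
                        species = sample(foreign_species, n_in_og,
                                         replace = TRUE),
                        stringsAsFactors = FALSE)
  orthogroups <- rbind(oat, foreign)
  rownames(orthogroups) <- NULL
  class(orthogroups) <- c("orthogroup_map", "data.frame")

  bg <- truth[truth$in_background, , drop = FALSE]
  background <- variant_table(chrom = bg$chrom, pos = bg$pos, ref = bg$ref,
                              alt = bg$alt, ad_ref = 0L,
                              ad_alt = rep(config$mean_depth, nrow(bg)))

  # two-genotype phenotype table (kernel length, mm)
  phenotypes <- data.frame(
    group = rep(c("wild_type", "mutant"), each = 8),
    kernel_length_mm = round(c(rnorm(8, 13.6, 0.3), rnorm(8, 8.6, 0.4)), 2),
    stringsAsFactors = FALSE
  )

  list(expression = expr, orthogroups = orthogroups,
       known_genes = known, background = background, phenotypes = phenotypes)
}

#' Simulate a complete mapping-by-sequencing experiment
#'
#' Runs [simulate_genome()], [simulate_mutations()], [simulate_f2_pool()],
#' [sample_pool_reads()] and [emit_side_tables()] under `config$seed`, and
#' optionally writes every artifact to `outdir` (reference.fasta, genes.gff3,
#' pool.vcf, background.vcf, expression.tsv, orthogroups.tsv, known_genes.tsv,
#' phenotypes.tsv, truth.tsv). All outputs are byte-identical across runs with
#' the same seed.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (created if missing).
#' @return A list with elements `genome`, `models`, `truth`, `pool`,
#'   `variants`, `expression`, `orthogroups`, `known_genes`, `background`,
#'   `phenotypes`, `config`.
#' @export
simulate_experiment <- function(config = sim_config(), outdir = NULL) {
  set.seed(config$seed)
  gen <- simulate_genome(config)
  truth <- simulate_mutations(gen$genome, gen$models, config)
  pool <- simulate_f2_pool(truth, config)
  variants <- sample_pool_reads(pool, truth, config)
  side <- emit_side_tables(gen$models, truth, config)

  result <- c(list(genome = gen$genome, models = gen$models, truth = truth,
                   pool = pool, variants = variants),
              side, list(config = config))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(gen$genome, file.path(outdir, "reference.fasta"))
    write_gff3(gen$models, file.path(outdir, "genes.gff3"))
    write_vcf(variants, file.path(outdir, "pool.vcf"))
    write_vcf(side$background, file.path(outdir, "background.vcf"),
              sample_name = "BACKGROUND")
    write_expression(side$expression, file.path(outdir, "expression.tsv"))
    write.table(side$orthogroups, file.path(outdir, "orthogroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(protein_id = side$known_genes),
                file.path(outdir, "known_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(side$phenotypes, file.path(outdir, "phenotypes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    tt <- as.data.frame(truth)
    tt$causal_gene <- ifelse(tt$is_causal, attr(truth, "causal_gene"), "")
    write.table(tt, file.path(outdir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
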