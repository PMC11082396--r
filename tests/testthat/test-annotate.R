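# hand-built plus-strand gene: 10 codons at chrA:11-40
#   ATG CCG CAG GCA AAA TTC GGT CTT TCT TAA
#   Met Pro Gln Ala Lys Phe Gly Leu Ser Ter
coding_fixture <- function() {
  cds <- "ATGCCGCAGGCAAAATTCGGTCTTTCTTAA"
  chrA <- paste0(strrep("A", 10), cds, strrep("A", 20))
  tx <- data.frame(gene_id = "gX", transcript_id = "gX.1", chrom = "chrA",
                   strand = "+", start = 11L, end = 40L,
                   stringsAsFactors = FALSE)
  seg <- data.frame(transcript_id = "gX.1", start = 11L, end = 40L,
                    stringsAsFactors = FALSE)
  list(genome = c(chrA = chrA), models = gene_models(tx, seg, seg))
}

one_effect <- function(fx, pos, ref, alt) {
  v <- variant_table(chrom = "chrA", pos = pos, ref = ref, alt = alt,
                     ad_ref = 0L, ad_alt = 20L)
  annotate_variants(v, fx$models, fx$genome)
}

test_that("coding consequences follow the genetic code, with 3-letter notation", {
  fx <- coding_fixture()

  e <- one_effect(fx, 15L, "C", "T")  # CCG -> CTG
  expect_equal(e$consequence, "missense")
  expect_equal(e$impact, "MODERATE")
  expect_equal(e$protein_change, "Pro2Leu")

  e <- one_effect(fx, 17L, "C", "T")  # CAG -> TAG
  expect_equal(e$consequence, "stop_gained")
  expect_equal(e$impact, "HIGH")
  expect_equal(e$protein_change, "Gln3Ter")

  e <- one_effect(fx, 22L, "A", "G")  # GCA -> GCG
  expect_equal(e$consequence, "synonymous")
  expect_equal(e$impact, "LOW")
  expect_equal(e$protein_change, "")

  e <- one_effect(fx, 11L, "A", "G")  # ATG -> GTG
  expect_equal(e$consequence, "start_lost")
  expect_equal(e$impact, "HIGH")
  expect_equal(e$protein_change, "Met1Val")

  e <- one_effect(fx, 38L, "T", "C")  # TAA -> CAA
  expect_equal(e$consequence, "stop_lost")
  expect_equal(e$impact, "HIGH")
  expect_equal(e$protein_change, "Ter10Gln")

  e <- one_effect(fx, 5L, "A", "C")   # outside any gene
  expect_equal(e$consequence, "intergenic")
  expect_equal(e$impact, "MODIFIER")
  expect_true(is.na(e$gene_id))
})

test_that("annotation guards against FASTA/VCF coordinate drift", {
  fx <- coding_fixture()
  v <- variant_table(chrom = "chrA", pos = 15L, ref = "G", alt = "T",
                     ad_ref = 0L, ad_alt = 20L)
  expect_error(annotate_variants(v, fx$models, fx$genome),
               "reference mismatch at chrA:15")
})

# UTR / intron / splice fixture: all-A chromosome, variants A>C
noncoding_fixture <- function() {
  chrB <- strrep("A", 200)
  tx <- data.frame(
    gene_id = c("gU", "gV"), transcript_id = c("gU.1", "gV.1"),
    chrom = "chrB", strand = c("+", "-"),
    start = c(21L, 121L), end = c(100L, 180L), stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("gU.1", "gU.1", "gV.1"),
    start = c(21L, 71L, 121L), end = c(50L, 100L, 180L),
    stringsAsFactors = FALSE)
  cds <- data.frame(
    transcript_id = c("gU.1", "gU.1", "gV.1"),
    start = c(31L, 71L, 141L), end = c(50L, 85L, 160L),
    stringsAsFactors = FALSE)
  list(genome = c(chrB = chrB), models = gene_models(tx, exons, cds))
}

test_that("UTR, intron and splice-site classification", {
  fx <- noncoding_fixture()
  cons_at <- function(pos, gene) {
    v <- variant_table(chrom = "chrB", pos = pos, ref = "A", alt = "C",
                       ad_ref = 0L, ad_alt = 20L)
    e <- annotate_variants(v, fx$models, fx$genome)
    e$consequence[e$gene_id == gene]
  }
  expect_equal(cons_at(25L, "gU"), "five_prime_UTR")   # exon, before CDS, +
  expect_equal(cons_at(95L, "gU"), "three_prime_UTR")  # exon, after CDS, +
  expect_equal(cons_at(55L, "gU"), "intron")           # 5 bp into the intron
  expect_equal(cons_at(51L, "gU"), "splice_site")      # 1 bp past exon 1
  expect_equal(cons_at(70L, "gU"), "splice_site")      # 1 bp before exon 2
  expect_equal(cons_at(53L, "gU"), "intron")           # 3 bp: outside window
  # minus strand: high coordinates are 5'
  expect_equal(cons_at(170L, "gV"), "five_prime_UTR")
  expect_equal(cons_at(130L, "gV"), "three_prime_UTR")
})

test_that("consequences agree with the whole-CDS translation oracle", {
  set.seed(31)
  cfg <- sim_config(n_chrom = 1, chrom_bp = 2e5, chrom_cM = 50, n_genes = 25,
                    n_mutations = 10, n_background = 2, seed = 31)
  gen <- simulate_genome(cfg)
  models <- gen$models
  expect_setequal(unique(models$transcripts$strand), c("+", "-"))

  # enumerate CDS sites with their transcript
  sites <- do.call(rbind, lapply(seq_len(nrow(models$cds)), function(k) {
    t_id <- models$cds$transcript_id[k]
    data.frame(transcript_id = t_id,
               chrom = models$transcripts$chrom[
                 models$transcripts$transcript_id == t_id],
               pos = seq(models$cds$start[k], models$cds$end[k]),
               stringsAsFactors = FALSE)
  }))
  picks <- sites[sample(nrow(sites), 200), ]
  for (i in seq_len(nrow(picks))) {
    pos <- picks$pos[i]; chrom <- picks$chrom[i]
    ref <- substr(gen$genome[[chrom]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- variant_table(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       ad_ref = 0L, ad_alt = 20L)
    eff <- annotate_variants(v, models, gen$genome)
    eff <- eff[!is.na(eff$transcript_id) &
                 eff$transcript_id == picks$transcript_id[i], ]
    orc <- oracle_effect(gen$genome, models, picks$transcript_id[i],
                         chrom, pos, ref, alt)
    expect_equal(eff$consequence, orc$consequence,
                 label = paste(chrom, pos, ref, alt))
    if (!is.na(orc$residue) && eff$protein_change != "") {
      res <- as.integer(gsub("[^0-9]", "", eff$protein_change))
      expect_equal(res, orc$residue)
    }
  }
})

test_that("annotation is symmetric under reverse-complementing the genome", {
  fx <- coding_fixture()
  L <- nchar(fx$genome[["chrA"]])
  rc <- oatmap:::revcomp(fx$genome[["chrA"]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  tx <- fx$models$transcripts
  tx$strand <- "-"
  tx2 <- transform(tx, start = L - end + 1L, end = L - start + 1L)
  seg <- fx$models$cds
  seg2 <- transform(seg, start = L - end + 1L, end = L - start + 1L)
  mirror <- gene_models(tx2[, names(tx)], seg2[, names(seg)],
                        seg2[, names(seg)])
  for (case in list(c(15L, "C", "T"), c(17L, "C", "T"), c(22L, "A", "G"),
                    c(11L, "A", "G"))) {
    pos <- as.integer(case[1])
    e1 <- one_effect(fx, pos, case[2], case[3])
    v2 <- variant_table(chrom = "chrA", pos = L - pos + 1L,
                        ref = comp[[case[2]]], alt = comp[[case[3]]],
                        ad_ref = 0L, ad_alt = 20L)
    e2 <- annotate_variants(v2, mirror, c(chrA = rc))
    expect_equal(e2$consequence, e1$consequence)
    expect_equal(e2$protein_change, e1$protein_change)
  }
})

test_that("gene_max_impact takes the most severe impact per gene", {
  eff <- data.frame(
    gene_id = c("g1", "g1", "g2", NA, "g3"),
    impact = c("LOW", "MODERATE", "HIGH", "MODIFIER", "MODIFIER"),
    stringsAsFactors = FALSE)
  out <- gene_max_impact(eff)
  expect_equal(out$gene_id, c("g1", "g2", "g3"))
  expect_equal(out$impact, c("MODERATE", "HIGH", "MODIFIER"))
  empty <- gene_max_impact(eff[0, ])
  expect_equal(nrow(empty), 0)
})
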