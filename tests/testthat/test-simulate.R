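test_that("simulate_genome honours size contracts and CDS construction", {
  set.seed(11)
  cfg <- sim_config(n_chrom = 1, chrom_bp = 1e4, chrom_cM = 50, n_genes = 3,
                    n_mutations = 10, n_background = 2, seed = 11)
  gen <- simulate_genome(cfg)
  expect_equal(nchar(gen$genome[["chr1"]]), 10000L)
  expect_equal(nrow(gen$models$transcripts), 3)
  for (t_id in gen$models$transcripts$transcript_id) {
    cds <- oatmap:::.cds_sequence(gen$models, t_id, gen$genome)
    expect_equal(nchar(cds) %% 3, 0)
    prot <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substr(prot, 1, 1), "M")
    # exactly one stop codon, at the end
    expect_equal(gregexpr("\\*", prot)[[1]], nchar(prot),
                 ignore_attr = TRUE)
  }
})

test_that("the simulator is fully deterministic under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_experiment(tiny_sim_config(seed = 7), outdir = d1)
  simulate_experiment(tiny_sim_config(seed = 7), outdir = d2)
  files <- list.files(d1)
  expect_true(length(files) >= 8)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("ems_fraction = 1 yields only C>T / G>A transitions", {
  set.seed(5)
  cfg <- tiny_sim_config(seed = 5, ems_fraction = 1)
  gen <- simulate_genome(cfg)
  truth <- simulate_mutations(gen$genome, gen$models, cfg)
  expect_true(all((truth$ref == "C" & truth$alt == "T") |
                    (truth$ref == "G" & truth$alt == "A")))
})

test_that("the designated causal mutation is a CDS missense change", {
  sim <- shared_sim()
  causal <- sim$truth[sim$truth$is_causal, ]
  expect_equal(nrow(causal), 1)
  expect_equal(causal$expected_af, 1.0)
  expect_true(all(sim$truth$expected_af >= 0.5 & sim$truth$expected_af <= 1))
  cv <- variant_table(chrom = causal$chrom, pos = causal$pos,
                      ref = causal$ref, alt = causal$alt,
                      ad_ref = 0L, ad_alt = 30L)
  eff <- annotate_variants(cv, sim$models, sim$genome)
  hit <- eff[!is.na(eff$gene_id) & eff$gene_id == attr(sim$truth, "causal_gene"), ]
  expect_true("missense" %in% hit$consequence)
})

test_that("F2 phenotype segregation follows the 1:3 recessive expectation", {
  set.seed(21)
  truth <- manual_truth("chr1", cm = c(10, 50), is_causal = c(TRUE, FALSE))
  cfg <- sim_config(n_chrom = 1, chrom_cM = 100, n_f2 = 2000, pool_size = 15,
                    n_mutations = 2, n_background = 0, seed = 21)
  pool <- simulate_f2_pool(truth, cfg)
  frac <- pool$n_positive / pool$n_f2
  tol <- 3 * sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(frac - 0.25), tol)
})

test_that("a fully linked marker is fixed in the pool", {
  set.seed(22)
  truth <- manual_truth("chr1", cm = c(30, 30), is_causal = c(TRUE, FALSE))
  cfg <- sim_config(n_chrom = 1, chrom_cM = 80, n_f2 = 100, pool_size = 10,
                    n_mutations = 2, n_background = 0, seed = 22)
  pool <- simulate_f2_pool(truth, cfg)
  expect_equal(sum(pool$genotypes[2, ]), 2 * cfg$pool_size)
  expect_equal(pool$pool_af, c(1, 1))
})

test_that("mean pooled AF at 0.1 Morgan matches the Haldane expectation", {
  set.seed(23)
  # r = 0.5 (1 - e^{-0.2}) = 0.0906; expected AF 0.9094
  truth <- manual_truth("chr1", cm = c(20, 30), is_causal = c(TRUE, FALSE))
  cfg <- sim_config(n_chrom = 1, chrom_cM = 100, n_f2 = 130, pool_size = 15,
                    n_mutations = 2, n_background = 0, seed = 23)
  afs <- replicate(150, simulate_f2_pool(truth, cfg)$pool_af[2])
  expected <- 1 - 0.5 * (1 - exp(-2 * 0.1))
  se <- sd(afs) / sqrt(length(afs))
  expect_lt(abs(mean(afs) - expected), 3 * se)
})

test_that("pooled AF on unlinked chromosomes is centred on 0.5", {
  set.seed(24)
  # sites within one pool are linked, so the sampling unit is the pool:
  # compare the mean of replicate per-pool means against 0.5
  truth <- manual_truth(c("chr1", rep("chr2", 600)),
                        cm = c(10, runif(600, 0, 100)),
                        is_causal = c(TRUE, rep(FALSE, 600)))
  cfg <- sim_config(n_chrom = 2, chrom_cM = 100, n_f2 = 130, pool_size = 15,
                    n_mutations = 601, n_background = 0, seed = 24)
  pool_means <- replicate(25, mean(simulate_f2_pool(truth, cfg)$pool_af[-1]))
  se <- sd(pool_means) / sqrt(length(pool_means))
  expect_lt(abs(mean(pool_means) - 0.5), 3 * se)
})

test_that("mean pooled AF decays monotonically with genetic distance", {
  set.seed(25)
  dists <- c(0, 5, 10, 20, 40)  # cM from the causal locus
  truth <- manual_truth("chr1", cm = c(50, 50 + dists),
                        is_causal = c(TRUE, rep(FALSE, length(dists))))
  cfg <- sim_config(n_chrom = 1, chrom_cM = 120, n_f2 = 130, pool_size = 15,
                    n_mutations = 6, n_background = 0, seed = 25)
  afs <- rowMeans(replicate(80, simulate_f2_pool(truth, cfg)$pool_af[-1]))
  expect_true(all(diff(afs) <= 0))
})

test_that("simulate_f2_pool errors when the pool cannot be filled", {
  set.seed(26)
  truth <- manual_truth("chr1", cm = 10, is_causal = TRUE)
  cfg <- sim_config(n_chrom = 1, n_f2 = 4, pool_size = 10,
                    n_mutations = 1, n_background = 0, seed = 26)
  expect_error(simulate_f2_pool(truth, cfg), "increase n_f2")
})

test_that("read sampling is error-free and unbiased where it should be", {
  sim <- shared_sim()  # seq_error = 0
  causal_i <- which(sim$truth$is_causal)
  expect_equal(sim$pool$pool_af[causal_i], 1.0)
  expect_equal(sim$variants$ad_ref[causal_i], 0L)

  set.seed(27)
  cfg <- tiny_sim_config(seed = 27)
  fake_pool <- structure(list(pool_af = rep(0.5, 1000)), class = "f2_pool")
  fake_truth <- manual_truth("chr1", cm = seq_len(1000) / 100,
                             is_causal = c(TRUE, rep(FALSE, 999)))
  reads <- sample_pool_reads(fake_pool, fake_truth, cfg)
  total <- reads$ad_ref + reads$ad_alt
  af <- reads$ad_alt[total > 0] / total[total > 0]
  se <- sd(af) / sqrt(length(af))
  expect_lt(abs(mean(af) - 0.5), 3 * se)
})

test_that("side tables honour their construction contracts", {
  sim <- shared_sim()
  causal_gene <- attr(sim$truth, "causal_gene")
  # expression: causal gene above threshold everywhere; default group sizes
  expect_true(all(sim$expression$tpm[causal_gene, ] > 0.5))
  expect_equal(unname(table(sim$expression$groups)[c("seed", "glume",
                                                     "spikelet")]),
               c(3L, 7L, 8L), ignore_attr = TRUE)
  # background variants are a subset of the pool variant sites
  bg_keys <- paste(sim$background$chrom, sim$background$pos)
  pool_keys <- paste(sim$variants$chrom, sim$variants$pos)
  expect_equal(length(bg_keys), sim$config$n_background)
  expect_true(all(bg_keys %in% pool_keys))
  # the causal gene's orthogroup contains a foreign known seed-shape protein
  og <- sim$orthogroups
  causal_og <- og$orthogroup_id[og$protein_id == paste0(causal_gene, ".1")]
  expect_length(causal_og, 1)
  members <- og[og$orthogroup_id == causal_og, ]
  expect_true(any(members$protein_id %in% sim$known_genes))
})
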