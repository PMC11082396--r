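# small-scale simulator configuration for fast tests
tiny_sim_config <- function(seed = 42, ...) {
  sim_config(n_chrom = 2, chrom_bp = 3e5, chrom_cM = 100, n_genes = 30,
             n_mutations = 80, n_f2 = 120, pool_size = 10, n_background = 10,
             seq_error = 0, n_known = 5, n_orthogroups = 15, seed = seed, ...)
}

# one shared tiny simulation, built once per test run
.shared_sim_env <- new.env()
shared_sim <- function() {
  if (is.null(.shared_sim_env$sim))
    .shared_sim_env$sim <- simulate_experiment(tiny_sim_config())
  .shared_sim_env$sim
}

# a minimal truth table for driving simulate_f2_pool directly
manual_truth <- function(chrom, cm, is_causal) {
  tt <- data.frame(chrom = chrom, pos = seq_along(cm) * 1000L,
                   ref = "C", alt = "T", cm = cm, is_causal = is_causal,
                   in_background = FALSE, expected_af = NA_real_,
                   stringsAsFactors = FALSE)
  class(tt) <- c("truth_table", "data.frame")
  tt
}

# independent brute-force effect oracle: mutate the chromosome, re-extract the
# spliced CDS with Biostrings, translate whole proteins, compare
oracle_effect <- function(genome, models, transcript_id, chrom, pos, ref, alt) {
  tx <- models$transcripts[models$transcripts$transcript_id == transcript_id, ]
  seg <- models$cds[models$cds$transcript_id == transcript_id, , drop = FALSE]
  seg <- seg[order(seg$start), , drop = FALSE]
  spliced <- function(seq_str) {
    s <- paste(substring(seq_str, seg$start, seg$end), collapse = "")
    d <- Biostrings::DNAString(s)
    if (tx$strand == "-") d <- Biostrings::reverseComplement(d)
    d
  }
  chr_wt <- genome[[chrom]]
  stopifnot(substr(chr_wt, pos, pos) == ref)
  chr_mut <- chr_wt
  substr(chr_mut, pos, pos) <- alt
  pwt <- strsplit(as.character(Biostrings::translate(spliced(chr_wt),
                                                     no.init.codon = TRUE)),
                  "")[[1]]
  pmut <- strsplit(as.character(Biostrings::translate(spliced(chr_mut),
                                                      no.init.codon = TRUE)),
                   "")[[1]]
  if (identical(pwt, pmut))
    return(list(consequence = "synonymous", residue = NA_integer_))
  i <- which(pwt != pmut)[1]
  cons <- if (i == 1 && pwt[1] == "M") "start_lost"
          else if (pmut[i] == "*") "stop_gained"
          else if (pwt[i] == "*") "stop_lost"
          else "missense"
  list(consequence = cons, residue = i)
}

# full-enumeration Wilcoxon oracle over all C(n, nx) group assignments
enumerate_wilcoxon_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  s <- sum(r[seq_along(x)])
  sums <- utils::combn(n, length(x), FUN = function(i) sum(r[i]))
  p_le <- mean(sums <= s + 1e-9)
  p_ge <- mean(sums >= s - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random annotated-variant fixture for funnel property tests
random_funnel_fixture <- function(n_genes = 8, n_variants = 20) {
  genes <- paste0("rg", seq_len(n_genes))
  chroms <- sample(c("chrA", "chrB"), n_variants, replace = TRUE)
  pos <- sample.int(1e6, n_variants)
  ref <- sample(c("C", "G"), n_variants, replace = TRUE)
  alt <- ifelse(ref == "C", "T", "A")
  variants <- variant_table(chrom = chroms, pos = pos, ref = ref, alt = alt,
                            ad_ref = sample(0:3, n_variants, replace = TRUE),
                            ad_alt = sample(5:40, n_variants, replace = TRUE))
  cons_pool <- c("missense", "synonymous", "stop_gained", "intron",
                 "five_prime_UTR")
  consequence <- sample(cons_pool, n_variants, replace = TRUE)
  impact_map <- c(missense = "MODERATE", synonymous = "LOW",
                  stop_gained = "HIGH", intron = "MODIFIER",
                  five_prime_UTR = "MODIFIER")
  gene <- sample(genes, n_variants, replace = TRUE)
  effects <- data.frame(
    variant_id = paste(chroms, pos, ref, alt, sep = ":"),
    chrom = chroms, pos = pos, ref = ref, alt = alt,
    gene_id = gene, transcript_id = paste0(gene, ".1"),
    consequence = consequence, impact = unname(impact_map[consequence]),
    protein_change = ifelse(consequence %in% c("missense", "stop_gained"),
                            "Ala1Val", ""),
    stringsAsFactors = FALSE)
  samples <- c("seed_1", "glume_1", "spikelet_1")
  groups <- stats::setNames(c("seed", "glume", "spikelet"), samples)
  tpm <- matrix(stats::runif(n_genes * 3, 0, 10), nrow = n_genes,
                dimnames = list(genes, samples))
  # some genes dip below threshold somewhere
  for (g in sample(genes, ceiling(n_genes / 3)))
    tpm[g, sample(3, 1)] <- stats::runif(1, 0, 0.4)
  list(variants = variants, effects = effects,
       expression = expression_matrix(tpm, groups),
       config = funnel_config(target_chrom = "chrA"))
}
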