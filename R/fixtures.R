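#' A small worked funnel example
#'
#' A hand-constructed 10-variant / 6-gene dataset illustrating every branch of
#' the filtering funnel: genes failing on impact, location, read support and
#' expression, a gene whose two variants each satisfy only part of the
#' i-iii conjunction (and which therefore does not qualify), and one true
#' candidate. Useful for demonstrations and as a fixed regression fixture.
#'
#' @return A list with `variants` (a [variant_table()]), `effects` (as from
#'   [annotate_variants()]), `expression` (an [expression_matrix()]) and
#'   `config` (a [funnel_config()] targeting `chr1`).
#' @examples
#' demo <- funnel_demo()
#' apply_funnel(demo$variants, demo$effects, demo$expression, demo$config)
#' @export
funnel_demo <- function() {
  variants <- variant_table(
    chrom = c("chr1", "chr1", "chr2", "chr1", "chr1",
              "chr1", "chr1", "chr1", "chr2", "chr1"),
    pos = c(1000L, 2000L, 3000L, 4000L, 5000L,
            6000L, 7000L, 1500L, 3500L, 4500L),
    ref = c("C", "G", "C", "C", "G", "C", "G", "C", "G", "C"),
    alt = c("T", "A", "T", "T", "A", "T", "A", "T", "A", "T"),
    ad_ref = c(0L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),
    ad_alt = c(20L, 30L, 25L, 20L, 10L, 18L, 50L, 22L, 40L, 16L)
  )
  eff_row <- function(i, gene, consequence, change = "") {
    data.frame(
      variant_id = variant_key(variants[i, ]), chrom = variants$chrom[i],
      pos = variants$pos[i], ref = variants$ref[i], alt = variants$alt[i],
      gene_id = gene, transcript_id = if (is.na(gene)) NA_character_
                                      else paste0(gene, ".1"),
      consequence = consequence,
      impact = .CONSEQUENCE_IMPACT[[consequence]],
      protein_change = change, stringsAsFactors = FALSE)
  }
  effects <- rbind(
    eff_row(1, "g1", "missense", "Pro10Leu"),     # full pass -> candidate
    eff_row(2, "g2", "synonymous"),               # fails i
    eff_row(3, "g3", "missense", "Ala5Val"),      # fails ii (chr2)
    eff_row(4, "g4", "stop_gained", "Gln7Ter"),   # fails iii (2 ref reads)
    eff_row(5, "g5", "missense", "Gly3Asp"),      # fails iii (alt depth 10)
    eff_row(6, "g6", "missense", "Ser9Phe"),      # fails iv (expression)
    eff_row(7, NA_character_, "intergenic"),
    eff_row(8, "g1", "intron"),
    eff_row(9, "g3", "missense", "Arg8His"),      # still chr2
    eff_row(10, "g4", "intron")                   # half-qualifier for g4
  )
  samples <- c("seed_1", "seed_2", "glume_1", "glume_2",
               "spikelet_1", "spikelet_2")
  groups <- setNames(rep(c("seed", "glume", "spikelet"), each = 2), samples)
  tpm <- matrix(5, nrow = 6, ncol = length(samples),
                dimnames = list(paste0("g", 1:6), samples))
  tpm["g6", "seed_2"] <- 0.2
  expression <- expression_matrix(tpm, groups)
  list(variants = variants, effects = effects, expression = expression,
       config = funnel_config(target_chrom = "chr1"))
}
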