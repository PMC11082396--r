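#' Configuration of the candidate-gene filtering funnel
#'
#' Defaults reproduce the classic pooled-F2 filtering recipe: a qualifying
#' variant must have moderate-or-high functional impact, lie on the mapped
#' chromosome (or inside a called region), carry at least 15
#' alternate-supporting reads with no reference-supporting reads, and sit in a
#' gene expressed above 0.5 TPM in every seed, glume and spikelet sample.
#'
#' @param min_alt_depth Minimum alternate-allele read depth (step iii).
#' @param max_ref_depth Maximum reference-allele read depth (step iii).
#' @param impact_min Minimum impact tier, `"MODERATE"` or `"HIGH"` (step i).
#' @param tpm_min Expression threshold; a gene must exceed this in every
#'   sample of every required group (step iv, strict inequality).
#' @param required_groups Tissue groups whose samples must all pass `tpm_min`.
#' @param region_mode `"chromosome"` (keep genes whose qualifying variant lies
#'   on `target_chrom`) or `"region"` (inside a called region).
#' @param target_chrom Target chromosome for chromosome mode; if `NULL` it is
#'   taken from the highest-AF called region.
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(min_alt_depth = 15, max_ref_depth = 0,
                          impact_min = "MODERATE", tpm_min = 0.5,
                          required_groups = c("seed", "glume", "spikelet"),
                          region_mode = c("chromosome", "region"),
                          target_chrom = NULL) {
  region_mode <- match.arg(region_mode)
  stopifnot(min_alt_depth >= 0, max_ref_depth >= 0,
            impact_min %in% c("MODERATE", "HIGH"))
  cfg <- list(min_alt_depth = min_alt_depth, max_ref_depth = max_ref_depth,
              impact_min = impact_min, tpm_min = tpm_min,
              required_groups = required_groups, region_mode = region_mode,
              target_chrom = target_chrom)
  class(cfg) <- "funnel_config"
  cfg
}

#' Remove variants present in background variant sets
#'
#' Drops every variant whose `(chrom, pos, ref, alt)` matches a record in any
#' background set — typically variants shared with the parents or with
#' independent sibling lines of the mutagenized population, which cannot be
#' causal.
#'
#' @param variants A [variant_table()].
#' @param background A [variant_table()] or a list of them.
#' @return The filtered [variant_table()].
#' @export
subtract_background <- function(variants, background) {
  if (is.data.frame(background)) background <- list(background)
  bg_keys <- unique(unlist(lapply(background, variant_key)))
  out <- variants[!(variant_key(variants) %in% bg_keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# gene passes the expression filter iff TPM > tpm_min in every sample of
# every required group
.expressed_everywhere <- function(expression, genes, config) {
  req <- config$required_groups
  missing_groups <- setdiff(req, unique(expression$groups))
  if (length(missing_groups) > 0)
    stop("expression matrix has no samples for required group(s): ",
         paste(missing_groups, collapse = ", "))
  cols <- names(expression$groups)[expression$groups %in% req]
  vapply(genes, function(g) {
    if (!g %in% rownames(expression$tpm)) return(FALSE)
    all(expression$tpm[g, cols] > config$tpm_min)
  }, logical(1))
}

#' Apply the four-step candidate-gene filtering funnel
#'
#' Steps, in order: (i) genes with a variant of at least `impact_min` impact;
#' (ii) whose qualifying variant lies on the target chromosome (chromosome
#' mode) or inside a called region (region mode); (iii) whose qualifying
#' variant has `ad_alt >= min_alt_depth` and `ad_ref <= max_ref_depth`;
#' (iv) that are expressed above `tpm_min` in every sample of every required
#' tissue group. A gene qualifies only if a single variant satisfies steps
#' i-iii simultaneously; two variants each satisfying a different subset do
#' not combine. Genes absent from the expression matrix fail step iv.
#'
#' @param variants A [variant_table()] (after background subtraction).
#' @param effects Matching annotation from [annotate_variants()].
#' @param expression An [expression_matrix()].
#' @param config A [funnel_config()].
#' @param regions Regions from [call_regions()]; required in region mode.
#' @param track Window track from [sliding_median()]; in chromosome mode with
#'   no explicit `target_chrom`, the target is the chromosome carrying the
#'   genome-wide maximum window median (falling back to the highest-AF region
#'   when only `regions` is given) — the automated analogue of reading the
#'   elevated chromosome off the allele-frequency plot.
#' @return A list of class `funnel_result`: `counts` (named vector `i`-`iv` of
#'   surviving gene counts), `candidates` (final candidate table with one row
#'   per qualifying variant), `target_chrom`.
#' @export
apply_funnel <- function(variants, effects, expression, config = funnel_config(),
                         regions = NULL, track = NULL) {
  # per variant x gene: best impact across transcripts
  eff <- effects[!is.na(effects$gene_id), , drop = FALSE]
  if (nrow(eff) > 0) {
    key <- paste(eff$variant_id, eff$gene_id, sep = "|")
    best <- tapply(.impact_rank(eff$impact), key, max)
    pick <- !duplicated(key)
    vg <- eff[pick, c("variant_id", "chrom", "pos", "ref", "alt", "gene_id"),
              drop = FALSE]
    vg$impact_rank <- as.integer(best[paste(vg$variant_id, vg$gene_id,
                                            sep = "|")])
    # representative consequence: the one attaining the max impact
    rep_rows <- vapply(which(pick), function(i) {
      k <- key[i]
      cand <- which(key == k)
      cand[which.max(.impact_rank(eff$impact[cand]))]
    }, integer(1))
    vg$consequence <- eff$consequence[rep_rows]
    vg$protein_change <- eff$protein_change[rep_rows]
  } else {
    vg <- data.frame(variant_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     gene_id = character(), impact_rank = integer(),
                     consequence = character(), protein_change = character(),
                     stringsAsFactors = FALSE)
  }

  ad <- data.frame(variant_id = variant_key(variants),
                   ad_ref = variants$ad_ref, ad_alt = variants$ad_alt,
                   stringsAsFactors = FALSE)
  vg <- merge(vg, ad, by = "variant_id", sort = FALSE)

  # step i: impact
  pass_i <- vg$impact_rank >= .impact_rank(config$impact_min)

  # step ii: location
  if (config$region_mode == "region") {
    if (is.null(regions))
      stop("region_mode = \"region\" requires called regions")
    in_region <- function(chrom, pos) {
      any(regions$chrom == chrom & regions$start <= pos & regions$end >= pos)
    }
    pass_ii <- mapply(in_region, vg$chrom, vg$pos)
    target <- NA_character_
  } else {
    target <- config$target_chrom
    if (is.null(target) && !is.null(track) && nrow(track) > 0)
      target <- track$chrom[which.max(track$median_af)]
    if (is.null(target)) {
      if (is.null(regions) || nrow(regions) == 0)
        stop("chromosome mode needs target_chrom, a window track, ",
             "or a non-empty region set")
      target <- regions$chrom[which.max(regions$mean_af)]
    }
    pass_ii <- vg$chrom == target
  }
  if (length(pass_ii) == 0) pass_ii <- logical(0)

  # step iii: read support
  pass_iii <- vg$ad_alt >= config$min_alt_depth &
    vg$ad_ref <= config$max_ref_depth

  genes_at <- function(mask) sort(unique(vg$gene_id[mask]))
  g_i <- genes_at(pass_i)
  g_ii <- genes_at(pass_i & pass_ii)
  g_iii <- genes_at(pass_i & pass_ii & pass_iii)

  # step iv: expression (gene-level)
  expressed <- .expressed_everywhere(expression, g_iii, config)
  g_iv <- g_iii[expressed]

  qual <- vg[pass_i & pass_ii & pass_iii & vg$gene_id %in% g_iv, , drop = FALSE]
  candidates <- data.frame(
    gene_id = qual$gene_id, chrom = qual$chrom, pos = qual$pos,
    ref = qual$ref, alt = qual$alt, consequence = qual$consequence,
    impact = .IMPACT_LEVELS[qual$impact_rank],
    protein_change = qual$protein_change,
    ad_ref = qual$ad_ref, ad_alt = qual$ad_alt, stringsAsFactors = FALSE)
  candidates <- candidates[order(candidates$gene_id, candidates$pos), ,
                           drop = FALSE]
  rownames(candidates) <- NULL

  out <- list(counts = c(i = length(g_i), ii = length(g_ii),
                         iii = length(g_iii), iv = length(g_iv)),
              candidates = candidates, target_chrom = target)
  class(out) <- "funnel_result"
  out
}

#' @export
print.funnel_result <- function(x, ...) {
  cat("funnel_result (genes surviving each step):\n")
  print(x$counts)
  cat("final candidates:", length(unique(x$candidates$gene_id)), "gene(s)\n")
  invisible(x)
}

#' Orthogroup-based screen for known seed-shape gene homologs
#'
#' Maps each queried foreign protein (genes known from other species to affect
#' the trait) to its orthogroup, collects the focal-species members of those
#' orthogroups, and intersects the corresponding genes with the set of genes
#' carrying impactful mutations.
#'
#' @param orthogroups An [read_orthogroups()] table.
#' @param known Character vector of queried foreign protein ids.
#' @param impacted_genes Character vector of gene ids carrying variants of at
#'   least moderate impact (e.g. from [gene_max_impact()]).
#' @param focal_species Species tag of the focal species in the orthogroup
#'   table (default `"oat"`).
#' @param protein_to_gene Function mapping focal protein ids to gene ids
#'   (default strips a trailing `.N` isoform suffix).
#' @return A list of class `screen_result`: `n_known`, `n_with_orthogroup`,
#'   `n_orthogroups`, `n_focal_proteins`, `hits` (genes in both the orthogroup
#'   set and `impacted_genes`).
#' @export
orthogroup_screen <- function(orthogroups, known, impacted_genes,
                              focal_species = "oat",
                              protein_to_gene = function(p)
                                sub("\\.[0-9]+$", "", p)) {
  found <- known[known %in% orthogroups$protein_id]
  ogs <- unique(orthogroups$orthogroup_id[
    orthogroups$protein_id %in% found])
  members <- orthogroups[orthogroups$orthogroup_id %in% ogs &
                           orthogroups$species == focal_species, , drop = FALSE]
  genes <- unique(protein_to_gene(members$protein_id))
  out <- list(n_known = length(known),
              n_with_orthogroup = length(found),
              n_orthogroups = length(ogs),
              n_focal_proteins = nrow(members),
              hits = sort(intersect(genes, impacted_genes)))
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat("orthogroup screen:", x$n_with_orthogroup, "of", x$n_known,
      "queried proteins in", x$n_orthogroups, "orthogroups containing",
      x$n_focal_proteins, "focal-species proteins;",
      length(x$hits), "with impactful mutations\n")
  invisible(x)
}
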