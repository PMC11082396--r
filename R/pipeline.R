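# deterministic per-stage seed derived from the run seed (kept < 2^31)
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) %% 1e6) * 2039 + h)
}

#' Configuration of a full pipeline run
#'
#' @param mode `"synthetic"` (simulate the experiment under `sim`) or
#'   `"real"` (read every input from `paths`). The modes are mutually
#'   exclusive per run.
#' @param outdir Output directory for intermediates and the report.
#' @param seed Global seed; per-stage seeds are derived from it
#'   deterministically so stages are individually rerunnable.
#' @param sim A [sim_config()] (synthetic mode).
#' @param funnel A [funnel_config()].
#' @param window_size,min_total_depth,af_min,min_windows Scan parameters, see
#'   [sliding_median()] and [call_regions()].
#' @param paths Named list of input paths for real mode: `vcf`, `gff`,
#'   `fasta`, `expression`, `orthogroups`, `known_genes`, and optionally
#'   `background` (vector of VCFs), `phenotypes`, plus `group_map` (named
#'   character vector sample -> tissue group).
#' @param segregation Optional list `list(n_mutant=, n_total=)` of observed F2
#'   phenotype counts (real mode); in synthetic mode the simulated counts are
#'   used.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), outdir, seed = 1,
                       sim = sim_config(), funnel = funnel_config(),
                       window_size = 100, min_total_depth = 15,
                       af_min = 0.9, min_windows = 5,
                       paths = list(), segregation = NULL) {
  mode <- match.arg(mode)
  if (mode == "real") {
    needed <- c("vcf", "gff", "fasta", "expression", "orthogroups",
                "known_genes")
    missing <- setdiff(needed, names(paths))
    if (length(missing) > 0)
      stop("real mode needs paths: ", paste(missing, collapse = ", "))
    files <- unlist(paths[setdiff(names(paths), "group_map")])
    absent <- files[!file.exists(files)]
    if (length(absent) > 0)
      stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  cfg <- list(mode = mode, outdir = outdir, seed = seed, sim = sim,
              funnel = funnel, window_size = window_size,
              min_total_depth = min_total_depth, af_min = af_min,
              min_windows = min_windows, paths = paths,
              segregation = segregation)
  class(cfg) <- "run_config"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full mapping-by-sequencing analysis
#'
#' Orchestrates simulate (synthetic mode) / load (real mode), background
#' subtraction, effect annotation, the sliding-window allele-frequency scan
#' with region calling, the candidate filtering funnel, the orthogroup screen
#' and the segregation/phenotype statistics. Every intermediate is persisted
#' under `config$outdir` and a machine-readable JSON report is written to
#' `report.json`. Reruns with the same seed reproduce every output
#' byte-identically (the report's `timestamp` field is the only exception).
#'
#' @param config A [run_config()].
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "synthetic") {
    sim <- config$sim
    sim$seed <- .stage_seed(config$seed, "simulate")
    sim_out <- .stage("simulate", simulate_experiment(sim, outdir = config$outdir))
    genome <- sim_out$genome
    models <- sim_out$models
    variants <- sim_out$variants
    expression <- sim_out$expression
    orthogroups <- sim_out$orthogroups
    known <- sim_out$known_genes
    background <- list(sim_out$background)
    phenotypes <- sim_out$phenotypes
    seg_counts <- list(n_mutant = sim_out$pool$n_positive,
                       n_total = sim_out$pool$n_f2)
    truth <- sim_out$truth
  } else {
    p <- config$paths
    genome <- .stage("load", read_fasta(p$fasta))
    models <- .stage("load", read_gff(p$gff))
    variants <- .stage("load", read_vcf(p$vcf))
    expression <- .stage("load",
                         read_expression(p$expression, p$group_map))
    orthogroups <- .stage("load", read_orthogroups(p$orthogroups))
    known <- .stage("load", read_known_genes(p$known_genes))
    background <- .stage("load", lapply(p$background %||% character(0),
                                        read_vcf))
    phenotypes <- if (!is.null(p$phenotypes))
      .stage("load", read.delim(p$phenotypes, stringsAsFactors = FALSE))
    else NULL
    seg_counts <- config$segregation
    truth <- NULL
  }

  n_before <- nrow(variants)
  variants <- .stage("subtract_background",
                     subtract_background(variants, background))
  n_after <- nrow(variants)

  effects <- .stage("annotate", annotate_variants(variants, models, genome))
  write.table(effects, file.path(config$outdir, "effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  track <- .stage("scan", sliding_median(variants, config$window_size,
                                         config$min_total_depth))
  regions <- .stage("scan", call_regions(track, config$af_min,
                                         config$min_windows))
  write.table(track, file.path(config$outdir, "track.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(regions, file.path(config$outdir, "regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  funnel <- .stage("filter", apply_funnel(variants, effects, expression,
                                          config$funnel, regions, track))
  write.table(funnel$candidates, file.path(config$outdir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  impacted <- gene_max_impact(effects)
  impacted <- impacted$gene_id[.impact_rank(impacted$impact) >=
                                 .impact_rank("MODERATE")]
  screen <- .stage("screen", orthogroup_screen(orthogroups, known, impacted))

  seg <- if (!is.null(seg_counts))
    .stage("stats", segregation_chisq(seg_counts$n_mutant,
                                      seg_counts$n_total))
  else NULL
  pheno_stats <- if (!is.null(phenotypes)) .stage("stats", {
    groups <- split(phenotypes[[2]], phenotypes[[1]])
    summary_table(groups)
  }) else NULL

  if (config$mode == "synthetic") {
    inputs <- file.path(config$outdir,
                        c("reference.fasta", "genes.gff3", "pool.vcf",
                          "background.vcf", "expression.tsv",
                          "orthogroups.tsv", "known_genes.tsv",
                          "phenotypes.tsv", "truth.tsv"))
  } else {
    inputs <- unlist(config$paths[setdiff(names(config$paths), "group_map")],
                     use.names = FALSE)
  }
  inputs <- inputs[file.exists(inputs)]
  hashes <- as.list(tools::md5sum(inputs))
  names(hashes) <- basename(names(hashes))

  report <- list(
    mode = config$mode,
    seed = config$seed,
    variant_counts = list(before_subtraction = n_before,
                          after_subtraction = n_after),
    funnel = list(counts = as.list(funnel$counts),
                  target_chrom = funnel$target_chrom,
                  candidates = funnel$candidates),
    regions = regions,
    screen = screen[c("n_known", "n_with_orthogroup", "n_orthogroups",
                      "n_focal_proteins", "hits")],
    segregation = seg,
    phenotype_stats = pheno_stats,
    causal_gene = if (!is.null(truth)) attr(truth, "causal_gene") else NULL,
    config = list(window_size = config$window_size,
                  min_total_depth = config$min_total_depth,
                  af_min = config$af_min, min_windows = config$min_windows,
                  funnel = unclass(config$funnel)),
    input_md5 = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
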