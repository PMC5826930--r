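#' Simulation configuration
#'
#' Bundles every tunable of the input simulator: genome geometry, EMS
#' mutation load, bulk design (pool size, coverage, linkage window),
#' expression design (genes, replicates, log-scale noise) and GO term
#' structure. Defaults mirror the study design the pipeline is built for:
#' an F2 bulk of 50 selected mutants sequenced to ~27x, 17 independent
#' mutant lines of which 7 are allelic at the causal gene, and a staged
#' pedicellate/sessile spikelet expression profile with 3 replicates.
#'
#' @param seed integer RNG seed; every simulator output is a pure
#'   function of the configuration including this seed.
#' @param n_chromosomes,chromosome_length genome geometry (bp).
#' @param n_genes number of non-overlapping gene models to pack.
#' @param mean_exons_per_gene mean exon count (>= 1).
#' @param gc_fraction background GC content, in (0, 1).
#' @param mutations_per_line Poisson mean of EMS mutations per line.
#' @param n_mutant_lines number of independent mutant lines.
#' @param n_allelic_lines lines carrying a causal-gene allele
#'   (<= n_mutant_lines).
#' @param bulk_size plants pooled in the F2 bulk.
#' @param bulk_coverage mean sequencing depth of the bulk pool.
#' @param line_coverage mean depth of individual-line records.
#' @param linked_window bp around the causal allele treated as fixed
#'   (homozygous) in the phenotype-selected bulk.
#' @param n_bulk_mutations planted size of the bulk pass-filter set
#'   (the causal allele plus intergenic linked sites).
#' @param n_parent_sites parental background SNPs versus the reference.
#' @param decoys_per_filter planted bulk variants violating exactly one
#'   filter predicate, per predicate.
#' @param line_decoys_per_filter same, per individual mutant line.
#' @param n_expressed_genes,n_unexpressed_genes expression matrix rows
#'   above / below the expressed-gene count threshold.
#' @param n_target_genes genes planted with the full target pattern.
#' @param n_replicates replicates per (genotype, stage, tissue).
#' @param noise_sd sd of log2-scale expression noise.
#' @param peak_log2fc planted log2 effect size of the stage-4
#'   pedicellate peak (and of the mutant loss).
#' @param go_enriched data.frame (term_id, n_targets, n_background)
#'   describing terms planted enriched in the target set; NULL for none.
#' @param go_n_null_terms,go_null_size_range unenriched terms drawn
#'   uniformly from the background.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 500000L,
                       n_genes = 120L,
                       mean_exons_per_gene = 3L,
                       gc_fraction = 0.44,
                       mutations_per_line = 25,
                       n_mutant_lines = 17L,
                       n_allelic_lines = 7L,
                       bulk_size = 50L,
                       bulk_coverage = 27,
                       line_coverage = 20,
                       linked_window = 100000L,
                       n_bulk_mutations = 14L,
                       n_parent_sites = 150L,
                       decoys_per_filter = 50L,
                       line_decoys_per_filter = 5L,
                       n_expressed_genes = 4900L,
                       n_unexpressed_genes = 100L,
                       n_target_genes = 167L,
                       n_replicates = 3L,
                       noise_sd = 0.25,
                       peak_log2fc = 4,
                       go_enriched = NULL,
                       go_n_null_terms = 12L,
                       go_null_size_range = c(20L, 200L)) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_genes = as.integer(n_genes),
    mean_exons_per_gene = mean_exons_per_gene,
    gc_fraction = gc_fraction,
    mutations_per_line = mutations_per_line,
    n_mutant_lines = as.integer(n_mutant_lines),
    n_allelic_lines = as.integer(n_allelic_lines),
    bulk_size = as.integer(bulk_size),
    bulk_coverage = bulk_coverage,
    line_coverage = line_coverage,
    linked_window = as.integer(linked_window),
    n_bulk_mutations = as.integer(n_bulk_mutations),
    n_parent_sites = as.integer(n_parent_sites),
    decoys_per_filter = as.integer(decoys_per_filter),
    line_decoys_per_filter = as.integer(line_decoys_per_filter),
    n_expressed_genes = as.integer(n_expressed_genes),
    n_unexpressed_genes = as.integer(n_unexpressed_genes),
    n_target_genes = as.integer(n_target_genes),
    n_replicates = as.integer(n_replicates),
    noise_sd = noise_sd,
    peak_log2fc = peak_log2fc,
    go_enriched = go_enriched,
    go_n_null_terms = as.integer(go_n_null_terms),
    go_null_size_range = as.integer(go_null_size_range)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_chromosomes", "chromosome_length", "n_genes",
              "n_mutant_lines", "n_allelic_lines", "bulk_size",
              "linked_window", "n_bulk_mutations", "n_parent_sites",
              "decoys_per_filter", "line_decoys_per_filter",
              "n_expressed_genes", "n_unexpressed_genes",
              "n_target_genes", "n_replicates")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("sim_config: '", f, "' must be a single non-negative count")
  }
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1)
    stop("sim_config: gc_fraction must lie strictly in (0, 1)")
  if (cfg$n_allelic_lines > cfg$n_mutant_lines)
    stop("sim_config: n_allelic_lines must not exceed n_mutant_lines")
  if (cfg$linked_window > cfg$chromosome_length)
    stop("sim_config: linked_window must not exceed chromosome_length")
  if (cfg$mutations_per_line < 0 || cfg$noise_sd < 0)
    stop("sim_config: rates and noise must be non-negative")
  invisible(cfg)
}

#' Load a shipped default scenario configuration
#'
#' Two scenarios ship with the package, encoding the study-scale truth
#' sizes: `"msd1_bulk"` (genome + 17 mutant lines + 50-plant F2 bulk at
#' ~27x with a 14-variant planted pass set and per-filter decoys) and
#' `"panicle_rnaseq"` (5,000-gene staged PS/SS expression matrix with
#' 167 planted pattern genes and enriched GO terms).
#'
#' @param name scenario name.
#' @param seed RNG seed overriding the file's value.
#' @param overrides named list of further field overrides.
#' @return a `sim_config`.
#' @export
scenario_config <- function(name = c("msd1_bulk", "panicle_rnaseq"),
                            seed = NULL, overrides = list()) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                      package = "panicleBSA", mustWork = TRUE)
  fields <- yaml::read_yaml(path)
  if (!is.null(fields$go_enriched))
    fields$go_enriched <- as.data.frame(fields$go_enriched,
                                        stringsAsFactors = FALSE)
  if (!is.null(seed)) fields$seed <- seed
  for (nm in names(overrides)) fields[[nm]] <- overrides[[nm]]
  do.call(sim_config, fields)
}
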