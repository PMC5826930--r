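#' Run a shipped simulation scenario
#'
#' `run_scenario()` builds every object of a scenario in memory;
#' `simulate_scenario()` additionally writes the standard-format files
#' (FASTA reference, GFF3 gene models, per-sample VCFs, TSV matrices
#' and metadata, TSV GO annotations, JSON truth manifest) to a
#' directory.
#'
#' @param name `"msd1_bulk"` or `"panicle_rnaseq"`, or a full
#'   [sim_config()] passed as `config`.
#' @param seed overrides the scenario seed.
#' @param config optional explicit configuration (then `name` only
#'   selects which generator family runs).
#' @return For `msd1_bulk`: genome, gene models, parent/line/bulk
#'   variant tables and the truth manifest. For `panicle_rnaseq`: the
#'   expression set, GO annotations and truth.
#' @export
run_scenario <- function(name = c("msd1_bulk", "panicle_rnaseq"),
                         seed = NULL, config = NULL) {
  name <- match.arg(name)
  if (is.null(config)) config <- scenario_config(name, seed = seed)
  if (name == "msd1_bulk") {
    sim <- simulate_genome(config)
    ml <- simulate_mutant_lines(sim, config)
    bulk <- simulate_bulk_pool(ml, sim, config)
    truth <- list(scenario = name, seed = config$seed,
                  causal_gene_id = ml$causal_gene_id,
                  alleles = ml$alleles,
                  window = ml$window,
                  lines = ml$truth,
                  bulk = bulk$truth,
                  bulk_expected_pass_n = sum(bulk$truth$expected_to_pass))
    list(config = config, genome = sim$genome, genes = sim$genes,
         parent = ml$parent, lines = ml$lines, bulk = bulk$bulk,
         truth = truth)
  } else {
    expr <- simulate_expression(config)
    go <- simulate_go_annotations(rownames(expr$values),
                                  expr$truth$target_gene_ids, config)
    truth <- list(scenario = name, seed = config$seed,
                  target_gene_ids = expr$truth$target_gene_ids,
                  n_target_genes = length(expr$truth$target_gene_ids),
                  gene_class = as.list(expr$truth$gene_class),
                  go_term_truth = go$truth)
    list(config = config,
         expression = expression_set(expr$values, expr$counts,
                                     expr$samples),
         annotations = go$annotations, truth = truth)
  }
}

#' @rdname run_scenario
#' @param outdir output directory (created if missing).
#' @export
simulate_scenario <- function(name = c("msd1_bulk", "panicle_rnaseq"),
                              seed = NULL, outdir, config = NULL) {
  name <- match.arg(name)
  obj <- run_scenario(name, seed = seed, config = config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (name == "msd1_bulk") {
    contigs <- nchar(obj$genome)
    paths$fasta <- write_fasta(obj$genome,
                               file.path(outdir, "reference.fasta"))
    paths$gff3 <- write_gff3(obj$genes, file.path(outdir, "genes.gff3"))
    paths$parent_vcf <- write_vcf(obj$parent, "parent",
                                  file.path(outdir, "parent.vcf"),
                                  contigs)
    dir.create(file.path(outdir, "lines"), showWarnings = FALSE)
    paths$line_vcfs <- vapply(names(obj$lines), function(id)
      write_vcf(obj$lines[[id]], id,
                file.path(outdir, "lines", paste0(id, ".vcf")),
                contigs), character(1))
    paths$bulk_vcf <- write_vcf(obj$bulk, "bulk",
                                file.path(outdir, "bulk.vcf"), contigs)
  } else {
    paths$values <- write_tsv_matrix(obj$expression$values,
                                     file.path(outdir, "values.tsv"))
    paths$counts <- write_tsv_matrix(obj$expression$counts,
                                     file.path(outdir, "counts.tsv"))
    paths$samples <- write_tsv(obj$expression$samples,
                               file.path(outdir, "samples.tsv"))
    paths$go <- write_tsv(obj$annotations,
                          file.path(outdir, "go_annotations.tsv"))
  }
  paths$truth <- write_truth_manifest(obj$truth,
                                      file.path(outdir, "truth.json"))
  invisible(c(obj, list(paths = paths)))
}
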