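#' Simulate staged pedicellate/sessile spikelet expression profiles
#'
#' Emits an FPKM-like value matrix, a consistent count matrix (a
#' monotone map of the values via per-sample library-size factors) and
#' sample metadata over the design WT/mutant x {S1-whole, S3-whole,
#' S4-PS, S4-SS, S5-PS, S5-SS} x replicates. Target genes are planted
#' to satisfy all three pattern rules in expectation (WT peak at S4-PS;
#' WT S4-PS above S4-SS with a strong loss in the mutant; mutant PS and
#' SS similar at S4); every other gene belongs to a construction class
#' violating at least one rule (flat, peak elsewhere, mutant PS/SS
#' divergence, no WT PS/SS contrast, no mutant loss, or not expressed).
#' Values are lognormal around the class condition means with log2-sd
#' `noise_sd`.
#'
#' @param config a [sim_config()].
#' @return list with `values`, `counts` (gene x sample matrices),
#'   `samples` (metadata data.frame), `truth` (planted target ids and
#'   per-gene class) .
#' @export
simulate_expression <- function(config) {
  validate_sim_config(config)
  if (config$n_replicates < 2L)
    stop("simulate_expression: need at least 2 replicates per condition")
  set.seed(config$seed + 3L)

  conds <- data.frame(
    stage = c("S1", "S3", "S4", "S4", "S5", "S5"),
    tissue = c("whole", "whole", "PS", "SS", "PS", "SS"),
    stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(c("WT", "mutant"), function(gt) {
    do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
      data.frame(genotype = gt, stage = conds$stage[ci],
                 tissue = conds$tissue[ci],
                 replicate = seq_len(config$n_replicates),
                 stringsAsFactors = FALSE)
    }))
  }))
  samples$sample_id <- sprintf("%s_%s_%s_r%d", samples$genotype,
                               samples$stage, samples$tissue,
                               samples$replicate)

  n_expr <- config$n_expressed_genes
  n_tar <- config$n_target_genes
  if (n_tar > n_expr)
    stop("simulate_expression: n_target_genes exceeds n_expressed_genes")
  n_other <- n_expr - n_tar
  other_classes <- c("flat", "peak_elsewhere", "fail_mutant_divergent",
                     "fail_no_wt_contrast", "fail_no_mutant_loss")
  cls <- c(rep("target", n_tar),
           sample(rep(other_classes,
                      times = round_shares(n_other,
                                           c(.6, .15, .1, .075, .075))),
                  n_other),
           rep("unexpressed", config$n_unexpressed_genes))
  n_genes <- length(cls)
  gene_ids <- sprintf("xgene%05d", seq_len(n_genes))
  cls <- stats::setNames(cls, gene_ids)

  base <- stats::runif(n_genes, 4, 7)
  d <- config$peak_log2fc
  key <- paste(samples$genotype, samples$stage, samples$tissue, sep = "_")
  mu <- matrix(rep(base, length(key)), nrow = n_genes)  # log2 means
  colnames(mu) <- samples$sample_id
  bump <- function(class, cond_keys, delta) {
    rows <- cls == class
    cols <- key %in% cond_keys
    mu[rows, cols] <<- mu[rows, cols] + delta
  }
  bump("target", "WT_S4_PS", d)
  bump("peak_elsewhere", c("WT_S3_whole", "mutant_S3_whole"), d)
  bump("fail_mutant_divergent", "WT_S4_PS", d)
  bump("fail_mutant_divergent", "mutant_S4_PS", d / 2)
  bump("fail_no_wt_contrast", c("WT_S4_PS", "WT_S4_SS"), d)
  bump("fail_no_mutant_loss", c("WT_S4_PS", "mutant_S4_PS"), d)
  mu[cls == "unexpressed", ] <- -3

  noise <- matrix(stats::rnorm(n_genes * nrow(samples), 0,
                               config$noise_sd),
                  nrow = n_genes)
  values <- 2 ^ (mu + noise)
  dimnames(values) <- list(gene_ids, samples$sample_id)
  sf <- stats::runif(nrow(samples), 8, 12)
  counts <- round(sweep(values, 2, sf, `*`))
  storage.mode(counts) <- "integer"

  list(values = values, counts = counts,
       samples = samples[, c("sample_id", "genotype", "stage",
                             "tissue", "replicate")],
       truth = list(target_gene_ids = gene_ids[cls == "target"],
                    gene_class = cls,
                    library_factors = stats::setNames(sf,
                                                      samples$sample_id)))
}

round_shares <- function(n, shares) {
  k <- floor(n * shares)
  rem <- n - sum(k)
  if (rem > 0) k[seq_len(rem)] <- k[seq_len(rem)] + 1L
  as.integer(k)
}

#' Simulate gene-to-GO annotations with planted enrichment
#'
#' Null terms annotate uniform random background genes; enriched terms
#' take a configured number of members from the planted target set and
#' the rest from the non-target background.
#'
#' @param gene_ids background gene universe.
#' @param target_gene_ids planted target genes (subset of background).
#' @param config a [sim_config()]; uses `go_enriched`,
#'   `go_n_null_terms`, `go_null_size_range`.
#' @return list with `annotations` (data.frame gene_id, term_id,
#'   description) and `truth` (per-term planted target members).
#' @export
simulate_go_annotations <- function(gene_ids, target_gene_ids, config) {
  set.seed(config$seed + 4L)
  stopifnot(all(target_gene_ids %in% gene_ids))
  rows <- list(); truth <- list()
  enr <- config$go_enriched
  if (!is.null(enr) && nrow(enr) > 0) {
    for (i in seq_len(nrow(enr))) {
      n_t <- enr$n_targets[i]
      n_b <- enr$n_background[i]
      stopifnot(n_t <= n_b, n_t <= length(target_gene_ids))
      members <- c(sample(target_gene_ids, n_t),
                   sample(setdiff(gene_ids, target_gene_ids), n_b - n_t))
      rows[[enr$term_id[i]]] <- data.frame(
        gene_id = members, term_id = enr$term_id[i],
        description = paste("planted enriched term", i),
        stringsAsFactors = FALSE)
      truth[[enr$term_id[i]]] <- members[seq_len(n_t)]
    }
  }
  if (config$go_n_null_terms > 0) {
    for (j in seq_len(config$go_n_null_terms)) {
      sz <- sample(seq(config$go_null_size_range[1],
                       config$go_null_size_range[2]), 1L)
      tid <- sprintf("GO:NULL%04d", j)
      rows[[tid]] <- data.frame(
        gene_id = sample(gene_ids, sz), term_id = tid,
        description = paste("null term", j),
        stringsAsFactors = FALSE)
    }
  }
  ann <- do.call(rbind, c(rows, list(data.frame(
    gene_id = character(0), term_id = character(0),
    description = character(0)))))
  rownames(ann) <- NULL
  list(annotations = ann, truth = truth)
}

#' Simulate an F2 genotype/phenotype co-segregation table
#'
#' Genotypes are drawn 1:2:1 (hom_alt : het : hom_ref); the phenotype
#' is mutant exactly when the genotype is hom_alt (fully penetrant
#' recessive), with an optional phenotype misclassification rate.
#'
#' @param n_plants number of F2 plants.
#' @param config a [sim_config()] (for the seed).
#' @param misclassification probability of flipping a phenotype call.
#' @param force_counts optional c(hom_alt, het, hom_ref) to reproduce a
#'   fixed segregation table instead of a random draw.
#' @return data.frame (plant_id, genotype, phenotype).
#' @export
simulate_f2_cosegregation <- function(n_plants = 48L,
                                      config = sim_config(),
                                      misclassification = 0,
                                      force_counts = NULL) {
  set.seed(config$seed + 5L)
  if (!is.null(force_counts)) {
    stopifnot(length(force_counts) == 3L, sum(force_counts) == n_plants)
    geno <- rep(c("hom_alt", "het", "hom_ref"), times = force_counts)
  } else {
    geno <- sample(c("hom_alt", "het", "hom_ref"), n_plants,
                   replace = TRUE, prob = c(1, 2, 1) / 4)
  }
  pheno <- ifelse(geno == "hom_alt", "mutant", "wild_type")
  if (misclassification > 0) {
    flip <- stats::runif(n_plants) < misclassification
    pheno[flip] <- ifelse(pheno[flip] == "mutant", "wild_type", "mutant")
  }
  data.frame(plant_id = sprintf("plant%03d", seq_len(n_plants)),
             genotype = geno, phenotype = pheno,
             stringsAsFactors = FALSE)
}
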