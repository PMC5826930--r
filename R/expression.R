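#' Expression set container
#'
#' Bundles an FPKM-like value matrix, its companion count matrix and
#' per-sample metadata (genotype, stage, tissue, replicate). Stages S1
#' and S3 are whole-panicle samples; stages S4 and S5 are dissected
#' pedicellate (PS) or sessile (SS) spikelet samples.
#'
#' @param values,counts gene x sample matrices with identical
#'   dimensions and matching dimnames.
#' @param samples data.frame with columns sample_id, genotype
#'   (WT/mutant), stage (S1/S3/S4/S5), tissue (whole/PS/SS),
#'   replicate.
#' @return an `expression_set`.
#' @export
expression_set <- function(values, counts, samples) {
  stopifnot(identical(dim(values), dim(counts)),
            identical(colnames(values), samples$sample_id),
            all(values >= 0), all(counts >= 0))
  structure(list(values = values, counts = counts, samples = samples),
            class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  invisible(x)
}

condition_key <- function(samples) {
  paste(samples$genotype, samples$stage, samples$tissue, sep = "_")
}

subset_samples <- function(es, keep_ids) {
  keep <- es$samples$sample_id %in% keep_ids
  expression_set(es$values[, keep, drop = FALSE],
                 es$counts[, keep, drop = FALSE],
                 es$samples[keep, , drop = FALSE])
}

#' Pattern-classification thresholds
#'
#' @param de_alpha adjusted-p cutoff for differential expression.
#' @param de_lfc minimum |log2 fold change| for a "different" call.
#' @param similar_lfc maximum |log2 fold change| for a "similar" call.
#' @param pseudocount added before log2 transform.
#' @param qc_r2_min replicate QC threshold on squared Pearson r
#'   (strictly below discards).
#' @param min_reads expressed-gene count threshold (at least this many
#'   reads in at least one sample).
#' @return a `pattern_thresholds` list.
#' @export
pattern_thresholds <- function(de_alpha = 0.05, de_lfc = 1.0,
                               similar_lfc = 1.0, pseudocount = 1.0,
                               qc_r2_min = 0.9, min_reads = 5L) {
  stopifnot(de_alpha > 0, de_lfc > 0, similar_lfc > 0,
            pseudocount > 0, qc_r2_min > 0, min_reads > 0,
            similar_lfc <= de_lfc)
  structure(list(de_alpha = de_alpha, de_lfc = de_lfc,
                 similar_lfc = similar_lfc, pseudocount = pseudocount,
                 qc_r2_min = qc_r2_min, min_reads = as.integer(min_reads)),
            class = "pattern_thresholds")
}

#' Replicate quality control by pairwise correlation
#'
#' Within each (genotype, stage, tissue) condition, Pearson
#' correlations between replicate pairs are computed on
#' log2(value + pseudocount); a replicate whose maximum squared
#' correlation against its siblings falls strictly below `qc_r2_min`
#' is discarded. Errors if any condition is left with fewer than two
#' replicates.
#'
#' @param es an [expression_set()].
#' @param qc_r2_min,pseudocount see [pattern_thresholds()].
#' @return list with `kept` (an expression_set), `discarded` (sample
#'   ids) and `condition_correlations` (mean pairwise r of kept
#'   replicates per condition).
#' @export
replicate_qc <- function(es, qc_r2_min = 0.9, pseudocount = 1.0) {
  lv <- log2(es$values + pseudocount)
  key <- condition_key(es$samples)
  discarded <- character(0)
  mean_r <- c()
  for (cond in unique(key)) {
    ids <- es$samples$sample_id[key == cond]
    if (length(ids) < 2L)
      stop("replicate_qc: condition ", cond, " has < 2 replicates")
    cm <- stats::cor(lv[, ids, drop = FALSE])
    diag(cm) <- NA
    max_r2 <- apply(cm^2, 1, max, na.rm = TRUE)
    bad <- ids[max_r2 < qc_r2_min]
    discarded <- c(discarded, bad)
    kept_ids <- setdiff(ids, bad)
    if (length(kept_ids) < 2L)
      stop("replicate_qc: condition ", cond,
           " left with < 2 replicates after QC")
    km <- stats::cor(lv[, kept_ids, drop = FALSE])
    mean_r[cond] <- mean(km[upper.tri(km)])
  }
  kept <- subset_samples(es, setdiff(es$samples$sample_id, discarded))
  list(kept = kept, discarded = discarded,
       condition_correlations = mean_r)
}

#' Expressed-gene filter
#'
#' A gene is kept when its count reaches `min_reads` in at least one
#' sample.
#'
#' @param es an [expression_set()].
#' @param min_reads count threshold (inclusive).
#' @return character vector of kept gene ids.
#' @export
filter_expressed <- function(es, min_reads = 5L) {
  rownames(es$counts)[apply(es$counts, 1, max) >= min_reads]
}

cond_ids <- function(es, cond) {
  key <- condition_key(es$samples)
  want <- paste(cond$genotype, cond$stage, cond$tissue, sep = "_")
  ids <- es$samples$sample_id[key == want]
  if (length(ids) == 0L)
    stop("condition ", want, " missing from the expression set")
  ids
}

#' Per-gene differential expression between two conditions
#'
#' A declared stand-in for a count-model DE engine: a Welch two-sample
#' test on log2(value + pseudocount) across replicates, with
#' Benjamini-Hochberg adjustment across all tested genes for the pair.
#' The log2 fold change is the difference of group means of the
#' transformed values. A gene with zero variance in both groups gets
#' p = 1 when the means agree and p = 0 otherwise.
#'
#' @param es an [expression_set()] (post QC).
#' @param cond_a,cond_b lists with genotype, stage, tissue; fold
#'   changes are a minus b.
#' @param thresholds a [pattern_thresholds()].
#' @param genes genes to test (default all rows).
#' @return data.frame (gene_id, lfc, p, padj, significant).
#' @export
differential_expression <- function(es, cond_a, cond_b,
                                    thresholds = pattern_thresholds(),
                                    genes = rownames(es$values)) {
  ia <- cond_ids(es, cond_a); ib <- cond_ids(es, cond_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("differential_expression: both conditions need >= 2 replicates")
  la <- log2(es$values[genes, ia, drop = FALSE] + thresholds$pseudocount)
  lb <- log2(es$values[genes, ib, drop = FALSE] + thresholds$pseudocount)
  n1 <- ncol(la); n2 <- ncol(lb)
  m1 <- rowMeans(la); m2 <- rowMeans(lb)
  v1 <- apply(la, 1, stats::var); v2 <- apply(lb, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  lfc <- m1 - m2
  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(abs(lfc[degenerate]) == 0, 1, 0)
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = genes, lfc = lfc, p = p, padj = padj,
             significant = padj < thresholds$de_alpha &
               abs(lfc) >= thresholds$de_lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

WT_CONDITIONS <- list(
  list(genotype = "WT", stage = "S1", tissue = "whole"),
  list(genotype = "WT", stage = "S3", tissue = "whole"),
  list(genotype = "WT", stage = "S4", tissue = "PS"),
  list(genotype = "WT", stage = "S4", tissue = "SS"),
  list(genotype = "WT", stage = "S5", tissue = "PS"),
  list(genotype = "WT", stage = "S5", tissue = "SS"))

#' Three-rule candidate-target classification
#'
#' A gene is a candidate regulatory target of the spikelet suppressor
#' when, on condition means of log2(value + pseudocount):
#' \describe{
#'   \item{R1 (peak)}{the WT S4-PS mean is the strict maximum over all
#'     six WT conditions (ties fail);}
#'   \item{R2 (WT contrast + mutant loss)}{WT S4-PS vs WT S4-SS is
#'     significantly different with positive log2 fold change, and
#'     mutant S4-PS vs WT S4-PS is significantly different with
#'     negative log2 fold change;}
#'   \item{R3 (mutant similarity)}{the absolute mean log2 difference
#'     between mutant S4-PS and mutant S4-SS is below `similar_lfc`
#'     and that pair is not significant.}
#' }
#'
#' @param es an [expression_set()] with QC and the expressed-gene
#'   filter already applied.
#' @param thresholds a [pattern_thresholds()].
#' @return list with `candidates` (gene ids) and `rules` (per-gene
#'   logical table R1, R2, R3, candidate).
#' @export
classify_candidate_targets <- function(es,
                                       thresholds = pattern_thresholds()) {
  lv <- log2(es$values + thresholds$pseudocount)
  wt_means <- sapply(WT_CONDITIONS, function(cond)
    rowMeans(lv[, cond_ids(es, cond), drop = FALSE]))
  if (is.null(dim(wt_means)))
    wt_means <- matrix(wt_means, nrow = 1)
  colnames(wt_means) <- vapply(WT_CONDITIONS, function(cond)
    paste(cond$stage, cond$tissue, sep = "_"), character(1))
  peak_col <- which(colnames(wt_means) == "S4_PS")
  r1 <- wt_means[, peak_col] >
    apply(wt_means[, -peak_col, drop = FALSE], 1, max)

  wt_ps <- list(genotype = "WT", stage = "S4", tissue = "PS")
  wt_ss <- list(genotype = "WT", stage = "S4", tissue = "SS")
  mu_ps <- list(genotype = "mutant", stage = "S4", tissue = "PS")
  mu_ss <- list(genotype = "mutant", stage = "S4", tissue = "SS")
  de_wt <- differential_expression(es, wt_ps, wt_ss, thresholds)
  de_loss <- differential_expression(es, mu_ps, wt_ps, thresholds)
  de_mut <- differential_expression(es, mu_ps, mu_ss, thresholds)
  r2 <- de_wt$significant & de_wt$lfc > 0 &
    de_loss$significant & de_loss$lfc < 0
  r3 <- abs(de_mut$lfc) < thresholds$similar_lfc & !de_mut$significant

  rules <- data.frame(gene_id = rownames(lv), R1 = r1, R2 = r2,
                      R3 = r3, candidate = r1 & r2 & r3,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(candidates = rules$gene_id[rules$candidate], rules = rules)
}

#' Full target-nomination pipeline on one expression set
#'
#' Runs replicate QC, the expressed-gene filter and the three-rule
#' classifier with one call.
#'
#' @param es an [expression_set()].
#' @param thresholds a [pattern_thresholds()].
#' @return list with `candidates`, `rules`, `qc` and `expressed`.
#' @export
nominate_targets <- function(es, thresholds = pattern_thresholds()) {
  qc <- replicate_qc(es, thresholds$qc_r2_min, thresholds$pseudocount)
  expressed <- filter_expressed(qc$kept, thresholds$min_reads)
  sub <- qc$kept
  sub$values <- sub$values[expressed, , drop = FALSE]
  sub$counts <- sub$counts[expressed, , drop = FALSE]
  cls <- classify_candidate_targets(sub, thresholds)
  list(candidates = cls$candidates, rules = cls$rules, qc = qc,
       expressed = expressed)
}
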