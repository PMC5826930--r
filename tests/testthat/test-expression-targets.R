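# flat per-gene baselines spread over log2 4..8 so replicate columns
# carry gene-to-gene signal for correlation QC
mk_flat_means <- function(n_genes = 40) {
  conds <- c(all_wt_conditions, all_mu_conditions)
  base <- seq(4, 8, length.out = n_genes)
  matrix(base, n_genes, length(conds),
         dimnames = list(sprintf("g%03d", seq_len(n_genes)), conds))
}

test_that("replicate QC keeps identical replicates and honours the strict boundary", {
  mu <- mk_flat_means(30)
  es <- es_from_means(mu, n_rep = 3, noise_sd = 0)
  qc <- replicate_qc(es, 0.9)
  expect_length(qc$discarded, 0)
  expect_true(all(abs(qc$condition_correlations - 1) < 1e-12))

  # pairs at exactly the threshold r^2 are kept (strictly below
  # discards): set the gate to the weakest observed pair
  es2 <- es_from_means(mu[, c("WT_S1_whole", "WT_S3_whole")],
                       n_rep = 2, noise_sd = 0.6, seed = 5)
  lv <- log2(es2$values + 1)
  key <- paste(es2$samples$genotype, es2$samples$stage,
               es2$samples$tissue, sep = "_")
  r2s <- vapply(unique(key), function(cond) {
    ids <- es2$samples$sample_id[key == cond]
    cor(lv[, ids[1]], lv[, ids[2]])^2
  }, numeric(1))
  qc2 <- replicate_qc(es2, qc_r2_min = min(r2s))
  expect_length(qc2$discarded, 0)

  # a condition reduced below 2 replicates is an error naming it
  es3 <- es_from_means(mu, n_rep = 2, noise_sd = 0.1, seed = 2)
  set.seed(3)
  es3$values[, "WT_S4_PS_r1"] <- 2 ^ rnorm(nrow(es3$values), 5, 2)
  expect_error(replicate_qc(es3, 0.9), "WT_S4_PS")
})

test_that("the expressed-gene filter is an inclusive row-max threshold", {
  counts <- rbind(zero = c(0L, 0L, 0L), boundary = c(0L, 5L, 0L),
                  below = c(4L, 4L, 4L), high = c(100L, 0L, 0L))
  vals <- matrix(1, 4, 3, dimnames = dimnames(counts))
  samples <- data.frame(sample_id = paste0("s", 1:3), genotype = "WT",
                        stage = "S1", tissue = "whole", replicate = 1:3)
  colnames(vals) <- colnames(counts) <- samples$sample_id
  es <- expression_set(vals, counts, samples)
  expect_setequal(filter_expressed(es, 5L), c("boundary", "high"))
  # row-max oracle on a random matrix
  set.seed(9)
  rc <- matrix(rpois(300, 3), 100,
               dimnames = list(sprintf("r%03d", 1:100), paste0("s", 1:3)))
  storage.mode(rc) <- "integer"
  es2 <- expression_set(matrix(1, 100, 3,
                               dimnames = dimnames(rc)), rc, samples)
  expect_setequal(filter_expressed(es2, 5L),
                  rownames(rc)[apply(rc, 1, function(x) max(x) >= 5)])
})

test_that("differential expression flags planted effects, not flat genes", {
  mu <- mk_flat_means(50)
  mu[1:10, "WT_S4_PS"] <- mu[1:10, "WT_S1_whole"] + 2  # planted 4-fold
  es <- es_from_means(mu, n_rep = 3, noise_sd = 0.1, seed = 21)
  wt_ps <- list(genotype = "WT", stage = "S4", tissue = "PS")
  wt_ss <- list(genotype = "WT", stage = "S4", tissue = "SS")
  de <- differential_expression(es, wt_ps, wt_ss)
  expect_true(all(de$significant[1:10]))
  expect_false(any(de$significant[11:50]))
  expect_true(all(de$lfc[1:10] > 1))
  # BH property: adjusted p monotone non-decreasing in raw-p rank
  o <- order(de$p)
  expect_true(all(diff(de$padj[o]) >= -1e-15))
  expect_true(all(de$padj >= de$p))

  # identical groups: no significance; zero-variance convention
  es0 <- es_from_means(mk_flat_means(5), n_rep = 3, noise_sd = 0)
  de0 <- differential_expression(es0, wt_ps, wt_ss)
  expect_true(all(de0$p == 1))
  expect_false(any(de0$significant))
})

test_that("the three rules encode peak, contrast-with-loss and similarity", {
  conds <- c(all_wt_conditions, all_mu_conditions)
  mu <- matrix(6, 6, length(conds),
               dimnames = list(c("target", "flat", "peak_elsewhere",
                                 "no_wt_contrast", "no_loss",
                                 "mut_divergent"), conds))
  mu["target", "WT_S4_PS"] <- 10
  mu["peak_elsewhere", "WT_S3_whole"] <- 10
  mu["no_wt_contrast", c("WT_S4_PS", "WT_S4_SS")] <- 10
  mu["no_loss", c("WT_S4_PS", "mutant_S4_PS")] <- 10
  mu["mut_divergent", "WT_S4_PS"] <- 10
  mu["mut_divergent", "mutant_S4_PS"] <- 8
  es <- es_from_means(mu, n_rep = 3, noise_sd = 0.05, seed = 31)
  cls <- classify_candidate_targets(es)
  expect_identical(cls$candidates, "target")
  rules <- cls$rules
  rownames(rules) <- rules$gene_id
  expect_true(all(unlist(rules["target", c("R1", "R2", "R3")])))
  expect_false(rules["flat", "R1"] && rules["flat", "R2"])
  expect_false(rules["peak_elsewhere", "R1"])
  expect_false(rules["no_wt_contrast", "R2"])
  expect_false(rules["no_loss", "R2"])
  expect_false(rules["mut_divergent", "R3"])
})

test_that("classification is invariant to permutations and positive scaling", {
  cfg <- small_expr_config(seed = 23)
  expr <- simulate_expression(cfg)
  es <- expression_set(expr$values, expr$counts, expr$samples)
  base <- classify_candidate_targets(es)
  # sample-column permutation
  set.seed(2)
  perm <- sample(ncol(es$values))
  es_p <- expression_set(es$values[, perm], es$counts[, perm],
                         es$samples[perm, ])
  expect_setequal(classify_candidate_targets(es_p)$candidates,
                  base$candidates)
  # gene-row permutation
  rperm <- sample(nrow(es$values))
  es_r <- expression_set(es$values[rperm, ], es$counts[rperm, ],
                         es$samples)
  expect_setequal(classify_candidate_targets(es_r)$candidates,
                  base$candidates)
  # positive scaling with a proportionally scaled pseudocount leaves
  # every log-difference, hence every decision, unchanged
  k <- 7.3
  es_s <- expression_set(es$values * k, es$counts, es$samples)
  scaled <- classify_candidate_targets(
    es_s, pattern_thresholds(pseudocount = k))
  expect_identical(scaled$rules[, c("R1", "R2", "R3", "candidate")],
                   base$rules[, c("R1", "R2", "R3", "candidate")])
})

test_that("a missing design condition is a named error", {
  mu <- mk_flat_means(5)
  mu <- mu[, setdiff(colnames(mu), "mutant_S4_SS")]
  es <- es_from_means(mu, n_rep = 3, noise_sd = 0)
  expect_error(classify_candidate_targets(es), "mutant_S4_SS")
})

test_that("a gene losing expression in mutant PS only fails the similarity rule", {
  # the suppressor's own profile: WT peak at S4-PS, reduced in the
  # mutant at S4-PS but not S4-SS -- rules applied uniformly exclude it
  conds <- c(all_wt_conditions, all_mu_conditions)
  mu <- matrix(6, 2, length(conds),
               dimnames = list(c("suppressor", "target"), conds))
  mu["suppressor", "WT_S4_PS"] <- 10
  mu["suppressor", "mutant_S4_PS"] <- 8  # partial loss, above SS level
  mu["target", "WT_S4_PS"] <- 10
  es <- es_from_means(mu, n_rep = 3, noise_sd = 0.05, seed = 41)
  cls <- classify_candidate_targets(es)
  rules <- cls$rules
  rownames(rules) <- rules$gene_id
  expect_true(rules["suppressor", "R1"] && rules["suppressor", "R2"])
  expect_false(rules["suppressor", "R3"])
  expect_identical(cls$candidates, "target")
})
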