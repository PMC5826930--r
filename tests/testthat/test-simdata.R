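test_that("seeded genome simulation is reproducible and degenerate counts work", {
  cfg <- small_variant_config(seed = 3)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes$models, b$genes$models)

  empty <- simulate_genome(small_variant_config(seed = 3, n_genes = 0L))
  expect_equal(length(empty$genes), 0L)
  expect_equal(nchar(empty$genome[[1]]),
               small_variant_config()$chromosome_length)

  expect_error(simulate_genome(small_variant_config(
    n_genes = 2000L)), "packing")
})

test_that("every emitted CDS re-translates cleanly from the FASTA/GFF3 pair", {
  cfg <- sim_config(seed = 5, n_chromosomes = 1L,
                    chromosome_length = 100000L, n_genes = 20L)
  sim <- simulate_genome(cfg)
  d <- withr::local_tempdir()
  write_fasta(sim$genome, file.path(d, "ref.fasta"))
  write_gff3(sim$genes, file.path(d, "genes.gff3"))
  seqs <- Biostrings::readDNAStringSet(file.path(d, "ref.fasta"))
  gff <- read.delim(file.path(d, "genes.gff3"), header = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
  names(gff) <- c("chrom", "src", "type", "start", "end", "score",
                  "strand", "frame", "attr")
  cds_rows <- gff[gff$type == "CDS", ]
  cds_rows$gene <- sub("^Parent=", "", cds_rows$attr)
  for (g in unique(cds_rows$gene)) {
    rows <- cds_rows[cds_rows$gene == g, ]
    rows <- rows[order(rows$start), ]
    seq <- paste0(vapply(seq_len(nrow(rows)), function(i)
      as.character(Biostrings::subseq(seqs[[rows$chrom[i]]],
                                      rows$start[i], rows$end[i])),
      character(1)), collapse = "")
    dna <- Biostrings::DNAString(seq)
    if (rows$strand[1] == "-") dna <- Biostrings::reverseComplement(dna)
    aa <- as.character(Biostrings::translate(dna))
    expect_identical(substr(aa, 1, 1), "M")
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    # no internal stops
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
})

test_that("planted mutations respect the EMS signature and the allelic design", {
  cfg <- small_variant_config(seed = 21)
  sim <- simulate_genome(cfg)
  ml <- simulate_mutant_lines(sim, cfg)
  # exhaustive scan: every truth record tagged canonical is G>A or C>T,
  # and every expected-pass record is canonical (no true transversions)
  for (tr in ml$truth) {
    tagged <- tr[tr$is_canonical_ems, ]
    expect_true(all((tagged$ref == "G" & tagged$alt == "A") |
                      (tagged$ref == "C" & tagged$alt == "T")))
    expect_true(all(tr$is_canonical_ems[tr$expected_to_pass]))
  }
  # allelic lines carry exactly one large-effect allele in the causal
  # gene at distinct positions; non-allelic lines carry none
  causal <- sim$genes$models[[ml$causal_gene_id]]
  in_causal <- function(v) sum(v$chrom == causal$chrom &
                                 v$pos >= causal$start &
                                 v$pos <= causal$end)
  n_lines <- cfg$n_mutant_lines
  hits <- vapply(ml$lines, in_causal, numeric(1))
  expect_equal(unname(hits),
               c(rep(1, cfg$n_allelic_lines),
                 rep(0, n_lines - cfg$n_allelic_lines)))
  expect_equal(anyDuplicated(ml$alleles$pos), 0L)
})

test_that("the study-scale scenario plants seven distinct causal alleles", {
  ml <- run_scenario("msd1_bulk", seed = 2)
  expect_equal(nrow(ml$truth$alleles), 7L)
  expect_equal(anyDuplicated(ml$truth$alleles$pos), 0L)
})

test_that("bulk manifest tags agree with independent per-predicate checks", {
  cfg <- small_variant_config(seed = 8)
  sim <- simulate_genome(cfg)
  ml <- simulate_mutant_lines(sim, cfg)
  bp <- simulate_bulk_pool(ml, sim, cfg)
  tab <- bp$bulk
  tr <- bp$truth
  fc <- filter_config()
  parent_keys <- paste(ml$parent$chrom, ml$parent$pos, ml$parent$ref,
                       ml$parent$alt)
  # brute-force predicate evaluation, written out independently
  p_qual <- tab$quality > 20
  p_hom <- tab$genotype == "hom_alt"
  p_ems <- (tab$ref == "G" & tab$alt == "A") |
    (tab$ref == "C" & tab$alt == "T")
  p_depth <- tab$depth >= 5 & tab$depth <= 100
  p_par <- !(paste(tab$chrom, tab$pos, tab$ref, tab$alt) %in% parent_keys)
  pass <- p_qual & p_hom & p_ems & p_depth & p_par
  expect_identical(unname(pass), unname(tr$expected_to_pass))
  # single-filter decoys fail exactly their tagged predicate
  fails <- cbind(quality = !p_qual, homozygous = !p_hom,
                 canonical_ems = !p_ems, depth = !p_depth,
                 parental = !p_par)
  single <- tr$violated_filter %in% colnames(fails)
  for (i in which(single)) {
    expect_identical(names(which(fails[i, ])), tr$violated_filter[i])
  }
  # schema invariants
  expect_true(all(tab$depth >= 0))
  expect_true(all(tab$genotype %in% c("hom_ref", "het", "hom_alt")))
})

test_that("a linkage window holding only the causal allele yields one pass record", {
  cfg <- small_variant_config(seed = 13, mutations_per_line = 0,
                              n_bulk_mutations = 1L, n_parent_sites = 0L,
                              decoys_per_filter = 0L,
                              line_decoys_per_filter = 0L,
                              n_allelic_lines = 1L, n_mutant_lines = 1L)
  sim <- simulate_genome(cfg)
  ml <- simulate_mutant_lines(sim, cfg)
  bp <- simulate_bulk_pool(ml, sim, cfg)
  expect_equal(nrow(bp$bulk), 1L)
  expect_equal(sum(bp$truth$expected_to_pass), 1L)
  expect_equal(bp$bulk$pos, ml$alleles$pos[1])
  # each line VCF contains only the single causal allele
  expect_equal(nrow(ml$lines[[1]]), 1L)
})

test_that("noiseless expression recovers planted targets exactly", {
  cfg <- small_expr_config(seed = 17, noise_sd = 0)
  expr <- simulate_expression(cfg)
  es <- expression_set(expr$values, expr$counts, expr$samples)
  res <- nominate_targets(es)
  expect_setequal(res$candidates, expr$truth$target_gene_ids)
  expect_length(res$qc$discarded, 0)
})

test_that("a replicate replaced by independent noise is the one flagged by QC", {
  cfg <- small_expr_config(seed = 19)
  expr <- simulate_expression(cfg)
  set.seed(1)
  bad <- "WT_S4_PS_r2"
  expr$values[, bad] <- 2 ^ rnorm(nrow(expr$values), 5, 2)
  es <- expression_set(expr$values, expr$counts, expr$samples)
  qc <- replicate_qc(es, 0.9)
  expect_identical(qc$discarded, bad)
})

test_that("simulated F2 tables segregate as a recessive single locus", {
  forced <- simulate_f2_cosegregation(48L, sim_config(seed = 1),
                                      force_counts = c(10L, 27L, 11L))
  expect_equal(as.vector(table(factor(forced$genotype,
                                      c("hom_alt", "het", "hom_ref")))),
               c(10, 27, 11))
  expect_true(all((forced$genotype == "hom_alt") ==
                    (forced$phenotype == "mutant")))
  # phenotype is a deterministic function of genotype at zero
  # misclassification, any seed
  for (s in 1:5) {
    tab <- simulate_f2_cosegregation(48L, sim_config(seed = s))
    expect_true(all((tab$genotype == "hom_alt") ==
                      (tab$phenotype == "mutant")))
  }
  # binomial expectation: mean hom-alt count over many draws near n/4
  counts <- vapply(1:10000, function(s)
    sum(simulate_f2_cosegregation(48L, sim_config(seed = s))$genotype ==
          "hom_alt"), numeric(1))
  expect_lt(abs(mean(counts) - 12), 0.5)
})

test_that("null GO annotations rarely produce a significant term", {
  genes <- sprintf("g%04d", 1:500)
  cfg <- sim_config(seed = 1, go_enriched = NULL, go_n_null_terms = 10L,
                    go_null_size_range = c(20L, 60L))
  any_hit <- vapply(1:200, function(s) {
    cfg$seed <- s
    ann <- simulate_go_annotations(genes, character(0), cfg)$annotations
    set.seed(s + 10000)
    cand <- sample(genes, 50)
    enr <- go_enrichment(cand, genes, ann, alpha = 0.01)
    any(enr$significant)
  }, logical(1))
  expect_lte(mean(any_hit), 0.05)
})
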