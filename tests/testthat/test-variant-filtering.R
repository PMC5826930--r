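test_that("the EMS signature admits exactly G>A and C>T", {
  expect_true(is_canonical_ems("G", "A"))
  expect_true(is_canonical_ems("C", "T"))
  expect_false(is_canonical_ems("A", "G"))
  # all 12 ordered substitutions: exactly 2 are canonical
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  expect_equal(sum(is_canonical_ems(pairs$ref, pairs$alt)), 2L)
  expect_error(is_canonical_ems("N", "A"), "A, C, G, T")
})

test_that("depth windows are closed intervals per sample class", {
  expect_true(passes_depth(3, "individual_mutant"))
  expect_true(passes_depth(50, "individual_mutant"))
  expect_false(passes_depth(2, "individual_mutant"))
  expect_false(passes_depth(51, "individual_mutant"))
  expect_true(passes_depth(5, "bulk"))
  expect_true(passes_depth(100, "bulk"))
  expect_false(passes_depth(4, "bulk"))
  expect_false(passes_depth(101, "bulk"))
  for (cl in c("parent", "individual_mutant", "bulk"))
    expect_false(passes_depth(0, cl))
  # the parent shares the individual window
  expect_true(passes_depth(3, "parent"))
  expect_false(passes_depth(51, "parent"))
  expect_error(passes_depth(-1, "bulk"), ">= 0")
})

mk_records <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(chrom = "chr01", pos = sample.int(1e5, n),
             ref = sample(c("G", "C"), n, replace = TRUE),
             alt = NA, genotype = "hom_alt",
             depth = sample(5:50, n, replace = TRUE),
             quality = runif(n, 25, 60), stringsAsFactors = FALSE) |>
    transform(alt = ifelse(ref == "G", "A", "T"))
}

test_that("background subtraction joins on the full variant key", {
  v <- mk_records(10)
  expect_identical(subtract_background(v, v[0, ]), v)
  expect_equal(nrow(subtract_background(v, v)), 0L)
  # 3 shared keys out of 10; brute-force pairwise comparison as oracle
  parent <- v[c(2, 5, 9), ]
  out <- subtract_background(v, parent)
  keep_oracle <- vapply(seq_len(nrow(v)), function(i)
    !any(v$chrom[i] == parent$chrom & v$pos[i] == parent$pos &
           v$ref[i] == parent$ref & v$alt[i] == parent$alt),
    logical(1))
  expect_identical(out, v[keep_oracle, ])
  expect_equal(nrow(out), 7L)
  # same position, different allele is NOT subtracted
  p2 <- v[1, ]
  p2$alt <- ifelse(p2$ref == "G", "T", "A")
  expect_equal(nrow(subtract_background(v, p2)), nrow(v))
})

test_that("the filter chain enforces every predicate with a per-filter tally", {
  v <- mk_records(8)
  # boundary: quality exactly at the gate is rejected (strict >)
  v$quality[1] <- 20
  v$genotype[2] <- "het"
  v$ref[3] <- "A"; v$alt[3] <- "T"
  v$depth[4] <- 2
  parent <- v[5, ]
  out <- filter_variants(v, "individual_mutant", filter_config(), parent)
  expect_identical(out$variants, v[c(6, 7, 8), ])
  expect_equal(out$tally[["quality"]], 1L)
  expect_equal(out$tally[["homozygous"]], 1L)
  expect_equal(out$tally[["canonical_ems"]], 1L)
  expect_equal(out$tally[["depth"]], 1L)
  expect_equal(out$tally[["parental"]], 1L)

  empty <- filter_variants(v[0, ], "bulk")
  expect_equal(nrow(empty$variants), 0L)
  expect_true(all(empty$tally == 0L))
})

test_that("filtering is idempotent, subsetting, and order-independent", {
  cfg <- small_variant_config(seed = 31)
  sim <- simulate_genome(cfg)
  ml <- simulate_mutant_lines(sim, cfg)
  bp <- simulate_bulk_pool(ml, sim, cfg)
  out1 <- filter_variants(bp$bulk, "bulk", filter_config(), ml$parent)
  # idempotence
  out2 <- filter_variants(out1$variants, "bulk", filter_config(),
                          ml$parent)
  expect_identical(out2$variants, out1$variants)
  expect_true(all(out2$tally == 0L))
  # subset-ness and per-record predicate re-check
  keys <- paste(bp$bulk$chrom, bp$bulk$pos)
  expect_true(all(paste(out1$variants$chrom, out1$variants$pos) %in% keys))
  with(out1$variants, {
    expect_true(all(quality > 20))
    expect_true(all(genotype == "hom_alt"))
    expect_true(all(is_canonical_ems(ref, alt)))
    expect_true(all(depth >= 5 & depth <= 100))
  })
  # permutation invariance of the surviving set
  set.seed(1)
  perm <- sample(nrow(bp$bulk))
  out3 <- filter_variants(bp$bulk[perm, ], "bulk", filter_config(),
                          ml$parent)
  expect_setequal(paste(out3$variants$chrom, out3$variants$pos),
                  paste(out1$variants$chrom, out1$variants$pos))
  expect_identical(out3$tally, out1$tally)
  # recovery of the manifest pass set: precision = recall = 1
  truth_keys <- with(bp$truth, paste(chrom, pos)[expected_to_pass])
  expect_setequal(paste(out1$variants$chrom, out1$variants$pos),
                  truth_keys)
})

test_that("VCF parsing keeps biallelic SNVs only", {
  d <- withr::local_tempdir()
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr01,length=1000>",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
             "chr01\t10\t.\tG\tA\t50\t.\t.\tGT:DP\t1/1:20",
             "chr01\t20\t.\tGT\tG\t50\t.\t.\tGT:DP\t1/1:20",
             "chr01\t30\t.\tC\tT,A\t50\t.\t.\tGT:DP\t0/1:20",
             "chr01\t40\t.\tC\tT\t33.5\t.\t.\tGT:DP\t0/1:15")
  f <- file.path(d, "t.vcf")
  writeLines(lines, f)
  v <- suppressMessages(read_vcf(f))
  expect_equal(nrow(v), 2L)
  expect_equal(attr(v, "n_rejected_parse"), 2L)
  expect_equal(v$genotype, c("hom_alt", "het"))
  expect_equal(v$depth, c(20L, 15L))
  expect_equal(v$quality, c(50, 33.5))
})
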