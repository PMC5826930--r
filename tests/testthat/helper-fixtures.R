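# Shared fixtures: all built in code at test time.

# a small, fast variant-simulation configuration
small_variant_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_chromosomes = 1L,
               chromosome_length = 150000L, n_genes = 40L,
               mutations_per_line = 10, n_mutant_lines = 3L,
               n_allelic_lines = 2L, linked_window = 30000L,
               n_bulk_mutations = 5L, n_parent_sites = 30L,
               decoys_per_filter = 8L, line_decoys_per_filter = 2L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a small expression configuration
small_expr_config <- function(seed = 11, noise_sd = 0.25, ...) {
  args <- list(seed = seed, n_expressed_genes = 300L,
               n_unexpressed_genes = 20L, n_target_genes = 25L,
               n_replicates = 3L, noise_sd = noise_sd)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# a 10-codon toy CDS used by the annotation oracles: ATG, a TGG
# (stop-prone), a GCG (synonymous third position), mixed codons,
# terminal TAA
TOY_CDS <- paste0("ATG", "TGG", "GCG", "CAA", "TCG", "GAC", "TGC",
                  "CGA", "AAG", "TAA", collapse = "")

# build a toy single-gene genome around an explicit coding sequence.
# The gene has two exons split mid-CDS with a GT..AG intron and 10 bp
# UTR flanks; strand "+" or "-". Returns the genome, the model set and
# the local->genomic map of CDS positions (in coding order).
toy_gene_genome <- function(cds, strand = "+", flank = 50L,
                            intron_len = 40L, split_at = NULL) {
  stopifnot(nchar(cds) %% 3 == 0)
  L <- nchar(cds)
  if (is.null(split_at)) split_at <- (L %/% 2) + 1L  # 2nd exon start
  utr <- 10L
  set.seed(4242)
  rb <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  intron <- paste0("GT", rb(intron_len - 4L), "AG")
  local_seq <- paste0(rb(utr), substr(cds, 1L, split_at - 1L), intron,
                      substr(cds, split_at, L), rb(utr))
  # local (coding-strand) intervals
  ex1 <- c(1L, utr + split_at - 1L)
  ex2 <- c(utr + split_at + intron_len,
           utr + L + intron_len + utr)
  cds1 <- c(utr + 1L, utr + split_at - 1L)
  cds2 <- c(utr + split_at + intron_len, utr + L + intron_len)
  gene_len <- nchar(local_seq)
  start <- flank + 1L
  if (strand == "+") {
    seg <- local_seq
    mapiv <- function(iv) iv + start - 1L
    cds_map <- c(seq.int(mapiv(cds1)[1], mapiv(cds1)[2]),
                 seq.int(mapiv(cds2)[1], mapiv(cds2)[2]))
  } else {
    seg <- panicleBSA:::revcomp(local_seq)
    mapiv <- function(iv) sort(start + gene_len - iv)
    cds_map <- c(seq.int(mapiv(cds1)[2], mapiv(cds1)[1]),
                 seq.int(mapiv(cds2)[2], mapiv(cds2)[1]))
  }
  chrom_seq <- paste0(rb(flank), seg, rb(flank))
  model <- gene_model("toy1", "chrT", strand,
                      rbind(mapiv(ex1), mapiv(ex2)),
                      rbind(mapiv(cds1), mapiv(cds2)))
  list(genome = c(chrT = chrom_seq),
       genes = gene_model_set(list(model)),
       model = model,
       cds = cds,
       cds_map = cds_map)   # cds_map[i] = genomic pos of coding base i
}

# independent consequence oracle: substitute coding base i of the CDS,
# translate whole reference and mutant CDS with Biostrings, and derive
# the term from the two protein sequences
oracle_consequence <- function(cds, i, alt_coding) {
  mut <- cds
  substr(mut, i, i) <- alt_coding
  aa_ref <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), no.init.codon = TRUE))
  aa_mut <- as.character(Biostrings::translate(
    Biostrings::DNAString(mut), no.init.codon = TRUE))
  codon_i <- (i - 1) %/% 3 + 1
  r <- substr(aa_ref, codon_i, codon_i)
  m <- substr(aa_mut, codon_i, codon_i)
  if (m == "*" && r != "*") return("stop_gained")
  if (codon_i == 1 && substr(cds, 1, 3) == "ATG" &&
      substr(mut, 1, 3) != "ATG") return("start_lost")
  if (r == m) return("synonymous")
  "missense"
}

# build an expression_set directly from a matrix of log2 condition
# means (rows genes, columns named genotype_stage_tissue), with
# n replicates and lognormal noise
es_from_means <- function(mu, n_rep = 3, noise_sd = 0, seed = 99) {
  set.seed(seed)
  cond <- do.call(rbind, strsplit(colnames(mu), "_"))
  samples <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    data.frame(genotype = cond[i, 1], stage = cond[i, 2],
               tissue = cond[i, 3], replicate = seq_len(n_rep),
               stringsAsFactors = FALSE)
  }))
  samples$sample_id <- sprintf("%s_%s_%s_r%d", samples$genotype,
                               samples$stage, samples$tissue,
                               samples$replicate)
  vals <- matrix(0, nrow(mu), nrow(samples),
                 dimnames = list(rownames(mu), samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    ck <- paste(samples$genotype[j], samples$stage[j],
                samples$tissue[j], sep = "_")
    vals[, j] <- 2 ^ (mu[, ck] + rnorm(nrow(mu), 0, noise_sd))
  }
  counts <- round(vals * 10)
  storage.mode(counts) <- "integer"
  expression_set(vals, counts, samples[, c("sample_id", "genotype",
                                           "stage", "tissue",
                                           "replicate")])
}

all_wt_conditions <- c("WT_S1_whole", "WT_S3_whole", "WT_S4_PS",
                       "WT_S4_SS", "WT_S5_PS", "WT_S5_SS")
all_mu_conditions <- sub("WT", "mutant", all_wt_conditions)
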