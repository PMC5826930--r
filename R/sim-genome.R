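#' Simulate a reference genome with packed gene models
#'
#' Generates `n_chromosomes` random sequences at the configured GC
#' content and packs `n_genes` non-overlapping, strand-assigned
#' single-transcript gene models into them. Every CDS begins with ATG,
#' ends with a stop codon, contains no internal stop, and has length
#' divisible by three; introns carry canonical GT..AG dinucleotides on
#' the coding strand; exons include short UTR flanks.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `genes` (a [gene_model_set()]).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
         config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
  chrom_names <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  genome <- lapply(chrom_names, function(ch) {
    sample(bases, config$chromosome_length, replace = TRUE, prob = p)
  })
  names(genome) <- chrom_names

  models <- list()
  if (config$n_genes > 0) {
    per_chrom <- diff(round(seq(0, config$n_genes,
                                length.out = config$n_chromosomes + 1)))
    gi <- 0L
    for (ci in seq_len(config$n_chromosomes)) {
      ng <- per_chrom[ci]
      if (ng == 0L) next
      slot <- config$chromosome_length %/% ng
      for (k in seq_len(ng)) {
        gi <- gi + 1L
        g <- build_gene_parts(config)
        if (g$length + 40L > slot)
          stop("simulate_genome: impossible packing -- gene of ",
               g$length, " bp does not fit a ", slot, " bp slot; ",
               "reduce n_genes or enlarge chromosome_length")
        offset <- sample.int(slot - g$length - 39L, 1L) + 19L
        start <- (k - 1L) * slot + offset
        gene_id <- sprintf("gene%04d", gi)
        placed <- place_gene(g, chrom_names[ci], start)
        genome[[ci]][seq.int(start, start + g$length - 1L)] <-
          strsplit(placed$seq, "")[[1]]
        models[[gene_id]] <- gene_model(gene_id, chrom_names[ci],
                                        placed$strand, placed$exons,
                                        placed$cds)
      }
    }
  }
  genome <- vapply(genome, paste0, character(1), collapse = "")
  list(genome = genome, genes = gene_model_set(models))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# draw the coding-strand anatomy of one gene in local coordinates
build_gene_parts <- function(config) {
  n_codons <- sample(60:220, 1L)
  n_exons <- 1L + stats::rpois(1L, max(config$mean_exons_per_gene - 1, 0))
  n_exons <- max(1L, min(n_exons, (3L * n_codons) %/% 12L))
  sense <- setdiff(mkAllCodons(), STOP_CODONS)
  cds_seq <- paste0(c("ATG",
                      sample(sense, n_codons - 2L, replace = TRUE),
                      sample(STOP_CODONS, 1L)), collapse = "")
  cds_len <- 3L * n_codons
  # composition of cds_len into n_exons chunks, each >= 9 bp
  extra <- cds_len - 9L * n_exons
  sizes <- 9L + as.vector(stats::rmultinom(1L, extra,
                                           rep(1 / n_exons, n_exons)))
  introns <- if (n_exons > 1L) {
    vapply(seq_len(n_exons - 1L), function(i) {
      mid <- sample(bases4(), sample(56:196, 1L), replace = TRUE)
      paste0("GT", paste0(mid, collapse = ""), "AG")
    }, character(1))
  } else character(0)
  utr <- 30L
  utr5 <- paste0(sample(bases4(), utr, replace = TRUE), collapse = "")
  utr3 <- paste0(sample(bases4(), utr, replace = TRUE), collapse = "")

  # assemble local sequence and 1-based local intervals
  ends <- cumsum(sizes)
  chunks <- substring(cds_seq, c(1L, ends[-n_exons] + 1L), ends)
  seq_parts <- character(0)
  exons <- matrix(0L, n_exons, 2)
  cds <- matrix(0L, n_exons, 2)
  cursor <- 0L
  for (i in seq_len(n_exons)) {
    ex_start <- cursor + 1L
    if (i == 1L) {
      seq_parts <- c(seq_parts, utr5)
      cursor <- cursor + utr
    }
    cds[i, 1] <- cursor + 1L
    seq_parts <- c(seq_parts, chunks[i])
    cursor <- cursor + sizes[i]
    cds[i, 2] <- cursor
    if (i == n_exons) {
      seq_parts <- c(seq_parts, utr3)
      cursor <- cursor + utr
    }
    exons[i, ] <- c(ex_start, cursor)
    if (i < n_exons) {
      seq_parts <- c(seq_parts, introns[i])
      cursor <- cursor + nchar(introns[i])
    }
  }
  list(seq = paste0(seq_parts, collapse = ""), exons = exons, cds = cds,
       length = cursor,
       strand = sample(c("+", "-"), 1L))
}

# map local-coordinate gene parts onto the genome at `start`
place_gene <- function(g, chrom, start) {
  L <- g$length
  if (g$strand == "+") {
    map <- function(iv) iv + start - 1L
    seq <- g$seq
  } else {
    map <- function(iv) {
      out <- cbind(start + L - iv[, 2], start + L - iv[, 1])
      out[order(out[, 1]), , drop = FALSE]
    }
    seq <- revcomp(g$seq)
  }
  list(seq = seq, strand = g$strand,
       exons = map(g$exons), cds = map(g$cds))
}

bases4 <- function() c("A", "C", "G", "T")

mkAllCodons <- function() {
  b <- bases4()
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
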