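#' Gene model containers
#'
#' A `gene_model` is one single-transcript protein-coding gene: strand,
#' sorted non-overlapping exon intervals (1-based, closed) and CDS
#' intervals contained in the exons, with total CDS length divisible by
#' three. A `gene_model_set` is a list of gene models indexed by
#' chromosome for fast lookup.
#'
#' @param gene_id character gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons,cds two-column integer matrices (start, end), 1-based
#'   closed intervals in genomic coordinates.
#' @return a `gene_model` / `gene_model_set` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  cds <- matrix(as.integer(cds), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1]) || any(cds[, 2] < cds[, 1]))
    stop("gene_model: interval end before start for ", gene_id)
  if (nrow(exons) > 1 &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("gene_model: overlapping exons in ", gene_id)
  cds_len <- sum(cds[, 2] - cds[, 1] + 1L)
  if (cds_len %% 3L != 0L)
    stop("gene_model: CDS length of ", gene_id, " not a multiple of 3")
  # every CDS interval must sit inside some exon
  inside <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
  }, logical(1))
  if (!all(inside))
    stop("gene_model: CDS outside exons in ", gene_id)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds,
                 start = min(exons[, 1]), end = max(exons[, 2]),
                 cds_length = cds_len),
            class = "gene_model")
}

#' @rdname gene_model
#' @param models list of `gene_model` objects.
#' @export
gene_model_set <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1), "gene_model")))
  ids <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("gene_model_set: duplicated gene ids")
  names(models) <- ids
  chroms <- vapply(models, `[[`, character(1), "chrom")
  structure(list(models = models,
                 by_chrom = split(ids, chroms)),
            class = "gene_model_set")
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", length(x$models), "genes on",
      length(x$by_chrom), "chromosome(s)\n")
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$models)

# genomic-position <-> coding-index map for one gene; coding index runs
# 5' -> 3' on the coding strand
coding_map <- function(gene) {
  pos <- unlist(lapply(seq_len(nrow(gene$cds)), function(i)
    seq.int(gene$cds[i, 1], gene$cds[i, 2])), use.names = FALSE)
  if (gene$strand == "-") pos <- rev(pos)
  pos
}

# coding-strand CDS sequence of a gene from a named character vector of
# chromosome sequences (or DNAStringSet)
gene_cds_seq <- function(gene, genome) {
  chrom_seq <- genome_chrom(genome, gene$chrom)
  pos <- coding_map(gene)
  bases <- substring(chrom_seq, pos, pos)
  if (gene$strand == "-") bases <- comp_base(bases)
  paste0(bases, collapse = "")
}

genome_chrom <- function(genome, chrom) {
  if (inherits(genome, "DNAStringSet"))
    return(as.character(genome[[chrom]]))
  genome[[chrom]]
}

comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}

revcomp <- function(s) {
  paste0(rev(comp_base(strsplit(s, "")[[1]])), collapse = "")
}
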