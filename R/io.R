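#' Read and write pipeline file formats
#'
#' Thin wrappers tying the simulator's in-memory objects to the
#' standard on-disk formats: FASTA via Biostrings, GFF3 read via
#' rtracklayer, VCF read via vcfR. The simulator writes VCF and GFF3 as
#' plain formatted lines since it owns the records it emits.
#'
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @param genome named character vector of chromosome sequences.
#' @param path output file.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname pipeline-io
#' @param genes a [gene_model_set()].
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes$models) {
    lines <- c(lines,
      sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$chrom, g$exons[, 1], g$exons[, 2], g$strand, g$gene_id),
      sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
              g$chrom, g$cds[, 1], g$cds[, 2], g$strand, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  parent <- vapply(df$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  gene_rows <- df$type == "gene"
  models <- lapply(which(gene_rows), function(i) {
    id <- df$ID[i]
    ex <- df[df$type == "exon" & parent == id, c("start", "end")]
    cd <- df[df$type == "CDS" & parent == id, c("start", "end")]
    gene_model(id, as.character(df$seqnames[i]),
               as.character(df$strand[i]),
               as.matrix(ex), as.matrix(cd))
  })
  gene_model_set(models)
}

GT_CODE <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")

#' @rdname pipeline-io
#' @param variants variant-call data.frame (chrom, pos, ref, alt,
#'   genotype, depth, quality).
#' @param sample_id sample column name.
#' @param contigs named integer vector of contig lengths for the
#'   header (optional).
#' @export
write_vcf <- function(variants, sample_id, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=panicleBSA-simulator",
           if (!is.null(contigs))
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_id))
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%.1f\t.\t.\tGT:DP\t%s:%d",
                  v$chrom, v$pos, v$ref, v$alt, v$quality,
                  GT_CODE[v$genotype], v$depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a one-sample VCF into a variant-call table
#'
#' Only biallelic SNVs are admitted; indels and multi-allelic records
#' are dropped with a message and counted in the `n_rejected_parse`
#' attribute. Requires QUAL and per-sample GT and DP fields.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return data.frame (chrom, pos, ref, alt, genotype, depth, quality)
#'   with attribute `n_rejected_parse`.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  n_rej <- sum(!snv)
  if (n_rej > 0)
    message("read_vcf: dropped ", n_rej,
            " non-biallelic-SNV record(s) from ", basename(path))
  gt <- vcfR::extract.gt(vcf, element = "GT")[snv, 1]
  dp <- as.integer(vcfR::extract.gt(vcf, element = "DP")[snv, 1])
  gt <- gsub("|", "/", gt, fixed = TRUE)
  genotype <- ifelse(gt %in% c("0/0"), "hom_ref",
               ifelse(gt %in% c("0/1", "1/0"), "het",
                ifelse(gt == "1/1", "hom_alt", NA_character_)))
  out <- data.frame(chrom = fix[snv, "CHROM"],
                    pos = as.integer(fix[snv, "POS"]),
                    ref = ref[snv], alt = alt[snv],
                    genotype = genotype, depth = dp,
                    quality = as.numeric(fix[snv, "QUAL"]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_rejected_parse") <- n_rej
  out
}

#' @rdname pipeline-io
#' @param x matrix or data.frame to write with a header row and
#'   row-name first column (`gene_id`) when `x` is a matrix.
#' @export
write_tsv_matrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname pipeline-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname pipeline-io
#' @param truth truth-manifest list.
#' @export
write_truth_manifest <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_truth_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = TRUE)
}
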