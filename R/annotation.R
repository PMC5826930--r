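#' Locate a position relative to gene models
#'
#' Assigns a genomic position to a gene and a region class: `cds`,
#' `exon_noncoding`, `intron`, `splice_2bp` (within 2 bp of an
#' exon-intron boundary, on the intron side) or `intergenic`. When gene
#' models overlap, a gene whose CDS contains the position wins; ties
#' break on the lexicographically smallest gene id.
#'
#' @param chrom,pos chromosome and 1-based position.
#' @param gene_models a [gene_model_set()].
#' @return list with `gene_id` (or `NA`) and `region`.
#' @export
locate_in_gene <- function(chrom, pos, gene_models) {
  ids <- gene_models$by_chrom[[chrom]]
  hits <- list()
  for (id in ids) {
    g <- gene_models$models[[id]]
    if (pos < g$start || pos > g$end) next
    hits[[id]] <- region_in_gene(pos, g)
  }
  if (length(hits) == 0L)
    return(list(gene_id = NA_character_, region = "intergenic"))
  ids <- sort(names(hits))
  in_cds <- ids[vapply(hits[ids], function(r) r == "cds", logical(1))]
  pick <- if (length(in_cds)) in_cds[1] else ids[1]
  list(gene_id = pick, region = hits[[pick]])
}

region_in_gene <- function(pos, g) {
  ex <- g$exons
  in_exon <- any(ex[, 1] <= pos & pos <= ex[, 2])
  if (in_exon) {
    if (any(g$cds[, 1] <= pos & pos <= g$cds[, 2])) return("cds")
    return("exon_noncoding")
  }
  # intronic: within 2 bp of an internal exon boundary?
  if (nrow(ex) > 1) {
    donors <- ex[-nrow(ex), 2]   # last exon base before each intron
    acceptors <- ex[-1, 1]       # first exon base after each intron
    if (any((pos - donors) %in% 1:2) || any((acceptors - pos) %in% 1:2))
      return("splice_2bp")
  }
  "intron"
}

#' Classify the predicted consequence of a SNV
#'
#' For CDS hits the affected codon is rebuilt on the coding strand
#' (reverse-complementing minus-strand genes), and the reference and
#' alternate codons are translated with the standard nuclear code:
#' `stop_gained` when the alternate codon is a stop and the reference
#' is not, `start_lost` when the first codon loses ATG, `synonymous`
#' when the amino acids agree, otherwise `missense`. Non-CDS hits map
#' to `splice_site`, `intronic`, `exonic_noncoding` or `intergenic`.
#'
#' @param chrom,pos,ref,alt the SNV (reference-strand bases).
#' @param gene_models a [gene_model_set()].
#' @param genome named character vector (or DNAStringSet) of
#'   chromosome sequences; the reference base at `pos` is checked
#'   against `ref`.
#' @return list with `term`, `gene_id`, `codon_change` (NA unless
#'   coding) and `region`.
#' @export
classify_consequence <- function(chrom, pos, ref, alt, gene_models,
                                 genome) {
  chrom_seq <- genome_chrom(genome, chrom)
  genome_base <- substring(chrom_seq, pos, pos)
  if (genome_base != ref)
    stop("classify_consequence: reference mismatch at ", chrom, ":",
         pos, " (VCF says ", ref, ", genome has ", genome_base, ")")
  loc <- locate_in_gene(chrom, pos, gene_models)
  term <- switch(loc$region,
                 intergenic = "intergenic",
                 intron = "intronic",
                 splice_2bp = "splice_site",
                 exon_noncoding = "exonic_noncoding",
                 cds = NA_character_)
  if (!is.na(term))
    return(list(term = term, gene_id = loc$gene_id,
                codon_change = NA_character_, region = loc$region))

  g <- gene_models$models[[loc$gene_id]]
  map <- coding_map(g)
  cpos <- match(pos, map)
  codon_i <- (cpos - 1L) %/% 3L
  codon_pos <- map[codon_i * 3L + 1:3]
  codon_bases <- substring(chrom_seq, codon_pos, codon_pos)
  if (g$strand == "-") codon_bases <- comp_base(codon_bases)
  ref_codon <- paste0(codon_bases, collapse = "")
  within <- (cpos - 1L) %% 3L + 1L
  alt_coding <- if (g$strand == "-") comp_base(alt) else alt
  alt_bases <- codon_bases
  alt_bases[within] <- alt_coding
  alt_codon <- paste0(alt_bases, collapse = "")

  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  term <- if (alt_aa == "*" && ref_aa != "*") "stop_gained"
    else if (codon_i == 0L && ref_codon == "ATG" && alt_codon != "ATG")
      "start_lost"
    else if (ref_aa == alt_aa) "synonymous"
    else "missense"
  list(term = term, gene_id = loc$gene_id,
       codon_change = paste0(ref_codon, ">", alt_codon),
       region = "cds")
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) stop("translate_codon: invalid codon ", codon)
  aa
}

#' Is a consequence term protein-disrupting?
#'
#' Large-effect terms are `stop_gained`, `missense`, `start_lost` and
#' `splice_site` -- the classes a forward-genetics screen prioritises.
#'
#' @param term consequence term(s).
#' @return logical vector.
#' @export
is_large_effect <- function(term) {
  term %in% c("stop_gained", "missense", "start_lost", "splice_site")
}

#' Annotate a table of filtered variants
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param gene_models a [gene_model_set()].
#' @param genome chromosome sequences.
#' @return the input with `gene_id`, `term`, `codon_change` and
#'   `region` columns appended.
#' @export
annotate_variants <- function(variants, gene_models, genome) {
  n <- nrow(variants)
  gene_id <- character(n); term <- character(n)
  codon_change <- character(n); region <- character(n)
  for (i in seq_len(n)) {
    cc <- classify_consequence(variants$chrom[i], variants$pos[i],
                               variants$ref[i], variants$alt[i],
                               gene_models, genome)
    gene_id[i] <- cc$gene_id; term[i] <- cc$term
    codon_change[i] <- cc$codon_change; region[i] <- cc$region
  }
  variants$gene_id <- gene_id
  variants$term <- term
  variants$codon_change <- codon_change
  variants$region <- region
  variants
}
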