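#' Mutant line container
#'
#' A named sample with its filtered (and annotated) variant table and
#' its role in the mapping design. Parent lines never enter the
#' candidate-gene intersection.
#'
#' @param line_id sample name.
#' @param role "bulk", "individual_mutant" or "parent".
#' @param variants annotated variant data.frame (columns chrom, pos,
#'   ref, alt, gene_id, term at minimum), post filtering.
#' @return a `mutant_line`.
#' @export
mutant_line <- function(line_id,
                        role = c("individual_mutant", "bulk", "parent"),
                        variants) {
  role <- match.arg(role)
  structure(list(line_id = line_id, role = role, variants = variants),
            class = "mutant_line")
}

#' Gene-level rollup of a line's variant hits
#'
#' @param line a [mutant_line()].
#' @param large_effect_only restrict to protein-disrupting
#'   consequences (see [is_large_effect()]).
#' @return named list mapping gene_id to the variant rows hitting it.
#' @export
genes_with_hits <- function(line, large_effect_only = TRUE) {
  v <- line$variants
  v <- v[!is.na(v$gene_id), , drop = FALSE]
  if (large_effect_only)
    v <- v[is_large_effect(v$term), , drop = FALSE]
  if (nrow(v) == 0L) return(list())
  split(v, v$gene_id)
}

#' Intersect candidate genes across lines
#'
#' Returns the genes hit (large-effect by default) in every supplied
#' line -- the bulk-segregant mapping step -- as candidate reports
#' sorted by the number of independent alleles (distinct pos/alt
#' pairs across lines) descending, then gene id.
#'
#' @param lines list of [mutant_line()] objects (at least 2; parents
#'   are a usage error).
#' @param large_effect_only see [genes_with_hits()].
#' @return list of candidate reports (gene_id, n_independent_alleles,
#'   allele_positions, supporting); empty list when the intersection
#'   is empty.
#' @export
intersect_candidate_genes <- function(lines, large_effect_only = TRUE) {
  if (length(lines) < 2L)
    stop("intersect_candidate_genes: need at least 2 lines")
  roles <- vapply(lines, `[[`, character(1), "role")
  if (any(roles == "parent"))
    stop("intersect_candidate_genes: parent lines cannot enter the ",
         "intersection")
  hit_maps <- lapply(lines, genes_with_hits, large_effect_only)
  shared <- Reduce(intersect, lapply(hit_maps, names))
  if (length(shared) == 0L) return(list())
  reports <- lapply(shared, function(gid) {
    sup <- lapply(hit_maps, function(h) h[[gid]])
    names(sup) <- vapply(lines, `[[`, character(1), "line_id")
    all_hits <- do.call(rbind, sup)
    key <- paste(all_hits$pos, all_hits$alt)
    uniq <- !duplicated(key)
    list(gene_id = gid,
         n_independent_alleles = sum(uniq),
         allele_positions = sort(unique(all_hits$pos)),
         supporting = sup)
  })
  n_all <- vapply(reports, `[[`, integer(1), "n_independent_alleles")
  gids <- vapply(reports, `[[`, character(1), "gene_id")
  reports[order(-n_all, gids)]
}

#' Collect the allelic series of a candidate gene
#'
#' Scans additional lines for filtered large-effect variants in the
#' candidate gene and reports the distinct additional alleles
#' (distinct pos/alt pairs), excluding positions already attributed to
#' the defining lines.
#'
#' @param gene_id the candidate gene.
#' @param other_lines list of [mutant_line()] objects to scan.
#' @param known_positions allele positions already attributed.
#' @param large_effect_only see [genes_with_hits()].
#' @return list with `gene_id`, `n_additional_alleles`, `alleles`
#'   (data.frame pos, alt, line_id) -- one row per distinct new
#'   allele, first carrier listed.
#' @export
collect_allelic_series <- function(gene_id, other_lines,
                                   known_positions = integer(0),
                                   large_effect_only = TRUE) {
  rows <- list()
  for (line in other_lines) {
    h <- genes_with_hits(line, large_effect_only)[[gene_id]]
    if (is.null(h)) next
    h <- h[!(h$pos %in% known_positions), , drop = FALSE]
    if (nrow(h) > 0)
      rows[[length(rows) + 1L]] <-
        data.frame(pos = h$pos, alt = h$alt, line_id = line$line_id,
                   stringsAsFactors = FALSE)
  }
  alleles <- do.call(rbind, c(rows, list(data.frame(
    pos = integer(0), alt = character(0), line_id = character(0)))))
  alleles <- alleles[!duplicated(paste(alleles$pos, alleles$alt)), ,
                     drop = FALSE]
  alleles <- alleles[order(alleles$pos), , drop = FALSE]
  rownames(alleles) <- NULL
  list(gene_id = gene_id, n_additional_alleles = nrow(alleles),
       alleles = alleles)
}
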