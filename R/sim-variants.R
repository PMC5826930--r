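#' Simulate EMS mutant lines, the parental background and the F2 bulk
#'
#' `simulate_mutant_lines()` designates a causal gene (the gene nearest
#' the centre of the first chromosome), plants one homozygous
#' large-effect canonical-EMS allele per allelic line at distinct CDS
#' positions, draws Poisson background mutations per line (never in the
#' causal gene), the parental SNP background shared by all lines, and
#' per-line decoys each violating exactly one filter predicate.
#' `simulate_bulk_pool()` then emits the phenotype-selected F2 pool of
#' the first allelic line: sites inside the linkage window are fixed
#' homozygous (the planted pass set), unlinked line mutations segregate
#' with pooled alternate fraction around 0.5, parental sites are fixed
#' in the cross, and per-filter decoys are planted. Ground truth is
#' tagged record by record in the returned manifest.
#'
#' @param sim output of [simulate_genome()].
#' @param config a [sim_config()].
#' @return `simulate_mutant_lines`: list with `causal_gene_id`,
#'   `alleles` (one row per allelic line), `parent` (variant table),
#'   `lines` (named list of variant tables), `truth` (per-line tag
#'   tables) and `window` (the linkage window). Variant tables carry
#'   chrom, pos, ref, alt, genotype, depth, quality.
#' @export
simulate_mutant_lines <- function(sim, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  genome <- sim$genome
  genes <- sim$genes
  if (length(genes) == 0L)
    stop("simulate_mutant_lines: no gene models; a causal gene must exist")

  chrom1 <- names(genome)[1]
  ids1 <- genes$by_chrom[[chrom1]]
  if (is.null(ids1))
    stop("simulate_mutant_lines: no genes on ", chrom1)
  mids <- vapply(genes$models[ids1], function(g) (g$start + g$end) / 2,
                 numeric(1))
  causal_id <- unname(ids1[which.min(abs(mids -
                                           nchar(genome[[chrom1]]) / 2))])
  causal <- genes$models[[causal_id]]

  cand <- causal_allele_candidates(causal, genes, genome)
  if (nrow(cand) < config$n_allelic_lines)
    stop("simulate_mutant_lines: causal gene ", causal_id,
         " too short to host ", config$n_allelic_lines,
         " distinct large-effect EMS alleles")
  pick <- sample.int(nrow(cand), config$n_allelic_lines)
  alleles <- cand[pick, , drop = FALSE]
  rownames(alleles) <- NULL

  used <- new.env(parent = emptyenv())
  mark_used(used, causal$chrom, alleles$pos)

  window <- c(max(1L, alleles$pos[1] - config$linked_window %/% 2L),
              min(nchar(genome[[chrom1]]),
                  alleles$pos[1] + config$linked_window %/% 2L))

  ind_lo <- 3L; ind_hi <- 50L
  parent <- make_parent_sites(genome, config, causal, used)

  line_ids <- sprintf("line%02d", seq_len(config$n_mutant_lines))
  lines <- list(); truth <- list()
  for (i in seq_along(line_ids)) {
    allelic <- i <= config$n_allelic_lines
    n_bg <- stats::rpois(1L, config$mutations_per_line)
    excl <- list(span(causal))
    if (i == 1L) excl <- c(excl, list(c(chrom1, window)))
    bg <- sample_sites(genome, n_bg, used, base_in = c("G", "C"),
                       exclude_spans = excl)
    bg$alt <- ems_partner(bg$ref)
    parts <- list(
      with_call(parent[, c("chrom", "pos", "ref", "alt")], "hom_alt",
                config$line_coverage, ind_lo, ind_hi,
                tag(parent$ems_like, "parental", "multiple")))
    if (allelic)
      parts <- c(parts, list(
        with_call(alleles[i, c("chrom", "pos", "ref", "alt")],
                  "hom_alt", config$line_coverage, ind_lo, ind_hi,
                  "none")))
    if (n_bg > 0)
      parts <- c(parts, list(
        with_call(bg, "hom_alt", config$line_coverage, ind_lo, ind_hi,
                  "none")))
    parts <- c(parts, line_decoys(genome, config, used, causal,
                                  config$line_decoys_per_filter,
                                  config$line_coverage, ind_lo, ind_hi))
    tab <- do.call(rbind, parts)
    rownames(tab) <- NULL
    lines[[line_ids[i]]] <- tab[, c("chrom", "pos", "ref", "alt",
                                    "genotype", "depth", "quality")]
    truth[[line_ids[i]]] <- truth_table(tab)
  }
  list(causal_gene_id = causal_id,
       alleles = cbind(line_id = line_ids[seq_len(config$n_allelic_lines)],
                       alleles),
       parent = parent[, c("chrom", "pos", "ref", "alt", "genotype",
                           "depth", "quality")],
       lines = lines, truth = truth, window = window,
       chrom1 = chrom1, used = used)
}

#' @rdname simulate_mutant_lines
#' @param ml output of [simulate_mutant_lines()].
#' @return `simulate_bulk_pool`: list with `bulk` (variant table) and
#'   `truth` (tag table; `expected_to_pass` marks the planted pass
#'   set).
#' @export
simulate_bulk_pool <- function(ml, sim, config) {
  set.seed(config$seed + 2L)
  genome <- sim$genome
  genes <- sim$genes
  used <- ml$used
  blo <- 5L; bhi <- 100L
  cov <- config$bulk_coverage

  causal_row <- ml$alleles[1, c("chrom", "pos", "ref", "alt")]
  n_extra <- config$n_bulk_mutations - 1L
  extra <- sample_sites(genome, n_extra, used, chrom = ml$chrom1,
                        range = ml$window, base_in = c("G", "C"),
                        exclude_spans = gene_spans(genes, ml$chrom1))
  extra$alt <- ems_partner(extra$ref)
  pass <- rbind(causal_row, extra[, c("chrom", "pos", "ref", "alt")])
  parts <- list(with_call(pass, "hom_alt", cov, blo, bhi, "none"))

  # unlinked mutations of the bulk's founder line segregate 1:2:1 in
  # the selected pool; pooled alternate fraction ~ Binomial(2N, 1/2)
  t1 <- ml$truth[[1]]
  unl <- t1[t1$violated_filter == "none" &
              !(t1$pos %in% causal_row$pos & t1$chrom == causal_row$chrom), ,
            drop = FALSE]
  if (nrow(unl) > 0) {
    frac <- stats::rbinom(nrow(unl), 2L * config$bulk_size, 0.5) /
      (2L * config$bulk_size)
    gt <- ifelse(frac >= 0.9, "hom_alt", "het")
    seg <- with_call(unl[, c("chrom", "pos", "ref", "alt")], "het",
                     cov, blo, bhi, "homozygous")
    seg$genotype <- gt
    seg$violated_filter <- ifelse(gt == "hom_alt", "none", "homozygous")
    parts <- c(parts, list(seg))
  }

  parts <- c(parts, list(
    with_call(ml$parent[, c("chrom", "pos", "ref", "alt")], "hom_alt",
              cov, blo, bhi,
              tag(is_canonical_ems(ml$parent$ref, ml$parent$alt),
                  "parental", "multiple"))))

  k <- config$decoys_per_filter
  nonems <- sample_sites(genome, k, used, base_in = c("A", "C", "G", "T"),
                         exclude_spans = list(span(genes$models[[ml$causal_gene_id]])))
  nonems$alt <- non_ems_alt(nonems$ref)
  het <- sample_sites(genome, k, used, base_in = c("G", "C"),
                      exclude_spans = list(span(genes$models[[ml$causal_gene_id]])))
  het$alt <- ems_partner(het$ref)
  dep <- sample_sites(genome, k, used, base_in = c("G", "C"),
                      exclude_spans = list(span(genes$models[[ml$causal_gene_id]])))
  dep$alt <- ems_partner(dep$ref)
  dd <- with_call(dep, "hom_alt", cov, blo, bhi, "depth")
  dd$depth <- sample(c(0:(blo - 1L), (bhi + 1L):(bhi + 40L)),
                     nrow(dd), replace = TRUE)
  parts <- c(parts,
             list(with_call(nonems, "hom_alt", cov, blo, bhi,
                            "canonical_ems"),
                  with_call(het, "het", cov, blo, bhi, "homozygous"),
                  dd))
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  list(bulk = tab[, c("chrom", "pos", "ref", "alt", "genotype",
                      "depth", "quality")],
       truth = truth_table(tab))
}

# ---- helpers ---------------------------------------------------------

# parental SNP background versus the reference: mostly EMS-like
# transitions plus a minority of other substitutions, all homozygous
make_parent_sites <- function(genome, config, causal, used) {
  n_ems <- max(config$decoys_per_filter,
               round(2 / 3 * config$n_parent_sites))
  n_other <- max(config$n_parent_sites - n_ems, 0L)
  excl <- list(span(causal))
  a <- sample_sites(genome, n_ems, used, base_in = c("G", "C"),
                    exclude_spans = excl)
  a$alt <- ems_partner(a$ref)
  a$ems_like <- rep(TRUE, nrow(a))
  b <- sample_sites(genome, n_other, used,
                    base_in = c("A", "C", "G", "T"),
                    exclude_spans = excl)
  if (n_other > 0) {
    b$alt <- non_ems_alt(b$ref)
    b$ems_like <- FALSE
  } else b <- NULL
  sites <- rbind(a, b)
  out <- with_call(sites, "hom_alt", config$line_coverage, 3L, 50L,
                   "none")
  out$ems_like <- sites$ems_like
  out
}

span <- function(g) c(g$chrom, g$start, g$end)

gene_spans <- function(genes, chrom) {
  lapply(genes$by_chrom[[chrom]], function(id) span(genes$models[[id]]))
}

ems_partner <- function(ref) ifelse(ref == "G", "A", "T")

# a substitution that is NOT a canonical EMS change
non_ems_alt <- function(ref) {
  vapply(ref, function(b) {
    opts <- setdiff(c("A", "C", "G", "T"), b)
    if (b == "G") opts <- setdiff(opts, "A")
    if (b == "C") opts <- setdiff(opts, "T")
    sample(opts, 1L)
  }, character(1), USE.NAMES = FALSE)
}

tag <- function(flag, yes, no) ifelse(flag, yes, no)

mark_used <- function(used, chrom, pos) {
  for (p in pos) assign(paste0(chrom, ":", p), TRUE, envir = used)
}

is_used <- function(used, chrom, pos) {
  exists(paste0(chrom, ":", pos), envir = used, inherits = FALSE)
}

in_spans <- function(chrom, pos, spans) {
  for (s in spans) {
    if (chrom == s[1] && pos >= as.integer(s[2]) &&
        pos <= as.integer(s[3])) return(TRUE)
  }
  FALSE
}

# rejection-sample genomic sites with a given reference base, marking
# them used so no two planted variants ever collide
sample_sites <- function(genome, k, used, chrom = NULL, range = NULL,
                         base_in = c("G", "C"), exclude_spans = list()) {
  out_chrom <- character(k); out_pos <- integer(k); out_ref <- character(k)
  chroms <- names(genome)
  lens <- nchar(genome)
  i <- 0L; tries <- 0L
  while (i < k) {
    tries <- tries + 1L
    if (tries > 200000L)
      stop("sample_sites: could not place ", k, " sites")
    ch <- if (is.null(chrom))
      sample(chroms, 1L, prob = lens / sum(lens)) else chrom
    p <- if (is.null(range)) sample.int(lens[[ch]], 1L)
      else sample.int(range[2] - range[1] + 1L, 1L) + range[1] - 1L
    b <- substring(genome[[ch]], p, p)
    if (!(b %in% base_in)) next
    if (is_used(used, ch, p)) next
    if (in_spans(ch, p, exclude_spans)) next
    i <- i + 1L
    out_chrom[i] <- ch; out_pos[i] <- p; out_ref[i] <- b
    mark_used(used, ch, p)
  }
  data.frame(chrom = out_chrom, pos = out_pos, ref = out_ref,
             stringsAsFactors = FALSE)
}

rdepth <- function(n, mean, lo, hi) {
  d <- stats::rpois(n, mean)
  bad <- which(d < lo | d > hi)
  while (length(bad)) {
    d[bad] <- stats::rpois(length(bad), mean)
    bad <- which(d < lo | d > hi)
  }
  as.integer(d)
}

# attach genotype, in-window depth, passing quality and a truth tag
with_call <- function(sites, genotype, cov, lo, hi, violated) {
  n <- nrow(sites)
  out <- sites[, c("chrom", "pos", "ref", "alt")]
  out$genotype <- rep(genotype, n)
  out$depth <- rdepth(n, cov, lo, hi)
  out$quality <- round(stats::runif(n, 30, 60), 1)
  out$violated_filter <- rep_len(violated, n)
  out
}

truth_table <- function(tab) {
  data.frame(chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
             alt = tab$alt,
             is_canonical_ems = is_canonical_ems(tab$ref, tab$alt),
             expected_to_pass = tab$violated_filter == "none",
             violated_filter = tab$violated_filter,
             stringsAsFactors = FALSE)
}

# scan the causal gene's CDS for EMS-mutable positions whose change is
# protein-disrupting
causal_allele_candidates <- function(causal, genes, genome) {
  map <- coding_map(causal)
  chrom_seq <- genome[[causal$chrom]]
  rows <- list()
  for (p in sort(map)) {
    b <- substring(chrom_seq, p, p)
    if (!(b %in% c("G", "C"))) next
    alt <- ems_partner(b)
    cc <- classify_consequence(causal$chrom, p, b, alt, genes, genome)
    if (identical(cc$gene_id, causal$gene_id) &&
        cc$term %in% c("stop_gained", "missense", "start_lost"))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = causal$chrom, pos = p, ref = b, alt = alt,
                   term = cc$term, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(data.frame(chrom = character(0),
                                         pos = integer(0),
                                         ref = character(0),
                                         alt = character(0),
                                         term = character(0)))))
}

line_decoys <- function(genome, config, used, causal, k, cov, lo, hi) {
  if (k == 0L) return(list())
  excl <- list(span(causal))
  nonems <- sample_sites(genome, k, used,
                         base_in = c("A", "C", "G", "T"),
                         exclude_spans = excl)
  nonems$alt <- non_ems_alt(nonems$ref)
  het <- sample_sites(genome, k, used, base_in = c("G", "C"),
                      exclude_spans = excl)
  het$alt <- ems_partner(het$ref)
  dep <- sample_sites(genome, k, used, base_in = c("G", "C"),
                      exclude_spans = excl)
  dep$alt <- ems_partner(dep$ref)
  dd <- with_call(dep, "hom_alt", cov, lo, hi, "depth")
  dd$depth <- sample(c(0:(lo - 1L), (hi + 1L):(hi + 30L)),
                     nrow(dd), replace = TRUE)
  list(with_call(nonems, "hom_alt", cov, lo, hi, "canonical_ems"),
       with_call(het, "het", cov, lo, hi, "homozygous"),
       dd)
}
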