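#' Filter configuration for EMS variant screening
#'
#' Defaults follow the screening protocol: variant quality strictly
#' above 20; read depth within a closed interval of 3--50 for the
#' parental line and individual mutants and 5--100 for the selected F2
#' bulk; homozygous-alternate calls only; canonical EMS changes
#' (G-to-A or C-to-T on the reference strand) only.
#'
#' @param min_quality phred quality gate (exclusive).
#' @param depth_min_individual,depth_max_individual inclusive depth
#'   window for parent / individual-mutant samples.
#' @param depth_min_bulk,depth_max_bulk inclusive depth window for the
#'   bulk pool.
#' @param require_homozygous keep only hom-alt calls.
#' @param require_canonical_ems keep only G>A / C>T changes.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_quality = 20,
                          depth_min_individual = 3L,
                          depth_max_individual = 50L,
                          depth_min_bulk = 5L,
                          depth_max_bulk = 100L,
                          require_homozygous = TRUE,
                          require_canonical_ems = TRUE) {
  if (depth_min_individual < 0 ||
      depth_min_individual > depth_max_individual ||
      depth_min_bulk < 0 || depth_min_bulk > depth_max_bulk)
    stop("filter_config: depth windows must satisfy 0 <= min <= max")
  structure(list(min_quality = min_quality,
                 depth_min_individual = as.integer(depth_min_individual),
                 depth_max_individual = as.integer(depth_max_individual),
                 depth_min_bulk = as.integer(depth_min_bulk),
                 depth_max_bulk = as.integer(depth_max_bulk),
                 require_homozygous = isTRUE(require_homozygous),
                 require_canonical_ems = isTRUE(require_canonical_ems)),
            class = "filter_config")
}

#' Canonical EMS change?
#'
#' EMS alkylates guanine and induces almost exclusively G/C-to-A/T
#' transitions, so on the reference strand a true EMS SNV is either
#' G>A or C>T.
#'
#' @param ref,alt single reference/alternate bases (vectorised).
#' @return logical vector.
#' @export
is_canonical_ems <- function(ref, alt) {
  ok <- c("A", "C", "G", "T")
  if (!all(ref %in% ok) || !all(alt %in% ok))
    stop("is_canonical_ems: bases must be one of A, C, G, T")
  (ref == "G" & alt == "A") | (ref == "C" & alt == "T")
}

#' Depth-window predicate
#'
#' @param depth read depth(s), >= 0.
#' @param sample_class one of "parent", "individual_mutant", "bulk";
#'   the parent uses the individual window.
#' @param config a [filter_config()].
#' @return logical vector.
#' @export
passes_depth <- function(depth, sample_class, config = filter_config()) {
  sample_class <- match.arg(sample_class,
                            c("parent", "individual_mutant", "bulk"))
  if (any(depth < 0)) stop("passes_depth: depth must be >= 0")
  if (sample_class == "bulk")
    depth >= config$depth_min_bulk & depth <= config$depth_max_bulk
  else
    depth >= config$depth_min_individual &
      depth <= config$depth_max_individual
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Subtract parental background variants
#'
#' Removes every variant whose (chrom, pos, ref, alt) key occurs in the
#' parental set; matching on the full key (not position alone) keeps a
#' true mutation that coincides positionally with a different parental
#' allele. Input order is preserved.
#'
#' @param variants,parental_variants data.frames with columns chrom,
#'   pos, ref, alt.
#' @return the non-parental subset of `variants`.
#' @export
subtract_background <- function(variants, parental_variants) {
  if (is.null(parental_variants) || nrow(parental_variants) == 0L)
    return(variants)
  keep <- !(variant_key(variants) %in% variant_key(parental_variants))
  variants[keep, , drop = FALSE]
}

#' Apply the full EMS filter chain
#'
#' A record survives iff quality strictly exceeds the gate, the call is
#' homozygous-alternate, the change is a canonical EMS transition, the
#' depth lies in the class-appropriate closed window, and the site is
#' absent from the parental background. The tally counts, per filter,
#' every record failing that predicate (a record failing several
#' predicates is tallied against each).
#'
#' @param records data.frame of variant calls (columns chrom, pos, ref,
#'   alt, genotype, depth, quality).
#' @param sample_class "parent", "individual_mutant" or "bulk".
#' @param config a [filter_config()].
#' @param parental_variants parental variant data.frame (may be NULL or
#'   empty, e.g. when filtering the parent itself).
#' @return list with `variants` (surviving records, input order) and
#'   `tally` (named integer vector of per-filter rejection counts).
#' @export
filter_variants <- function(records,
                            sample_class = c("individual_mutant",
                                             "parent", "bulk"),
                            config = filter_config(),
                            parental_variants = NULL) {
  sample_class <- match.arg(sample_class)
  n <- nrow(records)
  if (n == 0L) {
    tally <- c(quality = 0L, homozygous = 0L, canonical_ems = 0L,
               depth = 0L, parental = 0L)
    return(list(variants = records, tally = tally))
  }
  pass_qual <- records$quality > config$min_quality
  pass_hom <- if (config$require_homozygous)
    records$genotype == "hom_alt" else rep(TRUE, n)
  pass_ems <- if (config$require_canonical_ems)
    is_canonical_ems(records$ref, records$alt) else rep(TRUE, n)
  pass_depth <- passes_depth(records$depth, sample_class, config)
  in_parent <- if (is.null(parental_variants) ||
                   nrow(parental_variants) == 0L) rep(FALSE, n)
    else variant_key(records) %in% variant_key(parental_variants)
  tally <- c(quality = sum(!pass_qual),
             homozygous = sum(!pass_hom),
             canonical_ems = sum(!pass_ems),
             depth = sum(!pass_depth),
             parental = sum(in_parent))
  keep <- pass_qual & pass_hom & pass_ems & pass_depth & !in_parent
  list(variants = records[keep, , drop = FALSE], tally = tally)
}
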