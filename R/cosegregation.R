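#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by probability ordering: with margins fixed, the
#' hypergeometric probability of every achievable table is computed
#' and all tables no more probable than the observed one (up to a
#' small relative tolerance for floating-point ties) are summed.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0)
    stop("fisher_exact_2x2: all-zero table has no defined p-value")
  r1 <- sum(table[1, ]); r2 <- sum(table[2, ])
  c1 <- sum(table[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(table[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Chi-square goodness of fit to a phenotypic ratio
#'
#' Pearson chi-square of observed (wild-type, mutant) counts against
#' an a:b expectation (3:1 by default), with 1 degree of freedom.
#'
#' @param n_wild_type,n_mutant observed counts.
#' @param ratio c(a, b) expected wild-type:mutant ratio.
#' @return list with `statistic`, `df` and `p`.
#' @export
chi_square_ratio_fit <- function(n_wild_type, n_mutant, ratio = c(3, 1)) {
  if (n_wild_type < 0 || n_mutant < 0)
    stop("chi_square_ratio_fit: counts must be non-negative")
  total <- n_wild_type + n_mutant
  if (total == 0)
    stop("chi_square_ratio_fit: no observations")
  expected <- total * ratio / sum(ratio)
  stat <- sum((c(n_wild_type, n_mutant) - expected)^2 / expected)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

GENO_ALIASES <- c(AA = "hom_alt", GA = "het", AG = "het", GG = "hom_ref",
                  hom_alt = "hom_alt", het = "het", hom_ref = "hom_ref")
PHENO_ALIASES <- c(msd = "mutant", mutant = "mutant", WT = "wild_type",
                   wild_type = "wild_type")

#' Genotype-phenotype co-segregation report
#'
#' Builds the 3x2 segregation table, collapses it to 2x2 (hom_alt
#' versus het + hom_ref, since the trait is recessive) for the Fisher
#' exact test, tests the phenotype ratio against 3:1, and flags
#' perfect co-segregation (phenotype mutant exactly when genotype is
#' hom_alt, for every plant).
#'
#' @param geno_pheno data.frame with one row per plant: columns
#'   genotype (AA/GA/AG/GG or hom_alt/het/hom_ref) and phenotype
#'   (msd/mutant or WT/wild_type).
#' @param ratio expected wild-type:mutant ratio.
#' @return list with `table` (3x2 counts), `fisher_p`, `ratio_fit`
#'   and `perfect_cosegregation`.
#' @export
cosegregation_report <- function(geno_pheno, ratio = c(3, 1)) {
  geno <- GENO_ALIASES[as.character(geno_pheno$genotype)]
  pheno <- PHENO_ALIASES[as.character(geno_pheno$phenotype)]
  bad <- which(is.na(geno) | is.na(pheno))
  if (length(bad))
    stop("cosegregation_report: unrecognised genotype/phenotype in ",
         "row(s) ", paste(bad, collapse = ", "))
  tab <- table(factor(geno, levels = c("hom_alt", "het", "hom_ref")),
               factor(pheno, levels = c("mutant", "wild_type")))
  two <- rbind(hom_alt = tab["hom_alt", ],
               other = tab["het", ] + tab["hom_ref", ])
  fit <- chi_square_ratio_fit(sum(pheno == "wild_type"),
                              sum(pheno == "mutant"), ratio)
  list(table = tab,
       fisher_p = fisher_exact_2x2(two),
       ratio_fit = fit,
       perfect_cosegregation = all((geno == "hom_alt") ==
                                     (pheno == "mutant")))
}
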