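#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of
#' drawing at least k annotated genes in a sample of n from a universe
#' of N containing K annotated genes. Computed as a log-space sum of
#' `lchoose` terms for numerical safety at genome-scale N.
#'
#' @param k observed annotated genes in the sample (>= 0).
#' @param K annotated genes in the universe.
#' @param n sample size.
#' @param N universe size.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k > min(K, n))
    stop("hypergeom_upper_tail: k exceeds min(K, n)")
  if (k == 0) return(1)
  x <- k:min(K, n)
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Benjamini-Yekutieli adjustment (FDR under dependency)
#'
#' With m p-values and the harmonic factor c(m) = sum_{i=1..m} 1/i,
#' the sorted p-values are adjusted as
#' q_(i) = min_{j >= i} ( p_(j) * m * c(m) / j ), capped at 1 and
#' returned in the original order.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted values, same order.
#' @export
benjamini_yekutieli <- function(pvalues) {
  m <- length(pvalues)
  if (m == 0L) return(numeric(0))
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  cm <- sum(1 / seq_len(m))
  o <- order(pvalues)
  q <- pvalues[o] * m * cm / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' GO over-representation analysis of a candidate gene set
#'
#' Singular enrichment: for every term represented in the candidate
#' set (k >= 1), the hypergeometric upper-tail probability of its
#' candidate count against the background universe, with
#' Benjamini-Yekutieli adjustment across all tested terms. Rows are
#' sorted by p ascending, ties by term id.
#'
#' @param candidates candidate gene ids (must all be in `background`).
#' @param background background gene universe (e.g. the expressed
#'   genes).
#' @param annotations data.frame with columns gene_id, term_id and
#'   optionally description.
#' @param alpha significance level for the `significant` flag
#'   (applied to the raw p, agriGO-style singular enrichment).
#' @return data.frame (term_id, description, k, K, n, N, p, fdr,
#'   significant).
#' @export
go_enrichment <- function(candidates, background, annotations,
                          alpha = 0.01) {
  missing <- setdiff(candidates, background)
  if (length(missing))
    stop("go_enrichment: candidate gene(s) absent from background: ",
         paste(utils::head(missing, 5), collapse = ", "))
  empty <- data.frame(term_id = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), fdr = numeric(0),
                      significant = logical(0))
  if (nrow(annotations) == 0L) return(empty)
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- ann[!duplicated(paste(ann$gene_id, ann$term_id)), , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  desc <- if ("description" %in% names(ann))
    tapply(ann$description, ann$term_id, `[`, 1) else NULL
  K_all <- table(ann$term_id)
  in_cand <- ann[ann$gene_id %in% candidates, , drop = FALSE]
  if (nrow(in_cand) == 0L) return(empty)
  k_all <- table(in_cand$term_id)
  terms <- names(k_all)
  n <- length(candidates); N <- length(background)
  p <- vapply(terms, function(t)
    hypergeom_upper_tail(k_all[[t]], K_all[[t]], n, N), numeric(1))
  out <- data.frame(term_id = terms,
                    description = if (is.null(desc)) NA_character_
                      else as.character(desc[terms]),
                    k = as.integer(k_all[terms]),
                    K = as.integer(K_all[terms]),
                    n = n, N = N, p = unname(p),
                    fdr = benjamini_yekutieli(unname(p)),
                    stringsAsFactors = FALSE)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
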