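## Hypergeometric over-representation of flat term annotations within a
## protein subset against the quantified background.

#' Term over-representation by the hypergeometric test
#'
#' For each term, counts annotated proteins in the background (`K`) and in
#' the subset (`k`) and computes the upper-tail hypergeometric probability
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' background size and `n` the subset size — the chance of observing at
#' least as many annotated proteins in a random subset of size `n`.
#' Benjamini-Hochberg adjustment is applied across all tested terms.
#' Annotations carrying excluded evidence codes (by default IEA, inferred
#' from electronic annotation) are removed before counting; annotations to
#' proteins outside the background are ignored; terms with no background
#' annotation after filtering are skipped and do not count toward the BH
#' family size.
#'
#' @param subset Character vector of subset accessions; must be contained in
#'   `background`.
#' @param background Character vector of background accessions (the full
#'   quantified set).
#' @param annotations Data.frame from [read_term_annotations()].
#' @param exclude_evidence Evidence codes to drop (default `"IEA"`).
#' @param alpha FDR threshold for the `significant` flag (default 0.05).
#' @return Data.frame sorted by fdr then p: `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p_value`, `fdr`, `significant`.
#' @export
enrich <- function(subset, background, annotations,
                   exclude_evidence = "IEA", alpha = 0.05) {
  subset <- unique(subset)
  background <- unique(background)
  outside <- setdiff(subset, background)
  if (length(outside))
    .dp_stop("subset protein(s) not in background: ",
             paste(utils::head(outside, 10), collapse = ", "))
  ann <- annotations[!(annotations$evidence_code %in% exclude_evidence), ,
                     drop = FALSE]
  ann <- ann[ann$accession %in% background, , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("term_id", "accession")]), , drop = FALSE]
  if (!nrow(ann))
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0), fdr = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  N <- length(background)
  n <- length(subset)
  terms <- unique(ann[, c("term_id", "term_name")])
  K <- vapply(terms$term_id, function(t)
    sum(ann$term_id == t), integer(1))
  k <- vapply(terms$term_id, function(t)
    sum(ann$accession[ann$term_id == t] %in% subset), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term_id, term_name = terms$term_name,
                    k = k, K = K, n = n, N = N, p_value = p,
                    fdr = bh_adjust(p), stringsAsFactors = FALSE,
                    row.names = NULL)
  out$significant <- out$fdr < alpha
  out[order(out$fdr, out$p_value, out$term_id), , drop = FALSE]
}
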