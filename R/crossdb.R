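## Concordance categorisation of treatment results against a
## disease-vs-control reference list.

#' Categorise proteins by treatment direction versus a reference list
#'
#' Each quantified protein is assigned a treatment state from the discovery
#' results — increased (fdr below the threshold and median log2 FC > 0),
#' decreased (fdr below the threshold and FC < 0), otherwise unchanged —
#' and a reference state from the disease-vs-control list (increased,
#' decreased, unchanged, or absent). The joint state maps to exactly one of
#' six categories:
#' \itemize{
#'   \item \code{opposite}: changed in both, in opposing directions;
#'   \item \code{equal}: changed in both, in the same direction;
#'   \item \code{treatment_only}: changed under treatment, unchanged in the
#'     reference;
#'   \item \code{disease_only}: unchanged under treatment, changed in the
#'     reference;
#'   \item \code{not_changed}: unchanged in both;
#'   \item \code{unmatched}: absent from the reference list.
#' }
#' Proteins whose paired differences had zero variance (undefined p-value)
#' are classified by the sign of their median fold change: identical
#' nonzero differences in every patient are unambiguous evidence of change
#' even though the t-statistic is undefined.
#'
#' @param records Differential table from [run_discovery()] (needs
#'   `accession`, `median_log2_fc`, `fdr`, `undefined`).
#' @param reference Reference list from [read_reference_diffset()].
#' @param discovery_fdr Significance threshold on the adjusted p (default
#'   0.01).
#' @return List with `assignments` (accession, treatment_state,
#'   reference_state, category), `summary` (named category counts) and
#'   `reference_only` (reference accessions never quantified in the
#'   treatment data).
#' @export
categorize <- function(records, reference, discovery_fdr = 0.01) {
  changed <- (!is.na(records$fdr) & records$fdr < discovery_fdr) |
    (records$undefined & records$median_log2_fc != 0 & records$n_pairs >= 2)
  treatment_state <- ifelse(changed & records$median_log2_fc > 0, "increased",
                     ifelse(changed & records$median_log2_fc < 0, "decreased",
                            "unchanged"))
  idx <- match(records$accession, reference$accession)
  reference_state <- ifelse(is.na(idx), "absent", reference$direction[idx])
  category <- mapply(.concordance_category, treatment_state, reference_state,
                     USE.NAMES = FALSE)
  assignments <- data.frame(accession = records$accession,
                            treatment_state = treatment_state,
                            reference_state = reference_state,
                            category = category, stringsAsFactors = FALSE)
  cats <- c("opposite", "equal", "treatment_only", "disease_only",
            "not_changed", "unmatched")
  summary <- vapply(cats, function(cc) sum(category == cc), integer(1))
  list(assignments = assignments, summary = as.list(summary),
       reference_only = setdiff(reference$accession, records$accession))
}

.concordance_category <- function(treat, ref) {
  if (ref == "absent") return("unmatched")
  t_ch <- treat != "unchanged"
  r_ch <- ref != "unchanged"
  if (t_ch && r_ch) {
    if (treat == ref) "equal" else "opposite"
  } else if (t_ch) "treatment_only"
  else if (r_ch) "disease_only"
  else "not_changed"
}

#' Contingency table of treatment versus reference state
#'
#' @param assignments Assignment table from [categorize()].
#' @return 3x4 integer table (treatment state x reference state).
#' @export
concordance_contingency <- function(assignments) {
  table(factor(assignments$treatment_state,
               levels = c("increased", "decreased", "unchanged")),
        factor(assignments$reference_state,
               levels = c("increased", "decreased", "unchanged", "absent")))
}
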