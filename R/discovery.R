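## Discovery-stage statistics: identification filters, per-patient paired
## log2 fold changes, median FC + percent concordance, paired t-tests with
## Benjamini-Hochberg correction, immunoglobulin keyword handling, z-score
## fold-change cutoff and verification-candidate selection.

#' Filter a protein table on identification flags and pair coverage
#'
#' Removes proteins flagged as potential contaminant, decoy (reverse) or
#' "only identified by site", then removes proteins quantified in fewer than
#' `min_pairs` complete patient pairs (both baseline and follow-up present).
#'
#' @param pq A `protein_quant` object.
#' @param manifest Validated sample manifest.
#' @param min_pairs Minimum number of complete pairs to retain a protein.
#' @return The filtered `protein_quant` with a `filter_report` attribute
#'   listing counts at each step (`n_input`, `n_after_flags`,
#'   `n_after_min_pairs`).
#' @export
filter_proteins <- function(pq, manifest, min_pairs = 2) {
  p <- pq$proteins
  n_input <- nrow(p)
  keep_flags <- !(p$reverse | p$contaminant | p$only_by_site)
  pq1 <- new_protein_quant(p[keep_flags, , drop = FALSE],
                           pq$intensity[keep_flags, , drop = FALSE])
  n_after_flags <- nrow(pq1$proteins)
  npairs <- count_complete_pairs(pq1, manifest)
  keep_pairs <- npairs >= min_pairs
  out <- new_protein_quant(pq1$proteins[keep_pairs, , drop = FALSE],
                           pq1$intensity[keep_pairs, , drop = FALSE])
  if (!nrow(out$proteins)) .dp_log("no proteins survive filtering")
  attr(out, "filter_report") <- list(
    n_input = n_input, n_after_flags = n_after_flags,
    n_after_min_pairs = nrow(out$proteins), min_pairs = min_pairs)
  out
}

count_complete_pairs <- function(pq, manifest) {
  pairs <- manifest_pairs(manifest)
  b <- pq$intensity[, pairs$baseline, drop = FALSE]
  f <- pq$intensity[, pairs$followup, drop = FALSE]
  rowSums(!is.na(b) & !is.na(f))
}

#' Per-patient paired log2 fold changes
#'
#' For each protein and patient with both samples quantified, computes
#' `log2(followup) - log2(baseline)`; treatment-decreased proteins therefore
#' have negative fold changes. Missing pairs are dropped per protein
#' (pairwise-complete), not imputed.
#'
#' @param pq A (filtered) `protein_quant`.
#' @param manifest Validated sample manifest.
#' @return List with `fc` (proteins x patients matrix of log2 FCs, `NA`
#'   where either member of the pair is missing), `n_pairs` and `pct_blanks`
#'   (percent of patients with at least one missing value of the pair).
#' @export
paired_fold_changes <- function(pq, manifest) {
  pairs <- manifest_pairs(manifest)
  b <- pq$intensity[, pairs$baseline, drop = FALSE]
  f <- pq$intensity[, pairs$followup, drop = FALSE]
  if (any(b <= 0, na.rm = TRUE) || any(f <= 0, na.rm = TRUE))
    .dp_stop("nonpositive intensities present; zeros must be encoded missing")
  fc <- log2(f) - log2(b)
  colnames(fc) <- pairs$patient_id
  n_pairs <- rowSums(!is.na(fc))
  pct_blanks <- 100 * rowMeans(is.na(b) | is.na(f))
  list(fc = fc, n_pairs = n_pairs, pct_blanks = pct_blanks)
}

#' Median fold change and percent concordance of one FC vector
#'
#' The median of the available per-patient log2 fold changes summarises the
#' abundance change; `pct_changed` is the percentage of available fold
#' changes whose sign matches the median's sign (zero FCs count toward
#' neither sign). When the median is exactly zero the larger sign fraction
#' is reported.
#'
#' @param fc Numeric vector of per-patient log2 FCs (`NA` allowed).
#' @return List with `median_log2_fc`, `pct_changed`, `n_pairs`.
#' @export
summarize_fc <- function(fc) {
  fc <- fc[!is.na(fc)]
  if (!length(fc)) .dp_stop("no fold changes available")
  med <- stats::median(fc)
  n_pos <- sum(fc > 0)
  n_neg <- sum(fc < 0)
  pct <- if (med > 0) 100 * n_pos / length(fc)
  else if (med < 0) 100 * n_neg / length(fc)
  else 100 * max(n_pos, n_neg) / length(fc)
  list(median_log2_fc = med, pct_changed = pct, n_pairs = length(fc))
}

#' Paired t-tests with Benjamini-Hochberg correction across proteins
#'
#' Two-sided paired t-test on log2 intensities restricted to complete pairs,
#' per protein, followed by BH adjustment across all tested proteins.
#' Proteins with fewer than two complete pairs or zero variance of the
#' paired differences get an undefined p-value, are flagged, and are
#' excluded from the BH family size.
#'
#' @param pq A (filtered) `protein_quant`.
#' @param manifest Validated sample manifest.
#' @return Data.frame with `accession`, `n_pairs`, `t_stat`, `p_value`,
#'   `fdr`, `undefined` (logical flag).
#' @export
paired_test <- function(pq, manifest) {
  fcs <- paired_fold_changes(pq, manifest)
  d <- fcs$fc  # paired differences on the log2 scale
  n <- fcs$n_pairs
  m_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
  t_stat <- ifelse(n >= 2 & sd_d > 0, m_d / (sd_d / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  undefined <- is.na(p)
  fdr <- bh_adjust(p)
  data.frame(accession = pq$proteins$accession, n_pairs = n,
             t_stat = t_stat, p_value = p, fdr = fdr, undefined = undefined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment excluding undefined p-values
#'
#' Undefined (`NA`) p-values are excluded from the family size `m` and stay
#' `NA` in the output.
#'
#' @param p Numeric vector of p-values with possible `NA`s.
#' @return Adjusted p-values (same length, `NA` preserved).
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Flag immunoglobulin-class proteins by UniProt keyword
#'
#' @param accessions Character vector of accessions.
#' @param keyword_map Data.frame (`accession`, `keyword`) from
#'   [read_keyword_map()].
#' @param ig_keyword Keyword id(s)/name(s) identifying the class; default
#'   the UniProt Immunoglobulin keyword `KW-1280` (or its name).
#' @return Logical vector parallel to `accessions`.
#' @export
flag_immunoglobulins <- function(accessions, keyword_map,
                                 ig_keyword = c("KW-1280", "Immunoglobulin")) {
  ig_acc <- unique(keyword_map$accession[keyword_map$keyword %in% ig_keyword])
  accessions %in% ig_acc
}

#' z-score fold-change cutoff relative to the non-immunoglobulin distribution
#'
#' The mean and (sample) standard deviation of the median log2 fold changes
#' are estimated over non-immunoglobulin proteins only, because the
#' coherently shifted immunoglobulin class distorts the FC distribution.
#' Every protein (including immunoglobulins) is then scored against that
#' reference: `z_p` is the two-sided normal tail probability of its median
#' FC, and `high_fc` flags proteins with `z_p` strictly below `alpha_z`.
#'
#' @param median_fc Numeric vector of per-protein median log2 FCs.
#' @param is_ig Logical vector flagging immunoglobulin-class proteins.
#' @param alpha_z Two-sided tail cutoff (default 0.05).
#' @return Data.frame with `z`, `z_p`, `high_fc`.
#' @export
zscore_fc_flag <- function(median_fc, is_ig, alpha_z = 0.05) {
  ref <- median_fc[!is_ig & !is.na(median_fc)]
  if (length(ref) < 3) .dp_stop("need >= 3 non-immunoglobulin median FCs")
  s <- stats::sd(ref)
  if (s == 0) .dp_stop("zero spread in non-immunoglobulin median FCs")
  z <- (median_fc - mean(ref)) / s
  z_p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(z = z, z_p = z_p, high_fc = !is.na(z_p) & z_p < alpha_z)
}

#' Assemble the per-protein differential table for a paired cohort
#'
#' Runs the full discovery chain: flag/coverage filtering, per-patient
#' paired fold changes, median FC and percent concordance, paired t-test
#' with BH correction, immunoglobulin flagging and the z-score fold-change
#' cutoff (estimated after excluding immunoglobulins).
#'
#' @param pq A `protein_quant` (unfiltered).
#' @param manifest Validated sample manifest.
#' @param keyword_map Keyword map data.frame.
#' @param config Pipeline config (see [default_config()]).
#' @return Data.frame of differential records (one row per retained
#'   protein): accession, gene_name, n_pairs, pct_blanks, median_log2_fc,
#'   pct_changed, t_stat, p_value, fdr, undefined, is_immunoglobulin, z,
#'   z_p, significant, high_fc, candidate, neg_log10_p. The filter report is
#'   attached as attribute `filter_report`.
#' @export
run_discovery <- function(pq, manifest, keyword_map, config = default_config()) {
  flt <- filter_proteins(pq, manifest, min_pairs = config$min_pairs)
  report <- attr(flt, "filter_report")
  fcs <- paired_fold_changes(flt, manifest)
  summ <- apply(fcs$fc, 1, function(v) unlist(summarize_fc(v)))
  tt <- paired_test(flt, manifest)
  is_ig <- flag_immunoglobulins(flt$proteins$accession, keyword_map,
                                ig_keyword = config$ig_keyword)
  zz <- zscore_fc_flag(summ["median_log2_fc", ], is_ig, alpha_z = config$z_alpha)
  rec <- data.frame(
    accession = flt$proteins$accession,
    gene_name = flt$proteins$gene_name,
    n_pairs = fcs$n_pairs,
    pct_blanks = fcs$pct_blanks,
    median_log2_fc = summ["median_log2_fc", ],
    pct_changed = summ["pct_changed", ],
    t_stat = tt$t_stat, p_value = tt$p_value, fdr = tt$fdr,
    undefined = tt$undefined,
    is_immunoglobulin = is_ig,
    z = zz$z, z_p = zz$z_p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  rec$significant <- !is.na(rec$fdr) & rec$fdr < config$discovery_fdr
  rec$high_fc <- zz$high_fc
  rec$candidate <- select_candidates(rec, config = config)
  rec$neg_log10_p <- -log10(rec$p_value)
  attr(rec, "filter_report") <- report
  attr(rec, "fc_matrix") <- fcs$fc
  rec
}

#' Select verification candidates
#'
#' A protein is a candidate for targeted verification when it meets all
#' three discovery criteria: statistical significance (`fdr <
#' discovery_fdr`), extreme fold change (`z_p < z_alpha`), and concordance
#' across patients (`pct_changed > concordance_pct`, strictly). Proteins of
#' special interest can be force-included via `config$force_include`.
#'
#' @param records Differential table (needs `fdr`, `z_p`, `pct_changed`,
#'   `accession` columns).
#' @param config Pipeline config.
#' @return Logical candidate flag per record.
#' @export
select_candidates <- function(records, config = default_config()) {
  cand <- !is.na(records$fdr) & records$fdr < config$discovery_fdr &
    !is.na(records$z_p) & records$z_p < config$z_alpha &
    records$pct_changed > config$concordance_pct
  cand | records$accession %in% config$force_include
}

#' Prescreen discovery peptides for targeted-assay suitability
#'
#' Peptide intensities are log2-transformed and median-centred per sample,
#' then tested with a paired t-test (p < `p_cutoff`). Peptides containing
#' cysteine or methionine, or flagged with known modifications, are
#' excluded (residues prone to chemical modification make unreliable
#' standards); an `allow` list can override the residue rule for peptides of
#' special interest. Eligible peptides are ranked by mean intensity, then p.
#'
#' @param peptide_table Data.frame with `peptide_sequence`, `accession`, and
#'   one intensity column per sample (named by sample id), optionally a
#'   logical `modified` column.
#' @param manifest Validated sample manifest.
#' @param p_cutoff Paired-t p-value threshold (default 0.05).
#' @param allow Peptide sequences exempt from the residue/modification rule.
#' @return Data.frame of eligible peptides sorted by rank, with columns
#'   `peptide_sequence`, `accession`, `mean_log2_intensity`, `p_value`,
#'   `excluded_residue` for the full input (ineligible rows dropped).
#' @export
peptide_prescreen <- function(peptide_table, manifest, p_cutoff = 0.05,
                              allow = character(0)) {
  samp <- manifest$sample_id
  miss <- setdiff(samp, names(peptide_table))
  if (length(miss))
    .dp_stop("peptide table lacks sample column(s): ", paste(miss, collapse = ", "))
  m <- log2(as.matrix(peptide_table[, samp, drop = FALSE]))
  m <- sweep(m, 2, apply(m, 2, stats::median, na.rm = TRUE))  # per-sample centring
  pairs <- manifest_pairs(manifest)
  d <- m[, pairs$followup, drop = FALSE] - m[, pairs$baseline, drop = FALSE]
  n <- rowSums(!is.na(d))
  sd_d <- apply(d, 1, stats::sd, na.rm = TRUE)
  t_stat <- ifelse(n >= 2 & sd_d > 0,
                   rowMeans(d, na.rm = TRUE) / (sd_d / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(t_stat), df = n - 1, lower.tail = FALSE)
  bad_residue <- grepl("[CM]", peptide_table$peptide_sequence) &
    !peptide_table$peptide_sequence %in% allow
  modified <- if ("modified" %in% names(peptide_table))
    peptide_table$modified else FALSE
  out <- data.frame(peptide_sequence = peptide_table$peptide_sequence,
                    accession = peptide_table$accession,
                    mean_log2_intensity = rowMeans(m, na.rm = TRUE),
                    p_value = p,
                    excluded_residue = bad_residue,
                    stringsAsFactors = FALSE)
  keep <- !bad_residue & !modified & !is.na(p) & p < p_cutoff
  out <- out[keep, , drop = FALSE]
  out[order(-out$mean_log2_intensity, out$p_value), , drop = FALSE]
}

#' Percentile bootstrap confidence interval of the median
#'
#' Seeded percentile bootstrap of the median of a numeric vector. The
#' interval method for the median fold change is a package convention (no
#' canonical method is implied by the summary statistic itself).
#'
#' @param x Numeric vector (NAs dropped).
#' @param conf Confidence level (default 0.95).
#' @param n_boot Bootstrap draws (default 10000).
#' @param seed Integer seed.
#' @return Numeric `c(lower, upper)`.
#' @export
boot_median_ci <- function(x, conf = 0.95, n_boot = 10000, seed = 1L) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(c(NA_real_, NA_real_))
  .with_seed(seed, {
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(x, replace = TRUE)), numeric(1))
    unname(stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  })
}
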