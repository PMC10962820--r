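# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, enumeration, closed forms) so they share no
# code path with the implementation they check.

oracle_median <- function(x) {
  x <- sort(unname(x[!is.na(x)]))
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_pct_changed <- function(fc) {
  fc <- fc[!is.na(fc)]
  med <- oracle_median(fc)
  n_pos <- 0; n_neg <- 0
  for (v in fc) {
    if (v > 0) n_pos <- n_pos + 1
    if (v < 0) n_neg <- n_neg + 1
  }
  if (med > 0) 100 * n_pos / length(fc)
  else if (med < 0) 100 * n_neg / length(fc)
  else 100 * max(n_pos, n_neg) / length(fc)
}

# closed-form paired t: mean(d) / (sd(d)/sqrt(n)), two-sided p
oracle_paired_t <- function(before, after) {
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  n <- length(d)
  s <- sqrt(sum((d - mean(d))^2) / (n - 1))
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# hand step-up BH with explicit monotonicity pass
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- p[o[i]] * m / i
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# exact upper-tail hypergeometric by combinatorial enumeration
oracle_hyper_p <- function(k, K, n, N) {
  tot <- choose(N, n)
  p <- 0
  for (i in k:min(K, n)) p <- p + choose(K, i) * choose(N - K, n - i) / tot
  p
}

# weighted least squares by the closed-form normal equations
oracle_wls <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  b <- (sw * sxy - sx * sy) / (sw * sxx - sx * sx)
  a <- (sy - b * sx) / sw
  c(intercept = a, slope = b)
}

# --- fixture builders -------------------------------------------------------

make_manifest <- function(n_patients) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  data.frame(patient_id = rep(pid, each = 2),
             sample_id = as.vector(rbind(paste0(pid, "_B"), paste0(pid, "_F"))),
             timepoint = rep(c("baseline", "followup"), n_patients),
             stringsAsFactors = FALSE)
}

# protein_quant from a plain intensity matrix (rows = proteins)
make_quant <- function(intensity, reverse = FALSE, contaminant = FALSE,
                       only_by_site = FALSE) {
  ng <- nrow(intensity)
  proteins <- data.frame(
    accession = sprintf("ACC%03d", seq_len(ng)),
    gene_name = sprintf("G%03d", seq_len(ng)),
    unique_peptides = 2L,
    reverse = rep_len(reverse, ng),
    contaminant = rep_len(contaminant, ng),
    only_by_site = rep_len(only_by_site, ng),
    stringsAsFactors = FALSE)
  new_protein_quant(proteins, intensity)
}

write_protein_fixture <- function(path, manifest, intensity,
                                  accession = sprintf("ACC%03d", seq_len(nrow(intensity))),
                                  reverse = "", contaminant = "", site = "") {
  ng <- nrow(intensity)
  df <- data.frame(accession, sprintf("G%03d", seq_len(ng)), 2L,
                   rep_len(reverse, ng), rep_len(contaminant, ng),
                   rep_len(site, ng),
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("Majority protein IDs", "Gene names", "Unique peptides",
                 "Reverse", "Potential contaminant", "Only identified by site")
  m <- intensity
  colnames(m) <- paste0("LFQ intensity ", manifest$sample_id)
  utils::write.table(cbind(df, as.data.frame(m, check.names = FALSE)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

make_prm_rows <- function(peptide = "PEPTIDEK", sample = "S1", replicate = "rep1",
                          n_fragments = 4, light = 100, heavy = 50,
                          points = 10L, ppm = 0, truncated = FALSE) {
  data.frame(peptide_sequence = peptide, sample_id = sample,
             replicate_id = replicate,
             fragment_id = paste0("y", 3 + seq_len(n_fragments)),
             light_area = rep_len(light, n_fragments),
             heavy_area = rep_len(heavy, n_fragments),
             points_across_peak = as.integer(rep_len(points, n_fragments)),
             mass_error_ppm = rep_len(ppm, n_fragments),
             truncated = rep_len(truncated, n_fragments),
             stringsAsFactors = FALSE)
}

single_peptide_design <- function(spike_amount = 1, sample_conversion = 1,
                                  peptide = "PEPTIDEK") {
  spike_design(data.frame(peptide_sequence = peptide,
                          spike_amount = spike_amount,
                          sample_conversion = sample_conversion,
                          stringsAsFactors = FALSE),
               default_dilution_series())
}
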