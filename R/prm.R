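## PRM verification workflow: transition-level peak QC, weighted reverse
## calibration curves, linear-range / LOQ filtering, concentration
## computation with replicate handling, and paired verification statistics.

#' Quality-control PRM peak measurements
#'
#' Fragment rows with absolute mass error above `max_ppm` are dropped. A
#' measurement (one peptide x sample x replicate) is kept only if at least
#' `min_fragments` fragments survive and every surviving fragment has at
#' least `min_points` points across the chromatographic peak. The ratio to
#' standard of a kept measurement is the sum of surviving light areas over
#' the sum of surviving heavy areas. When one replicate of a sample has a
#' truncated peak and its sibling does not, the non-truncated replicate is
#' considered representative and the truncated one is discarded.
#'
#' @param rows Data.frame from [read_prm_export()].
#' @param min_fragments Minimum surviving fragments per measurement.
#' @param min_points Minimum points across the peak.
#' @param max_ppm Maximum absolute fragment mass error (ppm).
#' @return List with `accepted` (peptide_sequence, sample_id, replicate_id,
#'   ratio_to_standard, n_fragments, truncated) and `report` (counts dropped
#'   by each rule, including invalid zero-heavy measurements).
#' @export
qc_peaks <- function(rows, min_fragments = 3, min_points = 8, max_ppm = 10) {
  ppm_ok <- abs(rows$mass_error_ppm) <= max_ppm
  n_frag_dropped <- sum(!ppm_ok)
  surv <- rows[ppm_ok, , drop = FALSE]
  key <- interaction(surv$peptide_sequence, surv$sample_id, surv$replicate_id,
                     drop = TRUE, sep = "\r")
  groups <- split(surv, key)
  acc <- lapply(groups, function(g) {
    if (nrow(g) < min_fragments) return(NULL)
    if (min(g$points_across_peak) < min_points) return(NULL)
    heavy <- sum(g$heavy_area)
    data.frame(peptide_sequence = g$peptide_sequence[1],
               sample_id = g$sample_id[1],
               replicate_id = g$replicate_id[1],
               ratio_to_standard = if (heavy > 0) sum(g$light_area) / heavy
                                   else NA_real_,
               n_fragments = nrow(g),
               truncated = any(g$truncated),
               stringsAsFactors = FALSE)
  })
  acc <- do.call(rbind, acc[!vapply(acc, is.null, logical(1))])
  n_meas_total <- length(groups)
  n_invalid <- if (is.null(acc)) 0L else sum(is.na(acc$ratio_to_standard))
  if (!is.null(acc)) acc <- acc[!is.na(acc$ratio_to_standard), , drop = FALSE]
  n_trunc_dropped <- 0L
  if (!is.null(acc) && nrow(acc)) {
    sk <- interaction(acc$peptide_sequence, acc$sample_id, drop = TRUE, sep = "\r")
    drop <- unlist(lapply(split(seq_len(nrow(acc)), sk), function(ix) {
      tr <- acc$truncated[ix]
      if (any(tr) && any(!tr)) ix[tr] else integer(0)
    }))
    n_trunc_dropped <- length(drop)
    if (n_trunc_dropped) acc <- acc[-drop, , drop = FALSE]
    rownames(acc) <- NULL
  }
  if (is.null(acc))
    acc <- data.frame(peptide_sequence = character(0), sample_id = character(0),
                      replicate_id = character(0), ratio_to_standard = numeric(0),
                      n_fragments = integer(0), truncated = logical(0),
                      stringsAsFactors = FALSE)
  list(accepted = acc,
       report = list(n_fragment_rows = nrow(rows),
                     n_fragments_dropped_ppm = n_frag_dropped,
                     n_measurements = n_meas_total,
                     n_measurements_kept = nrow(acc),
                     n_invalid_zero_heavy = n_invalid,
                     n_truncated_replicates_dropped = n_trunc_dropped))
}

#' Fit a weighted calibration line for one peptide
#'
#' Weighted least squares of the ratio to standard on the theoretical
#' concentration (fmol/ul injected) with weights `1/theoretical_conc`,
#' down-weighting the more variable high-concentration points. With
#' `invert_ratio = TRUE` the response is inverted (`1/ratio`) before
#' fitting, for exports whose ratio decreases with the spiked
#' concentration.
#'
#' @param points Calibration points for a single peptide: data.frame with
#'   `theoretical_conc` (> 0) and `ratio_to_standard` columns.
#' @param invert_ratio Invert the response before fitting.
#' @return A `calibration_curve`: list with `peptide`, `slope`, `intercept`,
#'   `weight_rule`, `r_squared_weighted`, `points_used`, `invert_ratio`,
#'   `linear_range` (`NULL` until [determine_linear_range()] is applied).
#' @export
fit_calibration <- function(points, invert_ratio = FALSE) {
  if (nrow(points) < 3) .dp_stop("need at least 3 calibration points")
  if (any(points$theoretical_conc <= 0))
    .dp_stop("theoretical concentrations must be positive")
  x <- points$theoretical_conc
  if (length(unique(x)) < 2) .dp_stop("all calibration concentrations identical")
  y <- if (invert_ratio) 1 / points$ratio_to_standard else points$ratio_to_standard
  w <- 1 / x
  fit <- stats::lm(y ~ x, weights = w)
  mw <- sum(w * y) / sum(w)
  r2w <- 1 - sum(w * stats::residuals(fit)^2) / sum(w * (y - mw)^2)
  structure(list(
    peptide = if (!is.null(points$peptide_sequence)) points$peptide_sequence[1]
              else NA_character_,
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    weight_rule = "1/theoretical_conc",
    r_squared_weighted = r2w,
    points_used = nrow(points),
    invert_ratio = invert_ratio,
    linear_range = NULL
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("calibration_curve", if (!is.na(x$peptide)) paste0("[", x$peptide, "]"),
      ": ratio =", signif(x$intercept, 4), "+", signif(x$slope, 4),
      "* conc (w = 1/conc, R2w =", signif(x$r_squared_weighted, 4), ")\n")
  if (!is.null(x$linear_range))
    cat("  linear range:", signif(x$linear_range[1], 4), "-",
        signif(x$linear_range[2], 4), "fmol/ul injected\n")
  invisible(x)
}

#' Determine the linear range of a calibration curve
#'
#' Automated surrogate for visual inspection of the low-concentration end:
#' starting from the full series, the lowest concentration level is retained
#' such that, refitting the weighted line on points at or above that level,
#' every retained level's mean back-calculated concentration
#' (`(ratio - intercept) / slope`) is within `rel_bias_tol` relative bias of
#' its theoretical value. The upper bound is the top level. At least three
#' levels must remain.
#'
#' @param points Calibration points for one peptide.
#' @param rel_bias_tol Maximum tolerated relative back-calculation bias per
#'   level (default 0.20).
#' @param invert_ratio Passed to [fit_calibration()].
#' @return The refitted `calibration_curve` with `linear_range` set to
#'   `c(conc_lo, conc_hi)`; errors with "no linear range" if no candidate
#'   lower bound satisfies the tolerance.
#' @export
determine_linear_range <- function(points, rel_bias_tol = 0.20,
                                   invert_ratio = FALSE) {
  levels <- sort(unique(points$theoretical_conc))
  if (length(levels) < 3) .dp_stop("need at least 3 concentration levels")
  for (lo in seq_len(length(levels) - 2)) {
    keep <- points$theoretical_conc >= levels[lo]
    sub <- points[keep, , drop = FALSE]
    curve <- fit_calibration(sub, invert_ratio = invert_ratio)
    if (curve$slope <= 0) next
    y <- if (invert_ratio) 1 / sub$ratio_to_standard else sub$ratio_to_standard
    back <- (y - curve$intercept) / curve$slope
    lv <- sub$theoretical_conc
    bias <- vapply(levels[lo:length(levels)], function(L)
      abs(mean(back[lv == L]) - L) / L, numeric(1))
    if (all(bias <= rel_bias_tol)) {
      curve$linear_range <- c(levels[lo], levels[length(levels)])
      return(curve)
    }
  }
  .dp_stop("no linear range satisfies the back-calculation tolerance")
}

#' Fit calibration curves with linear ranges for all peptides
#'
#' @param points Calibration points for any number of peptides (with a
#'   `peptide_sequence` column).
#' @param rel_bias_tol,invert_ratio See [determine_linear_range()].
#' @return Named list of `calibration_curve` objects (by peptide); peptides
#'   without a valid linear range are dropped with a logged message.
#' @export
calibrate_peptides <- function(points, rel_bias_tol = 0.20,
                               invert_ratio = FALSE) {
  out <- list()
  for (pep in unique(points$peptide_sequence)) {
    sub <- points[points$peptide_sequence == pep, , drop = FALSE]
    curve <- tryCatch(
      determine_linear_range(sub, rel_bias_tol = rel_bias_tol,
                             invert_ratio = invert_ratio),
      deltaprot_error = function(e) {
        .dp_log("peptide ", pep, " dropped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(curve)) out[[pep]] <- curve
  }
  out
}

#' Curves as a tidy table
#'
#' @param curves Named list from [calibrate_peptides()].
#' @return Data.frame with one row per peptide curve.
#' @export
curves_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) data.frame(
    peptide_sequence = cu$peptide, slope = cu$slope, intercept = cu$intercept,
    r_squared_weighted = cu$r_squared_weighted, points_used = cu$points_used,
    conc_lo = cu$linear_range[1], conc_hi = cu$linear_range[2],
    stringsAsFactors = FALSE, row.names = NULL)))
}

#' Compute peptide concentrations from QC-accepted PRM measurements
#'
#' Each measurement's ratio to standard is converted to an injected
#' concentration via the peptide's calibration curve
#' (`(ratio - intercept) / slope`), measurements below the curve's
#' linear-range lower bound are flagged below the limit of quantification
#' and dropped, the remainder are scaled to fmol/ul sample via the spike
#' design's conversion factor and log2-transformed, and trypsinated
#' replicates are averaged. If only one replicate of a sample is valid it
#' is considered representative and used alone.
#'
#' @param measurements Accepted measurements from [qc_peaks()].
#' @param curves Named list of `calibration_curve`s with linear ranges.
#' @param design A [spike_design()].
#' @return Data.frame with one row per (peptide, sample):
#'   `peptide_sequence`, `sample_id`, `log2_conc` (log2 fmol/ul sample, `NA`
#'   when no replicate is quantifiable), `n_replicates_used`, `below_loq`
#'   (all replicates below the linear range).
#' @export
prm_quantify <- function(measurements, curves, design) {
  pepinfo <- design$peptides
  rows <- lapply(unique(measurements$peptide_sequence), function(pep) {
    curve <- curves[[pep]]
    if (is.null(curve)) return(NULL)
    if (curve$slope <= 0) .dp_stop("non-positive calibration slope for ", pep)
    if (is.null(curve$linear_range)) .dp_stop("curve for ", pep, " has no linear range")
    conv <- pepinfo$sample_conversion[match(pep, pepinfo$peptide_sequence)]
    if (is.na(conv)) conv <- 1
    m <- measurements[measurements$peptide_sequence == pep, , drop = FALSE]
    y <- if (curve$invert_ratio) 1 / m$ratio_to_standard else m$ratio_to_standard
    conc_inj <- (y - curve$intercept) / curve$slope
    ok <- conc_inj >= curve$linear_range[1]
    do.call(rbind, lapply(split(seq_len(nrow(m)), m$sample_id), function(ix) {
      valid <- ix[ok[ix] & conc_inj[ix] > 0]
      data.frame(peptide_sequence = pep, sample_id = m$sample_id[ix[1]],
                 log2_conc = if (length(valid))
                   mean(log2(conc_inj[valid] * conv)) else NA_real_,
                 n_replicates_used = length(valid),
                 below_loq = length(valid) == 0,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Paired verification statistics per peptide
#'
#' Per-patient log2 fold changes (follow-up minus baseline) of the
#' quantified peptide concentrations, summarised exactly as in the
#' discovery stage: median log2 FC, percent of patients changed in the
#' median's direction, a two-sided paired t-test and Benjamini-Hochberg
#' adjustment across peptides (threshold `alpha`, default 0.05), plus a
#' seeded percentile-bootstrap confidence interval of the median FC.
#'
#' @param quant Table from [prm_quantify()].
#' @param manifest Validated sample manifest.
#' @param alpha FDR threshold for the `significant` flag.
#' @param conf Confidence level of the bootstrap CI.
#' @param n_boot Bootstrap draws.
#' @param seed Integer seed for the bootstrap.
#' @return Data.frame with one row per peptide with >= 2 complete pairs:
#'   `peptide_sequence`, `n_pairs`, `median_log2_fc`, `ci_lo`, `ci_hi`,
#'   `pct_changed`, `p_value`, `fdr`, `undefined`, `significant`; peptides
#'   with fewer than two pairs are listed in attribute `skipped`.
#' @export
verify_differential <- function(quant, manifest, alpha = 0.05, conf = 0.95,
                                n_boot = 10000, seed = 1L) {
  pairs <- manifest_pairs(manifest)
  peps <- unique(quant$peptide_sequence)
  skipped <- character(0)
  rows <- list()
  for (pep in peps) {
    q <- quant[quant$peptide_sequence == pep, , drop = FALSE]
    lb <- q$log2_conc[match(pairs$baseline, q$sample_id)]
    lf <- q$log2_conc[match(pairs$followup, q$sample_id)]
    d <- lf - lb
    d_ok <- d[!is.na(d)]
    if (length(d_ok) < 2) { skipped <- c(skipped, pep); next }
    s <- summarize_fc(d_ok)
    sd_d <- stats::sd(d_ok)
    t_stat <- if (sd_d > 0) mean(d_ok) / (sd_d / sqrt(length(d_ok))) else NA_real_
    p <- if (!is.na(t_stat))
      2 * stats::pt(abs(t_stat), df = length(d_ok) - 1, lower.tail = FALSE)
    else NA_real_
    ci <- boot_median_ci(d_ok, conf = conf, n_boot = n_boot,
                         seed = seed + match(pep, peps))
    rows[[pep]] <- data.frame(
      peptide_sequence = pep, n_pairs = s$n_pairs,
      median_log2_fc = s$median_log2_fc, ci_lo = ci[1], ci_hi = ci[2],
      pct_changed = s$pct_changed, p_value = p, undefined = is.na(p),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(peptide_sequence = character(0), n_pairs = integer(0),
                      median_log2_fc = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), pct_changed = numeric(0),
                      p_value = numeric(0), undefined = logical(0),
                      stringsAsFactors = FALSE)
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
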