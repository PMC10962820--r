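test_that("peak QC applies the fragment, point and ppm rules", {
  # only 2 fragments survive: measurement rejected
  two <- make_prm_rows(n_fragments = 2)
  expect_equal(nrow(qc_peaks(two)$accepted), 0)

  # points across peak: 7 rejected, 8 kept
  expect_equal(nrow(qc_peaks(make_prm_rows(points = 7))$accepted), 0)
  expect_equal(nrow(qc_peaks(make_prm_rows(points = 8))$accepted), 1)

  # one of four fragments at 12 ppm: ratio over the remaining 3, hand-summed
  rows <- make_prm_rows(n_fragments = 4, light = c(100, 200, 300, 400),
                        heavy = c(50, 60, 70, 80), ppm = c(0, 2, 12, -3))
  out <- qc_peaks(rows)
  expect_equal(out$accepted$n_fragments, 3)
  expect_equal(out$accepted$ratio_to_standard,
               (100 + 200 + 400) / (50 + 60 + 80))
  expect_equal(out$report$n_fragments_dropped_ppm, 1)

  # zero heavy signal: measurement invalid and flagged
  zero <- make_prm_rows(heavy = 0)
  outz <- qc_peaks(zero)
  expect_equal(nrow(outz$accepted), 0)
  expect_equal(outz$report$n_invalid_zero_heavy, 1)
})

test_that("the non-truncated replicate replaces its truncated sibling", {
  rows <- rbind(make_prm_rows(replicate = "rep1", light = 120, truncated = TRUE),
                make_prm_rows(replicate = "rep2", light = 100))
  out <- qc_peaks(rows)
  expect_equal(out$accepted$replicate_id, "rep2")
  expect_equal(out$report$n_truncated_replicates_dropped, 1)

  # both truncated: both retained (no clean sibling to prefer)
  both <- rbind(make_prm_rows(replicate = "rep1", truncated = TRUE),
                make_prm_rows(replicate = "rep2", truncated = TRUE))
  expect_equal(nrow(qc_peaks(both)$accepted), 2)
})

test_that("weighted calibration fit recovers exact and oracle coefficients", {
  pts <- data.frame(theoretical_conc = c(0.1, 0.5, 1, 2, 4),
                    ratio_to_standard = 2 * c(0.1, 0.5, 1, 2, 4))
  cu <- fit_calibration(pts)
  expect_equal(cu$slope, 2)
  expect_equal(cu$intercept, 0, tolerance = 1e-12)
  expect_equal(cu$r_squared_weighted, 1)

  pts3 <- data.frame(theoretical_conc = c(1, 2, 4),
                     ratio_to_standard = c(1.1, 1.9, 4.2))
  cu3 <- fit_calibration(pts3)
  want <- oracle_wls(pts3$theoretical_conc, pts3$ratio_to_standard,
                     1 / pts3$theoretical_conc)
  expect_equal(cu3$slope, unname(want["slope"]), tolerance = 1e-12)
  expect_equal(cu3$intercept, unname(want["intercept"]), tolerance = 1e-12)

  expect_error(fit_calibration(pts3[1:2, ]), "at least 3")
  same <- data.frame(theoretical_conc = c(1, 1, 1), ratio_to_standard = 1:3)
  expect_error(fit_calibration(same), "identical")
})

test_that("weighted fit equals the normal-equation oracle on random point sets", {
  set.seed(77)
  for (iter in 1:50) {
    n <- sample(3:9, 1)
    x <- sort(10^runif(n, -1.5, 1))
    y <- 0.05 + 1.7 * x * exp(rnorm(n, 0, 0.05))
    cu <- fit_calibration(data.frame(theoretical_conc = x, ratio_to_standard = y))
    want <- oracle_wls(x, y, 1 / x)
    expect_equal(cu$slope, unname(want["slope"]), tolerance = 1e-9)
    expect_equal(cu$intercept, unname(want["intercept"]), tolerance = 1e-9)
  }
})

test_that("linear range keeps the full noiseless series and trims saturated levels", {
  d <- single_peptide_design()
  clean <- simulate_calibration(d, slope = 2, intercept = 0.01, cv = 0, seed = 1)
  cu <- determine_linear_range(clean)
  expect_equal(cu$linear_range, c(0.03, 8))

  # saturation drives >20% back-calculated bias into the two lowest levels
  sat <- simulate_calibration(d, slope = 2, intercept = 0, cv = 0,
                              saturation_conc = 0.15, seed = 1)
  cus <- determine_linear_range(sat)
  expect_equal(cus$linear_range[1], 0.12)   # third level from the bottom

  flat <- clean; flat$ratio_to_standard <- 10^rnorm(nrow(flat), 0, 2)
  expect_error(determine_linear_range(flat), "no linear range")
})

test_that("tightening the bias tolerance never widens the linear range", {
  set.seed(88)
  d <- single_peptide_design()
  for (iter in 1:20) {
    pts <- simulate_calibration(d, slope = 1.5, intercept = 0.02, cv = 0.08,
                                saturation_conc = sample(c(0, 0.02, 0.05), 1),
                                seed = iter)
    lo_for <- function(tol) tryCatch(
      determine_linear_range(pts, rel_bias_tol = tol)$linear_range[1],
      error = function(e) Inf)
    los <- vapply(c(0.4, 0.25, 0.15, 0.08), lo_for, numeric(1))
    expect_true(all(diff(los) >= 0))
  }
})

test_that("quantification converts ratios to sample concentrations with LOQ and replicate rules", {
  d <- single_peptide_design(spike_amount = 2, sample_conversion = 3)
  curve <- structure(list(peptide = "PEPTIDEK", slope = 1, intercept = 0,
                          weight_rule = "1/theoretical_conc",
                          r_squared_weighted = 1, points_used = 18,
                          invert_ratio = FALSE, linear_range = c(0.06, 16)),
                     class = "calibration_curve")
  meas <- data.frame(peptide_sequence = "PEPTIDEK",
                     sample_id = c("S1", "S1", "S2", "S2", "S3", "S3"),
                     replicate_id = rep(c("rep1", "rep2"), 3),
                     ratio_to_standard = c(2, 2, 0.01, 4, 0.01, 0.02),
                     stringsAsFactors = FALSE)
  q <- prm_quantify(meas, list(PEPTIDEK = curve), d)
  q <- q[order(q$sample_id), ]
  # S1: ratio at the 1:1 spike level (conc_inj = 2 = spike_amount), x3 to sample
  expect_equal(q$log2_conc[q$sample_id == "S1"], log2(2 * 3))
  # S2: one replicate below LOQ, the valid one used alone
  expect_equal(q$log2_conc[q$sample_id == "S2"], log2(4 * 3))
  expect_equal(q$n_replicates_used[q$sample_id == "S2"], 1)
  # S3: all replicates below the linear range
  expect_true(q$below_loq[q$sample_id == "S3"])
  expect_true(is.na(q$log2_conc[q$sample_id == "S3"]))

  # LOQ filter idempotence: requantifying the surviving measurements changes nothing
  keep <- meas$ratio_to_standard >= 0.06
  q2 <- prm_quantify(meas[keep, ], list(PEPTIDEK = curve), d)
  expect_equal(q2[!q2$below_loq, c("sample_id", "log2_conc")],
               q[!q$below_loq, c("sample_id", "log2_conc")],
               ignore_attr = TRUE)

  bad <- curve; bad$slope <- -1
  expect_error(prm_quantify(meas, list(PEPTIDEK = bad), d), "slope")
})

test_that("doubling the spike amount doubles reported concentrations exactly", {
  meas <- data.frame(peptide_sequence = "PEPTIDEK", sample_id = "S1",
                     replicate_id = "rep1", ratio_to_standard = 1.7,
                     stringsAsFactors = FALSE)
  set.seed(92)
  ratios <- 1 * default_dilution_series() + 0.05 + rnorm(9, 0, 0.01)
  conc_for <- function(spike) {
    # same measured ratios; the nominal spike amount only rescales the x axis
    d <- single_peptide_design(spike_amount = spike)
    pts <- data.frame(peptide_sequence = "PEPTIDEK",
                      theoretical_conc = default_dilution_series() * spike,
                      ratio_to_standard = ratios, stringsAsFactors = FALSE)
    cu <- determine_linear_range(pts)
    2 ^ prm_quantify(meas, list(PEPTIDEK = cu), d)$log2_conc
  }
  expect_equal(conc_for(2), 2 * conc_for(1), tolerance = 1e-9)
})

test_that("verification statistics mirror the discovery stage", {
  # uniform -1 shift, zero noise: median -1, 100% concordant, p undefined
  man <- make_manifest(5)
  quant <- data.frame(peptide_sequence = "AAAK",
                      sample_id = man$sample_id,
                      log2_conc = ifelse(man$timepoint == "followup", 9, 10),
                      stringsAsFactors = FALSE)
  v <- verify_differential(quant, man, n_boot = 200)
  expect_equal(v$median_log2_fc, -1)
  expect_equal(v$pct_changed, 100)
  expect_true(v$undefined)

  # identical matrices through both modules give identical statistics
  set.seed(61)
  m <- 2^matrix(rnorm(3 * 10, 10, 1), nrow = 3,
                dimnames = list(NULL, man$sample_id))
  pq <- make_quant(m)
  rec <- run_discovery(pq, man, data.frame(accession = character(0),
                                           keyword = character(0)))
  quant2 <- do.call(rbind, lapply(1:3, function(i)
    data.frame(peptide_sequence = paste0("PEP", i), sample_id = man$sample_id,
               log2_conc = log2(m[i, ]), stringsAsFactors = FALSE)))
  v2 <- verify_differential(quant2, man, n_boot = 100)
  expect_equal(v2$median_log2_fc, rec$median_log2_fc, ignore_attr = TRUE)
  expect_equal(v2$pct_changed, rec$pct_changed, ignore_attr = TRUE)
  expect_equal(v2$p_value, rec$p_value, ignore_attr = TRUE)
  expect_equal(v2$fdr, rec$fdr, ignore_attr = TRUE)

  # fewer than two pairs: peptide skipped and flagged
  one <- quant[quant$sample_id %in% c("P01_B", "P01_F"), ]
  vs <- verify_differential(one, man, n_boot = 50)
  expect_equal(nrow(vs), 0)
  expect_equal(attr(vs, "skipped"), "AAAK")
})

test_that("true shifts survive the full qc-fit-range-quantify-verify chain", {
  man <- make_manifest(20)
  design <- single_peptide_design(spike_amount = 1, sample_conversion = 2)
  vt <- data.frame(peptide_sequence = "PEPTIDEK", base_log2_conc = 1.5,
                   shift_log2 = -1.3, stringsAsFactors = FALSE)
  signs <- vapply(1:25, function(s) {
    conc <- simulate_verification_truth(man, vt, patient_sd = 0.4,
                                        noise_sd = 0.3, seed = s)
    prm <- simulate_prm_export(conc, design, slope = 1, intercept = 0.02,
                               cv = 0.05, seed = s + 1000)
    cal <- simulate_calibration(design, slope = 1, intercept = 0.02,
                                cv = 0.05, seed = s + 2000)
    curves <- calibrate_peptides(cal)
    qc <- qc_peaks(prm)
    quant <- prm_quantify(qc$accepted, curves, design)
    v <- verify_differential(quant, man, n_boot = 50, seed = s)
    sign(v$median_log2_fc)
  }, numeric(1))
  expect_gte(mean(signs == -1), 0.95)
})
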