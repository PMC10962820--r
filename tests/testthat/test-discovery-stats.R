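test_that("identification and pair-coverage filters remove the right proteins", {
  man <- make_manifest(3)
  m <- matrix(100, nrow = 10, ncol = 6, dimnames = list(NULL, man$sample_id))
  # protein 10: quantified in a single complete pair only
  m[10, ] <- c(100, 200, NA, 300, 400, NA)
  pq <- make_quant(m,
                   contaminant = c(TRUE, TRUE, rep(FALSE, 8)),
                   reverse = c(FALSE, FALSE, TRUE, rep(FALSE, 7)),
                   only_by_site = c(rep(FALSE, 3), TRUE, rep(FALSE, 6)))
  flt <- filter_proteins(pq, man, min_pairs = 2)
  expect_equal(nrow(flt$proteins), 5)   # 10 - 2 contam - 1 reverse - 1 site - 1 coverage
  rep_ <- attr(flt, "filter_report")
  expect_equal(rep_$n_input, 10)
  expect_equal(rep_$n_after_flags, 6)
  expect_equal(rep_$n_after_min_pairs, 5)

  # no flags, full data: identity
  pq2 <- make_quant(matrix(100, 4, 6, dimnames = list(NULL, man$sample_id)))
  expect_equal(nrow(filter_proteins(pq2, man)$proteins), 4)

  # min_pairs = 1 keeps the single-pair protein
  expect_true("ACC010" %in% filter_proteins(pq, man, min_pairs = 1)$proteins$accession)
})

test_that("paired fold changes are log2 ratios over complete pairs only", {
  man <- make_manifest(2)
  m <- matrix(c(100, 400, 100, 100,
                100, 100, NA, 200), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, man$sample_id))
  pq <- make_quant(m)
  fcs <- paired_fold_changes(pq, man)
  expect_equal(fcs$fc[1, ], c(P01 = 2, P02 = 0))   # log2(400/100) = 2 exactly
  expect_true(is.na(fcs$fc[2, "P02"]))
  expect_equal(fcs$n_pairs, c(ACC001 = 2, ACC002 = 1))
  expect_equal(fcs$pct_blanks, c(ACC001 = 0, ACC002 = 50))

  bad <- m; bad[1, 1] <- -5
  expect_error(paired_fold_changes(make_quant(bad), man), "nonpositive")
})

test_that("fold changes match an independent two-loop oracle on a random table", {
  man <- make_manifest(3)
  set.seed(42)
  m <- matrix(runif(120, 50, 5000), nrow = 20,
              dimnames = list(NULL, man$sample_id))
  m[sample(120, 15)] <- NA
  fcs <- paired_fold_changes(make_quant(m), man)
  pairs <- manifest_pairs(man)
  for (i in 1:20) for (j in seq_len(nrow(pairs))) {
    b <- m[i, pairs$baseline[j]]; f <- m[i, pairs$followup[j]]
    want <- if (is.na(b) || is.na(f)) NA_real_ else unname(log2(f) - log2(b))
    expect_equal(unname(fcs$fc[i, j]), want)
  }
})

test_that("median FC and percent changed follow the sign-of-median convention", {
  s <- summarize_fc(c(-1, -2, 0.5))
  expect_equal(s$median_log2_fc, -1)
  expect_equal(s$pct_changed, 100 * 2 / 3)
  expect_equal(summarize_fc(c(1, 1, 1, 1))$pct_changed, 100)
  tie <- summarize_fc(c(-1, 1))
  expect_equal(tie$median_log2_fc, 0)
  expect_equal(tie$pct_changed, 50)
  expect_equal(summarize_fc(c(-1, 0, 2, 3))$pct_changed, 50)  # zero counts neither
  expect_error(summarize_fc(c(NA_real_, NA_real_)), "no fold changes")
})

test_that("paired t matches the closed form and flags zero-variance proteins", {
  man <- make_manifest(4)
  lb <- c(10, 11, 12, 13); lf <- c(12, 13, 14, 15)
  m <- matrix(0, nrow = 2, ncol = 8, dimnames = list(NULL, man$sample_id))
  m[1, man$timepoint == "baseline"] <- 2^lb
  m[1, man$timepoint == "followup"] <- 2^lf  # differences all 2: zero variance
  set.seed(9)
  m[2, ] <- 2^rnorm(8, 20, 1)
  tt <- paired_test(make_quant(m), man)
  expect_true(tt$undefined[1])
  expect_true(is.na(tt$p_value[1]))
  pairs <- manifest_pairs(man)
  want <- oracle_paired_t(log2(m[2, pairs$baseline]), log2(m[2, pairs$followup]))
  expect_equal(tt$t_stat[2], want$t)
  expect_equal(tt$p_value[2], want$p)
  # and agrees with the standard implementation
  ref <- t.test(log2(m[2, pairs$followup]), log2(m[2, pairs$baseline]),
                paired = TRUE)
  expect_equal(tt$p_value[2], ref$p.value)
  # undefined p excluded from the BH family
  expect_equal(tt$fdr[2], tt$p_value[2])
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  p <- c(0.001, 0.01, 0.02, 0.04)
  expect_equal(bh_adjust(p), c(0.004, 0.02, 4 * 0.02 / 3, 0.04))
  withna <- bh_adjust(c(0.001, NA, 0.01, 0.02, 0.04))
  expect_true(is.na(withna[2]))
  expect_equal(withna[-2], c(0.004, 0.02, 4 * 0.02 / 3, 0.04))
})

test_that("immunoglobulin flagging matches the keyword map", {
  km <- data.frame(accession = c("A", "B", "C"),
                   keyword = c("KW-1280", "Signal", "Immunoglobulin"),
                   stringsAsFactors = FALSE)
  expect_identical(flag_immunoglobulins(c("A", "B", "C", "D"), km),
                   c(TRUE, FALSE, TRUE, FALSE))
})

test_that("z-score cutoff is estimated on non-immunoglobulin proteins only", {
  set.seed(8)
  ref <- scale(rnorm(51))[, 1]          # exact mean 0, sd 1
  med <- c(ref, 0, qnorm(0.975), 3)
  is_ig <- c(rep(FALSE, 51), TRUE, TRUE, TRUE)
  zz <- zscore_fc_flag(med, is_ig, alpha_z = 0.05)
  expect_equal(zz$z_p[52], 1)               # at the reference mean
  expect_false(zz$high_fc[52])
  expect_equal(zz$z_p[53], 0.05)            # exact boundary: not flagged (strict <)
  expect_false(zz$high_fc[53])
  expect_true(zz$high_fc[54])               # z = 3 well past the cutoff
  expect_error(zscore_fc_flag(rep(1, 10), rep(FALSE, 10)), "zero spread")
})

test_that("large injected shifts are recovered by the z-score flag", {
  hits <- vapply(1:25, function(s) {
    cfg <- sim_config(n_patients = 40, n_proteins = 100, frac_changed = 0.1,
                      frac_immunoglobulin = 0, effect_size_log2 = 1,
                      noise_sd = 0.2, missing_base_rate = 0, seed = s)
    sim <- simulate_cohort(cfg)
    rec <- run_discovery(sim$quant, sim$manifest, sim$keywords)
    truth_changed <- sim$truth$true_shift != 0
    sum(rec$high_fc[match(sim$truth$accession[truth_changed], rec$accession)]) /
      sum(truth_changed)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("candidate selection is the strict conjunction of the three criteria", {
  rec <- data.frame(accession = c("A", "B", "C", "D"),
                    fdr = c(0.005, 0.005, 0.02, 0.005),
                    z_p = c(0.01, 0.01, 0.01, 0.01),
                    pct_changed = c(79, 85, 85, 80),
                    stringsAsFactors = FALSE)
  expect_identical(select_candidates(rec), c(FALSE, TRUE, FALSE, FALSE))
  cfg <- default_config(); cfg$force_include <- "A"
  expect_identical(select_candidates(rec, cfg), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("discovery statistics equal naive oracles on random small tables", {
  set.seed(101)
  for (iter in 1:40) {
    np <- sample(3:8, 1); ng <- sample(3:12, 1)
    man <- make_manifest(np)
    m <- matrix(2^rnorm(ng * 2 * np, 20, 2), nrow = ng,
                dimnames = list(NULL, man$sample_id))
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    pq <- make_quant(m)
    flt <- filter_proteins(pq, man, min_pairs = 2)
    if (!nrow(flt$proteins)) next
    fcs <- paired_fold_changes(flt, man)
    tt <- paired_test(flt, man)
    for (i in seq_len(nrow(flt$proteins))) {
      v <- fcs$fc[i, ]
      expect_equal(summarize_fc(v)$median_log2_fc, oracle_median(v))
      expect_equal(summarize_fc(v)$pct_changed, oracle_pct_changed(v))
      pairs <- manifest_pairs(man)
      b <- log2(flt$intensity[i, pairs$baseline])
      f <- log2(flt$intensity[i, pairs$followup])
      ok <- !is.na(b) & !is.na(f)
      if (sum(ok) >= 2 && sd(f[ok] - b[ok]) > 0)
        expect_equal(tt$p_value[i], oracle_paired_t(b, f)$p)
    }
    expect_equal(tt$fdr[!tt$undefined], oracle_bh(tt$p_value[!tt$undefined]))
  }
})

test_that("injected negative shifts always yield negative medians without noise", {
  cfg <- sim_config(n_patients = 10, n_proteins = 40, frac_changed = 0.5,
                    frac_immunoglobulin = 0, effect_size_log2 = -0.8,
                    noise_sd = 0, missing_base_rate = 0, seed = 13)
  sim <- simulate_cohort(cfg)
  fcs <- paired_fold_changes(sim$quant, sim$manifest)
  med <- apply(fcs$fc, 1, median)
  neg <- sim$truth$true_shift < 0
  expect_true(all(med[neg] < 0))
  expect_true(all(abs(med[!neg]) < 1e-9))
})

test_that("peptide prescreen centres samples, applies the residue rule and ranks", {
  man <- make_manifest(6)
  set.seed(21)
  # 12 stable filler peptides anchor the per-sample medians; 3 shifted targets
  peps <- data.frame(peptide_sequence = c("SSEDPNEDIVER", "LVCYFTNWSQDR",
                                          "TTTVVVR", sprintf("FILLER%02dK", 1:12)),
                     accession = c("P01591", "Q15782", "P2",
                                   sprintf("F%02d", 1:12)),
                     stringsAsFactors = FALSE)
  n_pep <- nrow(peps)
  m <- 2^matrix(rnorm(n_pep * 12, 20, 0.3), n_pep, 12)
  shift <- c(4, 4, 1, rep(1, 12))  # 2 log2 units for the two targets
  m[, man$timepoint == "followup"] <- m[, man$timepoint == "followup"] * shift
  tab <- cbind(peps, as.data.frame(m))
  names(tab)[-(1:2)] <- man$sample_id
  out <- peptide_prescreen(tab, man)
  expect_true("SSEDPNEDIVER" %in% out$peptide_sequence)       # no C/M: eligible
  expect_false("LVCYFTNWSQDR" %in% out$peptide_sequence)      # contains C
  expect_false("TTTVVVR" %in% out$peptide_sequence)           # not significant
  allow <- peptide_prescreen(tab, man, allow = "LVCYFTNWSQDR")
  expect_true("LVCYFTNWSQDR" %in% allow$peptide_sequence)     # override list

  centred <- sweep(log2(m), 2, apply(log2(m), 2, median))
  expect_true(all(abs(apply(centred, 2, median)) < 1e-12))
})

test_that("bootstrap CI of the median is seeded and covers the point estimate", {
  x <- c(-1.2, -0.8, -1.1, -0.9, -1.3, -0.7, -1.0)
  ci1 <- boot_median_ci(x, n_boot = 500, seed = 4)
  ci2 <- boot_median_ci(x, n_boot = 500, seed = 4)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], median(x))
  expect_gte(ci1[2], median(x))
})
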