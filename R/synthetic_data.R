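## Synthetic paired-cohort generator. Every downstream stage is validated
## against the ground truth these functions emit.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Simulation configuration for a paired discovery cohort
#'
#' Defaults mirror the scale of a paired CSF discovery study: 56 patients,
#' 1200 proteins of which ~5% are immunoglobulin-class and 25% shift under
#' treatment by 0.5 on the log2 scale. Between-protein spread, shared
#' patient intercepts and residual noise are all normal on the log2 scale;
#' the probability that a measurement is missing increases logistically as
#' protein abundance decreases.
#'
#' @param n_patients Number of patients (each with a baseline and follow-up
#'   sample); must be at least 2.
#' @param n_proteins Number of simulated proteins.
#' @param frac_immunoglobulin Fraction of proteins carrying the
#'   Immunoglobulin keyword class.
#' @param frac_changed Fraction of non-immunoglobulin proteins with a true
#'   treatment shift.
#' @param effect_size_log2 True log2 shift(s) for changed proteins; a vector
#'   is sampled uniformly per changed protein (e.g. `c(-0.5, 0.5)`).
#' @param ig_effect_log2 Coherent log2 shift applied to immunoglobulin-class
#'   proteins (negative by default: treatment suppresses them).
#' @param patient_sd SD of the per-patient random intercept shared by the
#'   sample pair (log2 scale).
#' @param protein_sd SD of the between-protein baseline abundance (log2).
#' @param noise_sd Residual measurement SD per sample (log2).
#' @param baseline_mean Mean log2 baseline abundance across proteins.
#' @param missing_base_rate Missingness probability at average abundance.
#' @param missing_abundance_slope Logit-scale increase in missingness per
#'   log2 unit of abundance below the average.
#' @param ig_missing_logit Extra logit-scale missingness for
#'   immunoglobulin-class proteins.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 56, n_proteins = 1200,
                       frac_immunoglobulin = 0.05, frac_changed = 0.25,
                       effect_size_log2 = 0.5, ig_effect_log2 = -0.5,
                       patient_sd = 0.5, protein_sd = 2, noise_sd = 0.3,
                       baseline_mean = 25,
                       missing_base_rate = 0.10, missing_abundance_slope = 0.5,
                       ig_missing_logit = 1, seed = 1L) {
  cfg <- list(n_patients = n_patients, n_proteins = n_proteins,
              frac_immunoglobulin = frac_immunoglobulin,
              frac_changed = frac_changed,
              effect_size_log2 = effect_size_log2,
              ig_effect_log2 = ig_effect_log2,
              patient_sd = patient_sd, protein_sd = protein_sd,
              noise_sd = noise_sd, baseline_mean = baseline_mean,
              missing_base_rate = missing_base_rate,
              missing_abundance_slope = missing_abundance_slope,
              ig_missing_logit = ig_missing_logit, seed = as.integer(seed))
  frac <- c(cfg$frac_immunoglobulin, cfg$frac_changed, cfg$missing_base_rate)
  if (any(frac < 0 | frac > 1)) .dp_stop("fractions must lie in [0,1]")
  if (any(c(cfg$patient_sd, cfg$protein_sd) <= 0)) .dp_stop("sds must be > 0")
  if (cfg$noise_sd < 0) .dp_stop("noise_sd must be >= 0")
  if (cfg$n_patients < 2) .dp_stop("n_patients must be >= 2 (paired analysis undefined)")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired discovery cohort with known ground truth
#'
#' Generates a sample manifest, a protein quantification table in the
#' MaxQuant LFQ dialect, a keyword map flagging immunoglobulin-class
#' proteins, and the per-protein ground truth. Follow-up abundance equals
#' baseline plus the true shift plus noise; the patient intercept is shared
#' within each pair and cancels in the paired fold change.
#'
#' @param config A [sim_config()].
#' @return List with `manifest`, `quant` (a `protein_quant`), `keywords`
#'   (accession/keyword data.frame) and `truth` (accession, true_shift,
#'   is_immunoglobulin, baseline_log2).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    np <- config$n_patients
    ng <- config$n_proteins
    pid <- sprintf("P%03d", seq_len(np))
    manifest <- data.frame(
      patient_id = rep(pid, each = 2),
      sample_id  = as.vector(rbind(paste0(pid, "_B"), paste0(pid, "_F"))),
      timepoint  = rep(c("baseline", "followup"), np),
      stringsAsFactors = FALSE
    )
    acc <- sprintf("SP%05d", seq_len(ng))
    n_ig <- round(config$frac_immunoglobulin * ng)
    is_ig <- seq_len(ng) <= n_ig
    non_ig <- which(!is_ig)
    n_changed <- round(config$frac_changed * length(non_ig))
    changed <- sample(non_ig, n_changed)
    shift <- numeric(ng)
    shift[changed] <- sample(rep_len(config$effect_size_log2, max(n_changed, 1)),
                             n_changed)
    shift[is_ig] <- config$ig_effect_log2

    mu <- stats::rnorm(ng, config$baseline_mean, config$protein_sd)
    u  <- stats::rnorm(np, 0, config$patient_sd)
    eps_b <- matrix(stats::rnorm(ng * np, 0, config$noise_sd), ng, np)
    eps_f <- matrix(stats::rnorm(ng * np, 0, config$noise_sd), ng, np)
    log_b <- outer(mu, rep(1, np)) + outer(rep(1, ng), u) + eps_b
    log_f <- outer(mu, rep(1, np)) + outer(rep(1, ng), u) + shift + eps_f

    # missing-not-at-random: logistic in protein-level log2 abundance
    p_miss <- stats::plogis(stats::qlogis(config$missing_base_rate) -
                              config$missing_abundance_slope *
                                (mu - config$baseline_mean) +
                              ifelse(is_ig, config$ig_missing_logit, 0))
    miss_b <- matrix(stats::runif(ng * np) < p_miss, ng, np)
    miss_f <- matrix(stats::runif(ng * np) < p_miss, ng, np)

    intensity <- matrix(NA_real_, ng, np * 2,
                        dimnames = list(acc, manifest$sample_id))
    intensity[, manifest$timepoint == "baseline"] <- 2 ^ log_b
    intensity[, manifest$timepoint == "followup"] <- 2 ^ log_f
    intensity[, manifest$timepoint == "baseline"][miss_b] <- NA_real_
    intensity[, manifest$timepoint == "followup"][miss_f] <- NA_real_

    proteins <- data.frame(
      accession = acc,
      gene_name = paste0("GENE", seq_len(ng)),
      unique_peptides = 1L + stats::rpois(ng, 4),
      reverse = FALSE, contaminant = FALSE, only_by_site = FALSE,
      stringsAsFactors = FALSE
    )
    keywords <- if (n_ig > 0)
      data.frame(accession = acc[is_ig], keyword = "KW-1280",
                 stringsAsFactors = FALSE)
    else data.frame(accession = character(0), keyword = character(0),
                    stringsAsFactors = FALSE)
    truth <- data.frame(accession = acc, true_shift = shift,
                        is_immunoglobulin = is_ig, baseline_log2 = mu,
                        stringsAsFactors = FALSE)
    list(manifest = manifest, quant = new_protein_quant(proteins, intensity),
         keywords = keywords, truth = truth)
  })
}

#' Build a reference differential list that encodes a category scheme
#'
#' Given the cohort ground truth and a target concordance category per
#' protein, constructs the disease-vs-control reference directions such that
#' downstream categorisation must recover the scheme exactly: `opposite`
#' proteins get the direction opposite their true treatment shift, `equal`
#' the same direction, `treatment_only` are unchanged in the reference,
#' `disease_only` get a reference direction while truly unshifted,
#' `not_changed` are unchanged everywhere, and `unmatched` are omitted from
#' the reference list.
#'
#' @param truth Ground-truth data.frame from [simulate_cohort()].
#' @param scheme Data.frame with `accession` and `category` (one of
#'   opposite, equal, treatment_only, disease_only, not_changed, unmatched).
#' @return Reference list data.frame (`accession`, `direction`) covering all
#'   scheme proteins except the `unmatched` ones.
#' @export
simulate_reference_diffset <- function(truth, scheme) {
  stopifnot(all(c("accession", "category") %in% names(scheme)))
  bad <- setdiff(scheme$category,
                 c("opposite", "equal", "treatment_only", "disease_only",
                   "not_changed", "unmatched"))
  if (length(bad)) .dp_stop("unknown category: ", paste(bad, collapse = ", "))
  shift <- truth$true_shift[match(scheme$accession, truth$accession)]
  if (anyNA(shift)) .dp_stop("scheme accession(s) absent from truth")
  needs_change <- scheme$category %in% c("opposite", "equal", "treatment_only")
  if (any(needs_change & shift == 0))
    .dp_stop("categories opposite/equal/treatment_only require a nonzero true shift")
  needs_null <- scheme$category %in% c("disease_only", "not_changed")
  if (any(needs_null & shift != 0))
    .dp_stop("categories disease_only/not_changed require a zero true shift")
  dir <- character(nrow(scheme))
  dir[scheme$category == "opposite"] <-
    ifelse(shift[scheme$category == "opposite"] > 0, "decreased", "increased")
  dir[scheme$category == "equal"] <-
    ifelse(shift[scheme$category == "equal"] > 0, "increased", "decreased")
  dir[scheme$category == "treatment_only"] <- "unchanged"
  dir[scheme$category == "disease_only"] <- "increased"
  dir[scheme$category == "not_changed"] <- "unchanged"
  keep <- scheme$category != "unmatched"
  data.frame(accession = scheme$accession[keep], direction = dir[keep],
             stringsAsFactors = FALSE)
}

#' Simulate reverse calibration-curve points
#'
#' Generates nine-point (by default) reverse dilution series per peptide:
#' the expected ratio to standard is linear in the theoretical concentration
#' (`slope * conc + intercept`), perturbed by multiplicative noise with a
#' given coefficient of variation. An optional saturation term depresses the
#' response at concentrations near `saturation_conc`, creating a detectable
#' nonlinear low-concentration region.
#'
#' @param design A [spike_design()].
#' @param slope,intercept True calibration line (recycled over peptides).
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_replicates Trypsinated replicates per level (default 2).
#' @param seed Integer seed.
#' @param saturation_conc Concentration scale of low-end saturation
#'   (0 = perfectly linear). The expected response is multiplied by
#'   `conc / (conc + saturation_conc)`.
#' @return Data.frame of calibration points: `peptide_sequence`,
#'   `theoretical_conc` (fmol/ul injected), `ratio_to_standard`,
#'   `replicate_id`, `dilution_factor`.
#' @export
simulate_calibration <- function(design, slope = 1, intercept = 0, cv = 0.05,
                                 n_replicates = 2, seed = 1L,
                                 saturation_conc = 0) {
  stopifnot(inherits(design, "spike_design"), cv >= 0)
  pep <- design$peptides
  slope <- rep_len(slope, nrow(pep))
  intercept <- rep_len(intercept, nrow(pep))
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(pep)), function(i) {
      conc <- design$dilution_factors * pep$spike_amount[i]
      grid <- expand.grid(conc = conc, rep = seq_len(n_replicates),
                          KEEP.OUT.ATTRS = FALSE)
      mu <- (slope[i] * grid$conc + intercept[i]) *
        if (saturation_conc > 0) grid$conc / (grid$conc + saturation_conc) else 1
      noise <- if (cv > 0) {
        sdl <- sqrt(log(1 + cv^2))
        stats::rlnorm(nrow(grid), meanlog = -sdl^2 / 2, sdlog = sdl)
      } else 1
      data.frame(peptide_sequence = pep$peptide_sequence[i],
                 theoretical_conc = grid$conc,
                 ratio_to_standard = mu * noise,
                 replicate_id = paste0("cal_rep", grid$rep),
                 dilution_factor = rep(design$dilution_factors, n_replicates),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate true peptide concentrations for a paired verification cohort
#'
#' Per-peptide log2 concentrations with a shared patient intercept and a
#' treatment shift, mirroring the paired structure of the discovery model
#' but on the concentration (fmol/ul sample) scale.
#'
#' @param manifest Validated sample manifest.
#' @param peptides Data.frame with `peptide_sequence`, `base_log2_conc`
#'   (log2 fmol/ul sample at baseline) and `shift_log2` (true treatment
#'   effect).
#' @param patient_sd,noise_sd Log2-scale SDs of the shared patient intercept
#'   and residual noise.
#' @param seed Integer seed.
#' @return Data.frame: `peptide_sequence`, `patient_id`, `sample_id`,
#'   `timepoint`, `true_conc` (fmol/ul sample).
#' @export
simulate_verification_truth <- function(manifest, peptides, patient_sd = 0.4,
                                        noise_sd = 0.2, seed = 1L) {
  pairs <- manifest_pairs(manifest)
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(peptides)), function(i) {
      u <- stats::rnorm(nrow(pairs), 0, patient_sd)
      lb <- peptides$base_log2_conc[i] + u + stats::rnorm(nrow(pairs), 0, noise_sd)
      lf <- peptides$base_log2_conc[i] + u + peptides$shift_log2[i] +
        stats::rnorm(nrow(pairs), 0, noise_sd)
      data.frame(peptide_sequence = peptides$peptide_sequence[i],
                 patient_id = rep(pairs$patient_id, 2),
                 sample_id = c(pairs$baseline, pairs$followup),
                 timepoint = rep(c("baseline", "followup"), each = nrow(pairs)),
                 true_conc = 2 ^ c(lb, lf),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate a Skyline-style PRM export from true concentrations
#'
#' Converts per-sample true concentrations into fragment-level light/heavy
#' areas consistent with a per-peptide calibration line: the expected
#' summed-light over summed-heavy ratio of a measurement equals
#' `slope * conc_injected + intercept` where
#' `conc_injected = true_conc / sample_conversion`. Fragment heavy areas are
#' lognormal around a common base; per-fragment multiplicative noise with the
#' given coefficient of variation perturbs the light/heavy ratio.
#'
#' @param conc_table Output of [simulate_verification_truth()].
#' @param design A [spike_design()] carrying per-peptide `sample_conversion`.
#' @param slope,intercept True calibration line per peptide (recycled in the
#'   order of `design$peptides`).
#' @param cv Coefficient of variation of the per-fragment ratio noise.
#' @param n_fragments Fragments per measurement (default 4).
#' @param n_replicates Trypsinated replicates per sample (default 2).
#' @param seed Integer seed.
#' @return Data.frame in the [read_prm_export()] schema (all peaks pass QC:
#'   10 points across the peak, 0 ppm, untruncated).
#' @export
simulate_prm_export <- function(conc_table, design, slope = 1, intercept = 0,
                                cv = 0.05, n_fragments = 4, n_replicates = 2,
                                seed = 1L) {
  pep <- design$peptides
  slope <- rep_len(slope, nrow(pep))
  intercept <- rep_len(intercept, nrow(pep))
  .with_seed(seed, {
    rows <- lapply(seq_len(nrow(conc_table)), function(r) {
      i <- match(conc_table$peptide_sequence[r], pep$peptide_sequence)
      if (is.na(i)) .dp_stop("peptide absent from spike design: ",
                             conc_table$peptide_sequence[r])
      conc_inj <- conc_table$true_conc[r] / pep$sample_conversion[i]
      mu_ratio <- slope[i] * conc_inj + intercept[i]
      do.call(rbind, lapply(seq_len(n_replicates), function(rep_k) {
        heavy <- stats::rlnorm(n_fragments, meanlog = log(1e5), sdlog = 0.5)
        noise <- if (cv > 0) {
          sdl <- sqrt(log(1 + cv^2))
          stats::rlnorm(n_fragments, meanlog = -sdl^2 / 2, sdlog = sdl)
        } else 1
        data.frame(peptide_sequence = conc_table$peptide_sequence[r],
                   sample_id = conc_table$sample_id[r],
                   replicate_id = paste0("rep", rep_k),
                   fragment_id = paste0("y", 3 + seq_len(n_fragments)),
                   light_area = heavy * mu_ratio * noise,
                   heavy_area = heavy,
                   points_across_peak = 10L,
                   mass_error_ppm = 0,
                   truncated = FALSE,
                   stringsAsFactors = FALSE)
      }))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Write a full set of simulated pipeline inputs to a directory
#'
#' Emits manifest.tsv, protein_groups.tsv, keywords.tsv, reference.tsv,
#' annotations.tsv, spike_design.tsv, calibration_points.csv,
#' prm_export.csv and ground_truth.tsv in the dialects the readers expect.
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, the list of generated objects.
#' @export
write_simulated_inputs <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  utils::write.table(sim$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_protein_table(sim$quant, file.path(dir, "protein_groups.tsv"))
  utils::write.table(sim$keywords, file.path(dir, "keywords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # reference list: changed proteins split equal/opposite, nulls split
  # disease_only/not_changed, tail left unmatched
  tr <- sim$truth
  changed <- tr$accession[tr$true_shift != 0]
  nulls <- tr$accession[tr$true_shift == 0]
  cat_of <- function(ids, cats) if (length(ids))
    data.frame(accession = ids,
               category = rep_len(cats, length(ids)),
               stringsAsFactors = FALSE) else NULL
  scheme <- rbind(cat_of(changed, c("equal", "opposite", "treatment_only")),
                  cat_of(nulls, c("disease_only", "not_changed", "unmatched")))
  ref <- simulate_reference_diffset(tr, scheme)
  utils::write.table(ref, file.path(dir, "reference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  anns <- simulate_term_annotations(tr, seed = config$seed + 101L)
  utils::write.table(anns, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  peptides <- data.frame(
    peptide_sequence = sprintf("PEPTIDE%02dK", 1:8),
    spike_amount = rep(c(0.5, 1, 2, 5), 2),
    sample_conversion = 2,
    stringsAsFactors = FALSE
  )
  design <- spike_design(peptides, default_dilution_series())
  write_spike_design(design, file.path(dir, "spike_design.tsv"))
  cal <- simulate_calibration(design, slope = 1, intercept = 0.02, cv = 0.05,
                              seed = config$seed + 202L)
  utils::write.csv(cal, file.path(dir, "calibration_points.csv"),
                   row.names = FALSE, quote = FALSE)

  vtruth <- data.frame(
    peptide_sequence = peptides$peptide_sequence,
    base_log2_conc = log2(peptides$spike_amount * peptides$sample_conversion),
    shift_log2 = rep(c(-1, 0.8, 0, -0.5), 2),
    stringsAsFactors = FALSE
  )
  vc <- simulate_verification_truth(sim$manifest, vtruth,
                                    seed = config$seed + 303L)
  prm <- simulate_prm_export(vc, design, slope = 1, intercept = 0.02,
                             cv = 0.05, seed = config$seed + 404L)
  write_prm_export(prm, file.path(dir, "prm_export.csv"))

  gt <- merge(tr, scheme, by = "accession", all.x = TRUE, sort = TRUE)
  utils::write.table(gt, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vtruth, file.path(dir, "verification_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(sim = sim, reference = ref, annotations = anns,
                 design = design, calibration = cal,
                 verification_truth = vtruth, prm = prm))
}

#' Simulate a flat term-annotation table over the cohort proteins
#'
#' Random flat GO-biological-process-like annotations: terms of varying size
#' drawn from the cohort accessions, with a mix of curated and electronic
#' (IEA) evidence codes.
#'
#' @param truth Ground truth from [simulate_cohort()].
#' @param n_terms Number of terms.
#' @param seed Integer seed.
#' @return Data.frame in the [read_term_annotations()] schema.
#' @export
simulate_term_annotations <- function(truth, n_terms = 20, seed = 1L) {
  .with_seed(seed, {
    acc <- truth$accession
    do.call(rbind, lapply(seq_len(n_terms), function(t) {
      size <- max(3L, stats::rpois(1, 12))
      members <- sample(acc, min(size, length(acc)))
      data.frame(term_id = sprintf("GO:%07d", t),
                 term_name = paste0("process_", t),
                 accession = members,
                 evidence_code = sample(c("EXP", "IDA", "IMP", "IEA"),
                                        length(members), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
  })
}
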