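## End-to-end orchestration: one config, derived per-stage seeds, TSV/JSON
## artifacts and a machine-readable run summary.

#' Derive a reproducible per-stage seed from the global seed
#'
#' Hashes the stage name into the global seed so each stage can be rerun
#' independently with the same randomness. Result is kept below 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Run the full pipeline from a configuration
#'
#' Executes (optionally) simulation, then discovery statistics, reference
#' comparison, term enrichment and the PRM verification stages, writing TSV
#' artifacts plus a JSON run summary to the output directory. Stage outputs
#' are byte-identical across runs of the same config.
#'
#' @param config Config list (see [default_config()]) extended with
#'   `input_dir`, `out_dir`, optional `simulate` (logical) and `sim` (list
#'   of [sim_config()] overrides used when simulating).
#' @return The run summary (invisibly), also written to
#'   `out_dir/run_summary.json`.
#' @export
run_all <- function(config) {
  cfg <- validate_config(utils::modifyList(default_config(), config))
  if (is.null(cfg$input_dir) || is.null(cfg$out_dir))
    .dp_stop("config must provide input_dir and out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(package = "deltaprot",
                  version = as.character(utils::packageVersion("deltaprot")),
                  seed = cfg$seed,
                  thresholds = cfg[c("discovery_fdr", "z_alpha",
                                     "concordance_pct", "verification_fdr",
                                     "min_pairs", "go_fdr", "min_fragments",
                                     "min_points", "max_ppm", "rel_bias_tol")])

  if (isTRUE(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = derive_seed(cfg$seed, "simulate")),
                                  if (is.null(cfg[["sim"]])) list() else cfg[["sim"]])
    write_simulated_inputs(cfg$input_dir, do.call(sim_config, sim_args))
    summary$simulate <- sim_args
  }

  ip <- function(f) file.path(cfg$input_dir, f)
  op <- function(f) file.path(cfg$out_dir, f)

  manifest <- read_manifest(ip("manifest.tsv"))
  pq <- read_protein_table(ip("protein_groups.tsv"), manifest)
  keywords <- read_keyword_map(ip("keywords.tsv"))

  rec <- run_discovery(pq, manifest, keywords, cfg)
  utils::write.table(format(rec, digits = 15, scientific = FALSE, trim = TRUE),
                     op("differential_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(rec, "filter_report"), op("filter_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  summary$discovery <- c(attr(rec, "filter_report"),
                         list(n_significant = sum(rec$significant),
                              n_immunoglobulin = sum(rec$is_immunoglobulin),
                              n_high_fc = sum(rec$high_fc, na.rm = TRUE),
                              n_candidates = sum(rec$candidate)))

  reference <- read_reference_diffset(ip("reference.tsv"))
  cmp <- categorize(rec, reference, discovery_fdr = cfg$discovery_fdr)
  utils::write.table(cmp$assignments, op("categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(categories = cmp$summary,
         contingency = as.data.frame.matrix(concordance_contingency(cmp$assignments))),
    op("contingency.json"), auto_unbox = TRUE, pretty = TRUE)
  summary$compare <- cmp$summary

  anns <- read_term_annotations(ip("annotations.tsv"))
  subset <- rec$accession[rec$significant]
  enr <- enrich(subset, rec$accession, anns,
                exclude_evidence = cfg$exclude_evidence, alpha = cfg$go_fdr)
  utils::write.table(format(enr, digits = 15, scientific = FALSE, trim = TRUE),
                     op("enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$enrich <- list(n_terms_tested = nrow(enr),
                         n_significant_terms = sum(enr$significant),
                         subset_size = length(subset),
                         background_size = nrow(rec))

  design <- read_spike_design(ip("spike_design.tsv"))
  cal <- utils::read.csv(ip("calibration_points.csv"), stringsAsFactors = FALSE)
  curves <- calibrate_peptides(cal, rel_bias_tol = cfg$rel_bias_tol,
                               invert_ratio = cfg$invert_ratio)
  ct <- curves_table(curves)
  utils::write.table(format(ct, digits = 15, scientific = FALSE, trim = TRUE),
                     op("calibration_curves.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prm <- read_prm_export(ip("prm_export.csv"))
  qc <- qc_peaks(prm, min_fragments = cfg$min_fragments,
                 min_points = cfg$min_points, max_ppm = cfg$max_ppm)
  quant <- prm_quantify(qc$accepted, curves, design)
  ver <- verify_differential(quant, manifest, alpha = cfg$verification_fdr,
                             seed = derive_seed(cfg$seed, "verify"))
  utils::write.table(format(ver, digits = 15, scientific = FALSE, trim = TRUE),
                     op("verification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary$prm <- list(qc = qc$report,
                      n_curves = length(curves),
                      n_peptides_verified = nrow(ver),
                      n_significant_peptides = sum(ver$significant))

  write_run_summary(summary, op("run_summary.json"))
  invisible(summary)
}
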