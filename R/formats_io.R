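#' @keywords internal
"_PACKAGE"

## Column names of the MaxQuant proteinGroups dialect read by read_protein_table().
.pg_cols <- list(
  accession = "Majority protein IDs",
  gene      = "Gene names",
  unique    = "Unique peptides",
  reverse   = "Reverse",
  contam    = "Potential contaminant",
  site      = "Only identified by site",
  lfq       = "LFQ intensity "
)

.dp_stop <- function(..., class = "deltaprot_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.dp_log <- function(...) {
  message("[deltaprot] ", ...)
}

#' Read a sample manifest
#'
#' The manifest pairs each patient's baseline and follow-up CSF samples.
#' Required columns: `patient_id`, `sample_id`, `timepoint` (values
#' `baseline`/`followup`); optional free-text covariate columns are kept.
#'
#' @param path Path to a tab-separated manifest file.
#' @return A `data.frame` with one row per sample, validated so that every
#'   patient has exactly one baseline and one follow-up sample and sample ids
#'   are unique.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_manifest(df)
}

#' Validate a sample manifest
#'
#' @param df A data.frame with `patient_id`, `sample_id`, `timepoint` columns.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_manifest <- function(df) {
  need <- c("patient_id", "sample_id", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .dp_stop("manifest is missing required column(s): ", paste(miss, collapse = ", "),
             class = "deltaprot_parse_error")
  df$timepoint <- tolower(as.character(df$timepoint))
  bad <- setdiff(unique(df$timepoint), c("baseline", "followup"))
  if (length(bad))
    .dp_stop("unknown timepoint value(s): ", paste(bad, collapse = ", "),
             class = "deltaprot_parse_error")
  if (anyDuplicated(df$sample_id))
    .dp_stop("duplicate sample_id(s): ",
             paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
             class = "deltaprot_parse_error")
  tab <- table(df$patient_id, df$timepoint)
  if (!all(c("baseline", "followup") %in% colnames(tab)) || any(tab != 1))
    .dp_stop("each patient must have exactly one baseline and one followup sample",
             class = "deltaprot_parse_error")
  df
}

#' Baseline/follow-up sample ids per patient
#'
#' @param manifest A validated manifest.
#' @return A data.frame with columns `patient_id`, `baseline`, `followup`.
#' @export
manifest_pairs <- function(manifest) {
  b <- manifest[manifest$timepoint == "baseline", c("patient_id", "sample_id")]
  f <- manifest[manifest$timepoint == "followup", c("patient_id", "sample_id")]
  names(b)[2] <- "baseline"
  names(f)[2] <- "followup"
  m <- merge(b, f, by = "patient_id", sort = TRUE)
  m[order(m$patient_id), , drop = FALSE]
}

#' Read a MaxQuant-style protein quantification table
#'
#' Reads a tab-separated proteinGroups-dialect table with per-sample LFQ
#' intensity columns (`"LFQ intensity <sample_id>"`), identification flag
#' columns containing `"+"` or empty, and unique-peptide counts. Zero or empty
#' intensities are treated as missing (encoded `NA` in the intensity matrix),
#' following the MaxQuant LFQ convention.
#'
#' @param path Path to the TSV file.
#' @param manifest A validated sample manifest; every manifest sample must have
#'   an intensity column.
#' @return A `protein_quant` object: list with `proteins` (data.frame:
#'   accession, gene_name, unique_peptides, reverse, contaminant,
#'   only_by_site) and `intensity` (numeric matrix, proteins x samples, `NA`
#'   for missing).
#' @export
read_protein_table <- function(path, manifest) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(.pg_cols$accession, .pg_cols$gene, .pg_cols$unique,
            .pg_cols$reverse, .pg_cols$contam, .pg_cols$site)
  miss <- setdiff(need, names(df))
  if (length(miss))
    .dp_stop("protein table is missing required column(s): ",
             paste(miss, collapse = ", "), class = "deltaprot_parse_error")
  lfq_cols <- grep(paste0("^", .pg_cols$lfq), names(df), value = TRUE)
  samples <- sub(paste0("^", .pg_cols$lfq), "", lfq_cols)
  missing_samples <- setdiff(manifest$sample_id, samples)
  if (length(missing_samples))
    .dp_stop("protein table lacks intensity column(s) for manifest sample(s): ",
             paste(missing_samples, collapse = ", "), class = "deltaprot_parse_error")
  extra <- setdiff(names(df), c(need, lfq_cols))
  if (length(extra))
    .dp_log("ignoring unknown column(s): ", paste(extra, collapse = ", "))

  acc_full <- as.character(df[[.pg_cols$accession]])
  # protein groups may carry several accessions; the first is the join key
  acc <- vapply(strsplit(acc_full, ";", fixed = TRUE), `[`, character(1), 1L)
  multi <- acc_full[grepl(";", acc_full, fixed = TRUE)]
  if (length(multi))
    .dp_log(length(multi), " protein group(s) with multiple accessions; joined on the first")
  if (anyDuplicated(acc))
    .dp_stop("duplicate accession(s): ",
             paste(unique(acc[duplicated(acc)]), collapse = ", "),
             class = "deltaprot_parse_error")

  flag <- function(col) !is.na(df[[col]]) & trimws(as.character(df[[col]])) == "+"
  proteins <- data.frame(
    accession       = acc,
    gene_name       = as.character(df[[.pg_cols$gene]]),
    unique_peptides = as.integer(df[[.pg_cols$unique]]),
    reverse         = flag(.pg_cols$reverse),
    contaminant     = flag(.pg_cols$contam),
    only_by_site    = flag(.pg_cols$site),
    stringsAsFactors = FALSE
  )
  intensity <- as.matrix(df[, paste0(.pg_cols$lfq, manifest$sample_id), drop = FALSE])
  storage.mode(intensity) <- "double"
  if (any(intensity < 0, na.rm = TRUE))
    .dp_stop("negative intensity values are not allowed", class = "deltaprot_parse_error")
  intensity[!is.na(intensity) & intensity == 0] <- NA_real_
  dimnames(intensity) <- list(acc, manifest$sample_id)
  new_protein_quant(proteins, intensity)
}

#' Construct a protein_quant object
#'
#' @param proteins Data.frame of protein metadata (accession, gene_name,
#'   unique_peptides, reverse, contaminant, only_by_site).
#' @param intensity Numeric matrix (proteins x samples), `NA` = missing.
#' @return A `protein_quant` object.
#' @export
new_protein_quant <- function(proteins, intensity) {
  stopifnot(nrow(proteins) == nrow(intensity))
  rownames(intensity) <- proteins$accession
  structure(list(proteins = proteins, intensity = intensity),
            class = "protein_quant")
}

#' @export
print.protein_quant <- function(x, ...) {
  cat("protein_quant: ", nrow(x$proteins), " proteins x ",
      ncol(x$intensity), " samples (",
      sum(is.na(x$intensity)), " missing values)\n", sep = "")
  invisible(x)
}

#' Write a protein quantification table
#'
#' Inverse of [read_protein_table()]: missing intensities are written as 0.
#'
#' @param pq A `protein_quant` object.
#' @param path Output TSV path.
#' @export
write_protein_table <- function(pq, path) {
  p <- pq$proteins
  mark <- function(b) ifelse(b, "+", "")
  out <- data.frame(p$accession, p$gene_name, p$unique_peptides,
                    mark(p$reverse), mark(p$contaminant), mark(p$only_by_site),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(.pg_cols$accession, .pg_cols$gene, .pg_cols$unique,
                  .pg_cols$reverse, .pg_cols$contam, .pg_cols$site)
  m <- pq$intensity
  m[is.na(m)] <- 0
  colnames(m) <- paste0(.pg_cols$lfq, colnames(pq$intensity))
  utils::write.table(cbind(out, as.data.frame(m, check.names = FALSE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein keyword map
#'
#' TSV with columns `accession` and `keyword`; one row per (accession,
#' keyword) pair. Used to flag UniProt keyword classes such as
#' "Immunoglobulin" (KW-1280).
#'
#' @param path TSV path.
#' @return Data.frame with `accession`, `keyword` character columns.
#' @export
read_keyword_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "keyword"), names(df))
  if (length(miss))
    .dp_stop("keyword map is missing column(s): ", paste(miss, collapse = ", "),
             class = "deltaprot_parse_error")
  df[, c("accession", "keyword")]
}

#' Read a reference differential list
#'
#' Emulates a consolidated disease-vs-control export: TSV with `accession`
#' and `direction` columns. Direction tokens `up`/`increased`,
#' `down`/`decreased` and `unchanged`/`equal` are accepted
#' case-insensitively and normalised to `increased`/`decreased`/`unchanged`.
#'
#' @param path TSV path.
#' @return Data.frame with `accession` and normalised `direction`.
#' @export
read_reference_diffset <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("accession", "direction"), names(df))
  if (length(miss))
    .dp_stop("reference list is missing column(s): ", paste(miss, collapse = ", "),
             class = "deltaprot_parse_error")
  tok <- tolower(trimws(df$direction))
  map <- c(up = "increased", increased = "increased",
           down = "decreased", decreased = "decreased",
           unchanged = "unchanged", equal = "unchanged")
  bad <- which(!tok %in% names(map))
  if (length(bad))
    .dp_stop("unknown direction token '", df$direction[bad[1]],
             "' at row ", bad[1], class = "deltaprot_parse_error")
  out <- data.frame(accession = as.character(df$accession),
                    direction = unname(map[tok]),
                    stringsAsFactors = FALSE)
  dup <- unique(out$accession[duplicated(out$accession)])
  if (length(dup)) {
    conflicting <- vapply(dup, function(a)
      length(unique(out$direction[out$accession == a])) > 1, logical(1))
    if (any(conflicting))
      .dp_stop("conflicting directions for accession(s): ",
               paste(dup[conflicting], collapse = ", "),
               class = "deltaprot_parse_error")
    out <- out[!duplicated(out$accession), , drop = FALSE]
  }
  out
}

#' Read term-to-protein annotations with evidence codes
#'
#' Flat GO-style annotation table: TSV with columns `term_id`, `term_name`,
#' `accession`, `evidence_code` (one row per annotation).
#'
#' @param path TSV path.
#' @return Data.frame with those four character columns.
#' @export
read_term_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("term_id", "term_name", "accession", "evidence_code")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .dp_stop("term annotation table is missing column(s): ",
             paste(miss, collapse = ", "), class = "deltaprot_parse_error")
  df[, need]
}

#' Read a Skyline-style PRM transition export
#'
#' CSV with columns `peptide_sequence`, `sample_id`, `replicate_id`,
#' `fragment_id`, `light_area`, `heavy_area`, `points_across_peak`,
#' `mass_error_ppm`, `truncated` (logical or 0/1/true/false).
#'
#' @param path CSV path.
#' @return Data.frame of typed rows; `(peptide, sample, replicate, fragment)`
#'   is checked unique; negative areas and non-integer point counts error.
#' @export
read_prm_export <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("peptide_sequence", "sample_id", "replicate_id", "fragment_id",
            "light_area", "heavy_area", "points_across_peak",
            "mass_error_ppm", "truncated")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .dp_stop("PRM export is missing column(s): ", paste(miss, collapse = ", "),
             class = "deltaprot_parse_error")
  if (any(df$light_area < 0, na.rm = TRUE) || any(df$heavy_area < 0, na.rm = TRUE))
    .dp_stop("negative fragment area in PRM export", class = "deltaprot_parse_error")
  pts <- suppressWarnings(as.numeric(df$points_across_peak))
  if (any(is.na(pts)) || any(pts != round(pts)))
    .dp_stop("points_across_peak must be integer", class = "deltaprot_parse_error")
  df$points_across_peak <- as.integer(pts)
  df$truncated <- .parse_bool(df$truncated)
  key <- paste(df$peptide_sequence, df$sample_id, df$replicate_id, df$fragment_id)
  if (anyDuplicated(key))
    .dp_stop("duplicate (peptide, sample, replicate, fragment) row(s) in PRM export",
             class = "deltaprot_parse_error")
  df[, need]
}

.parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  tok <- tolower(trimws(as.character(x)))
  out <- tok %in% c("true", "t", "1", "yes")
  bad <- !tok %in% c("true", "t", "1", "yes", "false", "f", "0", "no")
  if (any(bad))
    .dp_stop("cannot parse boolean value '", x[which(bad)[1]], "'",
             class = "deltaprot_parse_error")
  out
}

#' Write a PRM export table
#'
#' @param df Data.frame in the [read_prm_export()] schema.
#' @param path Output CSV path.
#' @export
write_prm_export <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heavy-spike design table
#'
#' TSV with one row per peptide (`peptide_sequence`, `spike_amount` in
#' fmol/ul injected at the nominal 1:1 level, optional `sample_conversion`
#' from fmol/ul injected to fmol/ul sample, default 1) plus the shared
#' dilution series as columns `dilution_<k>` (strictly decreasing factors).
#'
#' @param path TSV path.
#' @return A list with `peptides` (data.frame) and `dilution_factors`
#'   (numeric, strictly decreasing).
#' @export
read_spike_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"peptide_sequence" %in% names(df) || !"spike_amount" %in% names(df))
    .dp_stop("spike design needs peptide_sequence and spike_amount columns",
             class = "deltaprot_parse_error")
  dil_cols <- grep("^dilution_", names(df), value = TRUE)
  if (!length(dil_cols))
    .dp_stop("spike design has no dilution_<k> columns", class = "deltaprot_parse_error")
  ord <- order(as.integer(sub("^dilution_", "", dil_cols)))
  dil <- as.numeric(df[1, dil_cols[ord]])
  sd_ <- df[, c("peptide_sequence", "spike_amount"), drop = FALSE]
  sd_$sample_conversion <- if ("sample_conversion" %in% names(df))
    as.numeric(df$sample_conversion) else 1
  spike_design(sd_, dil)
}

#' Construct a spike design
#'
#' @param peptides Data.frame with `peptide_sequence`, `spike_amount`
#'   (fmol/ul injected at the 1:1 level) and optionally `sample_conversion`.
#' @param dilution_factors Strictly decreasing positive multipliers of the
#'   1:1 level, one per calibration point.
#' @return A `spike_design` list.
#' @export
spike_design <- function(peptides, dilution_factors) {
  if (any(peptides$spike_amount <= 0))
    .dp_stop("spike_amount must be positive")
  if (any(dilution_factors <= 0) || any(diff(dilution_factors) >= 0))
    .dp_stop("dilution factors must be positive and strictly decreasing")
  if (is.null(peptides$sample_conversion)) peptides$sample_conversion <- 1
  structure(list(peptides = peptides, dilution_factors = dilution_factors),
            class = "spike_design")
}

#' Default nine-point reverse dilution series
#'
#' Nine spike levels from 8x the estimated 1:1 level down to 0.03x, the span
#' used for reverse calibration curves (2.4 orders of magnitude).
#'
#' @return Numeric vector of nine strictly decreasing dilution factors.
#' @export
default_dilution_series <- function() {
  c(8, 4, 2, 1, 0.5, 0.25, 0.12, 0.06, 0.03)
}

#' Write a spike design table
#'
#' @param design A `spike_design`.
#' @param path Output TSV path.
#' @export
write_spike_design <- function(design, path) {
  df <- design$peptides
  for (k in seq_along(design$dilution_factors))
    df[[paste0("dilution_", k)]] <- design$dilution_factors[k]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' Single structured YAML file with input paths, thresholds and seed; missing
#' fields take package defaults (see [default_config()]).
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(utils::modifyList(default_config(), cfg))
}

#' Default run configuration
#'
#' All thresholds the pipeline uses: discovery FDR 0.01, z-score cutoff 0.05,
#' percent-changed cutoff 80, verification FDR 0.05, minimum complete pairs 2,
#' and PRM QC rules (min 3 fragments, min 8 points across the peak, max 10
#' ppm mass error).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    discovery_fdr    = 0.01,
    z_alpha          = 0.05,
    concordance_pct  = 80,
    verification_fdr = 0.05,
    min_pairs        = 2,
    ig_keyword       = c("KW-1280", "Immunoglobulin"),
    exclude_evidence = "IEA",
    go_fdr           = 0.05,
    min_fragments    = 3,
    min_points       = 8,
    max_ppm          = 10,
    rel_bias_tol     = 0.20,
    invert_ratio     = FALSE,
    force_include    = character(0),
    seed             = 1L
  )
}

#' @rdname read_config
#' @param cfg Config list to validate.
#' @export
validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x <= 1
  if (!in01(cfg$discovery_fdr)) .dp_stop("discovery_fdr must be in (0,1]")
  if (!in01(cfg$z_alpha)) .dp_stop("z_alpha must be in (0,1]")
  if (!in01(cfg$verification_fdr)) .dp_stop("verification_fdr must be in (0,1]")
  if (!in01(cfg$go_fdr)) .dp_stop("go_fdr must be in (0,1]")
  if (!is.numeric(cfg$concordance_pct) || cfg$concordance_pct <= 0 ||
      cfg$concordance_pct > 100)
    .dp_stop("concordance_pct must be in (0,100]")
  if (cfg$min_pairs < 1) .dp_stop("min_pairs must be >= 1")
  cfg
}

#' Write a run summary JSON
#'
#' @param summary Named list of per-stage counts, thresholds and seeds.
#' @param path Output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
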