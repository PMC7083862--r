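# Table readers/writers with schema validation, pipeline configuration,
# and the end-to-end pipeline driver.

oxshift_schemas <- function() {
  list(
    states = c("sample_id", "tissue", "state", "flux"),
    hp_calls = c("patient_id", "sample_id", "tissue", "run_id", "pos",
                 "ref", "alt", "vaf", "fwd_cov", "rev_cov", "fwd_alt",
                 "rev_alt"),
    cq = c("sample_id", "cq_mt", "cq_n"),
    survival = c("sample_id", "time", "event"),
    clinical = c("patient_id", "age", "psa_total", "fpsa_pct", "gleason",
                 "stage")
  )
}

#' Read a validated pipeline table
#'
#' Reads a UTF-8 TSV with header ('.' as missing marker) and checks it
#' against one of the documented schemas; validation errors name the
#' offending column (and row where applicable).
#'
#' @param path File path.
#' @param schema One of `"states"`, `"hp_calls"`, `"cq"`, `"survival"`,
#'   `"clinical"`.
#' @return A tibble.
#' @export
read_table <- function(path,
                       schema = c("states", "hp_calls", "cq", "survival",
                                  "clinical")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input file: ", path, call. = FALSE)
  x <- readr::read_tsv(path, na = c("", "."), show_col_types = FALSE,
                       progress = FALSE)
  if (nrow(x) == 0) stop("empty input table: ", path, call. = FALSE)
  need <- oxshift_schemas()[[schema]]
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("schema '", schema, "' violation in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (schema == "hp_calls") assert_hp_calls(x)
  if (schema == "survival" && any(x$time <= 0, na.rm = TRUE)) {
    stop("schema 'survival' violation at row ",
         which(x$time <= 0)[1], ": time must be > 0", call. = FALSE)
  }
  x
}

#' Write a pipeline table
#'
#' UTF-8 TSV with header; missing values as '.'.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, na = ".")
  invisible(path)
}

#' Pipeline configuration
#'
#' Validated threshold and protocol settings; unknown keys are rejected.
#' Can be loaded from a YAML file.
#'
#' @param ... Overrides of the defaults: `min_vaf` (0.02),
#'   `min_strand_cov` (10), `detection_strand_cov` (5), `gm_threshold`
#'   (0.27), `r_min` (0.4), `inner_fraction` (0.8), `high_mutpred` (0.75),
#'   `homoplasmy_cut` (0.95), `chamber_volume_mL` (2), `window_s` (60),
#'   `efficiency` (2), `alpha` (0.05), `seed` (1).
#' @return Named list of class `oxs_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    min_vaf = 0.02, min_strand_cov = 10, detection_strand_cov = 5,
    gm_threshold = 0.27, r_min = 0.4, inner_fraction = 0.8,
    high_mutpred = 0.75, homoplasmy_cut = 0.95,
    chamber_volume_mL = 2, window_s = 60, efficiency = 2,
    alpha = 0.05, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  bounds <- list(min_vaf = c(0, 1), gm_threshold = c(0, 1.5),
                 r_min = c(0, 1), inner_fraction = c(0.1, 1),
                 high_mutpred = c(0, 1), homoplasmy_cut = c(0.5, 1),
                 efficiency = c(1, 2), alpha = c(0, 1))
  for (k in names(bounds)) {
    if (cfg[[k]] < bounds[[k]][1] || cfg[[k]] > bounds[[k]][2]) {
      stop("config key '", k, "' outside its documented bounds [",
           bounds[[k]][1], ", ", bounds[[k]][2], "]", call. = FALSE)
    }
  }
  structure(cfg, class = "oxs_config")
}

#' @rdname pipeline_config
#' @param path YAML file with config keys.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort with the seeded synthetic-data module, then executes
#' every stage in dependency order: state-flux processing (ROX correction,
#' FCRs, substrate effects, paired benign/tumor comparisons with Holm
#' correction), heteroplasmy processing (dual-run merge, filters,
#' private/shared and consequence classification, deleterious flags,
#' burden strata, MT-ND gene-size correlation), copy-number computation
#' and tumor/benign ratios, phenotype classification, metagene extraction
#' on the planted expression cohort, scoring, optimal cut-point search and
#' survival analysis. Writes all tables plus a JSON report if `out_dir`
#' is given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A named list report bundle (invisibly written to
#'   `report.json`/TSVs when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "oxs_config"))
  spec <- cohort_spec(seed = config$seed, efficiency = config$efficiency)

  resp <- gen_respirometry_cohort(spec)
  states <- rox_correct(resp$states)
  fcr <- flux_control_ratios(states)
  effects <- substrate_effects(states)
  gm <- states |>
    dplyr::filter(.data$state == "GM_P") |>
    dplyr::select("patient_id", "tissue", "flux") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "flux")
  paired <- select_paired_test(gm$benign, gm$malignant)

  hp <- gen_heteroplasmy_tables(spec, spike_worked_examples = TRUE)
  merged <- merge_runs(hp$calls)
  filt <- filter_calls(merged, min_vaf = config$min_vaf,
                       min_strand_cov = config$min_strand_cov,
                       homoplasmy_cut = config$homoplasmy_cut)
  # every patient was sequenced in both tissues even if a sample had no calls
  sample_index <- tidyr::crossing(
    patient_id = sprintf("P%03d", seq_len(spec$n_pairs)),
    tissue = c("benign", "malignant"))
  records <- filt$records |>
    classify_private_shared(sample_index = sample_index) |>
    classify_consequence() |>
    flag_deleterious()
  burden <- burden_and_strata(
    records, samples = dplyr::distinct(hp$calls, .data$sample_id))
  nd_corr <- tryCatch(nd_gene_size_correlation(records),
                      error = function(e) NULL)

  qp <- gen_qpcr(spec)
  cn <- mt_copy_number(qp$cq, efficiency = config$efficiency)

  tumor_fcr <- fcr |>
    dplyr::filter(.data$tissue == "malignant", .data$state == "GM_P") |>
    # a negative ROX-corrected GM flux means no measurable GM capacity
    dplyr::transmute(sample_id = .data$sample_id,
                     gm_fcr = pmax(0, .data$fcr))
  phenotype <- classify_phenotype(tumor_fcr,
                                  threshold = config$gm_threshold)

  cohort <- gen_expression_survival(spec)
  labels <- tibble::tibble(
    sample_id = names(cohort$truth$severe),
    label = ifelse(cohort$truth$severe == 1, "severe", "mild")
  )
  metagenes <- extract_metagenes(cohort$expr, labels,
                                 r_min = config$r_min,
                                 alpha = config$alpha)
  scores <- metagene_score(cohort$expr, metagenes)
  cutpt <- optimal_cutpoint(scores$score, cohort$survival$time,
                            cohort$survival$event,
                            inner_fraction = config$inner_fraction)
  # HR convention: low-score ("mild-like") group vs high-score group,
  # so a protective HR < 1 means high scorers progress faster
  km <- km_logrank_hr(cohort$survival$time, cohort$survival$event,
                      factor(cutpt$group, levels = c("high", "low")))

  report <- list(
    config = unclass(config),
    respirometry = list(
      paired_gm_test = paired,
      effects = effects
    ),
    heteroplasmy = list(
      n_records = nrow(records |>
                         dplyr::distinct(.data$sample_id, .data$pos,
                                         .data$ref, .data$alt)),
      privacy_counts = dplyr::count(
        dplyr::distinct(records, .data$patient_id, .data$pos, .data$ref,
                        .data$alt, .data$privacy), .data$privacy),
      nd_gene_size_r = if (is.null(nd_corr)) NA_real_ else nd_corr$r
    ),
    copy_number = list(median_cn = stats::median(cn$copy_number)),
    phenotype = dplyr::count(phenotype, .data$label),
    signature = list(
      n_selected = length(metagenes$genes),
      cut = cutpt$cut,
      corrected_p = cutpt$corrected_p,
      harrells_c = cutpt$harrells_c,
      hr = km$hr, ci = c(km$ci_lower, km$ci_upper),
      logrank_p = km$logrank_p
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(states, file.path(out_dir, "states.tsv"))
    write_table(records, file.path(out_dir, "hp_records.tsv"))
    write_table(cn, file.path(out_dir, "copy_number.tsv"))
    write_table(phenotype, file.path(out_dir, "phenotype.tsv"))
    write_table(scores, file.path(out_dir, "metagene_scores.tsv"))
    json <- list(
      config = unclass(config),
      paired_gm_p = paired$p_value,
      privacy_counts = stats::setNames(
        as.list(report$heteroplasmy$privacy_counts$n),
        report$heteroplasmy$privacy_counts$privacy),
      nd_gene_size_r = report$heteroplasmy$nd_gene_size_r,
      median_cn = report$copy_number$median_cn,
      signature = report$signature
    )
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
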