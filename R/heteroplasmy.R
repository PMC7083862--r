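# Heteroplasmy call processing: dual-run merging, threshold/strand
# filtering, private/shared classification, consequence and deleterious
# annotation, per-sample burden and allele-frequency strata, MutPred bins
# and the MT-ND gene-size correlation.

hp_call_columns <- c("patient_id", "sample_id", "tissue", "run_id", "pos",
                     "ref", "alt", "vaf", "fwd_cov", "rev_cov",
                     "fwd_alt", "rev_alt")

assert_hp_calls <- function(calls) {
  missing_cols <- setdiff(setdiff(hp_call_columns, "run_id"), names(calls))
  if (length(missing_cols) > 0) {
    stop("heteroplasmy call table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(calls$vaf < 0 | calls$vaf > 1, na.rm = TRUE)) {
    stop("vaf must lie in [0, 1]", call. = FALSE)
  }
  if (any(calls$pos < 1 | calls$pos > 16569)) {
    stop("pos must lie in 1..16569", call. = FALSE)
  }
  if (any(calls$fwd_alt > calls$fwd_cov | calls$rev_alt > calls$rev_cov,
          na.rm = TRUE)) {
    stop("alt read counts cannot exceed strand coverage", call. = FALSE)
  }
  invisible(calls)
}

#' Merge duplicate sequencing runs
#'
#' Each library is sequenced in (at least) two independent runs; only
#' variants observed in two different runs of the same sample are kept, and
#' the heteroplasmy level is the mean variant allele frequency across those
#' runs. Strand read counts are summed across runs. Single-run variants are
#' dropped and counted in the `dropped_single_run` attribute.
#'
#' @param calls Per-run call tibble with columns `patient_id`, `sample_id`,
#'   `tissue`, `run_id`, `pos`, `ref`, `alt`, `vaf`, `fwd_cov`, `rev_cov`,
#'   `fwd_alt`, `rev_alt` and optionally `mutpred`.
#' @return One record per (sample, variant) seen in >= 2 runs, with
#'   `hp_level` (mean VAF), per-strand totals, and `n_runs`. The number of
#'   discarded single-run observations is attached as attribute
#'   `dropped_single_run`.
#' @export
merge_runs <- function(calls) {
  assert_hp_calls(calls)
  if (!"run_id" %in% names(calls)) {
    stop("merge_runs needs a run_id column", call. = FALSE)
  }
  runs_per_sample <- calls |>
    dplyr::distinct(.data$sample_id, .data$run_id) |>
    dplyr::count(.data$sample_id)
  single <- runs_per_sample$sample_id[runs_per_sample$n < 2]
  if (length(single) > 0) {
    stop("sample(s) with calls from fewer than two runs: ",
         paste(single, collapse = ", "), call. = FALSE)
  }
  has_mutpred <- "mutpred" %in% names(calls)
  merged <- calls |>
    dplyr::group_by(.data$patient_id, .data$sample_id, .data$tissue,
                    .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      n_runs = dplyr::n_distinct(.data$run_id),
      hp_level = mean(.data$vaf),
      fwd_cov = sum(.data$fwd_cov),
      rev_cov = sum(.data$rev_cov),
      fwd_alt = sum(.data$fwd_alt),
      rev_alt = sum(.data$rev_alt),
      mutpred = if (has_mutpred) mean(.data$mutpred) else NA_real_,
      .groups = "drop"
    )
  kept <- dplyr::filter(merged, .data$n_runs >= 2)
  dropped <- sum(merged$n_runs[merged$n_runs < 2])
  attr(kept, "dropped_single_run") <- dropped
  kept
}

#' Filter heteroplasmy records
#'
#' Applies the acceptance thresholds: heteroplasmy level above `min_vaf`
#' (default 2%), coverage above `min_strand_cov` reads on *both* strands
#' (default 10; 5 is the detection-time setting), and forward/reverse
#' strand concordance. The default strand rule accepts a VAF difference up
#' to `max(0.1, 3 * binomial SD)` of the pooled VAF; pass
#' `strand_tolerance = Inf` to disable it. Records at or above
#' `homoplasmy_cut` are labeled homoplasmic and excluded from heteroplasmy
#' counts downstream.
#'
#' @param records Merged record tibble (see [merge_runs()]).
#' @param min_vaf Heteroplasmy detection threshold, exclusive (default 0.02).
#' @param min_strand_cov Minimum reads per strand, exclusive (default 10).
#' @param strand_tolerance Numeric absolute VAF difference allowed between
#'   strands, or `NULL` for the adaptive default, or `Inf` to disable.
#' @param homoplasmy_cut Records with `hp_level >= homoplasmy_cut` are
#'   flagged `homoplasmic` (default 0.95).
#' @return List with `records` (kept, with `homoplasmic` flag) and
#'   `rejections` (tibble of dropped records with a `reason` column).
#' @export
filter_calls <- function(records, min_vaf = 0.02, min_strand_cov = 10,
                         strand_tolerance = NULL, homoplasmy_cut = 0.95) {
  stopifnot(min_vaf > 0, min_vaf < 1, min_strand_cov > 0)
  fwd_vaf <- ifelse(records$fwd_cov > 0, records$fwd_alt / records$fwd_cov, NA)
  rev_vaf <- ifelse(records$rev_cov > 0, records$rev_alt / records$rev_cov, NA)
  tol <- if (is.null(strand_tolerance)) {
    pooled <- (records$fwd_alt + records$rev_alt) /
      pmax(1, records$fwd_cov + records$rev_cov)
    sd_f <- sqrt(pooled * (1 - pooled) / pmax(1, records$fwd_cov))
    sd_r <- sqrt(pooled * (1 - pooled) / pmax(1, records$rev_cov))
    pmax(0.1, 3 * sqrt(sd_f^2 + sd_r^2))
  } else {
    rep_len(strand_tolerance, nrow(records))
  }
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$hp_level <= min_vaf] <- "below_vaf_threshold"
  low_cov <- records$fwd_cov <= min_strand_cov |
    records$rev_cov <= min_strand_cov
  reason[is.na(reason) & low_cov] <- "low_strand_coverage"
  biased <- !is.na(fwd_vaf) & !is.na(rev_vaf) & abs(fwd_vaf - rev_vaf) > tol
  reason[is.na(reason) & biased] <- "strand_bias"
  kept <- records[is.na(reason), , drop = FALSE]
  kept$homoplasmic <- kept$hp_level >= homoplasmy_cut
  rejections <- records[!is.na(reason), , drop = FALSE]
  rejections$reason <- reason[!is.na(reason)]
  list(records = kept, rejections = rejections)
}

#' Classify variants as private or shared within a benign/tumor pair
#'
#' A variant key (`pos`, `ref`, `alt`) present in both tissue types of a
#' patient is `shared`; otherwise it is `private_benign` or
#' `private_cancer`. Patients with no benign (or no malignant) sample at
#' all raise an error; an empty-but-present sample simply contributes no
#' keys.
#'
#' @param records Record tibble with `patient_id`, `tissue` in
#'   `c("benign", "malignant")`, `pos`, `ref`, `alt`.
#' @param sample_index Optional tibble (`patient_id`, `tissue`) listing the
#'   sequenced samples, so that patients whose samples yielded no variants
#'   still count as complete pairs. Defaults to the tissues observed in
#'   `records`.
#' @return `records` with a `privacy` column.
#' @export
classify_private_shared <- function(records, sample_index = NULL) {
  stopifnot(all(records$tissue %in% c("benign", "malignant")))
  idx <- if (is.null(sample_index)) {
    dplyr::distinct(records, .data$patient_id, .data$tissue)
  } else {
    sample_index
  }
  pair_check <- idx |>
    dplyr::distinct(.data$patient_id, .data$tissue) |>
    dplyr::count(.data$patient_id)
  incomplete <- pair_check$patient_id[pair_check$n < 2]
  if (length(incomplete) > 0) {
    stop("patient(s) missing a pair member: ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$patient_id, .data$pos, .data$ref, .data$alt) |>
    dplyr::mutate(privacy = dplyr::case_when(
      dplyr::n_distinct(.data$tissue) == 2 ~ "shared",
      .data$tissue == "benign" ~ "private_benign",
      TRUE ~ "private_cancer"
    )) |>
    dplyr::ungroup()
}

#' Annotate records with codon-level consequences
#'
#' Delegates to [mt_annotate_variant()]; a variant overlapping two protein
#' genes yields two rows. Adds `gene`, `codon_index`, `ref_aa`, `alt_aa`,
#' `synonymy` and `region` (`coding` vs `control_region` for the D-loop
#' dichotomy; rRNA/tRNA genes count as coding and stay sub-classified).
#'
#' @param records Record tibble with `pos`, `ref`, `alt`.
#' @param model Gene model (default embedded rCRS model).
#' @param genome Reference sequence (default embedded).
#' @return `records` joined with consequence columns.
#' @export
classify_consequence <- function(records, model = mt_gene_model(),
                                 genome = mt_reference()) {
  keys <- dplyr::distinct(records, .data$pos, .data$ref, .data$alt)
  cons <- mt_annotate_variant(keys$pos, keys$ref, keys$alt,
                              model = model, genome = genome)
  cons$region <- ifelse(cons$synonymy == "control_region",
                        "control_region", "coding")
  dplyr::inner_join(records, cons, by = c("pos", "ref", "alt"),
                    relationship = "many-to-many")
}

# Gene sets used for the deleterious definition and CI stratification.
deleterious_genes <- function() {
  c(paste0("MT-ND", 1:6), "MT-ND4L", paste0("MT-CO", 1:3), "MT-CYB")
}

ci_genes <- function() {
  c(paste0("MT-ND", 1:6), "MT-ND4L")
}

#' Flag potentially deleterious variants
#'
#' Non-synonymous variants in genes relevant for OXPHOS assembly or
#' function (the MT-ND, MT-CO and MT-CYB genes) are flagged potentially
#' deleterious; ATP-synthase genes are excluded by this definition.
#'
#' @param records Consequence-annotated records (see
#'   [classify_consequence()]).
#' @return `records` with a logical `deleterious` column.
#' @export
flag_deleterious <- function(records) {
  if (!all(c("gene", "synonymy") %in% names(records))) {
    stop("records must be consequence-annotated first", call. = FALSE)
  }
  dplyr::mutate(records, deleterious =
                  .data$synonymy == "non_synonymous" &
                  .data$gene %in% deleterious_genes())
}

#' Per-sample heteroplasmy burden and strata
#'
#' Summarizes each sample: heteroplasmy count (homoplasmic records are
#' excluded), counts per allele-frequency stratum (left-closed bins
#' `[thr,0.10)`, `[0.10,0.20)`, `[0.20,0.50)`, `[0.50,1]`; a level of
#' exactly 10% falls in 10-20%), the maximum non-synonymous CI-gene
#' heteroplasmy level and the derived CI stratum (`none`, `30-60%`,
#' `>60%`).
#'
#' @param records Consequence-annotated records. A variant overlapping two
#'   genes is counted once for the burden (distinct variant keys) but each
#'   gene hit informs the CI stratum.
#' @param samples Optional tibble (`sample_id` and any id columns) so that
#'   variant-free samples appear with zero counts.
#' @param thr Detection threshold used for the lowest bin edge.
#' @return Per-sample tibble with `hp_count`, `af_lt10`, `af_10_20`,
#'   `af_20_50`, `af_ge50`, `max_ci_nonsyn_level`, `ci_stratum`.
#' @export
burden_and_strata <- function(records, samples = NULL, thr = 0.02) {
  recs <- records
  if ("homoplasmic" %in% names(recs)) {
    recs <- dplyr::filter(recs, !.data$homoplasmic)
  }
  per_variant <- recs |>
    dplyr::group_by(.data$sample_id, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      hp_level = .data$hp_level[1],
      ci_nonsyn = any(.data$synonymy == "non_synonymous" &
                        .data$gene %in% ci_genes()),
      .groups = "drop"
    )
  summary <- per_variant |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      hp_count = dplyr::n(),
      af_lt10 = sum(.data$hp_level >= thr & .data$hp_level < 0.10),
      af_10_20 = sum(.data$hp_level >= 0.10 & .data$hp_level < 0.20),
      af_20_50 = sum(.data$hp_level >= 0.20 & .data$hp_level < 0.50),
      af_ge50 = sum(.data$hp_level >= 0.50),
      max_ci_nonsyn_level = ifelse(any(.data$ci_nonsyn),
                                   max(.data$hp_level[.data$ci_nonsyn]),
                                   NA_real_),
      .groups = "drop"
    )
  if (!is.null(samples)) {
    summary <- samples |>
      dplyr::distinct(.data$sample_id, .keep_all = TRUE) |>
      dplyr::left_join(summary, by = "sample_id") |>
      dplyr::mutate(dplyr::across(
        c("hp_count", "af_lt10", "af_10_20", "af_20_50", "af_ge50"),
        ~ tidyr::replace_na(.x, 0L)
      ))
  }
  dplyr::mutate(summary, ci_stratum = dplyr::case_when(
    is.na(.data$max_ci_nonsyn_level) ~ "none",
    .data$max_ci_nonsyn_level > 0.60 ~ ">60%",
    .data$max_ci_nonsyn_level >= 0.30 ~ "30-60%",
    TRUE ~ "none"
  ))
}

#' MutPred score bins per tissue
#'
#' Proportion of non-synonymous heteroplasmies with a MutPred pathogenicity
#' score above `high_cut` (default 0.75) in each tissue type. Unscored
#' records are counted as `na`.
#'
#' @param records Consequence-annotated records with a `mutpred` column.
#' @param high_cut High-pathogenicity threshold (default 0.75).
#' @return Tibble with `tissue`, `n_nonsyn`, `n_high`, `n_na`,
#'   `prop_high` (among scored records).
#' @export
mutpred_bins <- function(records, high_cut = 0.75) {
  nonsyn <- dplyr::filter(records, .data$synonymy == "non_synonymous")
  out <- nonsyn |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      n_nonsyn = dplyr::n(),
      n_high = sum(.data$mutpred > high_cut, na.rm = TRUE),
      n_na = sum(is.na(.data$mutpred)),
      .groups = "drop"
    ) |>
    dplyr::mutate(prop_high = ifelse(.data$n_nonsyn - .data$n_na > 0,
                                     .data$n_high /
                                       (.data$n_nonsyn - .data$n_na),
                                     NA_real_))
  if (any(is.na(out$prop_high))) {
    warning("tissue(s) with no scored non-synonymous records", call. = FALSE)
  }
  out
}

#' Heteroplasmy count vs gene size in the MT-ND genes
#'
#' Correlates the number of malignant-sample heteroplasmies per MT-ND gene
#' with gene length (kbp): Pearson r with the two-tailed t-test on n-2
#' degrees of freedom. Genes without hits count as zero.
#'
#' @param records Consequence-annotated records.
#' @param model Gene model (for gene lengths).
#' @return List with `r`, `p_value`, `n_genes`, and the per-gene tibble
#'   `per_gene` (`gene`, `length_kbp`, `hp_count`).
#' @export
nd_gene_size_correlation <- function(records, model = mt_gene_model()) {
  nd <- model |>
    dplyr::filter(grepl("^MT-ND", .data$name)) |>
    dplyr::transmute(gene = .data$name,
                     length_kbp = (.data$end - .data$start + 1) / 1000)
  counts <- records |>
    dplyr::filter(.data$tissue == "malignant", .data$gene %in% nd$gene) |>
    dplyr::count(.data$gene, name = "hp_count")
  per_gene <- nd |>
    dplyr::left_join(counts, by = "gene") |>
    dplyr::mutate(hp_count = tidyr::replace_na(.data$hp_count, 0L))
  if (sum(per_gene$hp_count > 0) < 3) {
    stop("fewer than 3 MT-ND genes carry heteroplasmies", call. = FALSE)
  }
  ct <- stats::cor.test(per_gene$length_kbp, per_gene$hp_count,
                        method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_genes = nrow(per_gene), per_gene = per_gene)
}

#' Read heteroplasmy calls from a minimal VCF
#'
#' Supports the minimal single-sample VCF dialect documented for this
#' pipeline: one SNV per row, variant allele frequency in the `AF` INFO
#' field and per-strand read counts in `DP4`
#' (ref-forward, ref-reverse, alt-forward, alt-reverse). Sample metadata
#' not representable in a bare VCF is supplied as arguments. Positions
#' are taken as 1-based rCRS coordinates.
#'
#' @param path VCF file (plain or bgzipped).
#' @param patient_id,sample_id,tissue,run_id Metadata attached to every
#'   record.
#' @return A call tibble with the [merge_runs()] columns.
#' @export
read_hp_vcf <- function(path, patient_id, sample_id, tissue, run_id) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("empty VCF: ", path, call. = FALSE)
  if (any(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)) {
    i <- which(nchar(fix$REF) != 1 | nchar(fix$ALT) != 1)[1]
    stop("unsupported variant at VCF row ", i,
         ": only single-nucleotide variants are handled", call. = FALSE)
  }
  af <- as.numeric(vcfR::extract.info(v, "AF"))
  dp4 <- vcfR::extract.info(v, "DP4")
  if (anyNA(af) || anyNA(dp4)) {
    stop("minimal VCF input needs AF and DP4 INFO fields", call. = FALSE)
  }
  counts <- do.call(rbind, lapply(strsplit(dp4, ","), as.integer))
  tibble::tibble(
    patient_id = patient_id,
    sample_id = sample_id,
    tissue = tissue,
    run_id = run_id,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT),
    vaf = af,
    fwd_cov = counts[, 1] + counts[, 3],
    rev_cov = counts[, 2] + counts[, 4],
    fwd_alt = counts[, 3],
    rev_alt = counts[, 4]
  )
}
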