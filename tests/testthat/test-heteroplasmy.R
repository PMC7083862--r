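# Dual-run merging, filtering, privacy/consequence classification,
# burden strata and the gene-size correlation.

base_call <- function(pos = 5000, ref = NULL, alt = NULL, vaf = 0.2,
                      run_id = "run1", tissue = "malignant",
                      patient_id = "P1", cov = 100) {
  genome <- mt_reference()
  if (is.null(ref)) ref <- substr(genome, pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  tibble::tibble(
    patient_id = patient_id,
    sample_id = paste0(patient_id, "_", ifelse(tissue == "benign", "BE", "CA")),
    tissue = tissue, run_id = run_id, pos = pos, ref = ref, alt = alt,
    vaf = vaf, fwd_cov = cov, rev_cov = cov,
    fwd_alt = round(vaf * cov), rev_alt = round(vaf * cov),
    mutpred = NA_real_
  )
}

test_that("merge_runs keeps dual-run variants at the mean VAF", {
  calls <- dplyr::bind_rows(
    base_call(vaf = 0.10, run_id = "run1"),
    base_call(vaf = 0.20, run_id = "run2"),
    base_call(pos = 6000, vaf = 0.30, run_id = "run1"),  # single-run
    base_call(pos = 7000, vaf = 1.0, run_id = "run1"),
    base_call(pos = 7000, vaf = 1.0, run_id = "run2")
  )
  out <- merge_runs(calls)
  expect_equal(nrow(out), 2)
  expect_equal(out$hp_level[out$pos == 5000], 0.15)
  expect_equal(out$hp_level[out$pos == 7000], 1.0)
  expect_equal(attr(out, "dropped_single_run"), 1)
  expect_error(merge_runs(base_call(run_id = "only")), "fewer than two runs")
})

test_that("filter_calls applies the 2% threshold, strand coverage and bias rules", {
  recs <- tibble::tibble(
    patient_id = "P1", sample_id = "P1_CA", tissue = "malignant",
    pos = c(5000, 5001, 5002, 5003),
    ref = "A", alt = "G",
    hp_level = c(0.019, 0.021, 0.30, 0.16),
    fwd_cov = c(50, 50, 50, 5), rev_cov = 50,
    fwd_alt = c(1, 1, 15, 1), rev_alt = c(1, 1, 1, 8)
  )
  out <- filter_calls(recs, min_vaf = 0.02, min_strand_cov = 10,
                      strand_tolerance = 0.1)
  expect_equal(out$records$pos, 5001)
  expect_setequal(out$rejections$reason,
                  c("below_vaf_threshold", "strand_bias",
                    "low_strand_coverage"))
  expect_equal(
    out$rejections$reason[out$rejections$pos == 5000],
    "below_vaf_threshold")
  expect_equal(
    out$rejections$reason[out$rejections$pos == 5002], "strand_bias")
  # homoplasmic records are kept but flagged
  hp1 <- recs[2, ]; hp1$hp_level <- 0.99
  expect_true(filter_calls(hp1)$records$homoplasmic)
})

test_that("filtering per-run then merging equals merging then filtering", {
  spec <- cohort_spec(n_pairs = 15, seed = 33)
  calls <- gen_heteroplasmy_tables(spec)$calls
  # thresholds defined on both per-run calls (vaf) and merged records
  f_then_m <- calls |>
    dplyr::filter(.data$vaf > 0.05) |>
    dplyr::group_by(.data$sample_id, .data$pos) |>
    dplyr::filter(dplyr::n_distinct(.data$run_id) >= 2) |>
    dplyr::ungroup() |>
    merge_runs()
  m_then_f <- merge_runs(calls)
  m_then_f <- m_then_f[m_then_f$hp_level > 0.05, ]
  # same variant keys survive when run VAF jitter is small vs the threshold
  k1 <- paste(f_then_m$sample_id, f_then_m$pos)
  k2 <- paste(m_then_f$sample_id, m_then_f$pos)
  expect_gt(length(intersect(k1, k2)) / max(length(k1), length(k2)), 0.9)
})

test_that("privacy classification partitions each patient's variants", {
  calls <- dplyr::bind_rows(
    base_call(pos = 5000, tissue = "malignant"),
    base_call(pos = 5000, tissue = "benign"),
    base_call(pos = 6000, tissue = "malignant"),
    base_call(pos = 8000, tissue = "benign")
  )
  out <- classify_private_shared(calls)
  expect_equal(unique(out$privacy[out$pos == 5000]), "shared")
  expect_equal(out$privacy[out$pos == 6000], "private_cancer")
  expect_equal(out$privacy[out$pos == 8000], "private_benign")
  # empty benign sample: all tumor variants private_cancer
  idx <- tibble::tibble(patient_id = "P1",
                        tissue = c("benign", "malignant"))
  tum_only <- dplyr::bind_rows(base_call(pos = 6000),
                               base_call(pos = 9000))
  out2 <- classify_private_shared(tum_only, sample_index = idx)
  expect_equal(unique(out2$privacy), "private_cancer")
  expect_error(classify_private_shared(base_call()), "missing a pair")
  # property: counts per privacy class sum to distinct variant keys
  spec <- cohort_spec(n_pairs = 25, seed = 12)
  sim <- gen_heteroplasmy_tables(spec)
  rec <- merge_runs(sim$calls)
  idx_all <- tidyr::crossing(patient_id = sprintf("P%03d", 1:25),
                             tissue = c("benign", "malignant"))
  cls <- classify_private_shared(rec, sample_index = idx_all)
  per_pat <- cls |>
    dplyr::distinct(.data$patient_id, .data$pos, .data$ref, .data$alt,
                    .data$privacy) |>
    dplyr::count(.data$patient_id)
  keys <- cls |>
    dplyr::distinct(.data$patient_id, .data$pos, .data$ref, .data$alt) |>
    dplyr::count(.data$patient_id)
  expect_equal(per_pat, keys)
})

test_that("consequence and deleterious annotation follow the gene sets", {
  calls <- dplyr::bind_rows(
    base_call(pos = 11991, ref = "T", alt = "C"),   # MT-ND4 non-syn
    base_call(pos = 15995, ref = "G", alt = "A"),   # MT-TP tRNA
    base_call(pos = 300)                            # control region
  )
  ann <- classify_consequence(calls)
  nd4 <- ann[which(ann$gene == "MT-ND4"), ]
  expect_equal(nd4$synonymy, "non_synonymous")
  expect_equal(nd4$codon_index, 411L)
  expect_equal(ann$synonymy[ann$pos == 15995], "tRNA")
  expect_equal(ann$synonymy[ann$pos == 300], "control_region")
  expect_equal(ann$region[ann$pos == 300], "control_region")
  expect_equal(ann$region[ann$pos == 15995], "coding")
  fl <- flag_deleterious(ann)
  expect_true(fl$deleterious[which(fl$gene == "MT-ND4")])
  expect_false(any(fl$deleterious[fl$pos %in% c(15995, 300)]))
  # non-synonymous MT-ATP6 is excluded from the deleterious definition
  atp <- tibble::tibble(gene = c("MT-ATP6", "MT-ND1", "MT-ND1"),
                        synonymy = c("non_synonymous", "non_synonymous",
                                     "synonymous"))
  expect_equal(flag_deleterious(atp)$deleterious, c(FALSE, TRUE, FALSE))
})

test_that("burden summaries bin levels and derive the CI stratum", {
  rec <- tibble::tibble(
    patient_id = "P1", sample_id = "S1", tissue = "malignant",
    pos = c(1, 2, 3, 4), ref = "A", alt = "G",
    hp_level = c(0.05, 0.10, 0.35, 0.58),
    gene = c("CR", "MT-CO1", "MT-ND1", "MT-ND4L"),
    synonymy = c("control_region", "synonymous", "non_synonymous",
                 "non_synonymous")
  )
  out <- burden_and_strata(rec)
  expect_equal(out$hp_count, 4)
  expect_equal(out$af_lt10, 1)
  expect_equal(out$af_10_20, 1)   # exactly 0.10 falls in 10-20%
  expect_equal(out$af_20_50, 1)
  expect_equal(out$af_ge50, 1)
  expect_equal(out$max_ci_nonsyn_level, 0.58)
  expect_equal(out$ci_stratum, "30-60%")  # 0.58 is within 30-60%
  # a single 0.35-level CI variant lands in the 30-60% stratum
  one <- rec[3, ]
  expect_equal(burden_and_strata(one)$ci_stratum, "30-60%")
  # >60% stratum
  hi <- rec[4, ]; hi$hp_level <- 0.65
  expect_equal(burden_and_strata(hi)$ci_stratum, ">60%")
  # empty sample via the sample index
  empty <- burden_and_strata(rec[0, ],
                             samples = tibble::tibble(sample_id = "S9"))
  expect_equal(empty$hp_count, 0)
  expect_equal(empty$ci_stratum, "none")
})

test_that("MutPred bins report the proportion above the high cut", {
  rec <- tibble::tibble(
    tissue = c("malignant", "malignant", "benign"),
    synonymy = "non_synonymous",
    mutpred = c(0.9, 0.5, 0.8)
  )
  out <- mutpred_bins(rec)
  expect_equal(out$prop_high[out$tissue == "malignant"], 0.5)
  expect_equal(out$prop_high[out$tissue == "benign"], 1.0)
  rec2 <- rec; rec2$mutpred <- NA_real_
  expect_warning(out2 <- mutpred_bins(rec2), "no scored")
  expect_true(all(is.na(out2$prop_high)))
})

test_that("gene-size correlation is 1 for proportional counts and ~0 under permutation", {
  model <- mt_gene_model()
  nd <- model[grepl("^MT-ND", model$name), ]
  lens <- nd$end - nd$start + 1
  prop_counts <- round(lens / 100)
  rec <- tibble::tibble(
    tissue = "malignant",
    gene = rep(nd$name, prop_counts)
  )
  out <- nd_gene_size_correlation(rec)
  expect_gt(out$r, 0.99)
  expect_equal(nrow(out$per_gene), 7)
  # permuting counts across genes destroys the correlation on average
  set.seed(8)
  rs <- replicate(300, {
    perm <- sample(prop_counts)
    recp <- tibble::tibble(tissue = "malignant",
                           gene = rep(nd$name, perm))
    nd_gene_size_correlation(recp)$r
  })
  expect_lt(abs(mean(rs)), 0.12)
  expect_error(
    nd_gene_size_correlation(rec[rec$gene %in% c("MT-ND1", "MT-ND2"), ]),
    "fewer than 3")
})

test_that("minimal VCF input round-trips into the call schema", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Strand counts\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrM\t11991\t.\tT\tC\t.\tPASS\tAF=0.82;DP4=18,20,82,80",
    "chrM\t300\t.\tA\tG\t.\tPASS\tAF=0.10;DP4=90,88,10,12"
  ), vcf)
  calls <- read_hp_vcf(vcf, patient_id = "P1", sample_id = "P1_CA",
                       tissue = "malignant", run_id = "run1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$pos, c(11991L, 300L))
  expect_equal(calls$vaf, c(0.82, 0.10))
  expect_equal(calls$fwd_cov, c(100L, 100L))
  expect_equal(calls$rev_alt, c(80L, 12L))
  # indels are rejected, matching the SNV-only contract
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chrM\t100\t.\tAT\tA\t.\tPASS\tAF=0.1;DP4=1,1,1,1"
  ), vcf)
  expect_error(read_hp_vcf(vcf, "P1", "P1_CA", "malignant", "run1"),
               "single-nucleotide")
})
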