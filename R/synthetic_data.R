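# Seeded generators emulating the paired benign/malignant prostate cohort:
# respirometry state tables (with a programmable N->S substrate shift),
# dual-run heteroplasmy call tables, duplex qPCR Cq tables, and
# expression + survival cohorts with a planted severe-phenotype signature.

#' Cohort simulation specification
#'
#' Bundles and validates the knobs of all four generators. The defaults
#' mirror the study conditions: 50 benign/malignant pairs with 20%
#' high-grade tumors; benign tissue with higher glutamate&malate-driven
#' OXPHOS (ADP effect 4.5 vs 2.4 pmol s^-1 mg^-1 in tumors) and tumors
#' with a larger succinate gain and oxidative-stress decrement (1.7 vs
#' 1.1); a heteroplasmy spectrum of mostly low-level variants
#' (Beta(0.3, 2) truncated at the 2% detection threshold) with per-patient
#' expected counts of 1.68 private-cancer, 0.66 private-benign and 0.6
#' shared variants; mtDNA copy numbers around a median of ~310 per diploid
#' cell; and an expression cohort in which a latent severe phenotype
#' shifts 11 planted genes and doubles the hazard.
#'
#' @param n_pairs Number of benign/malignant pairs.
#' @param high_grade_fraction Fraction of tumors with Gleason > 7.
#' @param cv_subject Between-subject coefficient of variation of overall
#'   capacity (a multiplicative factor shared by both tissues of a pair;
#'   cancels exactly in flux control ratios).
#' @param cv_resid Residual per-state coefficient of variation.
#' @param n_integrity_sd Log-SD of the per-sample N-pathway integrity
#'   factor applied to the GM/N-linked states (larger in tumors than the
#'   benign `0.15`); this carries the between-sample spread of the
#'   relative GM capacity (~0.10 at the default).
#' @param hp_rates Named numeric: expected per-patient counts
#'   (`private_cancer`, `private_benign`, `shared`).
#' @param af_shape Beta parameters of the heteroplasmy-level spectrum.
#' @param strand_depth Expected per-strand read depth per run.
#' @param run_jitter_sd SD of the between-run VAF jitter.
#' @param cn_median,cn_log_sd Copy-number distribution (log-normal).
#' @param cq_noise_sd Per-Cq measurement noise (cycles).
#' @param efficiency qPCR amplification base E.
#' @param n_subjects,n_genes,n_planted Expression cohort size.
#' @param expr_effect Planted shift (log2 SD units) of signature genes in
#'   severe subjects; 1.96 corresponds to a point-biserial r of ~0.7.
#' @param hr_mild_vs_severe True hazard ratio of mild vs severe subjects.
#' @param baseline_hazard Event hazard of severe subjects (per time unit).
#' @param censor_rate Independent censoring hazard.
#' @param seed Default seed used when a generator is called without one.
#' @return A validated list of class `oxs_cohort_spec`.
#' @export
cohort_spec <- function(n_pairs = 50,
                        high_grade_fraction = 0.2,
                        cv_subject = 0.15,
                        cv_resid = 0.08,
                        n_integrity_sd = 0.35,
                        hp_rates = c(private_cancer = 1.68,
                                     private_benign = 0.66,
                                     shared = 0.60),
                        af_shape = c(0.3, 2),
                        strand_depth = 200,
                        run_jitter_sd = 0.01,
                        cn_median = 310,
                        cn_log_sd = 0.35,
                        cq_noise_sd = 0.1,
                        efficiency = 2,
                        n_subjects = 500,
                        n_genes = 1000,
                        n_planted = 11,
                        expr_effect = 1.96,
                        hr_mild_vs_severe = 0.5,
                        baseline_hazard = 0.08,
                        censor_rate = 0.03,
                        seed = 1L) {
  spec <- as.list(environment())
  problems <- character(0)
  if (n_pairs < 1) problems <- c(problems, "n_pairs must be >= 1")
  if (high_grade_fraction < 0 || high_grade_fraction > 1) {
    problems <- c(problems, "high_grade_fraction must lie in [0, 1]")
  }
  if (cv_subject < 0 || cv_resid < 0 || n_integrity_sd < 0) {
    problems <- c(problems, "noise SDs/CVs must be >= 0")
  }
  if (any(hp_rates < 0)) problems <- c(problems, "hp_rates must be >= 0")
  if (any(af_shape <= 0)) problems <- c(problems, "af_shape must be > 0")
  if (efficiency <= 1 || efficiency > 2) {
    problems <- c(problems, "efficiency must lie in (1, 2]")
  }
  if (hr_mild_vs_severe <= 0) {
    problems <- c(problems, "hr_mild_vs_severe must be > 0")
  }
  if (length(problems) > 0) {
    stop("invalid cohort spec: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  structure(spec, class = "oxs_cohort_spec")
}

# Programmed mean state fluxes (pmol s^-1 mg^-1). Tumor values reproduce
# the printed effect sizes: ADP effect 4.5 (benign) vs 2.4 (tumor),
# stress decrement 1.1 vs 1.7, a succinate gain larger in tumors, and a
# tumor GM_P/NS_E ratio near 0.27. High-grade tumors carry a deeper
# N-pathway loss fully compensated through succinate.
suit_state_means <- function(tissue = c("benign", "malignant"),
                             high_grade = FALSE) {
  tissue <- match.arg(tissue)
  if (tissue == "benign") {
    c(GM_L = 1.5, GM_P_pre = 6.0, GM_P = 4.9, N_P = 5.5, NS_P = 7.5,
      NS_E = 7.9, S_E = 3.9, ROX = 0.3)
  } else if (!high_grade) {
    c(GM_L = 1.6, GM_P_pre = 4.0, GM_P = 2.3, N_P = 3.8, NS_P = 6.8,
      NS_E = 7.2, S_E = 5.1, ROX = 0.3)
  } else {
    c(GM_L = 1.3, GM_P_pre = 2.9, GM_P = 1.2, N_P = 2.5, NS_P = 6.3,
      NS_E = 6.8, S_E = 5.6, ROX = 0.3)
  }
}

#' Simulate a paired respirometry cohort
#'
#' Generates long-format state tables for `n_pairs` benign/malignant
#' pairs. Noise is multiplicative: each pair shares a subject-level
#' capacity factor (CV `cv_subject`, cancelling in flux control ratios),
#' each sample draws an N-pathway integrity factor applied to the
#' GM/N-linked states (log-SD `n_integrity_sd` in tumors, 0.15 in benign
#' tissue), and every state adds residual noise with CV `cv_resid`; tumor
#' means carry the programmed N->S substrate shift, amplified in the
#' high-grade stratum.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param noise Multiplier on both SDs; 0 gives the programmed means
#'   exactly.
#' @return List with `states` (tibble: `patient_id`, `sample_id`,
#'   `tissue`, `gleason`, `high_grade`, `wet_mass_mg`, `state`, `flux`)
#'   and `truth` (programmed means per tissue/grade).
#' @export
gen_respirometry_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                                    noise = 1) {
  stopifnot(inherits(spec, "oxs_cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_pairs
    n_high <- round(spec$high_grade_fraction * n)
    high <- sample(rep(c(TRUE, FALSE), c(n_high, n - n_high)))
    gleason <- ifelse(high, sample(8:10, n, replace = TRUE),
                      sample(6:7, n, replace = TRUE))
    n_states <- c("GM_L", "GM_P_pre", "GM_P", "N_P")
    states <- purrr::map_dfr(seq_len(n), function(i) {
      sd_subj <- spec$cv_subject * noise
      f_subj <- exp(stats::rnorm(1, -sd_subj^2 / 2, sd_subj))
      purrr::map_dfr(c("benign", "malignant"), function(tis) {
        mu <- suit_state_means(tis, high_grade = high[i])
        sd_n <- ifelse(tis == "benign", 0.15, spec$n_integrity_sd) * noise
        n_fac <- exp(stats::rnorm(1, -sd_n^2 / 2, sd_n))
        flux <- mu * f_subj *
          ifelse(names(mu) %in% n_states, n_fac, 1) *
          (1 + stats::rnorm(length(mu), 0, spec$cv_resid * noise))
        flux <- pmax(flux, 0)
        tibble::tibble(
          patient_id = sprintf("P%03d", i),
          sample_id = sprintf("P%03d_%s", i,
                              ifelse(tis == "benign", "BE", "CA")),
          tissue = tis,
          gleason = gleason[i],
          high_grade = high[i],
          wet_mass_mg = round(stats::rnorm(1, 6.5, 1.5 * noise), 2),
          state = names(mu),
          flux = unname(flux)
        )
      })
    })
    truth <- list(
      means = list(benign = suit_state_means("benign"),
                   malignant = suit_state_means("malignant"),
                   malignant_high_grade = suit_state_means("malignant", TRUE)),
      high_grade = stats::setNames(high, sprintf("P%03d", seq_len(n)))
    )
    list(states = states, truth = truth)
  })
}

#' Simulate a titration trace from known state fluxes
#'
#' Builds a piecewise-constant volume-specific flux trace (1-s sampling,
#' default 300 s per state) with multiplicative noise, plus the matching
#' events table, so that [extract_state_fluxes()] round-trips the state
#' table.
#'
#' @param state_flux Named numeric of mass-specific state fluxes.
#' @param wet_mass_mg,chamber_volume_mL Scaling back to volume-specific
#'   flux.
#' @param state_duration_s Seconds per state.
#' @param noise_cv Coefficient of variation of the flux noise.
#' @param seed Integer seed.
#' @return List with `trace` and `events` tibbles.
#' @export
gen_trace <- function(state_flux, wet_mass_mg = 5, chamber_volume_mL = 2,
                      state_duration_s = 300, noise_cv = 0.01, seed = 1L) {
  withr::with_seed(seed, {
    states <- names(state_flux)
    n_per <- state_duration_s
    time <- seq_len(length(states) * n_per)
    vol_flux <- rep(state_flux * wet_mass_mg / chamber_volume_mL,
                    each = n_per)
    vol_flux <- vol_flux * (1 + stats::rnorm(length(vol_flux), 0, noise_cv))
    o2 <- 250 - cumsum(vol_flux) * 1e-3
    trace <- tibble::tibble(time_s = time, o2_uM = o2,
                            flux_pmol_s_mL = vol_flux)
    events <- tibble::tibble(time_s = (seq_along(states) - 1) * n_per,
                             label = states)
    list(trace = trace, events = events)
  })
}

#' Simulate dual-run heteroplasmy call tables
#'
#' Draws per-patient private-benign, private-cancer and shared variants at
#' the programmed expected counts, with positions uniform over the genome
#' (excluding the placeholder 3107) so the gene-size/count correlation
#' emerges, heteroplasmy levels from the truncated Beta spectrum, two
#' sequencing runs with jittered VAFs, and binomial per-strand read
#' counts. MutPred-like scores are attached to every variant (higher in
#' tumors). The three documented example variants can be spiked in.
#'
#' @param spec A [cohort_spec()].
#' @param model Gene model (used only for spike-in bookkeeping).
#' @param genome Reference sequence for ref alleles.
#' @param seed Integer seed.
#' @param spike_worked_examples Add 11991 T>C, 13495 A>G and 10551 T>C to
#'   the first three tumor samples at levels 0.82, 0.85, 0.58.
#' @return List with `calls` (per-run tibble, see [merge_runs()]) and
#'   `truth` (per-patient programmed variant table with privacy).
#' @export
gen_heteroplasmy_tables <- function(spec = cohort_spec(),
                                    model = mt_gene_model(),
                                    genome = mt_reference(),
                                    seed = spec$seed,
                                    spike_worked_examples = FALSE) {
  stopifnot(inherits(spec, "oxs_cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_pairs
    draw_af <- function(k) {
      out <- numeric(0)
      while (length(out) < k) {
        x <- stats::rbeta(k, spec$af_shape[1], spec$af_shape[2])
        out <- c(out, x[x > 0.02 & x < 0.95])
      }
      out[seq_len(k)]
    }
    sample_pos <- function(k) {
      p <- sample(setdiff(seq_len(16569L), 3107L), k, replace = FALSE)
      p
    }
    truth <- purrr::map_dfr(seq_len(n), function(i) {
      counts <- stats::rpois(3, spec$hp_rates[c("private_cancer",
                                                "private_benign", "shared")])
      k <- sum(counts)
      if (k == 0) return(NULL)
      pos <- sample_pos(k)
      ref <- substring(genome, pos, pos)
      alt <- vapply(ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1)
      }, character(1), USE.NAMES = FALSE)
      tibble::tibble(
        patient_id = sprintf("P%03d", i),
        privacy = rep(c("private_cancer", "private_benign", "shared"),
                      counts),
        pos = pos, ref = ref, alt = alt,
        hp_level = draw_af(k)
      )
    })
    if (spike_worked_examples) {
      spikes <- tibble::tibble(
        patient_id = sprintf("P%03d", 1:3),
        privacy = "private_cancer",
        pos = c(11991L, 13495L, 10551L),
        ref = c("T", "A", "T"),
        alt = c("C", "G", "C"),
        hp_level = c(0.82, 0.85, 0.58)
      )
      truth <- dplyr::bind_rows(spikes, truth) |>
        dplyr::distinct(.data$patient_id, .data$pos, .keep_all = TRUE)
    }
    expand <- truth |>
      dplyr::mutate(in_benign = .data$privacy != "private_cancer",
                    in_cancer = .data$privacy != "private_benign") |>
      tidyr::pivot_longer(c("in_benign", "in_cancer"), names_to = "which",
                          values_to = "present") |>
      dplyr::filter(.data$present) |>
      dplyr::mutate(tissue = ifelse(.data$which == "in_benign", "benign",
                                    "malignant")) |>
      dplyr::select(-"which", -"present")
    calls <- expand |>
      tidyr::crossing(run_id = c("run1", "run2")) |>
      dplyr::mutate(
        sample_id = sprintf("%s_%s", .data$patient_id,
                            ifelse(.data$tissue == "benign", "BE", "CA")),
        vaf_run = pmin(0.999, pmax(
          0.001, .data$hp_level +
            stats::rnorm(dplyr::n(), 0, spec$run_jitter_sd))),
        fwd_cov = stats::rpois(dplyr::n(), spec$strand_depth),
        rev_cov = stats::rpois(dplyr::n(), spec$strand_depth),
        fwd_alt = stats::rbinom(dplyr::n(), .data$fwd_cov, .data$vaf_run),
        rev_alt = stats::rbinom(dplyr::n(), .data$rev_cov, .data$vaf_run),
        vaf = (.data$fwd_alt + .data$rev_alt) /
          pmax(1L, .data$fwd_cov + .data$rev_cov),
        mutpred = ifelse(.data$tissue == "malignant",
                         stats::rbeta(dplyr::n(), 3, 1.2),
                         stats::rbeta(dplyr::n(), 1.2, 3))
      ) |>
      dplyr::group_by(.data$patient_id, .data$pos, .data$tissue) |>
      dplyr::mutate(mutpred = .data$mutpred[1]) |>
      dplyr::ungroup() |>
      dplyr::select("patient_id", "sample_id", "tissue", "run_id", "pos",
                    "ref", "alt", "vaf", "fwd_cov", "rev_cov", "fwd_alt",
                    "rev_alt", "mutpred")
    list(calls = calls, truth = truth)
  })
}

#' Simulate a duplex qPCR table
#'
#' True copy numbers are log-normal around the programmed median; sample
#' Cq pairs are derived from the copy-number formula and perturbed with
#' independent Gaussian Cq noise. The plasmid calibrator is reported
#' noise-free (it is measured once per plate at high precision).
#'
#' @param spec A [cohort_spec()].
#' @param n Number of samples (default `2 * n_pairs`).
#' @param seed Integer seed.
#' @return List with `cq` (tibble: `sample_id`, `cq_mt`, `cq_n`,
#'   `plasmid_cq_mt`, `plasmid_cq_n`) and `truth` (`sample_id`,
#'   `copy_number`).
#' @export
gen_qpcr <- function(spec = cohort_spec(), n = 2 * spec$n_pairs,
                     seed = spec$seed) {
  stopifnot(inherits(spec, "oxs_cohort_spec"))
  withr::with_seed(seed, {
    cn <- stats::rlnorm(n, log(spec$cn_median), spec$cn_log_sd)
    # CN = 2 * E^(-ddCq)  =>  ddCq = -log_E(CN / 2)
    ddcq <- -log(cn / 2, base = spec$efficiency)
    plasmid_cq_mt <- 15
    plasmid_cq_n <- 15
    cq_n <- stats::rnorm(n, 25, 0.5)
    cq_mt <- cq_n + ddcq + (plasmid_cq_mt - plasmid_cq_n)
    cq <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      cq_mt = cq_mt + stats::rnorm(n, 0, spec$cq_noise_sd),
      cq_n = cq_n + stats::rnorm(n, 0, spec$cq_noise_sd),
      plasmid_cq_mt = plasmid_cq_mt,
      plasmid_cq_n = plasmid_cq_n
    )
    truth <- tibble::tibble(sample_id = cq$sample_id, copy_number = cn)
    list(cq = cq, truth = truth)
  })
}

#' Simulate an expression + survival cohort with a planted signature
#'
#' A latent binary severe phenotype (prevalence 0.5) shifts `n_planted`
#' signature genes upward by `expr_effect` log2 SD units; survival times
#' are exponential with hazard `baseline_hazard` for severe and
#' `baseline_hazard * hr_mild_vs_severe` for mild subjects, with
#' independent exponential censoring.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return List with `expr` (gene x subject matrix, FPKM-like scale),
#'   `survival` (tibble: `sample_id`, `time`, `event`), and `truth`
#'   (`severe` labels, `planted_genes`, `hr_mild_vs_severe`).
#' @export
gen_expression_survival <- function(spec = cohort_spec(),
                                    seed = spec$seed) {
  stopifnot(inherits(spec, "oxs_cohort_spec"))
  withr::with_seed(seed, {
    n <- spec$n_subjects
    g <- spec$n_genes
    severe <- stats::rbinom(n, 1, 0.5)
    genes <- sprintf("G%04d", seq_len(g))
    planted <- genes[seq_len(spec$n_planted)]
    logexpr <- matrix(stats::rnorm(g * n, 5, 1), nrow = g,
                      dimnames = list(genes, sprintf("S%04d", seq_len(n))))
    logexpr[planted, ] <- logexpr[planted, ] +
      spec$expr_effect * matrix(severe, nrow = spec$n_planted, ncol = n,
                                byrow = TRUE)
    expr <- 2^logexpr - 1
    expr[expr < 0] <- 0
    hazard <- ifelse(severe == 1, spec$baseline_hazard,
                     spec$baseline_hazard * spec$hr_mild_vs_severe)
    t_event <- stats::rexp(n, hazard)
    t_cens <- stats::rexp(n, spec$censor_rate)
    surv <- tibble::tibble(
      sample_id = colnames(logexpr),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    list(expr = expr, survival = surv,
         truth = list(severe = stats::setNames(severe, colnames(logexpr)),
                      planted_genes = planted,
                      hr_mild_vs_severe = spec$hr_mild_vs_severe))
  })
}
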