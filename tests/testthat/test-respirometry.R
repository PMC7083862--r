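# State-flux extraction, ROX correction, FCRs and titration-effect deltas.

make_states <- function(flux, tissue = "malignant", id = "s1") {
  tibble::tibble(sample_id = id, tissue = tissue,
                 state = names(flux), flux = unname(flux))
}

test_that("state fluxes scale from volume to wet mass and resist spikes", {
  tr <- tibble::tibble(time_s = 1:200, o2_uM = 250,
                       flux_pmol_s_mL = rep(100, 200))
  ev <- tibble::tibble(time_s = c(0, 100), label = c("GM_L", "GM_P"))
  out <- extract_state_fluxes(tr, ev, wet_mass_mg = 5, window_s = 60,
                              chamber_volume_mL = 2)
  expect_equal(out$flux, c(40, 40))  # 100 * 2 mL / 5 mg
  # an outlier spike in the plateau leaves the median unchanged
  tr2 <- tr
  tr2$flux_pmol_s_mL[180] <- 1e4
  out2 <- extract_state_fluxes(tr2, ev, wet_mass_mg = 5, window_s = 60,
                               chamber_volume_mL = 2)
  expect_equal(out2$flux[2], 40)
  expect_error(
    extract_state_fluxes(tr, tibble::tibble(time_s = 0, label = "XX"),
                         wet_mass_mg = 5),
    "protocol error")
  expect_warning(
    extract_state_fluxes(tr, tibble::tibble(time_s = c(0, 30),
                                            label = c("GM_L", "GM_P")),
                         wet_mass_mg = 5, window_s = 60),
    "truncated")
})

test_that("synthetic traces round-trip the programmed state fluxes within 2%", {
  truth <- suppressWarnings(
    oxshift:::suit_state_means("malignant"))
  sim <- gen_trace(truth, wet_mass_mg = 5, chamber_volume_mL = 2,
                   noise_cv = 0.01, seed = 99)
  out <- extract_state_fluxes(sim$trace, sim$events, wet_mass_mg = 5,
                              window_s = 60, chamber_volume_mL = 2)
  got <- setNames(out$flux, out$state)[names(truth)]
  expect_true(all(abs(got / truth - 1) < 0.02))
})

test_that("ROX correction subtracts, zeroes ROX, and flags negatives", {
  st <- make_states(c(GM_P = 10, NS_E = 20, S_E = 0.5, ROX = 1))
  out <- rox_correct(st)
  f <- setNames(out$flux, out$state)
  expect_equal(unname(f[c("GM_P", "NS_E", "S_E", "ROX")]), c(9, 19, -0.5, 0))
  expect_true(out$negative_flux[out$state == "S_E"])
  # ROX = 0 leaves fluxes unchanged
  st0 <- make_states(c(GM_P = 10, NS_E = 20, ROX = 0))
  expect_equal(rox_correct(st0)$flux, st0$flux)
  expect_error(rox_correct(make_states(c(GM_P = 10))), "ROX")
})

test_that("split replicates average per state and concatenate ids", {
  a <- make_states(c(GM_P = 10, NS_E = 40, ROX = 1))
  b <- make_states(c(GM_P = 12, NS_E = 44, ROX = 1))
  a$replicate_id <- "A"; b$replicate_id <- "B"
  out <- average_splits(list(a, b))
  expect_equal(out$flux[out$state == "GM_P"], 11)
  expect_equal(unique(out$replicate_ids), "A+B")
  expect_equal(average_splits(list(a))$flux,
               a$flux[order(a$state)])
  b2 <- b[b$state != "NS_E", ]
  expect_error(average_splits(list(a, b2)), "NS_E")
})

test_that("FCRs normalize to NS_E and are scale invariant", {
  st <- make_states(c(GM_P = 10, NS_E = 40, S_E = 20, ROX = 0))
  out <- flux_control_ratios(st)
  expect_equal(out$fcr[out$state == "NS_E"], 1)
  expect_equal(out$fcr[out$state == "GM_P"], 0.25)
  expect_error(
    flux_control_ratios(make_states(c(GM_P = 1, NS_E = 0))),
    "degenerate")
  # property: multiplying all fluxes by c > 0 leaves every FCR unchanged
  set.seed(5)
  for (i in 1:25) {
    flux <- stats::runif(5, 0.5, 30)
    names(flux) <- c("GM_L", "GM_P", "NS_P", "NS_E", "S_E")
    cst <- stats::runif(1, 0.01, 50)
    f1 <- flux_control_ratios(make_states(flux))$fcr
    f2 <- flux_control_ratios(make_states(flux * cst))$fcr
    expect_equal(f1, f2)
  }
})

test_that("ROX correction then FCR equals FCR of pre-subtracted fluxes", {
  set.seed(6)
  for (i in 1:25) {
    flux <- c(stats::runif(4, 1, 30), ROX = stats::runif(1, 0, 0.9))
    names(flux)[1:4] <- c("GM_P", "N_P", "NS_P", "NS_E")
    a <- flux_control_ratios(rox_correct(make_states(flux)))
    pre <- c(flux[1:4] - flux["ROX"], ROX = 0)
    b <- flux_control_ratios(make_states(pre))
    expect_equal(dplyr::arrange(a, state)$fcr, dplyr::arrange(b, state)$fcr)
  }
})

test_that("substrate effects compute the documented deltas", {
  st <- make_states(c(GM_L = 2, GM_P_pre = 6, GM_P = 5, N_P = 6.5,
                      NS_P = 13, NS_E = 14, S_E = 9, ROX = 0))
  eff <- substrate_effects(st)
  d <- setNames(eff$delta, eff$effect)
  expect_equal(unname(d["ADP_effect"]), 4)
  expect_equal(unname(d["stress_effect"]), -1)
  expect_equal(unname(d["pyruvate_effect"]), 1.5)
  expect_equal(unname(d["succinate_effect"]), 6.5)
  expect_equal(unname(d["FCCP_effect"]), 1)
  expect_equal(unname(d["rotenone_effect"]), 5)
  # NS_E == S_E means no N-pathway contribution to ET capacity
  st2 <- make_states(c(NS_E = 10, S_E = 10, ROX = 0))
  eff2 <- substrate_effects(st2)
  expect_equal(eff2$delta[eff2$effect == "rotenone_effect"], 0)
  # absent states give NA for that delta only
  expect_true(is.na(eff2$delta[eff2$effect == "ADP_effect"]))
})

test_that("programmed tumor succinate shift exceeds the benign mean", {
  g <- gen_respirometry_cohort(cohort_spec(n_pairs = 30, seed = 21))
  eff <- substrate_effects(rox_correct(g$states))
  succ <- eff |>
    dplyr::filter(.data$effect == "succinate_effect") |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(m = mean(.data$delta))
  expect_gt(succ$m[succ$tissue == "malignant"],
            succ$m[succ$tissue == "benign"])
})

test_that("CIV activity is the azide-corrected flux", {
  expect_equal(civ_activity(50, 8)$civ_flux, 42)
  expect_equal(civ_activity(8, 8)$civ_flux, 0)
  expect_true(civ_activity(5, 8)$negative_flux)
})

test_that("rotenone titration recovers the programmed compensation slope", {
  # programmed: S-relative capacity rises linearly with N-inhibition
  slope_true <- 0.3
  doses <- c(0, 1, 2, 4, 8, 16)
  inhib <- c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
  set.seed(7)
  tt <- tibble::tibble(
    rotenone_dose_nM = doses,
    n_flux = 10 * (1 - inhib) * (1 + rnorm(6, 0, 0.005)),
    s_flux = 10 * (0.4 + slope_true * inhib) * (1 + rnorm(6, 0, 0.005)),
    ns_e = 10
  )
  out <- s_pathway_compensation(tt)
  expect_equal(out$n_inhibition_pct[1], 0)
  expect_lte(max(out$s_relative_capacity), 1)
  fit <- stats::lm(s_relative_capacity ~ I(n_inhibition_pct / 100),
                   data = out)
  expect_lt(abs(stats::coef(fit)[2] / slope_true - 1), 0.1)
  expect_error(s_pathway_compensation(tt[tt$rotenone_dose_nM > 0, ]),
               "baseline")
})
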