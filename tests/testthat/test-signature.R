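# Phenotype classification, metagene extraction/scoring, optimal
# cut-point search, KM/HR analysis, Harrell's C and Cox covariates.

test_that("phenotype classification uses the 27% boundary inclusively", {
  out <- classify_phenotype(c(0.27, 0.271, 0, 1.2))
  expect_equal(out$label, c("severe", "mild", "severe", "mild"))
  expect_equal(out$fcr_above_one, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(classify_phenotype(-0.1), ">= 0")
})

test_that("a gene equal to the label vector is selected with r = 1", {
  labels <- tibble::tibble(sample_id = paste0("s", 1:10),
                           label = rep(c("severe", "mild"), each = 5))
  expr <- rbind(
    PERFECT = as.numeric(labels$label == "severe"),
    FLAT = rep(1, 10),
    NOISE = c(0.2, 0.8, 0.4, 0.6, 0.5, 0.3, 0.9, 0.1, 0.55, 0.45)
  )
  colnames(expr) <- labels$sample_id
  expect_warning(mg <- extract_metagenes(expr, labels, already_log = TRUE),
                 "constant")
  expect_true("PERFECT" %in% mg$genes)
  expect_false("FLAT" %in% mg$genes)
  tab <- tidy(mg)
  expect_equal(tab$r[tab$gene == "PERFECT"], 1, tolerance = 1e-9)
})

test_that("null genes are selected at about the nominal rate", {
  set.seed(14)
  labels <- tibble::tibble(sample_id = paste0("s", 1:16),
                           label = rep(c("severe", "mild"), each = 8))
  n_sel <- replicate(30, {
    expr <- matrix(rnorm(1000 * 16), nrow = 1000,
                   dimnames = list(sprintf("G%04d", 1:1000),
                                   labels$sample_id))
    # r_min = 0 isolates the multiplicity-corrected significance filter
    length(extract_metagenes(expr, labels, r_min = 0,
                             already_log = TRUE)$genes)
  })
  # BH at alpha = 0.05 under the global null: false selections are rare
  expect_lt(mean(n_sel > 0), 0.25)
  expect_lt(mean(n_sel) / 1000, 0.01)
})

test_that("metagene score is the mean z-score and is affine invariant", {
  set.seed(15)
  expr <- matrix(rlnorm(50 * 20, 3, 1), nrow = 50,
                 dimnames = list(sprintf("G%02d", 1:50), paste0("s", 1:20)))
  genes <- sprintf("G%02d", 1:11)
  sc <- metagene_score(expr, genes)
  expect_equal(sc$sample_id, colnames(expr))
  # permuting gene order changes nothing
  sc2 <- metagene_score(expr, rev(genes))
  expect_equal(sc$score, sc2$score)
  # gene-wise affine rescaling of the log-expression leaves scores unchanged
  lg <- log2(expr + 1)
  lg2 <- lg * runif(50, 0.5, 2) + rnorm(50)
  expect_equal(metagene_score(lg, genes, already_log = TRUE)$score,
               metagene_score(lg2, genes, already_log = TRUE)$score,
               tolerance = 1e-8)
  # a subject one SD up on every gene scores 1
  z <- matrix(rnorm(11 * 30), nrow = 11,
              dimnames = list(genes, paste0("s", 1:30)))
  z <- t(scale(t(z)))
  z <- cbind(z, up = rowMeans(z) + apply(z, 1, sd))
  # recompute: the added subject shifts the cohort, so plant directly
  zz <- t(scale(t(z)))
  manual <- colMeans(zz)
  got <- metagene_score(z, genes, already_log = TRUE)$score
  expect_equal(got, unname(manual), tolerance = 1e-10)
  # missing genes: warn below 100%, error below 50%
  expect_warning(metagene_score(expr[-1, ], genes), "absent")
  expect_error(metagene_score(expr[1:20, ], sprintf("G%02d", 40:50)),
               "fewer than half")
  # pc1 alternative is sign-aligned with the mean z-score
  s_pc <- metagene_score(expr, genes, method = "pc1")
  expect_gt(cor(s_pc$score, sc$score), 0)
})

sim_surv <- function(n, hr_mild = 0.5, seed = 1, score_effect = TRUE) {
  withr::with_seed(seed, {
    severe <- rbinom(n, 1, 0.5)
    score <- rnorm(n, mean = if (score_effect) severe else 0, sd = 0.6)
    hz <- ifelse(severe == 1, 0.08, 0.08 * hr_mild)
    t_ev <- rexp(n, hz)
    t_c <- rexp(n, 0.03)
    list(score = score, time = pmin(t_ev, t_c),
         event = as.integer(t_ev <= t_c), severe = severe)
  })
}

test_that("cut-point search matches the exhaustive-scan oracle and respects the band", {
  d <- sim_surv(30, seed = 16)
  cp <- optimal_cutpoint(d$score, d$time, d$event)
  oracle <- oracle_cut_scan(d$score, d$time, d$event)
  expect_equal(cp$candidates$cut, oracle$cut)
  expect_equal(cp$candidates$raw_p, oracle$raw_p, tolerance = 1e-12)
  expect_equal(cp$corrected_p,
               min(bh_adjust(oracle$raw_p[!is.na(oracle$raw_p)])))
  # property: the selected cut always lies inside the inner band
  for (i in 1:200) {
    di <- sim_surv(25 + (i %% 20), seed = 300 + i, score_effect = FALSE)
    cpi <- tryCatch(optimal_cutpoint(di$score, di$time, di$event),
                    error = function(e) NULL)
    if (is.null(cpi)) next
    expect_gte(cpi$cut, quantile(di$score, 0.1, names = FALSE))
    expect_lte(cpi$cut, quantile(di$score, 0.9, names = FALSE))
  }
})

test_that("perfectly separated risk groups recover a cut between them", {
  withr::with_seed(17, {
    n <- 40
    grp <- rep(0:1, each = n / 2)
    score <- ifelse(grp == 1, rnorm(n, 3, 0.1), rnorm(n, 0, 0.1))
    tm <- rexp(n, ifelse(grp == 1, 0.4, 0.1))
    cp <- optimal_cutpoint(score, tm, rep(1, n))
    expect_gt(cp$cut, max(score[grp == 0]) - 1e-9)
    expect_lt(cp$cut, min(score[grp == 1]))
  })
})

test_that("KM estimates match the hand-computed product limit", {
  # 6 subjects: events at 1, 3, 5; censored at 2, 4, 6
  tm <- c(1, 2, 3, 4, 5, 6)
  ev <- c(1, 0, 1, 0, 1, 0)
  grp <- factor(rep("a", 6), levels = c("a", "b"))
  km <- survival::survfit(survival::Surv(tm, ev) ~ 1)
  # hand product-limit: S(1)=5/6, S(3)=5/6*3/4, S(5)=5/6*3/4*1/2
  expect_equal(km$surv[km$time == 1], 5 / 6)
  expect_equal(km$surv[km$time == 3], 5 / 6 * 3 / 4)
  expect_equal(km$surv[km$time == 5], 5 / 6 * 3 / 4 * 1 / 2)
  # the same numbers through the package wrapper, with two groups
  tm2 <- c(tm, tm); ev2 <- c(ev, ev)
  g2 <- rep(c("a", "b"), each = 6)
  res <- km_logrank_hr(tm2, ev2, g2)
  td <- tidy(res)
  expect_equal(td$estimate[td$group == "a" & td$time == 3], 5 / 6 * 3 / 4)
  expect_equal(res$hr, 1, tolerance = 1e-8)
  expect_equal(res$logrank_p, 1, tolerance = 1e-8)
})

test_that("a true hazard ratio of 0.5 is recovered at n = 500", {
  hits <- vapply(1:100, function(i) {
    d <- sim_surv(500, hr_mild = 0.5, seed = 500 + i)
    grp <- factor(ifelse(d$severe == 1, "severe", "mild"),
                  levels = c("severe", "mild"))
    km <- km_logrank_hr(d$time, d$event, grp)
    km$hr >= 0.40 && km$hr <= 0.62
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("stratified log-rank respects strata", {
  d1 <- sim_surv(100, seed = 21)
  d2 <- sim_surv(100, seed = 22)
  time <- c(d1$time, d2$time * 3)   # cohort 2 on a different time scale
  event <- c(d1$event, d2$event)
  grp <- c(d1$severe, d2$severe)
  strata <- rep(c("c1", "c2"), each = 100)
  out <- km_logrank_hr(time, event, grp, strata = strata)
  expect_true(is.finite(out$hr))
  expect_lt(out$logrank_p, 0.05)
})

test_that("Harrell's C equals the all-pairs oracle and the survival package", {
  expect_equal(harrells_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1)), 1)
  set.seed(23)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    sc <- rnorm(n)
    tm <- rexp(n, 0.1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    ours <- harrells_c(sc, tm, ev)
    expect_equal(ours, oracle_harrells_c(sc, tm, ev), info = i)
    cref <- survival::concordance(survival::Surv(tm, ev) ~ sc,
                                  reverse = TRUE)$concordance
    expect_equal(ours, unname(cref), tolerance = 1e-9, info = i)
  }
  # random scores at large n sit near 0.5
  set.seed(24)
  cs <- replicate(20, {
    n <- 200
    harrells_c(rnorm(n), rexp(n, 0.1), rbinom(n, 1, 0.7))
  })
  expect_lt(abs(mean(cs) - 0.5), 0.02)
  expect_error(harrells_c(c(1, 2), c(5, 5), c(0, 0)), "usable")
})

test_that("Cox group-only model reproduces the KM hazard ratio", {
  d <- sim_surv(200, seed = 25)
  grp <- factor(ifelse(d$severe == 1, "severe", "mild"),
                levels = c("severe", "mild"))
  km <- km_logrank_hr(d$time, d$event, grp)
  cx <- cox_covariates(d$time, d$event, grp)
  expect_equal(cx$univariate$hr[1], km$hr, tolerance = 1e-8)
  # planted binary covariate effect is recovered within its CI most times
  hits <- vapply(1:50, function(i) {
    withr::with_seed(600 + i, {
      n <- 300
      g <- rbinom(n, 1, 0.5)
      x <- rbinom(n, 1, 0.5)
      hz <- 0.08 * exp(log(2) * x) * exp(-log(2) * g)
      tm <- rexp(n, hz)
      ev <- as.integer(tm < quantile(tm, 0.8))
      tm <- pmin(tm, quantile(tm, 0.8))
      cc <- cox_covariates(tm, ev, g, covariates = tibble::tibble(x = x))
      row <- cc$multivariate[cc$multivariate$term == "x", ]
      row$ci_lower <= 2 && 2 <= row$ci_upper
    })
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_warning(
    cox_covariates(d$time, d$event, grp,
                   covariates = tibble::tibble(k = rep(1, 200))),
    "constant")
})

test_that("end-to-end: extracted metagenes dichotomize survival in the planted direction", {
  hits <- vapply(1:100, function(i) {
    spec <- cohort_spec(n_subjects = 500, n_genes = 200, seed = 800 + i)
    sim <- gen_expression_survival(spec)
    labels <- tibble::tibble(
      sample_id = names(sim$truth$severe),
      label = ifelse(sim$truth$severe == 1, "severe", "mild"))
    mg <- extract_metagenes(sim$expr, labels,
                            candidate_genes = rownames(sim$expr))
    if (length(mg$genes) == 0) return(FALSE)
    sc <- metagene_score(sim$expr, mg)
    cp <- optimal_cutpoint(sc$score, sim$survival$time, sim$survival$event)
    km <- km_logrank_hr(sim$survival$time, sim$survival$event,
                        factor(cp$group, levels = c("high", "low")))
    km$hr < 1 && cp$corrected_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
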