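# Statistical toolbox: Shapiro-Wilk-driven paired-test selection,
# Holm and Benjamini-Hochberg corrections, exact 2x2 tests, capacity
# comparisons by mutation category, and logistic regression of
# heteroplasmy presence on clinical covariates.

#' Normality-driven paired two-group test
#'
#' Runs a Shapiro-Wilk test on the pairwise differences; if normality is
#' not rejected (`p > alpha_normality`) a paired Student t-test is used,
#' otherwise a Wilcoxon signed-rank test. Two-sided throughout.
#'
#' @param x,y Paired numeric vectors of equal length (>= 5), no missing
#'   pairs.
#' @param alpha_normality Shapiro-Wilk rejection level (default 0.05).
#' @return Tibble with `test` (`"paired_t"` or `"wilcoxon_signed_rank"`),
#'   `statistic`, `p_value`, `shapiro_p`.
#' @export
select_paired_test <- function(x, y, alpha_normality = 0.05) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 5) stop("need at least 5 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed",
                                 call. = FALSE)
  d <- x - y
  shapiro_p <- if (stats::sd(d) == 0) 1 else stats::shapiro.test(d)$p.value
  if (shapiro_p > alpha_normality) {
    ht <- stats::t.test(x, y, paired = TRUE)
    test <- "paired_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    test <- "wilcoxon_signed_rank"
  }
  p <- if (all(d == 0)) 1 else ht$p.value
  tibble::tibble(test = test, statistic = unname(ht$statistic),
                 p_value = p, shapiro_p = shapiro_p)
}

check_pvalues <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Bonferroni-Holm step-down adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as the input), capped at 1 and
#'   monotone after ordering.
#' @export
holm_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "holm")
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return BH-adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  check_pvalues(pvalues)
  stats::p.adjust(pvalues, method = "BH")
}

#' Fisher's exact test on a 2x2 table with both odds-ratio estimators
#'
#' Two-sided p by the point-probability rule (summing tables whose
#' hypergeometric probability does not exceed the observed one). Reports
#' both the sample (cross-product) odds ratio and the conditional
#' maximum-likelihood estimate.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Tibble with `sample_or`, `conditional_mle_or`, `p_two_sided`.
#'   With a zero margin the ORs are `NA` and p is 1.
#' @export
#' @examples
#' fisher_2x2(matrix(c(72, 23, 12, 10), nrow = 2))
fisher_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble::tibble(sample_or = NA_real_,
                          conditional_mle_or = NA_real_,
                          p_two_sided = 1))
  }
  ft <- stats::fisher.test(table)
  sample_or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  tibble::tibble(sample_or = sample_or,
                 conditional_mle_or = unname(ft$estimate),
                 p_two_sided = ft$p.value)
}

#' Logistic regression of heteroplasmy presence on clinical covariates
#'
#' Maximum-likelihood logistic fit of a binary heteroplasmy indicator on
#' patient age, free-PSA percentage and pathological stage (stage coded as
#' the ordered integer 2/3/4 for pT2/pT3/pT4). Each predictor gets a
#' likelihood-ratio p-value from the nested-model deviance difference.
#' Quasi-complete separation is flagged and the affected Wald output
#' should not be trusted; LRT p-values are still reported.
#'
#' @param clinical Tibble with the outcome column plus `age`, `fpsa_pct`
#'   and `stage` (`"pT2"`/`"pT3"`/`"pT4"` or numeric).
#' @param outcome Name of the binary outcome column (default `has_hp`).
#' @param predictors Character vector of predictor columns.
#' @return List with `fit` (the glm), `coefficients` tibble (`term`,
#'   `estimate`, `lrt_p`) and `separation` flag.
#' @export
logistic_hp_model <- function(clinical, outcome = "has_hp",
                              predictors = c("age", "fpsa_pct", "stage")) {
  if (nrow(clinical) < 20) stop("need n >= 20", call. = FALSE)
  y <- clinical[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found",
                       call. = FALSE)
  if (length(unique(y)) < 2) stop("outcome is constant", call. = FALSE)
  dat <- clinical
  if ("stage" %in% predictors && is.character(dat$stage)) {
    dat$stage <- as.integer(sub("^pT", "", dat$stage))
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat)
  eps <- 1e-8
  separation <- any(fit$fitted.values > 1 - eps | fit$fitted.values < eps) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  lrt <- stats::drop1(fit, test = "Chisq")
  terms <- rownames(lrt)[-1]
  coefs <- tibble::tibble(
    term = terms,
    estimate = unname(stats::coef(fit)[terms]),
    lrt_p = lrt$`Pr(>Chi)`[-1]
  )
  list(fit = fit, coefficients = coefs, separation = separation)
}

#' Compare relative GM capacity across mutation categories
#'
#' Omnibus one-way ANOVA with Tukey HSD pairwise comparisons for three or
#' more groups; for exactly two groups the Wilcoxon rank-sum test is used.
#' Empty groups are dropped with a warning.
#'
#' @param data Tibble with the response and grouping columns.
#' @param value Name of the numeric response column (e.g. the GM_P/NS_E
#'   flux control ratio).
#' @param group Name of the grouping column (e.g. `none` / `CIII-CV` /
#'   `CI` mutation categories).
#' @return List with `method`, `omnibus` (tibble: statistic, p_value) and
#'   `pairwise` (Tukey-adjusted or rank-sum p-values).
#' @export
group_capacity_compare <- function(data, value = "fcr_gm", group = "group") {
  v <- data[[value]]
  g <- as.character(data[[group]])
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  counts <- table(g)
  if (any(counts == 0)) {
    warning("empty group(s) dropped", call. = FALSE)
  }
  if (length(counts) < 2 || any(counts < 3)) {
    stop("need >= 2 groups with >= 3 members each", call. = FALSE)
  }
  g <- factor(g)
  if (nlevels(g) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE))
    lv <- levels(g)
    return(list(
      method = "wilcoxon_rank_sum",
      omnibus = tibble::tibble(statistic = unname(ht$statistic),
                               p_value = ht$p.value),
      pairwise = tibble::tibble(contrast = paste(lv[2], "-", lv[1]),
                                p_adj = ht$p.value)
    ))
  }
  fit <- stats::aov(v ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  list(
    method = "anova_tukey",
    omnibus = tibble::tibble(statistic = an[["F value"]][1],
                             p_value = an[["Pr(>F)"]][1]),
    pairwise = tibble::tibble(contrast = rownames(tk),
                              diff = tk[, "diff"],
                              p_adj = tk[, "p adj"])
  )
}
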