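# Severe respiratory phenotype classification, metagene extraction and
# scoring, optimal survival cut-point search, Kaplan-Meier / hazard-ratio
# analysis, Harrell's C and Cox covariate models.

#' Classify the respiratory phenotype from relative GM capacity
#'
#' A GM-pathway contribution of at most `threshold` (default 27%) relative
#' to maximal NS-ET capacity is `severe`, above it `mild`. Ratios above 1
#' are kept but flagged.
#'
#' @param data Tibble with a `gm_fcr` column (GM_P / NS_E), or a numeric
#'   vector.
#' @param threshold Severe/mild boundary on the FCR scale (default 0.27).
#' @return The input tibble with `label` (`"severe"`/`"mild"`) and
#'   `fcr_above_one` flag columns (a bare vector input returns a tibble).
#' @export
classify_phenotype <- function(data, threshold = 0.27) {
  if (!is.data.frame(data)) data <- tibble::tibble(gm_fcr = data)
  if (any(data$gm_fcr < 0, na.rm = TRUE)) {
    stop("gm_fcr must be >= 0", call. = FALSE)
  }
  dplyr::mutate(data,
                label = ifelse(.data$gm_fcr <= threshold, "severe", "mild"),
                fcr_above_one = .data$gm_fcr > 1)
}

#' Extract the severe-phenotype metagene set
#'
#' For each candidate gene (typically the genes overexpressed in the
#' severe group from an external differential-expression analysis), the
#' Pearson correlation of its expression with the binary severe indicator
#' (1 = severe; the point-biserial correlation) is computed, together with
#' the correlation-test p-value; genes with `r > r_min` and
#' Benjamini-Hochberg adjusted `p < alpha` form the metagene set. Set
#' `against = "gm_fcr"` to correlate against the continuous GM flux
#' control ratio instead (with the sign flipped so that larger r still
#' means severe-associated).
#'
#' @param expr Gene-by-sample numeric matrix (rownames = genes) or a
#'   tibble with a `gene` column.
#' @param labels Tibble with `sample_id`, `label` and optionally `gm_fcr`,
#'   matching the columns of `expr`.
#' @param candidate_genes Character vector restricting the search.
#' @param r_min Minimum correlation (default 0.4).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @param against `"severe"` (default) or `"gm_fcr"`.
#' @param already_log Set `TRUE` if `expr` is already log-scaled;
#'   otherwise log2(x+1) is applied.
#' @return Object of class `oxs_metagenes`: list with `genes`, `table`
#'   (per-candidate r, p, q, selected) and the selection parameters.
#' @export
extract_metagenes <- function(expr, labels, candidate_genes = NULL,
                              r_min = 0.4, alpha = 0.05,
                              against = c("severe", "gm_fcr"),
                              already_log = FALSE) {
  against <- match.arg(against)
  mat <- as_expr_matrix(expr)
  if (!already_log) mat <- log2(mat + 1)
  mat <- mat[, labels$sample_id, drop = FALSE]
  if (against == "severe") {
    if (min(table(labels$label)) < 2) {
      stop("need >= 2 samples per phenotype label", call. = FALSE)
    }
    target <- as.numeric(labels$label == "severe")
  } else {
    target <- -labels$gm_fcr
  }
  genes <- if (is.null(candidate_genes)) rownames(mat) else
    intersect(candidate_genes, rownames(mat))
  if (length(genes) == 0) stop("no candidate genes found", call. = FALSE)
  res <- purrr::map_dfr(genes, function(gn) {
    x <- mat[gn, ]
    if (stats::sd(x) == 0) {
      return(tibble::tibble(gene = gn, r = NA_real_, p = NA_real_))
    }
    ct <- stats::cor.test(x, target, method = "pearson")
    tibble::tibble(gene = gn, r = unname(ct$estimate), p = ct$p.value)
  })
  skipped <- res$gene[is.na(res$r)]
  if (length(skipped) > 0) {
    warning("constant gene(s) skipped: ", paste(skipped, collapse = ", "),
            call. = FALSE)
  }
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- bh_adjust(res$p[ok])
  res$selected <- !is.na(res$r) & res$r > r_min & res$q < alpha
  structure(list(genes = res$gene[res$selected], table = res,
                 r_min = r_min, alpha = alpha, against = against),
            class = "oxs_metagenes")
}

as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) return(expr)
  if (is.data.frame(expr)) {
    if (!"gene" %in% names(expr)) {
      stop("expression data frame needs a 'gene' column", call. = FALSE)
    }
    m <- as.matrix(expr[, setdiff(names(expr), "gene")])
    rownames(m) <- expr$gene
    storage.mode(m) <- "double"
    return(m)
  }
  stop("expr must be a matrix or data frame", call. = FALSE)
}

#' Score subjects against a metagene set
#'
#' The metagene score of a subject is the mean of the per-gene z-scores
#' (each gene standardized across the cohort), computed on the log2(x+1)
#' scale unless `already_log`. At least half of the signature genes must
#' be present in the cohort matrix. `method = "pc1"` instead uses the
#' first principal component of the signature submatrix (sign-aligned with
#' the mean z-score).
#'
#' @param expr Gene-by-sample matrix or tibble with `gene` column.
#' @param genes Character vector or an `oxs_metagenes` object.
#' @param method `"mean_z"` (default) or `"pc1"`.
#' @param already_log See [extract_metagenes()].
#' @return Tibble with `sample_id` and `score`.
#' @export
metagene_score <- function(expr, genes, method = c("mean_z", "pc1"),
                           already_log = FALSE) {
  method <- match.arg(method)
  if (inherits(genes, "oxs_metagenes")) genes <- genes$genes
  mat <- as_expr_matrix(expr)
  if (!already_log) mat <- log2(mat + 1)
  present <- intersect(genes, rownames(mat))
  missing_genes <- setdiff(genes, rownames(mat))
  if (length(present) < length(genes) / 2) {
    stop("fewer than half of the signature genes present; missing: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  if (length(missing_genes) > 0) {
    warning("signature gene(s) absent from cohort: ",
            paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  sub <- mat[present, , drop = FALSE]
  z <- t(scale(t(sub)))
  z[is.nan(z)] <- 0
  score <- if (method == "mean_z") {
    colMeans(z)
  } else {
    pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
    s <- pc$x[, 1]
    if (stats::cor(s, colMeans(z)) < 0) s <- -s
    s
  }
  tibble::tibble(sample_id = colnames(mat), score = unname(score))
}

#' Optimal survival cut-point for a risk score
#'
#' Scans every observed score value inside the inner `inner_fraction`
#' quantile band as a candidate dichotomization cut, computes the log-rank
#' p of each split, corrects the candidate p-values for the multiplicity of
#' the search (Benjamini-Hochberg across the candidate set by default, or
#' the Lausen-Schumacher maximally-selected-rank-statistic bound), and
#' selects the cut with minimal corrected p, breaking ties by the larger
#' Harrell's C of the dichotomy. Candidates whose high/low group would
#' contain no event are not selectable.
#'
#' @param scores Numeric risk scores.
#' @param time,event Survival time and 0/1 event indicator.
#' @param inner_fraction Width of the central quantile search band
#'   (default 0.8, i.e. the inner 80%).
#' @param correction `"bh"` (default) or `"lausen"`.
#' @param tie_break `"harrells_c"` (default) or `"p_then_c"` order is
#'   always minimal corrected p first; this argument is kept for symmetry
#'   and currently only `"harrells_c"` is implemented.
#' @return Object of class `oxs_cutpoint`: list with `cut`, `corrected_p`,
#'   `raw_p`, `harrells_c`, `group` (factor `"low"`/`"high"`), and the
#'   full `candidates` audit tibble.
#' @export
optimal_cutpoint <- function(scores, time, event, inner_fraction = 0.8,
                             correction = c("bh", "lausen"),
                             tie_break = "harrells_c") {
  correction <- match.arg(correction)
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (n < 20) stop("need >= 20 subjects", call. = FALSE)
  if (sum(event) < 5) stop("need >= 5 events", call. = FALSE)
  lo <- stats::quantile(scores, (1 - inner_fraction) / 2, names = FALSE)
  hi <- stats::quantile(scores, 1 - (1 - inner_fraction) / 2, names = FALSE)
  cand <- sort(unique(scores[scores >= lo & scores <= hi]))
  # a cut at the largest candidate would leave an empty high group
  cand <- cand[cand < max(scores)]
  if (length(cand) == 0) stop("no usable candidate cuts", call. = FALSE)
  audit <- purrr::map_dfr(cand, function(cut) {
    grp <- scores > cut
    ev_hi <- sum(event[grp]); ev_lo <- sum(event[!grp])
    p <- if (ev_hi == 0 || ev_lo == 0) NA_real_ else {
      sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
      stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
    }
    tibble::tibble(cut = cut, n_high = sum(grp), events_high = ev_hi,
                   events_low = ev_lo, raw_p = p)
  })
  ok <- !is.na(audit$raw_p)
  if (!any(ok)) stop("every candidate split leaves a group without events",
                     call. = FALSE)
  m <- sum(ok)
  audit$corrected_p <- NA_real_
  if (correction == "bh") {
    audit$corrected_p[ok] <- bh_adjust(audit$raw_p[ok])
  } else {
    audit$corrected_p[ok] <- vapply(audit$raw_p[ok], lausen_corrected_p,
                                    numeric(1),
                                    eps = (1 - inner_fraction) / 2)
  }
  # concordance of each binary dichotomy via quadratic forms over the
  # (precomputed) usable-pair matrix; equals harrells_c() on 0/1 scores
  ev_i <- matrix(event == 1, n, n)
  early <- (outer(time, time, `<`) & ev_i) |
    (outer(time, time, `==`) & ev_i & !t(ev_i))
  storage.mode(early) <- "double"
  usable <- sum(early)
  audit$harrells_c <- vapply(audit$cut, function(cut) {
    g <- as.numeric(scores > cut)
    conc <- drop(t(g) %*% early %*% (1 - g)) +
      0.5 * (drop(t(g) %*% early %*% g) +
               drop(t(1 - g) %*% early %*% (1 - g)))
    conc / usable
  }, numeric(1))
  sel <- which(ok)
  best_p <- min(audit$corrected_p[sel])
  at_min <- sel[audit$corrected_p[sel] <= best_p + 1e-12]
  best <- at_min[which.max(audit$harrells_c[at_min])]
  structure(list(
    cut = audit$cut[best],
    corrected_p = audit$corrected_p[best],
    raw_p = audit$raw_p[best],
    harrells_c = audit$harrells_c[best],
    group = factor(ifelse(scores > audit$cut[best], "high", "low"),
                   levels = c("low", "high")),
    inner_fraction = inner_fraction,
    correction = correction,
    n_candidates = m,
    candidates = audit
  ), class = "oxs_cutpoint")
}

# Improved Bonferroni bound for maximally selected rank statistics
# (Lausen & Schumacher): p-value for the supremum of the standardized
# log-rank statistic over the (eps, 1-eps) quantile band.
lausen_corrected_p <- function(p, eps) {
  if (is.na(p)) return(NA_real_)
  b <- stats::qnorm(1 - p / 2)
  if (!is.finite(b) || b <= 0) return(1)
  k <- ((1 - eps)^2) / (eps^2)
  adj <- stats::dnorm(b) * (b - 1 / b) * log(k) + 4 * stats::dnorm(b) / b
  min(1, max(p, adj))
}

#' Kaplan-Meier curves, hazard ratio and (stratified) log-rank test
#'
#' Product-limit survival estimates per group, the hazard ratio of the
#' second group level versus the first from a proportional-hazards fit on
#' the group indicator (stratified by `strata` when given), and the
#' two-sided (stratified) log-rank p-value.
#'
#' @param time,event Survival time and 0/1 event indicator.
#' @param group Two-level factor (or coercible).
#' @param strata Optional stratification factor (e.g. cohort id).
#' @return Object of class `oxs_km`: list with `km` (a
#'   [survival::survfit] object), `hr`, `ci_lower`, `ci_upper`,
#'   `logrank_p`, `flag` (notes unbounded HR when a group has no events).
#' @export
km_logrank_hr <- function(time, event, group, strata = NULL) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("need exactly two nonempty groups",
                                call. = FALSE)
  surv <- survival::Surv(time, event)
  km <- survival::survfit(surv ~ group)
  ev <- tapply(event, group, sum)
  flag <- if (any(ev == 0)) "no events in a group; HR unbounded" else NA_character_
  dat <- data.frame(time = time, event = event, group = group)
  if (is.null(strata)) {
    cox <- survival::coxph(survival::Surv(time, event) ~ group, data = dat)
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  } else {
    dat$strata_var <- as.factor(strata)
    cox <- survival::coxph(
      survival::Surv(time, event) ~ group + survival::strata(strata_var),
      data = dat)
    sd <- survival::survdiff(
      survival::Surv(time, event) ~ group + survival::strata(strata_var),
      data = dat)
  }
  ci <- suppressMessages(stats::confint(cox))
  logrank_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  structure(list(
    km = km,
    hr = unname(exp(stats::coef(cox)[1])),
    ci_lower = exp(ci[1, 1]),
    ci_upper = exp(ci[1, 2]),
    logrank_p = logrank_p,
    groups = levels(group),
    flag = flag
  ), class = "oxs_km")
}

#' Harrell's concordance index
#'
#' Usable-pair concordance between a risk score and observed survival:
#' among pairs whose ordering of event times is determined under
#' censoring, the fraction in which the higher score goes with the earlier
#' event; score ties count 0.5. Computed over all pairs.
#'
#' @param scores Numeric risk scores (higher = higher risk).
#' @param time,event Survival time and 0/1 event indicator.
#' @return Concordance in `[0, 1]`.
#' @export
harrells_c <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, n >= 2)
  # ordered pairs (i, j) where i demonstrably fails before j: an observed
  # event strictly earlier than j's time, or an event tied in time with a
  # censoring (the censored subject's unobserved failure comes later)
  lt <- outer(time, time, `<`)
  eq <- outer(time, time, `==`)
  ev_i <- matrix(event == 1, n, n)
  ev_j <- t(ev_i)
  early <- (lt & ev_i) | (eq & ev_i & !ev_j)
  usable <- sum(early)
  if (usable == 0) stop("no usable pairs", call. = FALSE)
  conc <- sum(early & outer(scores, scores, `>`)) +
    0.5 * sum(early & outer(scores, scores, `==`))
  conc / usable
}

#' Uni- and multivariate Cox regression with clinical covariates
#'
#' Fits the group indicator alone and together with binary clinical
#' covariates (age, Gleason, stage, PSA dichotomized upstream). Constant
#' covariates are dropped with a warning; monotone-likelihood problems are
#' flagged.
#'
#' @param time,event Survival data.
#' @param group Two-level risk-group factor.
#' @param covariates Tibble of binary/numeric covariates (may be empty).
#' @return List with `univariate` and `multivariate` coefficient tibbles
#'   (`term`, `hr`, `ci_lower`, `ci_upper`, `p`) and a `flags` character
#'   vector.
#' @export
cox_covariates <- function(time, event, group, covariates = NULL) {
  if (sum(event) < 10) stop("need >= 10 events", call. = FALSE)
  flags <- character(0)
  dat <- data.frame(time = time, event = event,
                    group = droplevels(as.factor(group)))
  if (!is.null(covariates)) {
    keep <- vapply(covariates, function(x) length(unique(x[!is.na(x)])) > 1,
                   logical(1))
    if (any(!keep)) {
      warning("constant covariate(s) dropped: ",
              paste(names(covariates)[!keep], collapse = ", "),
              call. = FALSE)
      flags <- c(flags, paste0("dropped:", names(covariates)[!keep]))
    }
    covariates <- covariates[, keep, drop = FALSE]
    dat <- cbind(dat, covariates)
  }
  tidy_cox <- function(fit) {
    s <- summary(fit)
    ci <- s$conf.int
    tibble::tibble(
      term = rownames(s$coefficients),
      hr = unname(s$coefficients[, "exp(coef)"]),
      ci_lower = unname(ci[, "lower .95"]),
      ci_upper = unname(ci[, "upper .95"]),
      p = unname(s$coefficients[, "Pr(>|z|)"])
    )
  }
  uni <- survival::coxph(survival::Surv(time, event) ~ group, data = dat)
  terms <- c("group", if (!is.null(covariates)) names(covariates))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(terms, collapse = " + ")))
  multi <- tryCatch(survival::coxph(fml, data = dat),
                    warning = function(w) {
                      flags <<- c(flags, conditionMessage(w))
                      suppressWarnings(survival::coxph(fml, data = dat))
                    })
  if (any(abs(stats::coef(multi)) > 15)) {
    flags <- c(flags, "possible monotone likelihood / separation")
  }
  list(univariate = tidy_cox(uni), multivariate = tidy_cox(multi),
       flags = flags)
}
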