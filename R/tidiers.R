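# broom-style tidy()/glance() methods for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the metagene selection table
#'
#' @param x An `oxs_metagenes` object.
#' @param ... Unused.
#' @return Per-candidate tibble with `gene`, `r`, `p`, `q`, `selected`.
#' @export
tidy.oxs_metagenes <- function(x, ...) x$table

#' @rdname tidy.oxs_metagenes
#' @export
glance.oxs_metagenes <- function(x, ...) {
  tibble::tibble(n_candidates = nrow(x$table),
                 n_selected = length(x$genes),
                 r_min = x$r_min, alpha = x$alpha, against = x$against)
}

#' Tidy the cut-point audit table
#'
#' @param x An `oxs_cutpoint` object.
#' @param ... Unused.
#' @return The candidate audit tibble (`cut`, group sizes/events, `raw_p`,
#'   `corrected_p`, `harrells_c`).
#' @export
tidy.oxs_cutpoint <- function(x, ...) x$candidates

#' @rdname tidy.oxs_cutpoint
#' @export
glance.oxs_cutpoint <- function(x, ...) {
  tibble::tibble(cut = x$cut, corrected_p = x$corrected_p,
                 raw_p = x$raw_p, harrells_c = x$harrells_c,
                 n_candidates = x$n_candidates,
                 inner_fraction = x$inner_fraction,
                 correction = x$correction)
}

#' Tidy a Kaplan-Meier / hazard-ratio result
#'
#' @param x An `oxs_km` object.
#' @param ... Unused.
#' @return Step-level tibble of the product-limit curves.
#' @export
tidy.oxs_km <- function(x, ...) {
  km <- x$km
  tibble::tibble(
    time = km$time,
    n_risk = km$n.risk,
    n_event = km$n.event,
    estimate = km$surv,
    group = rep(sub("^group=", "", names(km$strata)), km$strata)
  )
}

#' @rdname tidy.oxs_km
#' @export
glance.oxs_km <- function(x, ...) {
  tibble::tibble(hr = x$hr, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 logrank_p = x$logrank_p,
                 reference = x$groups[1], comparison = x$groups[2],
                 flag = x$flag)
}

#' @export
print.oxs_cutpoint <- function(x, ...) {
  cat("Optimal survival cut-point\n")
  cat(sprintf("  cut = %.4g (searched %d candidates, inner %.0f%% band)\n",
              x$cut, x$n_candidates, 100 * x$inner_fraction))
  cat(sprintf("  corrected p = %.3g (%s), Harrell's C = %.3f\n",
              x$corrected_p, x$correction, x$harrells_c))
  invisible(x)
}

#' @export
print.oxs_km <- function(x, ...) {
  cat("Kaplan-Meier dichotomy:", x$groups[2], "vs", x$groups[1], "\n")
  cat(sprintf("  HR = %.3f (95%% CI %.3f-%.3f), log-rank p = %.3g\n",
              x$hr, x$ci_lower, x$ci_upper, x$logrank_p))
  if (!is.na(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' @export
print.oxs_metagenes <- function(x, ...) {
  cat("Metagene set:", length(x$genes), "gene(s) selected of",
      nrow(x$table), "candidates (r >", x$r_min, ", BH q <", x$alpha,
      ")\n")
  if (length(x$genes) > 0) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
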