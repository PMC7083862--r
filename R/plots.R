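# ggplot2 figures for the main result types.

#' Plot state fluxes or flux control ratios by tissue
#'
#' @param states Long state table (`state`, `flux`, `tissue`), e.g. from
#'   [rox_correct()] or [flux_control_ratios()].
#' @param y Column to plot (`"flux"` or `"fcr"`).
#' @return A ggplot object.
#' @export
plot_state_fluxes <- function(states, y = "flux") {
  states$state <- factor(states$state, levels = suit_states())
  ggplot2::ggplot(states,
                  ggplot2::aes(x = .data$state, y = .data[[y]],
                               fill = .data$tissue)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, position = "dodge") +
    ggplot2::scale_fill_manual(values = c(benign = "#4477AA",
                                          malignant = "#CC4444",
                                          cell_line = "grey60")) +
    ggplot2::labs(x = NULL,
                  y = if (y == "flux")
                    expression(O[2] ~ flux ~ (pmol ~ s^-1 ~ mg^-1))
                  else "Flux control ratio (state / NS_E)") +
    ggplot2::theme_minimal()
}

#' Plot the heteroplasmy allele-frequency spectrum along the genome
#'
#' @param records Consequence-annotated heteroplasmy records.
#' @return A ggplot object.
#' @export
plot_hp_spectrum <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$pos, y = .data$hp_level,
                               colour = .data$tissue)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(benign = "#4477AA",
                                            malignant = "#CC4444")) +
    ggplot2::labs(x = "mtDNA position (rCRS)",
                  y = "Heteroplasmy level") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Audit plot of the optimal cut-point search
#'
#' Shows the corrected log-rank p across candidate cuts with the selected
#' cut marked.
#'
#' @param object An `oxs_cutpoint` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxs_cutpoint <- function(object, ...) {
  cand <- object$candidates
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$cut,
                                     y = -log10(.data$corrected_p))) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cut, colour = "#CC4444",
                        linetype = 2) +
    ggplot2::labs(x = "Candidate cut (metagene score)",
                  y = expression(-log[10] ~ "corrected p")) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier plot of a dichotomized cohort
#'
#' @param object An `oxs_km` result from [km_logrank_hr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxs_km <- function(object, ...) {
  km <- object$km
  d <- tibble::tibble(
    time = km$time,
    surv = km$surv,
    group = rep(sub("^group=", "", names(km$strata)), km$strata)
  )
  d0 <- tibble::tibble(time = 0, surv = 1, group = unique(d$group))
  ggplot2::ggplot(dplyr::bind_rows(d0, d),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  subtitle = sprintf("HR %.2f (%.2f-%.2f), log-rank p = %.3g",
                                     object$hr, object$ci_lower,
                                     object$ci_upper, object$logrank_p)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
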