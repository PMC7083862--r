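# SUIT-protocol respirometry: state-flux extraction from O2 traces,
# ROX correction, flux control ratios and substrate/stress effect deltas.

#' Protocol coupling/pathway states
#'
#' Canonical ordering of the SUIT states handled by the package:
#' LEAK with glutamate&malate (`GM_L`), OXPHOS before and after the
#' oxidative-stress step (`GM_P_pre`, `GM_P`), OXPHOS after pyruvate
#' (`N_P`) and succinate (`NS_P`), uncoupled ET capacity (`NS_E`),
#' S-pathway ET capacity after rotenone (`S_E`), residual oxygen
#' consumption (`ROX`) and the single-step CIV assay states.
#'
#' @return Character vector of state names.
#' @export
suit_states <- function() {
  c("GM_L", "GM_P_pre", "GM_P", "N_P", "NS_P", "NS_E", "S_E", "ROX",
    "CIV_raw", "CIV_azide")
}

assert_state_table <- function(states) {
  bad <- setdiff(unique(states$state), suit_states())
  if (length(bad) > 0) {
    stop("unknown protocol state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(states)
}

#' Extract state fluxes from a titration trace
#'
#' Reads one mass-specific flux per protocol state out of a volume-specific
#' O2 flux trace. The state flux is the median of the volume-specific flux
#' over the trailing `window_s` seconds before the next titration event
#' (or the end of the trace), scaled by the chamber volume and divided by
#' the wet tissue mass, giving pmol O2 per second per mg. The plateau
#' coefficient of variation is reported per state as a quality measure.
#'
#' @param trace Tibble with columns `time_s`, `o2_uM`, `flux_pmol_s_mL`
#'   (strictly increasing `time_s`).
#' @param events Tibble with columns `time_s`, `label`; each label marks
#'   the titration that *starts* the state of that name.
#' @param wet_mass_mg Wet tissue mass in mg (> 0). For cell suspensions
#'   pass the number of 1e6-cell units instead and document the basis.
#' @param window_s Trailing plateau window in seconds (default 60).
#' @param chamber_volume_mL Chamber volume (default 2).
#' @return Tibble with columns `state`, `flux` (pmol s^-1 mg^-1),
#'   `plateau_cv`, `n_points`.
#' @export
extract_state_fluxes <- function(trace, events, wet_mass_mg,
                                 window_s = 60, chamber_volume_mL = 2) {
  stopifnot(is.data.frame(trace), is.data.frame(events))
  if (!all(c("time_s", "flux_pmol_s_mL") %in% names(trace))) {
    stop("trace needs columns time_s and flux_pmol_s_mL", call. = FALSE)
  }
  if (is.unsorted(trace$time_s, strictly = TRUE)) {
    stop("trace time_s must be strictly increasing", call. = FALSE)
  }
  if (anyDuplicated(events$label)) {
    stop("each protocol event label may appear at most once", call. = FALSE)
  }
  if (!is.numeric(wet_mass_mg) || wet_mass_mg <= 0) {
    stop("wet_mass_mg must be > 0", call. = FALSE)
  }
  if (window_s <= 0) stop("window_s must be > 0", call. = FALSE)
  bad <- setdiff(events$label, suit_states())
  if (length(bad) > 0) {
    stop("protocol error: unknown event label(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  ev <- dplyr::arrange(events, .data$time_s)
  ends <- c(ev$time_s[-1], max(trace$time_s))
  purrr::pmap_dfr(list(ev$label, ev$time_s, ends),
                  function(label, t0, t1) {
    lo <- max(t0, t1 - window_s)
    if (t1 - window_s < t0) {
      warning("plateau window for state '", label,
              "' truncated to the available ", signif(t1 - t0, 3),
              " s", call. = FALSE)
    }
    sel <- trace$flux_pmol_s_mL[trace$time_s > lo & trace$time_s <= t1]
    if (length(sel) == 0) {
      stop("protocol error: no trace points in the plateau window of '",
           label, "'", call. = FALSE)
    }
    vol_flux <- stats::median(sel)
    tibble::tibble(
      state = label,
      flux = vol_flux * chamber_volume_mL / wet_mass_mg,
      plateau_cv = stats::sd(sel) / abs(vol_flux),
      n_points = length(sel)
    )
  })
}

#' Subtract residual oxygen consumption (ROX)
#'
#' Residual oxygen consumption, measured after inhibition of Complexes I,
#' II and III, is subtracted from every other state flux. Negative
#' corrected fluxes are retained (clamping would bias downstream deltas)
#' and flagged.
#'
#' @param states Long state table with columns `sample_id` (optional),
#'   `state`, `flux`.
#' @return The table with corrected `flux`, `ROX` set to 0, and a logical
#'   `negative_flux` flag column.
#' @export
rox_correct <- function(states) {
  assert_state_table(states)
  grp <- intersect(c("sample_id", "tissue"), names(states))
  do_one <- function(d) {
    rox <- d$flux[d$state == "ROX"]
    if (length(rox) != 1L) {
      stop("ROX state missing (or duplicated) in state table", call. = FALSE)
    }
    d$flux <- ifelse(d$state == "ROX", 0, d$flux - rox)
    d$negative_flux <- d$flux < 0
    d
  }
  if (length(grp) == 0) {
    do_one(states)
  } else {
    states |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(~ do_one(.x)) |>
      dplyr::ungroup()
  }
}

#' Average split-sample replicates
#'
#' Split biopsies measured in parallel chambers are averaged state by state
#' before statistics; replicate identifiers are concatenated.
#'
#' @param tables List of state tables for one biopsy (columns `state`,
#'   `flux`, optionally `replicate_id`).
#' @return One state table with the per-state arithmetic mean flux and a
#'   `replicate_ids` attribute-free column.
#' @export
average_splits <- function(tables) {
  stopifnot(length(tables) >= 1)
  sets <- purrr::map(tables, ~ sort(unique(.x$state)))
  ref <- sets[[1]]
  for (i in seq_along(sets)) {
    if (!identical(sets[[i]], ref)) {
      diff <- union(setdiff(sets[[i]], ref), setdiff(ref, sets[[i]]))
      stop("replicate state sets differ (", paste(diff, collapse = ", "),
           ")", call. = FALSE)
    }
  }
  ids <- purrr::imap_chr(tables, function(t, i) {
    if ("replicate_id" %in% names(t)) as.character(t$replicate_id[1]) else
      as.character(i)
  })
  dplyr::bind_rows(tables) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(flux = mean(.data$flux), .groups = "drop") |>
    dplyr::mutate(replicate_ids = paste(ids, collapse = "+"))
}

#' Flux control ratios
#'
#' Normalizes every state flux to the maximal convergent NS-pathway ET
#' capacity `NS_E` (the internal reference state), giving dimensionless
#' flux control ratios; `FCR(NS_E)` is exactly 1.
#'
#' @param states State table (columns `state`, `flux`, optional grouping
#'   columns `sample_id`/`tissue`).
#' @return The table with an added `fcr` column.
#' @export
flux_control_ratios <- function(states) {
  assert_state_table(states)
  grp <- intersect(c("sample_id", "tissue"), names(states))
  do_one <- function(d) {
    ref <- d$flux[d$state == "NS_E"]
    if (length(ref) != 1L || is.na(ref) || ref <= 0) {
      stop("degenerate reference: NS_E must be present and > 0",
           call. = FALSE)
    }
    d$fcr <- d$flux / ref
    d$fcr[d$state == "NS_E"] <- 1
    d
  }
  if (length(grp) == 0) {
    do_one(states)
  } else {
    states |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(~ do_one(.x)) |>
      dplyr::ungroup()
  }
}

# Effect deltas of the titration steps, defined on one sample's state set.
.effect_defs <- list(
  ADP_effect       = c("GM_P_pre", "GM_L"),
  stress_effect    = c("GM_P", "GM_P_pre"),
  pyruvate_effect  = c("N_P", "GM_P"),
  succinate_effect = c("NS_P", "N_P"),
  FCCP_effect      = c("NS_E", "NS_P"),
  rotenone_effect  = c("NS_E", "S_E")
)

#' Substrate, stress and inhibitor effects
#'
#' Titration-step deltas: coupling activation by ADP
#' (`GM_P_pre - GM_L`), the oxidative-stress decrement (`GM_P - GM_P_pre`,
#' usually negative), the pyruvate (`N_P - GM_P`) and succinate
#' (`NS_P - N_P`) increments, the uncoupler reserve (`NS_E - NS_P`) and
#' the rotenone-sensitive N-pathway share of ET capacity (`NS_E - S_E`).
#' Deltas whose states are absent come back as `NA` rather than failing.
#'
#' @param states State table for one sample (columns `state`, `flux`) or
#'   with grouping columns `sample_id`/`tissue`.
#' @return Tibble with columns `effect`, `delta` (plus grouping columns).
#' @export
substrate_effects <- function(states) {
  assert_state_table(states)
  grp <- intersect(c("sample_id", "tissue"), names(states))
  do_one <- function(d) {
    f <- stats::setNames(d$flux, d$state)
    purrr::imap_dfr(.effect_defs, function(pair, nm) {
      delta <- if (all(pair %in% names(f))) {
        unname(f[pair[1]] - f[pair[2]])
      } else {
        NA_real_
      }
      tibble::tibble(effect = nm, delta = delta)
    })
  }
  if (length(grp) == 0) {
    do_one(states)
  } else {
    states |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
      dplyr::group_modify(~ do_one(.x)) |>
      dplyr::ungroup()
  }
}

#' Complex IV single-step activity
#'
#' Ascorbate/TMPD-driven flux corrected for the chemical background
#' measured after CIV inhibition with sodium azide.
#'
#' @param raw Flux with ascorbate+TMPD.
#' @param azide Flux after azide inhibition.
#' @return Tibble with `civ_flux` and a `negative_flux` flag.
#' @export
civ_activity <- function(raw, azide) {
  stopifnot(is.finite(raw), is.finite(azide))
  flux <- raw - azide
  tibble::tibble(civ_flux = flux, negative_flux = flux < 0)
}

#' S-pathway compensation under stepwise CI inhibition
#'
#' For a rotenone titration series on one cell line, computes the percent
#' inhibition of N-pathway flux relative to the dose-0 baseline and the
#' relative S-pathway OXPHOS capacity (S-linked OXPHOS flux normalized to
#' the same run's total `NS_E` capacity).
#'
#' @param titration Tibble with columns `rotenone_dose_nM`, `n_flux`
#'   (rotenone-sensitive N-pathway OXPHOS flux), `s_flux` (S-linked OXPHOS
#'   flux) and `ns_e` (total ET reference capacity of the run).
#' @return Tibble with `rotenone_dose_nM`, `n_inhibition_pct`,
#'   `s_relative_capacity`.
#' @export
s_pathway_compensation <- function(titration) {
  need <- c("rotenone_dose_nM", "n_flux", "s_flux", "ns_e")
  if (!all(need %in% names(titration))) {
    stop("titration needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!any(titration$rotenone_dose_nM == 0)) {
    stop("no rotenone dose-0 baseline present", call. = FALSE)
  }
  base <- titration$n_flux[titration$rotenone_dose_nM == 0][1]
  if (base <= 0) stop("baseline N-pathway flux must be > 0", call. = FALSE)
  titration |>
    dplyr::arrange(.data$rotenone_dose_nM) |>
    dplyr::transmute(
      rotenone_dose_nM = .data$rotenone_dose_nM,
      n_inhibition_pct = 100 * pmax(0, 1 - .data$n_flux / base),
      s_relative_capacity = .data$s_flux / .data$ns_e
    )
}
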