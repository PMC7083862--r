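# mtDNA copy number per diploid cell from duplex qPCR (MT-TL1 vs B2M)
# with plasmid calibration, CN = 2 * E^(-ddCq).

#' mtDNA copy number from duplex qPCR
#'
#' Computes copies per diploid cell as `2 * E^(-ddCq)` where
#' `ddCq = (Cq_mt - Cq_n)_sample - (Cq_mt - Cq_n)_plasmid`. The plasmid
#' standard carries the mitochondrial and nuclear amplicons in a 1:1 ratio,
#' so its delta-Cq anchors the scale; `E` is the amplification base
#' (2 = perfect doubling per cycle).
#'
#' @param measurements Tibble with columns `sample_id`, `cq_mt`, `cq_n`
#'   and either per-row `plasmid_cq_mt`/`plasmid_cq_n` columns or the
#'   scalar arguments below.
#' @param plasmid_cq_mt,plasmid_cq_n Calibrator cycles (used when the
#'   columns are absent).
#' @param efficiency Amplification base `E`, in (1, 2] (default 2).
#' @return The input with added `ddcq` and `copy_number` columns.
#' @export
#' @examples
#' m <- tibble::tibble(sample_id = "s1", cq_mt = 12, cq_n = 22)
#' mt_copy_number(m, plasmid_cq_mt = 15, plasmid_cq_n = 15)
mt_copy_number <- function(measurements, plasmid_cq_mt = NULL,
                           plasmid_cq_n = NULL, efficiency = 2) {
  if (!all(c("sample_id", "cq_mt", "cq_n") %in% names(measurements))) {
    stop("measurements need columns sample_id, cq_mt, cq_n", call. = FALSE)
  }
  if (efficiency <= 1 || efficiency > 2) {
    stop("efficiency base E must lie in (1, 2]", call. = FALSE)
  }
  if (!"plasmid_cq_mt" %in% names(measurements)) {
    if (is.null(plasmid_cq_mt) || is.null(plasmid_cq_n)) {
      stop("plasmid calibrator cycles are required", call. = FALSE)
    }
    measurements$plasmid_cq_mt <- plasmid_cq_mt
    measurements$plasmid_cq_n <- plasmid_cq_n
  }
  cq <- c(measurements$cq_mt, measurements$cq_n,
          measurements$plasmid_cq_mt, measurements$plasmid_cq_n)
  if (any(!is.finite(cq) | cq <= 0)) {
    stop("all Cq values must be finite and > 0", call. = FALSE)
  }
  dplyr::mutate(
    measurements,
    ddcq = (.data$cq_mt - .data$cq_n) -
      (.data$plasmid_cq_mt - .data$plasmid_cq_n),
    copy_number = 2 * efficiency^(-.data$ddcq)
  )
}

#' Tumor/benign copy-number ratio
#'
#' @param tumor_cn,benign_cn Copy numbers per diploid cell; `benign_cn`
#'   must be > 0. Vectorized.
#' @return Numeric ratio(s) `tumor_cn / benign_cn`.
#' @export
cn_ratio <- function(tumor_cn, benign_cn) {
  if (any(!is.finite(benign_cn) | benign_cn <= 0)) {
    stop("benign copy number must be finite and > 0", call. = FALSE)
  }
  tumor_cn / benign_cn
}
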