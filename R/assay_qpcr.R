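#' Amplification efficiency from a qPCR dilution series
#'
#' Fits Cq = a + s * log10(dilution) by OLS and returns the efficiency
#' 10^(-1/s), expressed as fold amplification per cycle (perfect doubling:
#' slope -3.3219, efficiency 2.0).
#'
#' @param series A data frame with columns `dilution` (relative template
#'   amount, e.g. 1, 0.1, 0.01) and `cq`; at least 3 distinct dilutions.
#' @return Efficiency (fold per cycle), with the fitted slope as attribute
#'   `slope`.
#' @examples
#' s <- tibble::tibble(dilution = 10^-(0:3), cq = 12 + 3.3219 * (0:3))
#' qpcr_efficiency(s)  # 2.0
#' @export
qpcr_efficiency <- function(series) {
  stopifnot(all(c("dilution", "cq") %in% names(series)))
  if (length(unique(series$dilution)) < 3) {
    stop("need a dilution series with >= 3 distinct points", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10(dilution), data = series)
  s <- unname(stats::coef(fit)[2])
  if (abs(s) < 1e-6) stop("degenerate dilution-series fit (slope ~ 0)",
                          call. = FALSE)
  structure(10^(-1 / s), slope = s)
}

#' Efficiency-corrected relative quantification (Pfaffl)
#'
#' ratio = E_target^dCq_target / E_ref^dCq_ref, with dCq = Cq(calibrator) -
#' Cq(sample) per channel. With a single-copy calibrator and a reference locus
#' outside the amplified region, the ratio is the relative copy number of the
#' target locus.
#'
#' @param e_target,e_ref Amplification efficiencies (fold per cycle, in
#'   (1, 3]).
#' @param dcq_target,dcq_ref Cq(calibrator) - Cq(sample) for the target and
#'   reference primer pairs.
#' @return Relative copy number (numeric scalar).
#' @examples
#' pfaffl_ratio(2, 2, 2, 0)  # 4
#' @export
pfaffl_ratio <- function(e_target, dcq_target, e_ref, dcq_ref) {
  for (e in c(e_target, e_ref)) {
    if (!(e > 1 && e <= 3)) {
      stop("efficiency out of range (1, 3]: ", e, call. = FALSE)
    }
  }
  e_target^dcq_target / e_ref^dcq_ref
}

#' Relative copy number from a full qPCR run
#'
#' Pipeline wrapper: estimates per-channel efficiencies from the run's
#' dilution series, averages technical-replicate Cq values, and applies
#' [pfaffl_ratio()] with the single-copy calibrator.
#'
#' @param run A `qpcr_run` as produced by [gen_qpcr_run()] or assembled from
#'   [read_cq_csv()]: a list with elements `cq` (tibble `sample`, `channel`,
#'   `replicate`, `cq`; `sample` includes `"calibrator"`; `channel` is
#'   `"target"` or `"reference"`) and `dilution_series` (tibble `channel`,
#'   `dilution`, `cq`).
#' @return A tibble with one row per non-calibrator sample: `sample`,
#'   `e_target`, `e_ref`, `dcq_target`, `dcq_ref`, `copy_number`.
#' @export
estimate_copy_number <- function(run) {
  stopifnot(is.list(run), all(c("cq", "dilution_series") %in% names(run)))
  eff <- run$dilution_series |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(e = as.numeric(qpcr_efficiency(dplyr::pick(dplyr::everything()))),
                     .groups = "drop")
  e_t <- eff$e[eff$channel == "target"]
  e_r <- eff$e[eff$channel == "reference"]
  mean_cq <- run$cq |>
    dplyr::group_by(.data$sample, .data$channel) |>
    dplyr::summarise(cq = mean(.data$cq), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "channel", values_from = "cq")
  cal <- mean_cq[mean_cq$sample == "calibrator", ]
  if (nrow(cal) != 1) stop("run must contain exactly one calibrator sample",
                           call. = FALSE)
  mean_cq |>
    dplyr::filter(.data$sample != "calibrator") |>
    dplyr::mutate(
      e_target = e_t, e_ref = e_r,
      dcq_target = cal$target - .data$target,
      dcq_ref = cal$reference - .data$reference,
      copy_number = pfaffl_ratio(e_t, .data$dcq_target, e_r, .data$dcq_ref)
    ) |>
    dplyr::select("sample", "e_target", "e_ref", "dcq_target", "dcq_ref",
                  "copy_number")
}
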