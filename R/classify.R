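#' Classification thresholds on normalized fluorescence
#'
#' The (yfp_norm, cfp_norm) plane is partitioned into four exhaustive,
#' mutually exclusive fractions: ancestral, YFP+ (expression up at single
#' copy), YFP+CFP+ (amplified: both channels up along the dosage diagonal) and
#' mixed (CFP up with YFP elevated above the pure-amplification diagonal,
#' indicating combination mutants). The original partition is drawn by eye;
#' these cutoffs operationalize it and are reported alongside any output.
#'
#' @param theta_y YFP elevation cutoff in ancestor-normalized units.
#' @param theta_c CFP elevation cutoff.
#' @param rho YFP/CFP ratio separating pure amplification from mixed.
#' @param detection_floor Minimum subpopulation frequency callable from
#'   single-cell events.
#' @return An object of class `dupdiv_thresholds`.
#' @export
thresholds <- function(theta_y = 1.5, theta_c = 1.5, rho = 1.5,
                       detection_floor = 0.01) {
  stopifnot(theta_y > 1, theta_c > 1, rho > 1,
            detection_floor > 0, detection_floor < 0.5)
  structure(list(theta_y = theta_y, theta_c = theta_c, rho = rho,
                 detection_floor = detection_floor),
            class = "dupdiv_thresholds")
}

fraction_levels <- c("ANCESTRAL", "YFP_PLUS", "YFP_CFP_PLUS", "MIXED")

#' Classify populations by normalized bulk fluorescence
#'
#' Rule: cfp <= theta_c & yfp <= theta_y -> ANCESTRAL; cfp <= theta_c &
#' yfp > theta_y -> YFP_PLUS; cfp > theta_c & yfp/cfp <= rho -> YFP_CFP_PLUS;
#' cfp > theta_c & yfp/cfp > rho -> MIXED.
#'
#' @param fluor A data frame with columns `yfp_norm` and `cfp_norm` (e.g. from
#'   [population_fluorescence()]); all values must be positive.
#' @param t [thresholds()].
#' @return The input tibble with an added factor column `label` with levels
#'   ANCESTRAL, YFP_PLUS, YFP_CFP_PLUS, MIXED.
#' @examples
#' classify_population(tibble::tibble(yfp_norm = 6, cfp_norm = 2.5))
#' @export
classify_population <- function(fluor, t = thresholds()) {
  stopifnot(all(c("yfp_norm", "cfp_norm") %in% names(fluor)),
            inherits(t, "dupdiv_thresholds"))
  if (any(fluor$yfp_norm <= 0) || any(fluor$cfp_norm <= 0)) {
    stop("normalized fluorescence must be positive", call. = FALSE)
  }
  y <- fluor$yfp_norm; c_ <- fluor$cfp_norm
  lab <- ifelse(
    c_ <= t$theta_c,
    ifelse(y <= t$theta_y, "ANCESTRAL", "YFP_PLUS"),
    ifelse(y / c_ <= t$rho, "YFP_CFP_PLUS", "MIXED")
  )
  dplyr::mutate(tibble::as_tibble(fluor),
                label = factor(lab, levels = fraction_levels))
}

#' Classify single-cell events against an ancestral reference
#'
#' Events are normalized per channel by the median fluorescence of an
#' ancestral reference sample (medians rather than means for robustness to the
#' lognormal tail), then each event is labelled with the population rule.
#'
#' @param events Event tibble (`yfp`, `cfp`), raw fluorescence.
#' @param ancestral_ref Event tibble measured on a purely ancestral sample.
#' @param t [thresholds()].
#' @return The event tibble with added columns `yfp_norm`, `cfp_norm`,
#'   `label`.
#' @seealso [label_frequencies()], [detect_combination()]
#' @export
classify_events <- function(events, ancestral_ref, t = thresholds()) {
  stopifnot(nrow(events) > 0, nrow(ancestral_ref) > 0)
  y0 <- stats::median(ancestral_ref$yfp)
  c0 <- stats::median(ancestral_ref$cfp)
  events |>
    tibble::as_tibble() |>
    dplyr::mutate(yfp_norm = .data$yfp / y0, cfp_norm = .data$cfp / c0) |>
    classify_population(t = t)
}

#' Subpopulation frequencies of labelled events
#'
#' @param labelled Output of [classify_events()] (or any tibble with a
#'   `label` factor).
#' @return A tibble with one row per fraction label and its frequency
#'   (frequencies sum to 1).
#' @export
label_frequencies <- function(labelled) {
  stopifnot("label" %in% names(labelled))
  labelled |>
    dplyr::count(.data$label, .drop = FALSE, name = "count") |>
    dplyr::mutate(frequency = .data$count / sum(.data$count))
}

#' Detect combination mutants in single-cell data
#'
#' TRUE iff the MIXED fraction (CFP elevated and YFP above the amplification
#' diagonal) reaches the detection floor.
#'
#' @inheritParams classify_events
#' @return Logical scalar.
#' @export
detect_combination <- function(events, ancestral_ref, t = thresholds()) {
  fr <- label_frequencies(classify_events(events, ancestral_ref, t))
  fr$frequency[fr$label == "MIXED"] >= t$detection_floor
}

#' Fraction counts of replicate populations per day
#'
#' Applies [population_fluorescence()] and [classify_population()] to every
#' per-replicate per-day snapshot and tallies replicates per fraction label.
#'
#' @param experiment A `dupdiv_experiment` (or any tibble with `replicate`,
#'   `day`, `k`, `m`, `count`, optionally `condition`).
#' @inheritParams population_fluorescence
#' @param t [thresholds()].
#' @return A tibble with grouping columns (`condition` if present, `day`),
#'   `label` and `n_replicates`; counts within a day sum to the number of
#'   replicates.
#' @export
fraction_table <- function(experiment, alleles = allele_params(),
                           reporter = reporter_params(), t = thresholds()) {
  stopifnot(nrow(experiment) > 0)
  lab <- population_fluorescence(experiment, alleles, reporter) |>
    classify_population(t = t)
  grp <- intersect(c("condition", "day"), names(lab))
  lab |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::count(.data$label, .drop = FALSE, name = "n_replicates") |>
    dplyr::ungroup()
}
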