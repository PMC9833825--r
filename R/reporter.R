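#' Dual-fluorophore reporter parameters
#'
#' The virtual reporter cassette: YFP is transcribed from the selected
#' promoter, so it reads out total expression E of the locus; CFP is driven by
#' an independent constitutive promoter on the same cassette, so it reads out
#' copy number k only. Single-cell noise is multiplicative lognormal with
#' mean 1.
#'
#' @param yfp_gain Fluorescence units per expression unit.
#' @param cfp_per_copy Fluorescence units per gene copy.
#' @param yfp_background,cfp_background Autofluorescence floors.
#' @param noise_cv Total lognormal coefficient of variation per cell and
#'   channel (default 0.25). Most of it is extrinsic (cell size, expression
#'   capacity) and therefore shared between the two channels of the same
#'   cell, which keeps the YFP/CFP ratio much tighter than either channel —
#'   the property that makes ratio-based gating of combination mutants work.
#' @param intrinsic_cv The independent per-channel component of `noise_cv`
#'   (default 0.05; must not exceed `noise_cv`).
#' @return An object of class `reporter_params`.
#' @export
reporter_params <- function(yfp_gain = 100, cfp_per_copy = 100,
                            yfp_background = 50, cfp_background = 50,
                            noise_cv = 0.25,
                            intrinsic_cv = min(0.05, noise_cv)) {
  stopifnot(yfp_gain > 0, cfp_per_copy > 0, yfp_background >= 0,
            cfp_background >= 0, noise_cv >= 0, intrinsic_cv >= 0)
  if (intrinsic_cv > noise_cv) {
    stop("intrinsic_cv must not exceed the total noise_cv", call. = FALSE)
  }
  structure(list(yfp_gain = yfp_gain, cfp_per_copy = cfp_per_copy,
                 yfp_background = yfp_background,
                 cfp_background = cfp_background, noise_cv = noise_cv,
                 intrinsic_cv = intrinsic_cv),
            class = "reporter_params")
}

# lognormal multiplier with mean exactly 1 and coefficient of variation cv
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# per-cell noise factors for the two channels: a shared extrinsic lognormal
# factor times independent intrinsic ones; each channel has mean 1 and total
# CV = noise_cv, the cross-channel correlation comes from the shared part
cell_noise_factors <- function(n, noise_cv, intrinsic_cv) {
  if (noise_cv == 0) return(list(yfp = rep(1, n), cfp = rep(1, n)))
  var_tot <- log(1 + noise_cv^2)
  var_int <- log(1 + intrinsic_cv^2)
  var_sh <- var_tot - var_int
  shared <- stats::rnorm(n, -var_sh / 2, sqrt(var_sh))
  int_y <- stats::rnorm(n, -var_int / 2, sqrt(var_int))
  int_c <- stats::rnorm(n, -var_int / 2, sqrt(var_int))
  list(yfp = exp(shared + int_y), cfp = exp(shared + int_c))
}

#' Single-cell fluorescence of genotypes
#'
#' yfp = (yfp_background + yfp_gain * E) * eps_y, cfp = (cfp_background +
#' cfp_per_copy * k) * eps_c, with lognormal mean-1 noise factors of CV
#' `noise_cv` per channel that share a common extrinsic component (see
#' [reporter_params()]).
#'
#' @param genotypes Data frame with columns `k`, `m` (one row per cell).
#' @param alleles [allele_params()].
#' @param reporter [reporter_params()].
#' @return The input tibble with added columns `yfp` and `cfp`.
#' @export
cell_fluorescence <- function(genotypes, alleles = allele_params(),
                              reporter = reporter_params()) {
  stopifnot(inherits(reporter, "reporter_params"))
  e <- expression_level(genotypes, alleles)
  eps <- cell_noise_factors(nrow(e), reporter$noise_cv, reporter$intrinsic_cv)
  dplyr::mutate(
    e,
    yfp = (reporter$yfp_background + reporter$yfp_gain * .data$expression) *
      eps$yfp,
    cfp = (reporter$cfp_background + reporter$cfp_per_copy * .data$k) *
      eps$cfp
  )
}

ancestral_reference_fluor <- function(alleles, reporter) {
  list(yfp = reporter$yfp_background + reporter$yfp_gain * alleles$beta_anc,
       cfp = reporter$cfp_background + reporter$cfp_per_copy * 1)
}

#' Bulk (population-mean) fluorescence, normalized to the ancestor
#'
#' Abundance-weighted mean of the noiseless per-class fluorescence, divided by
#' the noiseless ancestral value in each channel — the plate-reader analogue.
#' A fully ancestral population maps to (1, 1); a pure k-copy amplification
#' with zero backgrounds maps onto the (k, k) diagonal.
#'
#' @param state A population tibble (`k`, `m`, `n` or `count`), optionally
#'   with grouping columns such as `replicate`, `day` (each group is one
#'   population, e.g. a `dupdiv_experiment`).
#' @inheritParams cell_fluorescence
#' @return A tibble with the grouping columns plus `yfp_norm`, `cfp_norm`.
#' @export
population_fluorescence <- function(state, alleles = allele_params(),
                                    reporter = reporter_params()) {
  ncol <- if ("n" %in% names(state)) "n" else "count"
  stopifnot(ncol %in% names(state))
  if (sum(state[[ncol]]) <= 0) stop("empty-population", call. = FALSE)
  ref <- ancestral_reference_fluor(alleles, reporter)
  grp <- setdiff(names(state), c("k", "m", ncol, "frequency"))
  e <- expression_level(state[c("k", "m")], alleles)
  state |>
    dplyr::mutate(
      .yfp = reporter$yfp_background + reporter$yfp_gain * e$expression,
      .cfp = reporter$cfp_background + reporter$cfp_per_copy * .data$k,
      .w = .data[[ncol]]
    ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      yfp_norm = sum(.data$.yfp * .data$.w) / sum(.data$.w) / ref$yfp,
      cfp_norm = sum(.data$.cfp * .data$.w) / sum(.data$.w) / ref$cfp,
      .groups = "drop"
    )
}

#' Sample single-cell flow-cytometry-like events from a population
#'
#' Cells are drawn multinomially by class frequency and passed through
#' [cell_fluorescence()]; roughly 6000 events per sample mirrors a typical
#' gated acquisition.
#'
#' @param state Population tibble (`k`, `m`, `n`/`count`) for one population.
#' @inheritParams cell_fluorescence
#' @param n_events Number of events to draw.
#' @return An event tibble with columns `event`, `yfp`, `cfp`.
#' @export
sample_flow_events <- function(state, alleles = allele_params(),
                               reporter = reporter_params(),
                               n_events = 6000) {
  stopifnot(n_events >= 1)
  ncol <- if ("n" %in% names(state)) "n" else "count"
  tot <- sum(state[[ncol]])
  if (tot <= 0) stop("empty-population", call. = FALSE)
  counts <- as.numeric(stats::rmultinom(1, n_events, state[[ncol]] / tot))
  cells <- tibble::tibble(
    k = rep(state$k, counts),
    m = rep(state$m, counts)
  )
  fl <- cell_fluorescence(cells, alleles, reporter)
  tibble::tibble(event = seq_len(n_events), yfp = fl$yfp, cfp = fl$cfp)
}
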