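# Generators for the four real-data-shaped inputs (plate-reader time series,
# flow-cytometry-like event tables, amplicon FASTQ, qPCR Cq tables), each with
# known ground truth, so every measurement stage can be tested round-trip
# without any external data.

#' Generate a synthetic OD growth curve
#'
#' Three-phase curve: flat lag, then logistic growth (exponential at rate `r`
#' while far below capacity), sampled at 10-minute intervals with
#' multiplicative lognormal noise. The generating rate is recorded as the
#' attribute `true_rate`.
#'
#' @param r True maximal growth rate (per hour, >= 0).
#' @param lag_hours Lag-phase duration.
#' @param k_over_od0 Fold-change between carrying capacity and starting OD.
#' @param od0 Starting OD.
#' @param duration_hours Total sampled time.
#' @param noise_sd Standard deviation of the multiplicative log-noise.
#' @param dt Sampling interval in hours (default 1/6 = 10 min).
#' @param seed Optional seed.
#' @return A tibble (`time`, `od`) with attribute `true_rate`.
#' @examples
#' curve <- gen_growth_curve(r = 0.8, seed = 1)
#' max_growth_rate(curve)
#' @export
gen_growth_curve <- function(r, lag_hours = 1, k_over_od0 = 100, od0 = 0.01,
                             duration_hours = 16, noise_sd = 0, dt = 1 / 6,
                             seed = NULL) {
  stopifnot(r >= 0, lag_hours >= 0, k_over_od0 > 1, od0 > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  time <- seq(0, duration_hours, by = dt)
  k_abs <- od0 * k_over_od0
  grow_t <- pmax(time - lag_hours, 0)
  od <- if (r == 0) rep(od0, length(time)) else {
    k_abs / (1 + (k_abs / od0 - 1) * exp(-r * grow_t))
  }
  if (noise_sd > 0) od <- od * exp(stats::rnorm(length(od), 0, noise_sd))
  out <- tibble::tibble(time = time, od = od)
  attr(out, "true_rate") <- r
  out
}

well_ids_96 <- function(n) {
  stopifnot(n <= 96)
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[seq_len(n)]
}

#' Generate a 96-well plate-reader endpoint time series
#'
#' One well per replicate population of a simulated experiment; each day's row
#' carries endpoint OD and raw bulk YFP/CFP computed from the population
#' composition via [population_fluorescence()], times multiplicative
#' measurement noise. A ground-truth sidecar with the noiseless normalized
#' fluorescence and fraction label per well and day is attached as attribute
#' `truth`.
#'
#' @param experiment A `dupdiv_experiment` (<= 96 replicates).
#' @param alleles,reporter,t Model parameters ([allele_params()],
#'   [reporter_params()], [thresholds()]); `reporter$noise_cv` is reused as
#'   the well-level multiplicative noise CV.
#' @param od_endpoint Mean endpoint OD of a saturated culture.
#' @param seed Optional seed.
#' @return A tibble (`well`, `day`, `od`, `yfp`, `cfp`), raw fluorescence
#'   units, with attribute `truth`.
#' @export
gen_plate_timeseries <- function(experiment, alleles = allele_params(),
                                 reporter = reporter_params(),
                                 t = thresholds(), od_endpoint = 1.0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  reps <- sort(unique(experiment$replicate))
  if (length(reps) > 96) stop("over-capacity plate: > 96 populations",
                              call. = FALSE)
  wells <- tibble::tibble(replicate = reps, well = well_ids_96(length(reps)))
  fl <- population_fluorescence(experiment, alleles, reporter)
  ref <- ancestral_reference_fluor(alleles, reporter)
  truth <- fl |>
    classify_population(t = t) |>
    dplyr::left_join(wells, by = "replicate") |>
    dplyr::select("well", "replicate", "day", "yfp_norm", "cfp_norm", "label")
  nr <- nrow(fl)
  noisy <- fl |>
    dplyr::left_join(wells, by = "replicate") |>
    dplyr::mutate(
      # bulk measurements average over >> 1e5 cells, so per-cell noise cancels
      # and only instrument-level noise (a fifth of the single-cell CV) remains
      od = od_endpoint * rlnorm_mean1(nr, reporter$noise_cv / 5),
      yfp = .data$yfp_norm * ref$yfp * rlnorm_mean1(nr, reporter$noise_cv / 5),
      cfp = .data$cfp_norm * ref$cfp * rlnorm_mean1(nr, reporter$noise_cv / 5)
    ) |>
    dplyr::select("well", "day", "od", "yfp", "cfp")
  attr(noisy, "truth") <- truth
  noisy
}

#' Classify a plate time series
#'
#' Normalizes each well/day's raw fluorescence by the mean over all day-0
#' wells (the ancestral inoculum) and applies [classify_population()].
#'
#' @param plate A plate tibble (`well`, `day`, `od`, `yfp`, `cfp`).
#' @param t [thresholds()].
#' @return The plate tibble with `yfp_norm`, `cfp_norm`, `label` columns.
#' @export
classify_plate <- function(plate, t = thresholds()) {
  stopifnot(all(c("well", "day", "yfp", "cfp") %in% names(plate)))
  day0 <- plate[plate$day == min(plate$day), ]
  if (nrow(day0) == 0) stop("plate has no reference (earliest-day) rows",
                            call. = FALSE)
  plate |>
    dplyr::mutate(yfp_norm = .data$yfp / mean(day0$yfp),
                  cfp_norm = .data$cfp / mean(day0$cfp)) |>
    classify_population(t = t)
}

# sample genotype classes for template molecules: a cell of class (k, m)
# contributes k template copies, m of them evolved
sample_templates <- function(state, n_reads) {
  ncol <- if ("n" %in% names(state)) "n" else "count"
  w <- state[[ncol]] * state$k
  if (sum(w) <= 0) stop("empty composition", call. = FALSE)
  cls <- sample.int(nrow(state), n_reads, replace = TRUE, prob = w)
  evolved <- stats::runif(n_reads) < (state$m[cls] / state$k[cls])
  evolved
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent per-base substitutions at rate e; only reads drawn with >= 1
# error are touched, so the cost scales with the error count, not read count
mutate_bases <- function(seqs, e) {
  if (e <= 0) return(seqs)
  len <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), len, e)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0)) {
    pos <- sample.int(len[i], nerr[i])
    chars <- strsplit(seqs[i], "")[[1]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
    seqs[i] <- paste(chars, collapse = "")
  }
  seqs
}

#' Generate synthetic amplicon reads from population compositions
#'
#' Template molecules are drawn in proportion to cell frequency times copy
#' number k; each template from a (k, m) cell is an evolved one with
#' probability m/k (the evolved allele sits on m of the k tandem copies).
#' Reads are windows of the reference around the start codon carrying the
#' ancestral or the all-SNPs evolved promoter motif, with independent per-base
#' substitution errors at rate `error_rate`, random strand orientation, and an
#' optional contaminant spike-in.
#'
#' @param state A population tibble (`k`, `m`, `n`/`count`) — e.g. one
#'   replicate's final snapshot, or several pooled.
#' @param motifs A `motif_set`; templates use its `ancestral` motif, its last
#'   `evolved` motif (the all-SNPs combination when present) and its `control`
#'   motif; contaminant reads embed the first `contaminant` sequence.
#' @param n_reads Number of reads.
#' @param read_length Read length (>= 100 recommended; reads are windows of
#'   the 120-nt reference when shorter).
#' @param error_rate Per-base substitution error rate.
#' @param contaminant_frac Fraction of reads drawn from the contaminant
#'   template.
#' @param reference Reference sequence; default [synthetic_p0_reference()].
#' @param start_codon_at Position of the start codon in `reference`.
#' @param seed Optional seed.
#' @return A tibble (`id`, `seq`, `qual`) of class `fastq_reads` with
#'   attribute `truth` (template counts).
#' @export
gen_amplicon_reads <- function(state, motifs, n_reads = 10000,
                               read_length = 100, error_rate = 0.001,
                               contaminant_frac = 0,
                               reference = synthetic_p0_reference(),
                               start_codon_at = 61, seed = NULL) {
  stopifnot(inherits(motifs, "motif_set"), n_reads >= 1,
            error_rate >= 0, error_rate <= 0.1,
            contaminant_frac >= 0, contaminant_frac < 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (read_length < 39) stop("read length below motif length", call. = FALSE)
  ev <- motifs[motifs$role == "evolved", ]
  evolved_motif <- if (nrow(ev) > 0) ev$sequence[nrow(ev)] else NULL
  anc_template <- reference
  evo_template <- reference
  if (!is.null(evolved_motif)) {
    substr(evo_template, start_codon_at - 39, start_codon_at - 1) <- evolved_motif
  }
  is_cont <- stats::runif(n_reads) < contaminant_frac
  evolved <- sample_templates(state, n_reads)
  evolved[is_cont] <- FALSE
  cont_template <- NULL
  if (any(is_cont)) {
    cm <- motifs[motifs$role == "contaminant", ]
    if (nrow(cm) == 0) stop("contaminant spike-in requested but motif set ",
                            "has no contaminant", call. = FALSE)
    # embed the contaminant sequence in its own synthetic flanking context
    pad <- max(0, nchar(reference) - nchar(cm$sequence[1]))
    left <- random_dna(ceiling(pad / 2)); right <- random_dna(floor(pad / 2))
    cont_template <- paste0(left, cm$sequence[1], right)
  }
  template <- ifelse(is_cont, cont_template %||% "",
                     ifelse(evolved, evo_template, anc_template))
  # window containing the upstream motif: keep offsets [-39, -1] inside
  tlen <- nchar(reference)
  if (read_length >= tlen) {
    reads <- template
  } else {
    max_start <- min(start_codon_at - 39, tlen - read_length + 1)
    starts <- sample.int(max_start, n_reads, replace = TRUE)
    reads <- substr(template, starts, starts + read_length - 1L)
  }
  reads <- mutate_bases(reads, error_rate)
  flip <- stats::runif(n_reads) < 0.5
  reads[flip] <- revcomp(reads[flip])
  out <- tibble::tibble(
    id = sprintf("read%06d", seq_len(n_reads)),
    seq = reads,
    qual = strrep("I", nchar(reads))
  )
  class(out) <- c("fastq_reads", class(out))
  attr(out, "truth") <- tibble::tibble(
    n_reads = n_reads,
    n_evolved_templates = sum(evolved & !is_cont),
    n_ancestral_templates = sum(!evolved & !is_cont),
    n_contaminant = sum(is_cont),
    error_rate = error_rate
  )
  out
}

#' Generate a synthetic qPCR run
#'
#' Cq values follow Cq = intercept - log_E(relative template amount) plus
#' Gaussian noise. The target channel scales with the true copy number; the
#' reference channel is copy-invariant. Both channels get a 4-point 10-fold
#' dilution series (for efficiency estimation) and `n_reps` technical
#' replicates per sample; the calibrator is the single-copy ancestor.
#'
#' @param true_copies True relative copy number of the sample (>= 1).
#' @param e_target,e_ref True amplification efficiencies (fold per cycle, in
#'   (1, 2.2]).
#' @param noise_sd Gaussian Cq noise (cycles).
#' @param n_reps Technical replicates.
#' @param seed Optional seed.
#' @return A `qpcr_run` list (`cq`, `dilution_series`) with attribute
#'   `truth`; see [estimate_copy_number()].
#' @examples
#' run <- gen_qpcr_run(true_copies = 4, seed = 1)
#' estimate_copy_number(run)
#' @export
gen_qpcr_run <- function(true_copies, e_target = 2, e_ref = 2, noise_sd = 0,
                         n_reps = 3, seed = NULL) {
  stopifnot(true_copies >= 1, e_target > 1, e_target <= 2.2,
            e_ref > 1, e_ref <= 2.2, noise_sd >= 0, n_reps >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  a_t <- 18; a_r <- 20  # arbitrary intercepts (Cq of one template unit)
  cq_of <- function(amount, eff, a) a - log(amount, base = eff)
  noise <- function(n) stats::rnorm(n, 0, noise_sd)
  samples <- tidyr::expand_grid(
    sample = c("calibrator", "sample"),
    channel = c("target", "reference"),
    replicate = seq_len(n_reps)
  )
  samples$cq <- with(samples, ifelse(
    channel == "target",
    cq_of(ifelse(sample == "sample", true_copies, 1), e_target, a_t),
    cq_of(1, e_ref, a_r)
  )) + noise(nrow(samples))
  dil <- tidyr::expand_grid(channel = c("target", "reference"),
                            dilution = 10^-(0:3))
  dil$cq <- with(dil, ifelse(channel == "target",
                             cq_of(dilution, e_target, a_t),
                             cq_of(dilution, e_ref, a_r))) + noise(nrow(dil))
  run <- list(cq = samples[c("sample", "channel", "replicate", "cq")],
              dilution_series = dil)
  class(run) <- "qpcr_run"
  attr(run, "truth") <- list(true_copies = true_copies, e_target = e_target,
                             e_ref = e_ref, noise_sd = noise_sd)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a
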