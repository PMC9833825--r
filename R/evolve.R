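# Internal dense representation of a population: one abundance per genotype
# class (k, m), 1 <= k <= kmax, 0 <= m <= k, stored as a flat vector indexed by
# idx(k, m) = (k - 1)(k + 2)/2 + m + 1. Mutation targets are precomputed once
# per kmax so per-substep flows are fully vectorised.

class_offsets <- function(kmax) ((seq_len(kmax) - 1L) * (seq_len(kmax) + 2L)) %/% 2L

class_table <- function(kmax) {
  kmax <- as.integer(kmax)
  k <- rep.int(seq_len(kmax), seq_len(kmax) + 1L)
  m <- unlist(lapply(seq_len(kmax), function(kk) 0:kk), use.names = FALSE)
  off <- class_offsets(kmax)
  idx <- function(k, m) off[k] + m + 1L
  nC <- length(k)
  na_if_false <- function(ok, i) ifelse(ok, i, NA_integer_)
  list(
    kmax = kmax, n_classes = nC, k = k, m = m, idx = idx,
    # duplication (k = 1 only): (1, m) -> (2, 2m)
    dup_to = na_if_false(k == 1L, idx(pmin(2L, kmax), pmin(2L * m, kmax))),
    # amplification (2 <= k < kmax): (k, m) -> (k+1, m+1) w.p. m/k else (k+1, m)
    amp_hi = na_if_false(k >= 2L & k < kmax, idx(pmin(k + 1L, kmax), pmin(m + 1L, kmax))),
    amp_lo = na_if_false(k >= 2L & k < kmax, idx(pmin(k + 1L, kmax), m)),
    # deletion (k >= 2): (k, m) -> (k-1, m-1) w.p. m/k else (k-1, m)
    del_hi = na_if_false(k >= 2L & m >= 1L, idx(pmax(k - 1L, 1L), pmax(m - 1L, 0L))),
    del_lo = na_if_false(k >= 2L & m <= k - 1L, idx(pmax(k - 1L, 1L), pmin(m, pmax(k - 1L, 1L)))),
    # point mutation: (k, m < k) -> (k, m + 1)
    pm_to = na_if_false(m < k, idx(k, pmin(m + 1L, k))),
    frac_hi = m / k
  )
}

state_to_vec <- function(state, ct) {
  validate_genotype(state)
  stopifnot("n" %in% names(state), all(state$n >= 0))
  if (any(state$k > ct$kmax)) stop("state contains k > kmax", call. = FALSE)
  v <- numeric(ct$n_classes)
  v[ct$idx(state$k, state$m)] <- v[ct$idx(state$k, state$m)] + state$n
  v
}

vec_to_state <- function(v, ct, drop_zero = TRUE) {
  keep <- if (drop_zero) v > 0 else rep(TRUE, length(v))
  if (!any(keep)) keep <- 1L  # keep one row so the frame is never empty
  tibble::tibble(k = ct$k[keep], m = ct$m[keep], n = v[keep])
}

#' Create a population state
#'
#' @param k,m,n Parallel vectors: genotype class (k copies, m mutant copies)
#'   and its abundance (cells; non-negative, real-valued between bottlenecks).
#' @return A tibble with columns `k`, `m`, `n`.
#' @examples
#' population_state(k = c(1, 4), m = c(0, 0), n = c(9e5, 1e5))
#' @export
population_state <- function(k = 1L, m = 0L, n = 1e5) {
  d <- tibble::tibble(k = as.integer(k), m = as.integer(m), n = as.numeric(n))
  validate_genotype(d)
  if (any(d$n < 0)) stop("abundances must be non-negative", call. = FALSE)
  d
}

# binomial draw robust to sizes that rpois returned as large doubles
rbinom_safe <- function(size, prob) {
  small <- size <= .Machine$integer.max
  out <- numeric(length(size))
  out[small] <- stats::rbinom(sum(small), size[small], prob[small])
  if (any(!small)) {  # normal approximation for astronomically large counts
    mu <- size[!small] * prob[!small]
    out[!small] <- round(mu + stats::rnorm(sum(!small), 0,
                                           sqrt(mu * (1 - prob[!small]))))
  }
  pmin(pmax(out, 0), size)
}

#' Hours of growth needed to reach the daily carrying capacity
#'
#' Solves sum_i n_i exp(r_i T) = k_cap for T by bisection (relative tolerance
#' 1e-10). Returns 0 if nothing grows or the population already is at capacity.
#'
#' @param state A population tibble (`k`, `m`, `n`).
#' @param env,alleles,protocol Model parameters.
#' @return Day duration in hours. If capacity is unreachable within 1000 h a
#'   warning of class `dupdiv_unreachable_capacity` is raised and the day is
#'   truncated at 1000 h.
#' @export
solve_day_duration <- function(state, env = env_params(),
                               alleles = allele_params(),
                               protocol = serial_protocol()) {
  total <- sum(state$n)
  stopifnot(total > 0)
  r <- growth_rate_of(state[c("k", "m")], env, alleles)$growth_rate
  solve_duration_vec(state$n, r, protocol$k_cap)
}

solve_duration_vec <- function(n, r, k_cap, t_max = 1000) {
  total_at <- function(t) sum(n * exp(r * t))
  if (sum(n) >= k_cap || all(r <= 0)) {
    if (sum(n) < k_cap && all(r <= 0)) {
      rlang::warn("population cannot regrow to capacity (all rates zero)",
                  class = "dupdiv_unreachable_capacity")
    }
    return(0)
  }
  if (total_at(t_max) < k_cap) {
    rlang::warn("capacity unreachable within 1000 h; day truncated",
                class = "dupdiv_unreachable_capacity")
    return(t_max)
  }
  lo <- 0; hi <- 1
  while (total_at(hi) < k_cap) hi <- min(hi * 2, t_max)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (total_at(mid) < k_cap) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-10 * hi) break
  }
  (lo + hi) / 2
}

# Core tau-leap mutation step on the flat class vector. `gens` is the number of
# generations elapsed for each class over the sub-interval. Poisson event
# counts (or their means when deterministic) move abundance between classes;
# total abundance is conserved and flows are capped at the source abundance.
mutation_step_vec <- function(v, ct, rates, gens, deterministic = FALSE) {
  act <- which(v > 0)
  if (length(act) == 0) return(v)
  n <- v[act]; g <- gens[act]
  k <- ct$k[act]; m <- ct$m[act]
  p_dup <- ifelse(k == 1L, rates$mu_dup, 0) * g
  p_amp <- ifelse(!is.na(ct$amp_hi[act]), rates$mu_step * (k - 1), 0) * g
  p_del <- ifelse(k >= 2L, rates$mu_step * (k - 1), 0) * g
  p_pm  <- rates$mu_pm * (k - m) * g
  if (max(p_dup, p_amp, p_del, p_pm) >= 1) {
    stop("invalid-rate: per-substep mutation probability >= 1; ",
         "increase protocol substeps", call. = FALSE)
  }
  draw <- function(lambda) {
    if (deterministic) lambda
    else {
      x <- numeric(length(lambda))
      pos <- lambda > 0
      x[pos] <- stats::rpois(sum(pos), lambda[pos])
      x
    }
  }
  x_dup <- draw(n * p_dup); x_amp <- draw(n * p_amp)
  x_del <- draw(n * p_del); x_pm <- draw(n * p_pm)
  # split amplification / deletion events by which copy the event duplicates
  # or removes: with probability m/k the affected copy is a mutant one
  split_hi <- function(x, frac) {
    if (deterministic) x * frac
    else {
      h <- numeric(length(x)); pos <- x > 0 & frac > 0 & frac < 1
      h[pos] <- rbinom_safe(x[pos], frac[pos])
      h[x > 0 & frac >= 1] <- x[x > 0 & frac >= 1]
      h
    }
  }
  frac <- ct$frac_hi[act]
  amp_hi <- split_hi(x_amp, frac); amp_lo <- x_amp - amp_hi
  del_hi <- split_hi(x_del, frac); del_lo <- x_del - del_hi
  out_tot <- x_dup + x_amp + x_del + x_pm
  over <- out_tot > n
  if (any(over)) {
    sc <- n[over] / out_tot[over]
    x_dup[over] <- x_dup[over] * sc
    amp_hi[over] <- amp_hi[over] * sc; amp_lo[over] <- amp_lo[over] * sc
    del_hi[over] <- del_hi[over] * sc; del_lo[over] <- del_lo[over] * sc
    x_pm[over] <- x_pm[over] * sc
    out_tot[over] <- n[over]
  }
  v2 <- v
  v2[act] <- v2[act] - out_tot
  add <- function(v2, tgt, amt) {
    ok <- !is.na(tgt) & amt > 0
    if (any(ok)) {
      s <- rowsum(amt[ok], tgt[ok])
      ii <- as.integer(rownames(s))
      v2[ii] <- v2[ii] + s[, 1]
    }
    v2
  }
  v2 <- add(v2, ct$dup_to[act], x_dup)
  v2 <- add(v2, ct$amp_hi[act], amp_hi)
  v2 <- add(v2, ct$amp_lo[act], amp_lo)
  v2 <- add(v2, ct$del_hi[act], del_hi)
  v2 <- add(v2, ct$del_lo[act], del_lo)
  v2 <- add(v2, ct$pm_to[act], x_pm)
  v2
}

#' Apply stochastic mutation flows to a population
#'
#' Tau-leap step: for each genotype class, Poisson-distributed numbers of cells
#' (mean = abundance x rate x generations) move to their mutational targets.
#' The single-copy class duplicates to (2, 2m) — a tandem duplication copies
#' the resident allele. Arrays (k >= 2) amplify to k + 1 or delete to k - 1 at
#' rate `mu_step` per junction (k - 1 junctions); the affected copy is a mutant
#' one with probability m/k, encoding random gain or loss of the diverged copy.
#' Point mutation converts one ancestral copy (rate `mu_pm` per copy).
#'
#' @param state Population tibble (`k`, `m`, `n`).
#' @param rates [mutation_rates()].
#' @param generations Generations elapsed; scalar or one value per row of
#'   `state`.
#' @param kmax Largest array size tracked.
#' @param deterministic If `TRUE`, replace random draws by their expectations.
#' @return A population tibble; total abundance is conserved.
#' @export
mutation_flows <- function(state, rates, generations, kmax = 20,
                           deterministic = FALSE) {
  stopifnot(inherits(rates, "mutation_rates"), all(generations >= 0))
  ct <- class_table(kmax)
  v <- state_to_vec(state, ct)
  gens <- numeric(ct$n_classes)
  gens[ct$idx(state$k, state$m)] <- rep_len(generations, nrow(state))
  vec_to_state(mutation_step_vec(v, ct, rates, gens, deterministic), ct)
}

grow_day_vec <- function(v, ct, r, config, deterministic = FALSE) {
  pro <- config$protocol
  act <- v > 0
  t_day <- solve_duration_vec(v[act], r[act], pro$k_cap)
  if (t_day == 0) return(list(v = v, hours = 0))
  dt <- t_day / pro$substeps
  growth <- exp(r * dt)
  gens <- r * dt / log(2)
  for (s in seq_len(pro$substeps)) {
    v <- v * growth
    v <- mutation_step_vec(v, ct, config$rates, gens, deterministic)
  }
  list(v = v, hours = t_day)
}

#' One day of batch growth with mutation
#'
#' The day duration is solved so the population exactly reaches carrying
#' capacity, then split into `substeps` equal sub-intervals; within each,
#' every class grows exponentially at its own rate and mutation flows are
#' applied with the class-specific number of generations elapsed
#' (r * dt / ln 2).
#'
#' @inheritParams solve_day_duration
#' @param config A [sim_config()].
#' @param deterministic Use expected mutation flows instead of Poisson draws.
#' @return A population tibble with attribute `hours` (the solved duration).
#' @export
grow_day <- function(state, config, deterministic = FALSE) {
  ct <- class_table(config$kmax)
  v <- state_to_vec(state, ct)
  r <- class_growth_rates(ct, config)
  res <- grow_day_vec(v, ct, r, config, deterministic)
  out <- vec_to_state(res$v, ct)
  attr(out, "hours") <- res$hours
  out
}

class_growth_rates <- function(ct, config) {
  growth_rate_of(tibble::tibble(k = ct$k, m = ct$m), config$env,
                 config$alleles)$growth_rate
}

#' Daily serial-transfer bottleneck
#'
#' Multinomial sampling of round(total / dilution_factor) cells with
#' probabilities equal to the class frequencies.
#'
#' @inheritParams grow_day
#' @param protocol [serial_protocol()].
#' @return An integer-valued population tibble.
#' @export
bottleneck <- function(state, protocol = serial_protocol()) {
  total <- sum(state$n)
  stopifnot(total > 0)
  n_b <- round(total / protocol$dilution_factor)
  if (n_b == 0) stop("extinct: bottleneck removed every cell", call. = FALSE)
  counts <- as.numeric(stats::rmultinom(1, n_b, state$n / total))
  out <- state
  out$n <- counts
  out[out$n > 0, , drop = FALSE]
}

#' Simulate one replicate of the serial-passage evolution experiment
#'
#' Starts from round(k_cap / dilution_factor) ancestral cells, then for each
#' day grows the population to capacity ([grow_day()]), records the
#' pre-dilution snapshot, and applies the [bottleneck()]. Fully reproducible
#' given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed for this replicate.
#' @return A tibble of class `dupdiv_trajectory` with columns
#'   `day`, `k`, `m`, `count` (day 0 is the inoculum; days 1..n_days are
#'   pre-dilution snapshots at carrying capacity).
#' @examples
#' cfg <- sim_config(env = demand_preset("low"), rates = rate_preset("IS+"),
#'                   protocol = serial_protocol(k_cap = 1e5, n_days = 3))
#' run_replicate(cfg, seed = 1)
#' @export
run_replicate <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  ct <- class_table(config$kmax)
  r <- class_growth_rates(ct, config)
  pro <- config$protocol
  n_b <- round(pro$k_cap / pro$dilution_factor)
  v <- numeric(ct$n_classes)
  v[ct$idx(1L, 0L)] <- n_b
  snap <- function(day, v) {
    s <- vec_to_state(v, ct)
    tibble::tibble(day = day, k = s$k, m = s$m, count = s$n)
  }
  out <- vector("list", pro$n_days + 1L)
  out[[1]] <- snap(0L, v)
  for (day in seq_len(pro$n_days)) {
    v <- grow_day_vec(v, ct, r, config)$v
    out[[day + 1L]] <- snap(day, v)
    # bottleneck into the next day
    total <- sum(v)
    nb <- round(total / pro$dilution_factor)
    if (nb == 0) {
      rlang::warn(sprintf("replicate extinct at day %d", day),
                  class = "dupdiv_extinct")
      out <- out[seq_len(day + 1L)]
      break
    }
    act <- which(v > 0)
    v2 <- numeric(ct$n_classes)
    v2[act] <- as.numeric(stats::rmultinom(1, nb, v[act] / total))
    v <- v2
  }
  traj <- dplyr::bind_rows(out)
  class(traj) <- c("dupdiv_trajectory", class(traj))
  attr(traj, "seed") <- as.integer(seed)
  attr(traj, "config") <- config
  traj
}

#' Simulate many replicate populations
#'
#' Replicate i uses seed `base_seed + i - 1`, so any replicate can be
#' reproduced in isolation with [run_replicate()].
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicate populations.
#' @param base_seed Seed of replicate 1.
#' @return A tibble of class `dupdiv_experiment` with columns
#'   `replicate`, `day`, `k`, `m`, `count`.
#' @export
run_experiment <- function(config, n_replicates, base_seed = 1) {
  out <- purrr::map(seq_len(n_replicates), function(i) {
    tr <- run_replicate(config, seed = base_seed + i - 1)
    dplyr::mutate(tibble::as_tibble(tr), replicate = i, .before = 1)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("dupdiv_experiment", class(res))
  attr(res, "config") <- config
  attr(res, "base_seed") <- as.integer(base_seed)
  attr(res, "n_replicates") <- as.integer(n_replicates)
  res
}

#' Deterministic (infinite-population) expectation of the experiment
#'
#' Identical recursion to [run_replicate()] with Poisson flows replaced by
#' their means and the multinomial bottleneck replaced by exact dilution; the
#' law-of-large-numbers oracle for the stochastic simulator.
#'
#' @inheritParams run_replicate
#' @return A tibble with columns `day`, `k`, `m`, `count`, `frequency`.
#' @export
deterministic_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ct <- class_table(config$kmax)
  r <- class_growth_rates(ct, config)
  pro <- config$protocol
  v <- numeric(ct$n_classes)
  v[ct$idx(1L, 0L)] <- pro$k_cap / pro$dilution_factor
  snap <- function(day, v) {
    s <- vec_to_state(v, ct)
    tibble::tibble(day = day, k = s$k, m = s$m, count = s$n,
                   frequency = s$n / sum(s$n))
  }
  out <- vector("list", pro$n_days + 1L)
  out[[1]] <- snap(0L, v)
  for (day in seq_len(pro$n_days)) {
    v <- grow_day_vec(v, ct, r, config, deterministic = TRUE)$v
    out[[day + 1L]] <- snap(day, v)
    v <- v / pro$dilution_factor
  }
  dplyr::bind_rows(out)
}

#' Per-day class frequencies of a simulated experiment
#'
#' @param x A `dupdiv_trajectory` or `dupdiv_experiment` tibble.
#' @return The input with an added `frequency` column (within replicate/day).
#' @export
class_frequencies <- function(x) {
  grp <- intersect(c("replicate", "day"), names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
}

#' Summarise an experiment
#'
#' One row per replicate with day-12 (final-day) composition summaries:
#' frequency of amplified cells (k >= 2) and of combination mutants
#' (k >= 2 and m >= 1).
#'
#' @param x A `dupdiv_experiment`.
#' @param ... Unused.
#' @return A tibble with columns `replicate`, `final_day`, `amplified_freq`,
#'   `combination_freq`, `point_mutant_freq`.
#' @exportS3Method generics::glance
#' @export
glance.dupdiv_experiment <- function(x, ...) {
  x |>
    dplyr::group_by(.data$replicate) |>
    dplyr::filter(.data$day == max(.data$day)) |>
    dplyr::summarise(
      final_day = .data$day[1],
      amplified_freq = sum(.data$count[.data$k >= 2]) / sum(.data$count),
      combination_freq =
        sum(.data$count[.data$k >= 2 & .data$m >= 1]) / sum(.data$count),
      point_mutant_freq =
        sum(.data$count[.data$m >= 1]) / sum(.data$count),
      .groups = "drop"
    )
}
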