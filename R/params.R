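#' Promoter allele expression parameters
#'
#' Per-copy expression strengths of the two promoter alleles carried by copies
#' of the reporter locus: the weak random promoter present in the ancestor
#' (leaky baseline expression) and the evolved allele created by an adaptive
#' point mutation.
#'
#' @param beta_anc Per-copy expression of the ancestral (random) promoter, in
#'   arbitrary expression units. Must be positive and smaller than `beta_mut`.
#' @param beta_mut Per-copy expression of the evolved promoter allele.
#' @return An object of class `allele_params`.
#' @examples
#' allele_params()
#' @export
allele_params <- function(beta_anc = 1, beta_mut = 20) {
  stopifnot(is.numeric(beta_anc), is.numeric(beta_mut),
            length(beta_anc) == 1, length(beta_mut) == 1)
  if (!(beta_anc > 0 && beta_mut > beta_anc)) {
    stop("allele_params: need 0 < beta_anc < beta_mut", call. = FALSE)
  }
  structure(list(beta_anc = beta_anc, beta_mut = beta_mut),
            class = "allele_params")
}

#' Environment / fitness-map parameters
#'
#' The selective environment is summarised by the gene-expression demand `demand`:
#' growth rate rises linearly with expression until it saturates at `rmax`
#' once expression reaches `demand`, and each tandem copy beyond the first pays a
#' constant growth-rate cost. Low demand means a small expression improvement
#' already confers the full benefit; high demand requires a large one.
#'
#' @param demand Expression level at which growth saturates (expression units).
#' @param r0 Growth rate at zero expression of the selected gene (per hour);
#'   positive because the medium supports growth without it.
#' @param rmax Growth rate at or above demand (per hour).
#' @param cost Growth-rate penalty per extra tandem copy (per hour per copy).
#' @return An object of class `env_params`.
#' @examples
#' env_params(demand = 4)          # low demand
#' demand_preset("high")
#' @export
env_params <- function(demand = 4, r0 = 0.2, rmax = 0.9, cost = 0.01) {
  stopifnot(length(demand) == 1, length(r0) == 1, length(rmax) == 1,
            length(cost) == 1)
  if (!(rmax > r0 && r0 >= 0 && demand > 0 && cost >= 0)) {
    stop("env_params: need rmax > r0 >= 0, demand > 0, cost >= 0",
         call. = FALSE)
  }
  structure(list(demand = demand, r0 = r0, rmax = rmax, cost = cost),
            class = "env_params")
}

#' @rdname env_params
#' @param level One of `"low"`, `"intermediate"`, `"high"` — the three
#'   qualitative demand regimes (galactose concentrations). With the default
#'   allele strengths (`beta_anc = 1`, `beta_mut = 20`), low demand (4) is
#'   satisfiable by amplification to four copies OR by one point mutation;
#'   intermediate (25) by neither single route alone but nearly by a point
#'   mutation; high demand (60) only by a combination of both mutation types.
#' @export
demand_preset <- function(level = c("low", "intermediate", "high")) {
  level <- match.arg(level)
  env_params(demand = switch(level, low = 4, intermediate = 25, high = 60))
}

#' Copy-number and point mutation rates
#'
#' Rates of the three mutational moves acting on a tandem array: de novo
#' duplication of the single-copy locus, expansion/contraction of an existing
#' array by homologous recombination between repeats (applied per junction,
#' i.e. scaled by k - 1), and the adaptive promoter point mutation (applied
#' per gene copy).
#'
#' @param mu_dup Single-copy to two-copy duplication rate, per cell per
#'   generation.
#' @param mu_step Per-junction amplification/deletion rate for arrays with
#'   k >= 2, per cell per generation.
#' @param mu_pm Adaptive point-mutation rate per gene copy per generation.
#' @return An object of class `mutation_rates`.
#' @examples
#' rate_preset("IS+")
#' rate_preset("IS-")
#' @export
mutation_rates <- function(mu_dup = 1e-3, mu_step = 1e-2, mu_pm = 1e-7) {
  r <- c(mu_dup = mu_dup, mu_step = mu_step, mu_pm = mu_pm)
  if (any(r < 0) || any(r >= 1)) {
    stop("mutation_rates: all rates must lie in [0, 1)", call. = FALSE)
  }
  structure(list(mu_dup = mu_dup, mu_step = mu_step, mu_pm = mu_pm),
            class = "mutation_rates")
}

#' @rdname mutation_rates
#' @param strain `"IS+"` for the duplication-prone strain (flanking insertion
#'   sequences provide a recombination substrate, duplication ~1e-3 per cell
#'   per generation); `"IS-"` for the strain lacking the repeat, where only a
#'   rare repeat-independent duplication route remains (~1e-6). Once a
#'   duplication exists, array expansion/contraction is repeat-driven in both
#'   strains, so `mu_step` is unchanged.
#' @export
rate_preset <- function(strain = c("IS+", "IS-")) {
  strain <- match.arg(strain)
  mutation_rates(mu_dup = if (strain == "IS+") 1e-3 else 1e-6,
                 mu_step = 1e-2, mu_pm = 1e-7)
}

#' Serial-dilution passage protocol
#'
#' Daily regrowth to a fixed carrying capacity followed by a ~1:820 dilution
#' into fresh medium, corresponding to roughly ten generations of regrowth per
#' day (`log2(820)` is 9.68).
#'
#' @param dilution_factor Daily dilution (default 820).
#' @param k_cap Carrying capacity in cells (default 1e8; scale down for tests).
#' @param n_days Number of daily transfers (default 12).
#' @param substeps Number of equal sub-intervals per day over which mutation
#'   flows are applied (tau-leaping; default 10, roughly one per generation).
#' @return An object of class `serial_protocol`.
#' @export
serial_protocol <- function(dilution_factor = 820, k_cap = 1e8, n_days = 12,
                            substeps = 10) {
  if (!(dilution_factor > 1)) stop("dilution_factor must exceed 1", call. = FALSE)
  if (!(k_cap / dilution_factor >= 10)) {
    stop("k_cap/dilution_factor must be >= 10 (bottleneck too small)",
         call. = FALSE)
  }
  stopifnot(n_days >= 1, substeps >= 1)
  structure(list(dilution_factor = dilution_factor, k_cap = k_cap,
                 n_days = as.integer(n_days), substeps = as.integer(substeps)),
            class = "serial_protocol")
}

#' Bundle a full simulation configuration
#'
#' @param alleles [allele_params()].
#' @param env [env_params()] or a [demand_preset()].
#' @param rates [mutation_rates()] or a [rate_preset()].
#' @param protocol [serial_protocol()].
#' @param kmax Maximum tandem-array size tracked (default 20). Amplification
#'   events that would exceed `kmax` are suppressed.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(env = demand_preset("low"), rates = rate_preset("IS+"),
#'                   protocol = serial_protocol(k_cap = 1e6))
#' @export
sim_config <- function(alleles = allele_params(), env = env_params(),
                       rates = mutation_rates(), protocol = serial_protocol(),
                       kmax = 20) {
  stopifnot(inherits(alleles, "allele_params"), inherits(env, "env_params"),
            inherits(rates, "mutation_rates"),
            inherits(protocol, "serial_protocol"), kmax >= 1)
  structure(list(alleles = alleles, env = env, rates = rates,
                 protocol = protocol, kmax = as.integer(kmax)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  alleles : beta_anc=%g beta_mut=%g\n",
              x$alleles$beta_anc, x$alleles$beta_mut))
  cat(sprintf("  env     : demand=%g r0=%g rmax=%g cost=%g\n",
              x$env$demand, x$env$r0, x$env$rmax, x$env$cost))
  cat(sprintf("  rates   : mu_dup=%g mu_step=%g mu_pm=%g\n",
              x$rates$mu_dup, x$rates$mu_step, x$rates$mu_pm))
  cat(sprintf("  protocol: 1:%g dilution, K=%g, %d days, %d substeps\n",
              x$protocol$dilution_factor, x$protocol$k_cap,
              x$protocol$n_days, x$protocol$substeps))
  cat(sprintf("  kmax    : %d\n", x$kmax))
  invisible(x)
}
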