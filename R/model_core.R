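#' Genotype classes of the tandem-array locus
#'
#' A genotype is the state of the reporter tandem array: `k` copies of the
#' locus, `m` of which carry the adaptive promoter allele. The ancestor is
#' (k = 1, m = 0); a pure amplification is (k >= 2, m = 0); a pure promoter
#' mutant is (1, 1); a combination mutant carries both (k >= 2, m >= 1).
#'
#' @param k Integer vector of copy counts (>= 1).
#' @param m Integer vector of mutant-copy counts (0 <= m <= k), recycled
#'   against `k`.
#' @return A tibble with integer columns `k` and `m`.
#' @examples
#' genotype(c(1, 4, 4), c(0, 0, 1))
#' @export
genotype <- function(k, m = 0L) {
  d <- tibble::tibble(k = as.integer(k), m = as.integer(m))
  validate_genotype(d)
  d
}

validate_genotype <- function(d) {
  stopifnot(is.data.frame(d), all(c("k", "m") %in% names(d)))
  if (any(d$k < 1) || any(d$m < 0) || any(d$m > d$k)) {
    stop("invalid genotype: need k >= 1 and 0 <= m <= k", call. = FALSE)
  }
  invisible(d)
}

#' Expression level of a genotype
#'
#' Total expression of the selected gene under a pure dosage model: each of the
#' k - m ancestral copies contributes `beta_anc`, each of the m evolved copies
#' `beta_mut`, so E = (k - m) * beta_anc + m * beta_mut. Strictly increasing in
#' both k and m.
#'
#' @param genotypes A data frame with columns `k` and `m` (see [genotype()]).
#' @param alleles [allele_params()].
#' @return The input tibble with an added numeric column `expression`.
#' @examples
#' expression_level(genotype(4, 1), allele_params(1, 20))  # 3*1 + 20 = 23
#' @export
expression_level <- function(genotypes, alleles = allele_params()) {
  validate_genotype(genotypes)
  stopifnot(inherits(alleles, "allele_params"))
  dplyr::mutate(
    tibble::as_tibble(genotypes),
    expression = (.data$k - .data$m) * alleles$beta_anc +
      .data$m * alleles$beta_mut
  )
}

#' Growth rate of a genotype in a given environment
#'
#' The expression-fitness map is piecewise linear with a hard plateau:
#' r = r0 + (rmax - r0) * min(E / demand, 1) - cost * (k - 1), clamped below at
#' zero. Past the demand plateau extra expression adds nothing while extra
#' copies still pay the per-copy cost; this is the mechanism of negative
#' epistasis between dosage and promoter mutations under low demand.
#'
#' @inheritParams expression_level
#' @param env [env_params()].
#' @return The input tibble with added columns `expression` and `growth_rate`
#'   (per hour).
#' @examples
#' growth_rate_of(genotype(c(1, 4, 1), c(0, 0, 1)),
#'                env_params(demand = 4), allele_params())
#' @export
growth_rate_of <- function(genotypes, env = env_params(),
                           alleles = allele_params()) {
  stopifnot(inherits(env, "env_params"))
  expression_level(genotypes, alleles) |>
    dplyr::mutate(
      growth_rate = pmax(
        0,
        env$r0 + (env$rmax - env$r0) * pmin(.data$expression / env$demand, 1) -
          env$cost * (.data$k - 1)
      )
    )
}
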