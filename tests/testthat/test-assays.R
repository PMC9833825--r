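test_that("max growth rate is exact on exponentials and matches the OLS oracle", {
  tt <- seq(0, 5, by = 1 / 6)
  exp_curve <- tibble::tibble(time = tt, od = 0.01 * exp(0.5 * tt))
  expect_equal(max_growth_rate(exp_curve), 0.5, tolerance = 1e-9)
  flat <- tibble::tibble(time = tt, od = rep(0.3, length(tt)))
  expect_equal(max_growth_rate(flat), 0)
  # logistic curve: equality with the brute-force all-windows lm() oracle
  logi <- gen_growth_curve(r = 0.8, lag_hours = 1, k_over_od0 = 100,
                           duration_hours = 12, noise_sd = 0.01, seed = 4)
  expect_equal(max_growth_rate(logi), oracle_max_slope(logi), tolerance = 1e-9)
  # invariances: OD scale and time offset
  expect_equal(max_growth_rate(dplyr::mutate(logi, od = od * 17)),
               max_growth_rate(logi), tolerance = 1e-9)
  expect_equal(max_growth_rate(dplyr::mutate(logi, time = time + 3.2)),
               max_growth_rate(logi), tolerance = 1e-9)
  expect_error(max_growth_rate(exp_curve[1:10, ]), "shorter")
  expect_error(max_growth_rate(dplyr::mutate(exp_curve, od = od - 1)),
               "non-positive")
})

test_that("growth fit exposes tidy per-window slopes", {
  logi <- gen_growth_curve(r = 0.6, seed = 1)
  fit <- fit_growth_rate(logi)
  td <- tidy(fit)
  expect_equal(nrow(td), nrow(logi) - 20 + 1)
  expect_equal(max(td$slope), glance(fit)$max_rate)
})

test_that("qPCR efficiency comes from the dilution-series slope", {
  make_series <- function(slope) {
    tibble::tibble(dilution = 10^-(0:3), cq = 12 - slope * (0:3))
  }
  expect_equal(as.numeric(qpcr_efficiency(make_series(-3.3219))), 2.0,
               tolerance = 1e-3)
  expect_equal(as.numeric(qpcr_efficiency(make_series(-3.6))), 10^(1 / 3.6),
               tolerance = 1e-9)
  # round-trip through the generator at E = 1.95
  run <- gen_qpcr_run(true_copies = 2, e_target = 1.95, noise_sd = 0)
  tgt <- run$dilution_series[run$dilution_series$channel == "target", ]
  expect_equal(as.numeric(qpcr_efficiency(tgt)), 1.95, tolerance = 1e-6)
  expect_error(qpcr_efficiency(tibble::tibble(dilution = c(1, 0.1), cq = 1:2)),
               "3 distinct")
})

test_that("Pfaffl ratio evaluates the efficiency-corrected formula", {
  expect_equal(pfaffl_ratio(2, 0, 2, 0), 1.0)
  expect_equal(pfaffl_ratio(2, 2, 2, 0), 4.0)
  expect_equal(pfaffl_ratio(1.9, 3.1, 2.05, -0.2), 1.9^3.1 / 2.05^-0.2)
  expect_equal(round(pfaffl_ratio(1.9, 3.1, 2.05, -0.2), 2), 8.44)
  # multiplicative in dCq on the target channel
  expect_equal(pfaffl_ratio(1.9, 1.3 + 0.9, 2, 0),
               pfaffl_ratio(1.9, 1.3, 2, 0) * pfaffl_ratio(1.9, 0.9, 2, 0))
  expect_error(pfaffl_ratio(0.9, 1, 2, 0), "out of range")
})

test_that("motif construction follows the start-codon coordinate convention", {
  ms <- build_motif_set(synthetic_p0_reference(), 61)
  seqs <- setNames(ms$sequence, ms$motif)
  expect_true(all(nchar(ms$sequence) == 39))
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  # -30 sits at 0-based window index 9 (39 - 30)
  diff_pos <- which(strsplit(seqs[["ancestral"]], "")[[1]] !=
                      strsplit(seqs[["-30T>A"]], "")[[1]])
  expect_equal(diff_pos, 10)  # 1-based
  expect_equal(hamming(seqs[["ancestral"]], seqs[["double"]]), 2)
  expect_equal(hamming(seqs[["-30T>A"]], seqs[["double"]]), 1)
  expect_equal(hamming(seqs[["-37C>T"]], seqs[["double"]]), 1)
  # no SNPs: only ancestral + control remain
  ms0 <- build_motif_set(synthetic_p0_reference(), 61,
                         snps = canonical_p0_snps()[0, ])
  expect_setequal(ms0$motif, c("ancestral", "control"))
  expect_error(build_motif_set("ACGT", 2), "too short")
  expect_error(
    build_motif_set(synthetic_p0_reference(), 61,
                    snps = tibble::tibble(offset = -30L, from = "G", to = "A")),
    "reference base")
})

test_that("motif counting matches the worked fixture and its oracle", {
  ms <- build_motif_set(synthetic_p0_reference(), 61)
  seqs <- setNames(ms$sequence, ms$motif)
  pad <- function(x) paste0("AATTC", x, "GGACT")
  reads <- c(pad(seqs[["ancestral"]]), pad(seqs[["ancestral"]]),
             pad(seqs[["ancestral"]]), pad(seqs[["-30T>A"]]),
             strrep("ACGT", 15))
  counts <- count_motifs(reads, ms)
  get <- function(mo) counts$count[counts$motif == mo]
  expect_equal(get("ancestral"), 3L)
  expect_equal(get("-30T>A"), 1L)
  expect_equal(get("unassigned"), 1L)
  # strand symmetry
  counts_rc <- count_motifs(oracle_revcomp(reads), ms)
  expect_equal(counts_rc$count, counts$count)
  # oracle equivalence on a random fixture with contaminants and errors
  ms2 <- build_motif_set(synthetic_p0_reference(), 61,
                         contaminants = c(p0_2 = strrep("TTGACA", 7)))
  pool <- withr::with_seed(31, {
    st <- population_state(c(1, 4), c(0, 1), c(6e4, 4e4))
    gen_amplicon_reads(st, ms2, n_reads = 400, error_rate = 0.02,
                       contaminant_frac = 0.15)
  })
  got <- count_motifs(pool, ms2)
  want <- oracle_count_motifs(pool$seq, ms2)
  for (mo in names(want$counts)) {
    expect_equal(got$count[got$motif == mo], unname(want$counts[mo]))
  }
  expect_equal(sum(got$count[got$role == "contaminant"]), want$excluded)
  expect_equal(got$count[got$motif == "unassigned"], want$unassigned)
  # the partition adds up to the total
  expect_equal(sum(got$count[got$role %in% c("ancestral", "evolved",
                                             "contaminant", "unassigned")]),
               attr(got, "total"))
})

test_that("divergence fractions normalize to ancestral reads only", {
  ms <- build_motif_set(synthetic_p0_reference(), 61)
  seqs <- setNames(ms$sequence, ms$motif)
  reads <- c(rep(seqs[["ancestral"]], 3), seqs[["-30T>A"]])
  fr <- divergence_fractions(count_motifs(reads, ms))
  expect_equal(fr$fraction[fr$motif == "-30T>A"], 1 / 3)
  # adding unassigned junk leaves fractions unchanged
  fr2 <- divergence_fractions(count_motifs(c(reads, strrep("ACGT", 15)), ms))
  expect_equal(fr2$fraction, fr$fraction)
  expect_error(divergence_fractions(count_motifs(strrep("ACGT", 15), ms)),
               "zero ancestral")
})

test_that("single-SNP control counts distance-1 reads per exact read", {
  ms <- build_motif_set(synthetic_p0_reference(), 61)
  ctrl <- ms$sequence[ms$role == "control"]
  # error-free ancestral reads -> zero
  clean <- withr::with_seed(41, gen_amplicon_reads(
    population_state(1, 0, 1e4), ms, n_reads = 200, error_rate = 0))
  expect_equal(single_snp_control(clean, ctrl), 0)
  # constructed 2-in-10 fixture: 8 exact, 2 with one substitution
  flip1 <- function(s, i) { substr(s, i, i) <- if (substr(s, i, i) == "A") "C" else "A"; s }
  reads <- c(rep(ctrl, 8), flip1(ctrl, 5), flip1(ctrl, 20))
  expect_equal(single_snp_control(reads, ctrl), 0.25)
  # per-base error rate e: odds of exactly one error in the 39-bp window
  e <- 0.004
  noisy <- withr::with_seed(42, gen_amplicon_reads(
    population_state(1, 0, 1e4), ms, n_reads = 12000, error_rate = e))
  expected <- 39 * e * (1 - e)^38 / (1 - e)^39  # = 39e/(1-e)
  got <- single_snp_control(noisy, ctrl)
  n0 <- 12000 * (1 - e)^39
  expect_lt(abs(got - expected), 3 * sqrt(expected / n0))
})
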