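test_that("the four-fraction rule reproduces its worked examples", {
  t <- thresholds()
  lab <- function(y, c) {
    as.character(classify_population(
      tibble::tibble(yfp_norm = y, cfp_norm = c), t)$label)
  }
  expect_equal(lab(1.0, 1.0), "ANCESTRAL")
  expect_equal(lab(3.0, 1.1), "YFP_PLUS")
  expect_equal(lab(3.2, 3.0), "YFP_CFP_PLUS")   # ratio 1.07 <= 1.5
  expect_equal(lab(6.0, 2.5), "MIXED")          # ratio 2.4 > 1.5
  expect_error(lab(-1, 1), "positive")
})

test_that("the rule partitions the positive quadrant exhaustively", {
  t <- thresholds()
  withr::with_seed(1, {
    pts <- tibble::tibble(yfp_norm = 10^runif(500, -1, 2),
                          cfp_norm = 10^runif(500, -1, 2))
  })
  lab <- classify_population(pts, t)$label
  expect_false(any(is.na(lab)))
  # independent re-derivation of the same partition
  manual <- with(pts, ifelse(
    cfp_norm <= t$theta_c & yfp_norm <= t$theta_y, "ANCESTRAL",
    ifelse(cfp_norm <= t$theta_c, "YFP_PLUS",
           ifelse(yfp_norm / cfp_norm <= t$rho, "YFP_CFP_PLUS", "MIXED"))))
  expect_equal(as.character(lab), manual)
})

test_that("event classification is invariant to a common scale factor", {
  a <- allele_params(); p <- reporter_params()
  st <- population_state(c(1, 4), c(1, 0), c(5e4, 5e4))
  ev <- withr::with_seed(2, sample_flow_events(st, a, p, 2000))
  ref <- withr::with_seed(3, sample_flow_events(population_state(1, 0, 1e5),
                                                a, p, 2000))
  l1 <- classify_events(ev, ref)
  scaled <- dplyr::mutate(ev, yfp = .data$yfp * 37.5, cfp = .data$cfp * 37.5)
  ref_s <- dplyr::mutate(ref, yfp = .data$yfp * 37.5, cfp = .data$cfp * 37.5)
  l2 <- classify_events(scaled, ref_s)
  expect_equal(l1$label, l2$label)
})

test_that("event fractions match their lognormal-noise expectations", {
  a <- allele_params(1, 20)
  p <- reporter_params()  # cv 0.25, intrinsic 0.05
  t <- thresholds()
  # closed-form oracle: per-channel log-noise is N(-v/2, v), v = log(1 + cv^2);
  # normalization by the reference median cancels the median of the noise
  v <- log(1 + p$noise_cv^2)
  p_channel_high <- 1 - pnorm(log(t$theta_y) / sqrt(v))
  anc_expected <- pnorm(log(t$theta_y) / sqrt(v)) *
    pnorm(log(t$theta_c) / sqrt(v))  # upper bound ignoring correlation
  ref <- withr::with_seed(10, sample_flow_events(population_state(1, 0, 1e5),
                                                 a, p, 6000))
  ev <- withr::with_seed(11, sample_flow_events(population_state(1, 0, 1e5),
                                                a, p, 6000))
  fr <- label_frequencies(classify_events(ev, ref, t))
  f_anc <- fr$frequency[fr$label == "ANCESTRAL"]
  # with a shared extrinsic component the two channels exceed the threshold
  # together, so ANCESTRAL lies between the independent-channel product and
  # the perfectly-correlated single-channel probability
  expect_gt(f_anc, anc_expected - 0.02)
  expect_lt(f_anc, 1 - p_channel_high + 0.02)
  # 50/50 point-mutant / amplified mixture: the two single-mutant fractions
  # dominate and MIXED stays at the noise floor
  st <- population_state(c(1, 4), c(1, 0), c(5e4, 5e4))
  ev2 <- withr::with_seed(12, sample_flow_events(st, a, p, 6000))
  fr2 <- label_frequencies(classify_events(ev2, ref, t))
  get <- function(l) fr2$frequency[fr2$label == l]
  expect_equal(get("YFP_PLUS"), 0.5, tolerance = 0.1)
  expect_equal(get("YFP_CFP_PLUS"), 0.5, tolerance = 0.1)
  expect_lt(get("MIXED"), 0.05)
  # pure combination mutants land in MIXED
  ev3 <- withr::with_seed(13, sample_flow_events(population_state(4, 1, 1e5),
                                                 a, p, 6000))
  fr3 <- label_frequencies(classify_events(ev3, ref, t))
  expect_gt(fr3$frequency[fr3$label == "MIXED"], 0.9)
})

test_that("combination detection respects the frequency floor", {
  a <- allele_params(); p <- reporter_params(); t <- thresholds()
  ref <- withr::with_seed(20, sample_flow_events(population_state(1, 0, 1e5),
                                                 a, p, 6000))
  pure <- withr::with_seed(21, sample_flow_events(population_state(1, 0, 1e5),
                                                  a, p, 6000))
  expect_false(detect_combination(pure, ref, t))
  spike5 <- population_state(c(1, 4), c(0, 1), c(9.5e4, 0.5e4))
  ev5 <- withr::with_seed(22, sample_flow_events(spike5, a, p, 6000))
  expect_true(detect_combination(ev5, ref, t))
  spike01 <- population_state(c(1, 4), c(0, 1), c(99900, 100))
  ev01 <- withr::with_seed(23, sample_flow_events(spike01, a, p, 6000))
  expect_false(detect_combination(ev01, ref, t))
})

test_that("fraction_table partitions replicates by day", {
  cfg <- low_demand_config(rates = mutation_rates(0, 0, 0), n_days = 2)
  ex <- run_experiment(cfg, 5, base_seed = 1)
  ft <- fraction_table(ex)
  expect_true(all(ft$n_replicates[ft$label == "ANCESTRAL"] == 5))
  totals <- ft |> dplyr::group_by(.data$day) |>
    dplyr::summarise(n = sum(.data$n_replicates))
  expect_true(all(totals$n == 5))
})
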