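test_that("day duration matches the closed form and a brute-force root", {
  pro <- serial_protocol(k_cap = 1e8)
  # single class at rate 0.7/h starting from K/820: T = ln(820)/0.7
  env <- env_params(demand = 4, r0 = 0.2, rmax = 0.7)
  a <- allele_params(1, 20)   # (1,1): E = 20 >= 4, k = 1 -> r = rmax = 0.7
  st <- population_state(1, 1, 1e8 / 820)
  expect_equal(solve_day_duration(st, env, a, pro), log(820) / 0.7,
               tolerance = 1e-9)
  # two classes: compare against an independent uniroot solve
  env2 <- env_params(demand = 10, r0 = 0.4, rmax = 1.0)
  a2 <- allele_params(beta_anc = 5 / 3, beta_mut = 10)
  st2 <- population_state(c(1, 1), c(0, 1), c(1e5, 1e2))
  r <- c(0.4 + 0.6 * (5 / 3) / 10, 1.0)  # 0.5 and 1.0 per hour
  t_oracle <- uniroot(function(t) 1e5 * exp(r[1] * t) + 1e2 * exp(r[2] * t) - 1e8,
                      c(0, 100), tol = 1e-12)$root
  expect_equal(solve_day_duration(st2, env2, a2, pro), t_oracle,
               tolerance = 1e-8)
})

test_that("day duration is zero when nothing can grow", {
  env <- env_params(demand = 1000, r0 = 0, rmax = 0.01, cost = 0.05)
  st <- population_state(10, 0, 1e4)
  expect_warning(
    t0 <- solve_day_duration(st, env, allele_params(), serial_protocol(k_cap = 1e6)),
    class = "dupdiv_unreachable_capacity"
  )
  expect_equal(t0, 0)
})

test_that("mutation flows conserve abundance and vanish at zero rates", {
  st <- population_state(c(1, 2, 4, 7), c(0, 1, 3, 2), c(1e5, 2e4, 3e3, 17))
  expect_equal(mutation_flows(st, mutation_rates(0, 0, 0), 1), st)
  withr::with_seed(42, {
    for (i in 1:20) {
      rates <- mutation_rates(mu_dup = runif(1, 0, 1e-2),
                              mu_step = runif(1, 0, 5e-2),
                              mu_pm = runif(1, 0, 1e-4))
      out <- mutation_flows(st, rates, generations = runif(1, 0, 2))
      expect_equal(sum(out$n), sum(st$n), tolerance = 1e-9)
      expect_true(all(out$n >= 0))
    }
  })
})

test_that("duplication flow matches its Poisson expectation", {
  rates <- mutation_rates(mu_dup = 1e-3, mu_step = 0, mu_pm = 0)
  st <- population_state(1, 0, 1e6)
  withr::with_seed(7, {
    flows <- vapply(1:400, function(i) {
      out <- mutation_flows(st, rates, 1)
      sum(out$n[out$k == 2])
    }, numeric(1))
  })
  # mean of 400 Poisson(1000) draws: SE = sqrt(1000/400)
  expect_lt(abs(mean(flows) - 1000), 3 * sqrt(1000 / 400))
})

test_that("deletion picks the mutant copy with probability m/k", {
  # from (4,1) the deleted copy is the mutant one 1/4 of the time -> (3,0)
  rates <- mutation_rates(mu_dup = 0, mu_step = 1e-2, mu_pm = 0)
  st <- population_state(4, 1, 1e6)
  out <- withr::with_seed(11, mutation_flows(st, rates, 1))
  del_30 <- sum(out$n[out$k == 3 & out$m == 0])
  del_31 <- sum(out$n[out$k == 3 & out$m == 1])
  n_del <- del_30 + del_31
  expect_gt(n_del, 10000)
  p_hat <- del_30 / n_del
  expect_lt(abs(p_hat - 0.25), 3 * sqrt(0.25 * 0.75 / n_del))
  # duplication from (1,1) lands only in (2,2)
  out2 <- withr::with_seed(12, mutation_flows(population_state(1, 1, 1e6),
                                              mutation_rates(1e-2, 0, 0), 1))
  expect_setequal(paste(out2$k, out2$m), c("1 1", "2 2"))
})

test_that("tau-leap validity is enforced", {
  st <- population_state(5, 0, 1e4)
  expect_error(mutation_flows(st, mutation_rates(0, 0.3, 0), generations = 1),
               "invalid-rate")
})

test_that("grow_day reaches capacity and selection shifts frequencies", {
  cfg <- low_demand_config(rates = mutation_rates(0, 0, 0))
  st <- population_state(c(1, 4), c(0, 0), c(1e3, 10))
  out <- grow_day(st, cfg)
  expect_equal(sum(out$n), cfg$protocol$k_cap, tolerance = 1e-6)
  f0 <- 10 / 1010
  f1 <- out$n[out$k == 4] / sum(out$n)
  expect_gt(f1, f0)  # the fitter 4-copy class gains
  # neutrality: equal rates leave frequencies untouched
  env_flat <- env_params(demand = 0.5, r0 = 0.2, rmax = 0.9, cost = 0)
  cfg2 <- sim_config(env = env_flat, rates = mutation_rates(0, 0, 0),
                     protocol = test_protocol())
  st2 <- population_state(c(1, 1), c(0, 1), c(7e2, 3e2))  # both at plateau, k = 1
  out2 <- grow_day(st2, cfg2)
  expect_equal(out2$n / sum(out2$n), c(0.7, 0.3), tolerance = 1e-12)
})

test_that("bottleneck samples the right number of cells", {
  pro <- serial_protocol(k_cap = 1e8)
  st <- population_state(1, 0, 8.2e7)
  out <- withr::with_seed(1, bottleneck(st, pro))
  expect_equal(out$n, 1e5)  # deterministic single-class multinomial
  # binomial expectation for a 1% class
  st2 <- population_state(c(1, 4), c(0, 0), c(8.2e7 * 0.99, 8.2e7 * 0.01))
  withr::with_seed(2, {
    draws <- vapply(1:200, function(i) {
      b <- bottleneck(st2, pro)
      sum(b$n[b$k == 4])
    }, numeric(1))
  })
  expect_lt(abs(mean(draws) - 1000), 3 * sqrt(1000 * 0.99 / 200))
  expect_error(bottleneck(population_state(1, 0, 300), serial_protocol(k_cap = 1e6)),
               "extinct")
})

test_that("replicates are reproducible and ancestral without mutation", {
  cfg <- low_demand_config(rates = mutation_rates(0, 0, 0), n_days = 4)
  tr <- run_replicate(cfg, seed = 3)
  expect_equal(nrow(tr), 5)           # day 0..4, one pure class per day
  expect_true(all(tr$k == 1 & tr$m == 0))
  cfg2 <- low_demand_config(n_days = 4)
  expect_identical(
    tibble::as_tibble(run_replicate(cfg2, seed = 9)),
    tibble::as_tibble(run_replicate(cfg2, seed = 9))
  )
})

test_that("deterministic trajectory is the exact mean-field recursion", {
  cfg0 <- low_demand_config(rates = mutation_rates(0, 0, 0), n_days = 6)
  det <- deterministic_trajectory(cfg0)
  expect_true(all(det$frequency == 1))  # zero rates: constant composition
  # two-type selection: day-over-day frequency follows p' = p w / (p w + 1 - p)
  # with w = exp((r1 - r0) T) and T the solved day length
  cfg <- low_demand_config(n_days = 1)
  a <- cfg$alleles; env <- cfg$env
  st <- population_state(c(1, 4), c(0, 0), c(9e2, 1e2))
  out <- grow_day(st, sim_config(alleles = a, env = env,
                                 rates = mutation_rates(0, 0, 0),
                                 protocol = cfg$protocol),
                  deterministic = TRUE)
  t_day <- attr(out, "hours")
  r <- growth_rate_of(genotype(c(1, 4), c(0, 0)), env, a)$growth_rate
  w <- exp((r[2] - r[1]) * t_day)
  p <- 0.1
  expect_equal(out$n[out$k == 4] / sum(out$n), p * w / (p * w + 1 - p),
               tolerance = 1e-9)
})

test_that("stochastic means track the deterministic oracle when supply is large", {
  # copy-number-only flows (supply ~ 1e3/day) over a short horizon where
  # mean-field and finite-N agree well; full-horizon agreement at the stated
  # tolerance is exercised by the acceptance suite
  cfg <- sim_config(env = demand_preset("low"),
                    rates = mutation_rates(1e-3, 1e-2, 0),
                    protocol = test_protocol(n_days = 1))
  det <- deterministic_trajectory(cfg)
  ex <- run_experiment(cfg, 100, base_seed = 5)
  mean_f <- class_frequencies(ex) |>
    dplyr::filter(.data$day == 1) |>
    dplyr::group_by(.data$k, .data$m) |>
    dplyr::summarise(freq = sum(.data$frequency) / 100, .groups = "drop")
  cmp <- dplyr::full_join(mean_f,
                          det[det$day == 1, c("k", "m", "frequency")],
                          by = c("k", "m")) |>
    dplyr::mutate(dev = abs(dplyr::coalesce(.data$freq, 0) -
                              dplyr::coalesce(.data$frequency, 0)))
  expect_lt(max(cmp$dev), 0.01)
})

test_that("amplification dominates low demand; combinations need high demand", {
  gl <- glance(run_experiment(low_demand_config(), 12, base_seed = 1))
  gh <- glance(run_experiment(high_demand_config(), 12, base_seed = 1))
  expect_gte(sum(gl$amplified_freq > 0.5), 10)    # amplification sweeps
  expect_true(all(gl$combination_freq < 0.05))     # combinations stay rare
  expect_gte(sum(gh$combination_freq >= 0.01),
             sum(gl$combination_freq >= 0.01))     # demand direction
})
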