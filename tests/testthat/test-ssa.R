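test_that("reaction systems recover the ODE right-hand sides in the mean field", {
  set.seed(5)
  for (i in 1:50) {
    p <- random_conjugate_params(feasible = FALSE)
    sys <- build_reactions(p = p, mu = 1e-6)
    st <- round(unclass(random_state()))
    mean_field <- drop(sys$stoichiometry %*% propensities(sys, st))
    expect_equal(mean_field[c("E", "T", "C")], rhs_conjugate(st, p),
                 tolerance = 1e-12, ignore_attr = "names")

    pr <- random_reduced_params(feasible = FALSE)
    sysr <- build_reactions(p = pr, mu = 1e-6)
    st2 <- round(unclass(random_state(with_C = FALSE)))
    mf2 <- drop(sysr$stoichiometry %*% propensities(sysr, st2))
    expect_equal(mf2[c("E", "T")], rhs_reduced(st2, pr),
                 tolerance = 1e-12, ignore_attr = "names")
  }
})

test_that("reaction systems have the documented sizes and zero-state propensities", {
  p <- fig4a_params()
  sys <- build_reactions(p = p)
  expect_equal(nrow(sys$reactions), 6)
  sys_mu <- build_reactions(p = p, mu = 1e-6)
  expect_equal(nrow(sys_mu$reactions), 7)
  expect_true(all(propensities(sys_mu, c(E = 0, T = 0, C = 0)) == 0))

  pr <- fig6a_params()
  sysr <- build_reactions(p = pr)
  expect_equal(nrow(sysr$reactions), 5)
  expect_true(all(propensities(sysr, c(E = 0, T = 0)) == 0))

  expect_error(build_reactions("both", p), "unknown model tag")
  expect_error(build_reactions("reduced", p), "does not match")
})

test_that("mapped conjugate rates equal the printed reduced rates after rounding", {
  pr <- reduce_params(conjugate_params(0.05, 0.15, 0.1, 0.2, 0.4, 0.05))
  expect_equal(round(pr$beta1, 2), 0.18)
  expect_equal(round(pr$beta2, 2), 0.02)
})

test_that("degenerate starts terminate with the right outcome", {
  pr <- fig6a_params()
  res <- simulate_ssa(pr, system_state(E = 5, T = 0, discrete = TRUE),
                      ssa_config(seed = 1))
  expect_identical(res$outcome, "extinct")
  expect_equal(res$extinction_time, 0)

  # conjugate model is not extinct while a conjugate persists
  p <- fig4a_params()
  res_c <- simulate_ssa(build_reactions(p = p),
                        system_state(E = 0, T = 0, C = 1, discrete = TRUE),
                        ssa_config(t_max = 5000, mu = 0, seed = 2))
  expect_identical(res_c$outcome, "extinct")
  expect_gt(res_c$extinction_time, 0)

  # tiny horizon relative to the event scale: censored
  res_t <- simulate_ssa(pr, system_state(E = 50, T = 100, discrete = TRUE),
                        ssa_config(t_max = 1e-6, mu = 0, seed = 3))
  expect_identical(res_t$outcome, "censored")
  expect_equal(res_t$end_time, 1e-6)

  expect_error(
    simulate_ssa(pr, c(E = 1.5, T = 2), ssa_config(seed = 1)),
    "integer")
})

test_that("identical seeds give bitwise-identical runs, different seeds differ", {
  pr <- fig6a_params()
  init <- system_state(E = 50, T = 100, discrete = TRUE)
  cfg <- ssa_config(t_max = 2000, seed = 42, record_mode = "full")
  r1 <- simulate_ssa(pr, init, cfg)
  r2 <- simulate_ssa(pr, init, cfg)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$extinction_time, r2$extinction_time)
  r3 <- simulate_ssa(pr, init, ssa_config(t_max = 2000, seed = 43))
  expect_false(identical(r1$extinction_time, r3$extinction_time))
})

test_that("stoichiometric bookkeeping holds along full event logs", {
  # E + C + Ed changes only via influx (+1) and effector death (-1);
  # T + C + Td changes only via tumor division (+1)
  p <- fig4a_params()
  res <- simulate_ssa(build_reactions(p = p),
                      system_state(E = 30, T = 50, C = 0, discrete = TRUE),
                      ssa_config(t_max = 3000, mu = 0, seed = 7,
                                 record_mode = "full"))
  log <- res$log
  expect_gt(nrow(log), 100)
  expect_true(all(log[c("E", "T", "C", "Ed", "Td")] >= 0))

  d_eff <- diff(log$E + log$C + log$Ed)
  d_tum <- diff(log$T + log$C + log$Td)
  rxn <- log$reaction[-1]
  expect_true(all(d_eff[rxn == "effector_influx"] == 1))
  expect_true(all(d_eff[rxn == "effector_death"] == -1))
  expect_true(all(d_eff[!rxn %in% c("effector_influx", "effector_death")] == 0))
  expect_true(all(d_tum[rxn == "tumor_division"] == 1))
  expect_true(all(d_tum[rxn != "tumor_division"] == 0))
})

test_that("waiting times of a constant-propensity reaction are exponential", {
  # freeze every channel except the tumor-driven effector influx: with
  # d = r = beta1 = beta2 = 0 the tumor count stays at T0 and events arrive
  # as a Poisson process with rate s*T0
  p <- reduced_params(s = 0.01, r = 0, d = 0, beta1 = 0, beta2 = 0)
  T0 <- 100           # rate a = 1 per day
  res <- simulate_ssa(build_reactions(p = p),
                      system_state(E = 0, T = T0, discrete = TRUE),
                      ssa_config(t_max = 1e9, mu = 0, seed = 11,
                                 record_mode = "full", max_events = 1e4))
  waits <- diff(res$log$time)   # includes the t = 0 anchor row
  expect_equal(length(waits), 1e4)
  ks <- stats::ks.test(waits, "pexp", rate = p$s * T0)
  expect_gt(ks$p.value, 0.01)
})

test_that("scaled-population ensemble means match the ODE (mean-field check)", {
  # 100x the Fig 6a populations with matching volume; densities unchanged
  v <- 100
  pr <- fig6a_params()
  init <- system_state(E = 5000, T = 10000, discrete = TRUE)
  sys <- build_reactions(p = pr, v = v)
  t_obs <- 10
  n <- 200
  finals <- purrr::map(seq_len(n), function(i) {
    res <- simulate_ssa(sys, init, ssa_config(t_max = t_obs, mu = 0,
                                              seed = 100 + i))
    res$final_state[c("E", "T")]
  })
  m <- do.call(rbind, finals)
  se <- apply(m, 2, stats::sd) / sqrt(n)

  # ODE oracle: bimolecular rates scale as beta/v in the mean field
  p_ode <- reduced_params(pr$s, pr$r, pr$d, pr$beta1 / v, pr$beta2 / v)
  tr <- integrate_model(p_ode, system_state(E = 5000, T = 10000),
                        t_max = t_obs, dt = t_obs)
  ode_end <- unlist(dplyr::slice_tail(tr, n = 1)[c("E", "T")])
  expect_lt(abs(mean(m[, "E"]) - ode_end[["E"]]), 3 * se[["E"]])
  expect_lt(abs(mean(m[, "T"]) - ode_end[["T"]]), 3 * se[["T"]])
})

test_that("ensembles are reproducible, seed-indexed, and order-invariant", {
  pr <- fig6a_params()
  init <- system_state(E = 50, T = 100, discrete = TRUE)
  cfg <- ssa_config(t_max = 5000)
  e1 <- run_ensemble(pr, init, cfg, n_reps = 20, seed_base = 100)
  e2 <- run_ensemble(pr, init, cfg, n_reps = 20, seed_base = 100)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(e1$seed, 100:119)

  # n_reps = 1 reduces to a single run with the same seed
  single <- simulate_ssa(pr, init, ssa_config(t_max = 5000, seed = 100))
  expect_equal(e1$extinction_time[1], single$extinction_time)

  # summaries are invariant under replicate reordering
  shuffled <- e1[sample(nrow(e1)), ]
  expect_equal(summarize_ensemble(shuffled), summarize_ensemble(e1))
})

test_that("conjugate binding speeds extinction relative to the matched reduced model", {
  # matched rate pairs: gamma=0.02 maps to (beta1, beta2) ~ (0.018, 0.002)
  init <- system_state(E = 30, T = 50, discrete = TRUE)
  cfg <- ssa_config(t_max = 50000)
  e_conj <- run_ensemble(build_reactions(p = fig4a_params()), init, cfg,
                         n_reps = 100, seed_base = 1)
  e_red <- run_ensemble(reduced_params(0.05, 0.15, 0.1, 0.018, 0.002), init,
                        cfg, n_reps = 100, seed_base = 1)
  s_conj <- summarize_ensemble(e_conj)
  s_red <- summarize_ensemble(e_red)
  expect_lt(s_conj$median_time, s_red$median_time)
})

test_that("per-cell mutation mode fires escapes at the expected rate", {
  # with no other reactions possible and T frozen, escapes arrive at mu*T
  p <- reduced_params(s = 0, r = 0, d = 0, beta1 = 0, beta2 = 0)
  init <- system_state(E = 0, T = 100, discrete = TRUE)
  times <- vapply(1:200, function(i) {
    res <- simulate_ssa(build_reactions(p = p, mu = 1e-3), init,
                        ssa_config(t_max = 1e9, mu = 1e-3,
                                   mutation_mode = "per_cell", seed = i))
    expect_identical(res$outcome, "escaped")
    res$end_time
  }, numeric(1))
  # mean waiting time 1/(mu*T) = 10 days
  expect_lt(abs(mean(times) - 10), 3 * 10 / sqrt(200))
})
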