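# Gillespie engine: direct-method reference path, osmotic rebalance,
# reproducibility, SSA-ODE consistency, hybrid accelerator.

test_that("direct method draws follow the exponential law", {
  reg <- fx_registry()
  # isolate a single active channel: dimer dissociation only
  p <- kinetic_parameters(P_P = 0, P_NTP = 0, k_in = 0, k_out = 0,
                          k_RatS = 0, k_NTP = 0, k_L = 0, k_SS = 0)
  set.seed(21)
  net <- build_reaction_network(reg, p)
  env <- environment_spec(conc_P_ex = 0, conc_N_ex = 0, conc_I_ex = 0.3,
                          conc_L_ex = 0, params = p)
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L.cR_L = 1000))
  a0 <- 1000 * 2.2e-6
  set.seed(99)
  taus <- replicate(5000, direct_method_step(net, st, env)$tau)
  se <- (1 / a0) / sqrt(5000)
  expect_lt(abs(mean(taus) - 1 / a0), 3 * se)

  # two active channels with 3:1 propensities pick channels 3:1
  st2 <- st
  st2$counts[["R_L.cR_L"]] <- 300
  st2$counts[["R_P.cR_P"]] <- 100
  set.seed(7)
  js <- replicate(4000, direct_method_step(net, st2, env)$channel)
  nm <- net$channels$name[js]
  f <- mean(nm == "dissoc:R_L.cR_L")
  expect_lt(abs(f - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
})

test_that("events rebalance the volume through the osmotic identity", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  set.seed(13)
  st <- make_initial_state(reg, env, N_0 = 5, r_0 = 50,
                           extra_counts = c(R_P = 2, R_L = 2))
  st$counts <- round(st$counts)
  st$V_C <- osmotic_volume(st$counts, env$C_T_E, reg)
  NAv <- 6.02214e23
  for (k in 1:300) {
    step <- direct_method_step(net, st, env)
    st2 <- apply_event_and_rebalance(st, net, step$channel, env)
    # identity holds exactly after every event
    tot <- sum(st2$counts[reg$species$osmotic])
    expect_equal(tot, NAv * env$C_T_E * st2$V_C, tolerance = 1e-12)
    # the volume change per unit count change is 1/(N_A C_T_E)
    dtot <- tot - sum(st$counts[reg$species$osmotic])
    expect_equal(st2$V_C - st$V_C, dtot / (NAv * env$C_T_E),
                 tolerance = 1e-9)
    expect_true(all(st2$counts >= 0))
    st <- st2
  }
})

test_that("an event that would drive a count negative is an error", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50)
  j <- which(net$channels$name == "dissoc:R_P.cR_P")
  expect_error(apply_event_and_rebalance(st, net, j, env), "negative")
})

test_that("a fixed seed reproduces a stochastic episode exactly", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 1, r_0 = 50)
  run_once <- function(accel, days) {
    set.seed(4242)
    simulate_vesicle(st, net, env,
                     opts = ssa_options(acceleration = accel),
                     t_max_days = days)
  }
  for (accel in c("hybrid", "exact")) {
    days <- if (accel == "hybrid") 30 else 0.001
    a <- run_once(accel, days); b <- run_once(accel, days)
    expect_identical(a$fate, b$fate)
    expect_identical(a$t, b$t)
    expect_identical(a$state$counts, b$state$counts)
  }
})

test_that("zero-genome vesicle stays quiescent (phi ~ 1) until timeout", {
  reg <- fx_registry()
  net <- fx_network()
  # no substrate gradients: nothing can move
  env <- environment_spec(conc_P_ex = 0, conc_N_ex = 0, conc_I_ex = 0.35,
                          conc_L_ex = 0)
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50)
  set.seed(3)
  res <- simulate_vesicle(st, net, env, t_max_days = 50)
  expect_identical(res$fate, "timeout")
  S <- membrane_surface(res$state$counts[["L_mem"]])
  expect_equal(reduced_surface(S, res$state$V_C), 1, tolerance = 5e-3)
})

test_that("SSA mean trajectory matches the ODE for the lipid subsystem", {
  reg <- fx_registry()
  # membrane exchange off: the synthesised lipid accumulates in the aqueous
  # pool, giving a churn-free readout of the precursor -> lipid flux
  p <- kinetic_parameters(P_NTP = 0, k_in = 0, k_out = 0)
  set.seed(55)
  net <- build_reaction_network(reg, p)
  env <- environment_spec(conc_N_ex = 0, conc_L_ex = 0, params = p)
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L = 1000))
  t_end <- 2000
  det <- integrate_generation(st, net, env,
                              opts = det_options(t_cap_days = t_end / 86400,
                                                rtol = 1e-9, atol = 1e-4))
  target <- det$state$counts[["L_aq"]]
  expect_gt(target, 2000) # enough signal
  set.seed(202)
  la <- replicate(10, {
    r <- simulate_vesicle(st, net, env,
                          opts = ssa_options(acceleration = "exact"),
                          t_max_days = t_end / 86400)
    r$state$counts[["L_aq"]]
  })
  expect_equal(mean(la), target, tolerance = 0.02)
})

test_that("hybrid and exact engines agree on the same subsystem", {
  reg <- fx_registry()
  p <- kinetic_parameters(P_NTP = 0, k_in = 0, k_out = 0)
  set.seed(55)
  net <- build_reaction_network(reg, p)
  env <- environment_spec(conc_N_ex = 0, conc_L_ex = 0, params = p)
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L = 1000))
  t_days <- 2000 / 86400
  set.seed(303)
  ex <- replicate(10, simulate_vesicle(st, net, env,
          opts = ssa_options(acceleration = "exact"),
          t_max_days = t_days)$state$counts[["L_aq"]])
  set.seed(304)
  hy <- replicate(10, simulate_vesicle(st, net, env,
          opts = ssa_options(acceleration = "hybrid"),
          t_max_days = t_days)$state$counts[["L_aq"]])
  expect_equal(mean(hy), mean(ex), tolerance = 0.02)
})

test_that("hybrid with an infinite threshold reduces to the exact engine", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 1, r_0 = 50)
  set.seed(17)
  inf_thr <- simulate_vesicle(st, net, env,
    opts = ssa_options(acceleration = "hybrid", hybrid_threshold = Inf),
    t_max_days = 2e-4)
  expect_identical(unname(inf_thr$steps["leap"]) > 0, TRUE)
  # every "leap" fired at the hazard times; no channel was Poisson-leapt,
  # so all counts stay integral and the osmotic identity is exact
  expect_true(all(inf_thr$state$counts == round(inf_thr$state$counts)))
  set.seed(17)
  ex <- simulate_vesicle(st, net, env,
    opts = ssa_options(acceleration = "exact"), t_max_days = 2e-4)
  expect_equal(sum(inf_thr$state$counts), sum(ex$state$counts),
               tolerance = 0.02)
})

test_that("membrane growth of a self-producing vesicle equals synthesis", {
  # every synthesised lipid must end up in the membrane (hybrid QSS route):
  # membrane gain = precursor consumed via synthesis
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L = 1))
  set.seed(23)
  res <- simulate_vesicle(st, net, env, t_max_days = 0.04)
  n0 <- round(st$counts); n1 <- res$state$counts
  gain <- n1[["L_mem"]] - n0[["L_mem"]]
  expect_gt(gain, 100)
  p_in_minus_out <- (n1[["P"]] + n1[["L_aq"]] + gain) - n0[["P"]]
  # P entered through the membrane must account for P standing + lipid made
  expect_gt(p_in_minus_out, 0)
})

test_that("SSA division partitions binomially and returns twin daughters", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 30,
                           extra_counts = c(R_L = 1, W = 4000))
  set.seed(29)
  res <- simulate_vesicle(st, net, env, t_max_days = 5)
  expect_identical(res$fate, "divide")
  d <- res$daughters
  expect_length(d, 2)
  tot <- d[[1]]$counts + d[[2]]$counts
  expect_equal(unname(tot[["L_mem"]]),
               unname(res$state$counts[["L_mem"]]))
  expect_equal(unname(tot[["W"]]), unname(round(res$state$counts[["W"]])))
  for (dd in d) {
    S <- membrane_surface(dd$counts[["L_mem"]])
    expect_equal(reduced_surface(S, dd$V_C), 1, tolerance = 0.05)
  }
})
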