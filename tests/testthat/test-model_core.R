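# Species registry and reaction network construction; rate laws.

test_that("species registry enumerates the full Ribocell species set", {
  reg <- fx_registry()
  # 4 monomers + 2 dimers + 4*(100+1) complexes + 4 NTP + W + P + L_aq + B
  # + membrane lipid
  expect_identical(reg$n_species, 4L + 2L + 4L * 101L + 4L + 5L)
  expect_identical(sum(reg$species$osmotic), reg$n_species - 1L)
  expect_identical(
    reg$species$id[!reg$species$osmotic], "L_mem")

  reg20 <- build_species_registry(20, 20)
  expect_identical(sum(reg20$species$role == "rna_complex"), 4L * 21L)

  expect_error(build_species_registry(19, 100), "20")
  expect_error(build_species_registry(100, 10), "20")
})

test_that("reaction network has the expected channel structure", {
  net <- fx_network()
  # 4 dimerisation (2 fwd + 2 rev) + 4 initiation + 4*100 elongation
  # + 4 release + 1 lipid synthesis
  expect_identical(net$n_internal, 413L)
  ch <- net$channels
  expect_identical(sum(ch$kind == "reaction"), 413L)
  # P and 4 NTP pools get influx/efflux; W, B, RNA get none
  expect_identical(sum(ch$kind == "influx"), 5L)
  expect_identical(sum(ch$kind == "efflux"), 5L)
  expect_false(any(grepl("W|^influx:B", ch$name[ch$kind != "reaction"])))
  # the self-template initiation R_P + R_P is the single homo channel
  expect_identical(ch$name[which(ch$homo)], "init:R_P")
})

test_that("strand content is conserved by every channel except completion", {
  net <- fx_network()
  reg <- fx_registry()
  ds <- t(vapply(net$stoich, function(s)
    colSums(reg$strands[s$idx, , drop = FALSE] * s$del), numeric(4)))
  net_change <- rowSums(ds)
  completing <- grepl("^elong:(R_P|cR_P|R_L|cR_L)_100$", net$channels$name)
  # the final elongation step creates exactly one complementary strand
  expect_true(all(net_change[completing] == 1))
  expect_true(all(ds[completing, ] %in% c(0, 1)))
  expect_true(all(net_change[!completing] == 0))
  # release hands the duplex over intact: e.g. RP@cR_L_100 -> R_P + R_L.cR_L
  j <- which(net$channels$name == "release:cR_L")
  prod <- net$stoich[[j]]
  expect_setequal(reg$species$id[prod$idx[prod$del > 0]],
                  c("R_P", "R_L.cR_L"))
})

test_that("elongation consumes one NTP and produces one W per step", {
  net <- fx_network()
  reg <- fx_registry()
  el <- grep("^elong:", net$channels$name)
  for (j in el[c(1, 57, 200, 400)]) {
    s <- net$stoich[[j]]
    ids <- reg$species$id[s$idx]
    expect_identical(sum(s$del[grepl("^NTP_", ids)]), -1)
    expect_identical(sum(s$del[ids == "W"]), 1)
    expect_identical(sum(s$del), 0) # complex ladder moves, total conserved
  }
})

test_that("lipid synthesis conserves the catalyst", {
  net <- fx_network()
  reg <- fx_registry()
  j <- which(net$channels$name == "synth:lipid")
  s <- net$stoich[[j]]
  expect_false(reg$idx$monomers[["R_L"]] %in% s$idx)
  expect_identical(setNames(s$del, reg$species$id[s$idx]),
                   c(P = -1, L_aq = 1))
})

test_that("propensities match hand-computed oracles", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L = 1, cR_L = 1,
                                            R_L.cR_L = 3))
  a <- propensities(net, st, env)
  # bimolecular k_SS = 8.8e6 /M/s in V = 5.236e-19 L with n1 = n2 = 1:
  # a = k/(V*N_A) = 27.9 /s
  expect_equal(a[["assoc:R_L.cR_L"]],
               8.8e6 / (st$V_C * 6.02214e23), tolerance = 1e-12)
  expect_equal(a[["assoc:R_L.cR_L"]], 27.9, tolerance = 1e-3)
  # unimolecular: 3 dimers dissociating at k_S
  expect_equal(a[["dissoc:R_L.cR_L"]], 3 * 2.2e-6)
  # NTP influx through a 50 nm sphere at 1e-2 M: ~3.6e-2 /s
  expect_equal(a[["influx:NTP_1"]], 3.594e-2, tolerance = 1e-3)
  # lipid release: k_out * n_L_mu ~ 1.59e4 /s
  expect_equal(a[["lipid:release_int"]],
               7.6e-2 * st$counts[["L_mem"]])
  expect_equal(a[["lipid:release_int"]], 1.59e4, tolerance = 1e-2)
})

test_that("deterministic rates and propensities agree at large counts", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 1000, r_0 = 50,
                           extra_counts = c(R_P = 500, cR_P = 400,
                                            NTP_1 = 2000, P = 1500))
  a <- propensities(net, st, env)                       # events/s
  r <- deterministic_rate(net, st, env)                  # M/s
  i <- which(net$channels$kind == "reaction")
  conv <- r * st$V_C * 6.02214e23                        # -> events/s
  big <- a[i] > 1e-6
  expect_equal(unname(conv[big]), unname(a[i][big]), tolerance = 3e-3)
})

test_that("homo-bimolecular self-template initiation uses ordered pairs", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_P = 4))
  a <- propensities(net, st, env)
  VN <- st$V_C * 6.02214e23
  expect_equal(a[["init:R_P"]], 5.32e5 / VN * 4 * 3)   # n(n-1)
  r <- deterministic_rate(net, st, env)
  expect_equal(r[["init:R_P"]] * VN, 5.32e5 / VN * 4 * 4) # mass action n^2
})

test_that("compiled propensities equal the R reference implementation", {
  reg <- fx_registry()
  net <- fx_network()
  env <- fx_env_opt()
  set.seed(5)
  st <- make_initial_state(reg, env, N_0 = 7, r_0 = 50,
                           extra_counts = c(R_P = 3, R_L = 2, NTP_2 = 40,
                                            P = 11, L_aq = 9, W = 123))
  aR <- propensities(net, st, env)
  xptr <- ribocell:::.compile_network(net, env, geometry_params(),
                                      physical_constants())
  aC <- ribocell:::rc_propensities(xptr, st$counts, st$V_C, TRUE)
  expect_equal(unname(aR), as.numeric(aC), tolerance = 1e-12)
})

test_that("lipid exchange equilibrium matches the closed-form balance", {
  expect_equal(lipid_exchange_equilibrium(), 6.667e-5, tolerance = 1e-3)
  # balance: k_in * S_mu * [L] = k_out * n_L with S_mu = alpha_L n_L / 2
  p <- kinetic_parameters()
  nL <- 2.094e5
  S <- membrane_surface(nL)
  Leq <- lipid_exchange_equilibrium()
  expect_equal(p$k_in * S * Leq, p$k_out * nL, tolerance = 1e-3)
})

test_that("dimerisation-only subsystem reaches detailed balance", {
  # closed reactor, no transport/water/lipid flux; test-scale constants so
  # that equilibrium free-monomer counts are resolvable
  p <- kinetic_parameters(k_SS = 1e6, k_S = 10, P_P = 0, P_NTP = 0,
                          k_in = 0, k_out = 0, P_aq = 0, k_RatS = 0,
                          k_NTP = 0, k_L = 0)
  set.seed(9)
  reg <- fx_registry()
  net <- build_reaction_network(reg, p)
  env <- environment_spec(conc_P_ex = 0, conc_N_ex = 0, conc_I_ex = 0.3,
                          conc_L_ex = 0, params = p)
  st <- make_initial_state(reg, env, N_0 = 0, r_0 = 50,
                           extra_counts = c(R_L = 5000, cR_L = 4000))
  res <- integrate_generation(st, net, env,
                              opts = det_options(t_cap_days = 0.5,
                                                rtol = 1e-9, atol = 1e-6))
  n <- res$state$counts
  VN <- res$state$V_C * 6.02214e23
  K_obs <- (n[["R_L.cR_L"]] / VN) / ((n[["R_L"]] / VN) * (n[["cR_L"]] / VN))
  expect_equal(unname(K_obs), 1e6 / 10, tolerance = 1e-3)
})

test_that("network JSON dump round-trips the channel structure", {
  net <- fx_network()
  f <- tempfile(fileext = ".json")
  network_to_json(net, f)
  j <- jsonlite::read_json(f, simplifyVector = FALSE)
  expect_length(j$channels, net$n_channels)
  expect_length(j$species, fx_registry()$n_species)
  expect_identical(j$channels[[1]]$name, net$channels$name[1])
  unlink(f)
})
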