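# Shared fixtures, built lazily and cached for the whole test session.
# The 100-nt network is deterministic given the seed used for the random
# template sequences; long lineage runs are computed once and reused.

.fx <- new.env(parent = emptyenv())

fx_registry <- function() {
  if (is.null(.fx$reg)) .fx$reg <- build_species_registry(100, 100)
  .fx$reg
}

fx_network <- function() {
  if (is.null(.fx$net)) {
    set.seed(1203)
    .fx$net <- build_reaction_network(fx_registry())
  }
  .fx$net
}

fx_env_opt <- function() environment_spec()  # optimal external conditions

# the 20-generation deterministic lineage at the optimal conditions
fx_lineage_opt <- function() {
  if (is.null(.fx$lin_opt)) {
    st <- make_initial_state(fx_registry(), fx_env_opt(), N_0 = 100, r_0 = 50)
    .fx$lin_opt <- run_lineage(st, fx_network(), fx_env_opt(),
                               n_generations = 20)
  }
  .fx$lin_opt
}

# the 20-generation lineage at the low-substrate scan conditions
# ([P_ex] = [N_ex] = 5e-4 M), where replication is nucleotide-limited
fx_lineage_lowsub <- function() {
  if (is.null(.fx$lin_low)) {
    env <- environment_spec(conc_P_ex = 5e-4, conc_N_ex = 5e-4,
                            conc_I_ex = 0.3)
    st <- make_initial_state(fx_registry(), env, N_0 = 100, r_0 = 50)
    .fx$lin_low <- run_lineage(st, fx_network(), env, n_generations = 20,
                               keep_trajectory = FALSE,
                               opts = det_options(t_cap_days = 5000))
  }
  .fx$lin_low
}

# stationary daughter radius (nm) of the optimal-conditions lineage
fx_rho_stationary <- function() {
  tail(fx_lineage_opt()$stats$rho_nm, 1)
}

# a small network with transport and lipid exchange switched off (closed
# reactor), used for conservation and equilibrium tests
fx_closed_network <- function(params = kinetic_parameters(
                                P_P = 0, P_NTP = 0, k_in = 0, k_out = 0)) {
  set.seed(77)
  build_reaction_network(fx_registry(), params)
}
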