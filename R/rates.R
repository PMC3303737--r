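# Channel rate laws (R reference implementation; the compiled engine in
# src/ribocell.cpp evaluates the same formulas).
#
# Per-channel stochastic propensity (events/s), with VN = V_C * N_A:
#   reaction, M=1:   k * n1
#   reaction, M=2:   k / VN * n1 * n2     (n1 * (n1 - 1) if homo-bimolecular)
#   influx:          P_dm * S_mu * N_A * C_ex
#   efflux:          P_dm * S_mu * n / V_C
#   lipid uptake:    k_in * S_mu * [L]      ([L] internal or external)
#   lipid release:   k_out * n_L_mu         (towards each solution)
# The deterministic rates are identical except that the homo-bimolecular
# channel uses n^2 (mass action).

.channel_values <- function(network, counts, V_C, env,
                            geom = geometry_params(),
                            consts = physical_constants(),
                            stochastic = TRUE) {
  ch <- network$channels
  reg <- network$registry
  n <- pmax(counts, 0)
  VN <- V_C * consts$N_A
  S <- membrane_surface(n[reg$idx$Lmem], geom$alpha_L)
  cx <- setNames(numeric(reg$n_species), reg$species$id)
  cx[reg$idx$P] <- env$conc_P_ex
  cx[reg$idx$ntp] <- env$conc_N_ex
  cx[reg$idx$B] <- env$conc_I_ex
  a <- numeric(nrow(ch))
  for (j in seq_along(a)) {
    a[j] <- switch(ch$kind[j],
      reaction = if (ch$M[j] == 1L) ch$k[j] * n[ch$r1[j]] else {
        x1 <- n[ch$r1[j]]
        x2 <- if (ch$homo[j]) (if (stochastic) max(x1 - 1, 0) else x1)
              else n[ch$r2[j]]
        ch$k[j] / VN * x1 * x2
      },
      influx = ch$k[j] * S * consts$N_A * cx[ch$species[j]],
      efflux = ch$k[j] * S * n[ch$species[j]] / V_C,
      uptake_int = ch$k[j] * S * n[reg$idx$Laq] / VN,
      uptake_ext = ch$k[j] * S * env$conc_L_ex,
      release_int = ch$k[j] * n[reg$idx$Lmem],
      release_ext = ch$k[j] * n[reg$idx$Lmem])
  }
  names(a) <- ch$name
  a
}

#' Stochastic propensities of every channel
#'
#' Event probability densities (events/s) for the Gillespie algorithm, for
#' all reaction and transport channels of the network, evaluated at a
#' vesicle state. Counts must be non-negative; integer counts are expected
#' in stochastic use.
#'
#' @param network [build_reaction_network()].
#' @param state [vesicle_state()] (\code{V_C > 0}).
#' @param env [environment_spec()].
#' @param geom,consts model parameters.
#' @return Named vector of propensities, events/s.
#' @export
propensities <- function(network, state, env = environment_spec(),
                         geom = geometry_params(),
                         consts = physical_constants()) {
  if (!isTRUE(state$V_C > 0)) stop("V_C must be > 0")
  if (any(state$counts < 0)) stop("negative species count")
  .channel_values(network, state$counts, state$V_C, env, geom, consts,
                  stochastic = TRUE)
}

#' Deterministic mass-action rates of the internal reactions
#'
#' Concentration change rates in M/s for every internal reaction channel,
#' using concentrations \code{n_j / (V_C N_A)}.
#'
#' @inheritParams propensities
#' @return Named vector over internal reaction channels, M/s.
#' @export
deterministic_rate <- function(network, state, env = environment_spec(),
                               geom = geometry_params(),
                               consts = physical_constants()) {
  if (!isTRUE(state$V_C > 0)) stop("V_C must be > 0")
  v <- .channel_values(network, state$counts, state$V_C, env, geom, consts,
                       stochastic = FALSE)
  i <- which(network$channels$kind == "reaction")
  v[i] / (state$V_C * consts$N_A)
}

#' Transport channel propensities
#'
#' The membrane transport and lipid exchange channels only: permeation is
#' split into unidirectional influx (\code{P S_mu N_A C_ex}) and efflux
#' (\code{P S_mu n / V_C}) channels whose difference is the net
#' deterministic transport rate; lipid uptake and release follow
#' \code{k_in S_mu [L]} and \code{k_out n_L_mu}.
#'
#' @inheritParams propensities
#' @return Named vector over transport channels, events/s.
#' @export
transport_propensity <- function(network, state, env = environment_spec(),
                                 geom = geometry_params(),
                                 consts = physical_constants()) {
  v <- propensities(network, state, env, geom, consts)
  v[network$channels$kind != "reaction"]
}

# Flatten a network + environment into the compiled engine representation.
.compile_network <- function(network, env, geom = geometry_params(),
                             consts = physical_constants()) {
  ch <- network$channels
  reg <- network$registry
  kindcode <- c(reaction = 0L, influx = 1L, efflux = 2L, uptake_int = 3L,
                uptake_ext = 4L, release_int = 5L, release_ext = 6L)
  sptr <- cumsum(c(1L, vapply(network$stoich, function(s) length(s$idx), 1L)))
  sidx <- unlist(lapply(network$stoich, `[[`, "idx"), use.names = FALSE)
  sdel <- unlist(lapply(network$stoich, `[[`, "del"), use.names = FALSE)
  conc_ex <- numeric(reg$n_species)
  conc_ex[reg$idx$P] <- env$conc_P_ex
  conc_ex[reg$idx$ntp] <- env$conc_N_ex
  rc_compile(list(
    nsp = reg$n_species, nch = nrow(ch),
    kind = kindcode[ch$kind], k = ch$k,
    M = ifelse(is.na(ch$M), 1L, ch$M),
    r1 = ch$r1, r2 = ch$r2, homo = as.integer(ch$homo),
    sp = ch$species, leap = as.integer(ch$leapable),
    sptr = as.integer(sptr), sidx = as.integer(sidx), sdel = sdel,
    osm = as.integer(reg$species$osmotic),
    iLaq = reg$idx$Laq, iLmem = reg$idx$Lmem,
    iUpInt = match("lipid:uptake_int", ch$name),
    iRelInt = match("lipid:release_int", ch$name),
    iSynth = match("synth:lipid", ch$name),
    conc_ex = conc_ex, C_L_ex = env$conc_L_ex, C_T_E = env$C_T_E,
    NAv = consts$N_A, alpha_half = .nm2_to_dm2(geom$alpha_L) / 2,
    v_aq = consts$v_aq,
    P_aq = .cm_per_s_to_dm(network$params$P_aq),
    k_in = network$params$k_in, k_out = network$params$k_out,
    phi_div = 2^(1 / 3) * (1 + geom$eta), phi_burst = 1 - geom$epsilon))
}
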