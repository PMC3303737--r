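# Deterministic engine: stiff ODE integration of the average vesicle.
#
# State vector: all species counts (reals) followed by the core volume V_C.
# Counts (not concentrations) are the ODE variables so that halving at
# division is exact. dV_C/dt follows the explicit water-flux law; division
# and burst are located by root-finding on the reduced surface.

#' Water flux rate
#'
#' Explicit volume dynamics of the deterministic engine:
#' \code{dV_C/dt = v_aq P_aq S_mu (C_T_C - C_T_E)} — a hypertonic interior
#' draws water in and swells the vesicle. (In the stochastic engine the flux
#' is instantaneous; see [osmotic_volume()].)
#'
#' @param state [vesicle_state()].
#' @param network [build_reaction_network()] (for P_aq and the registry).
#' @param env [environment_spec()].
#' @param geom,consts model parameters.
#' @return dV_C/dt in L/s.
#' @export
water_flux_rate <- function(state, network, env = environment_spec(),
                            geom = geometry_params(),
                            consts = physical_constants()) {
  reg <- network$registry
  S <- membrane_surface(state$counts[reg$idx$Lmem], geom$alpha_L)
  CTC <- sum(state$counts[reg$species$osmotic]) / (state$V_C * consts$N_A)
  unname(consts$v_aq * .cm_per_s_to_dm(network$params$P_aq) * S *
           (CTC - env$C_T_E))
}

# Closure of the species support under the reaction/transport channels:
# which species can ever acquire a nonzero count from this starting state.
# Unreachable species are pinned to zero during integration, since solver
# noise in an exactly-zero gene sector would otherwise be amplified by the
# autocatalytic replication dynamics.
.reachable_mask <- function(network, counts, env) {
  ch <- network$channels
  reg <- network$registry
  present <- counts > 1e-9
  # environment-fed influx species
  feed <- logical(length(present))
  infl <- which(ch$kind == "influx")
  for (j in infl) {
    sp <- ch$species[j]
    conc <- if (sp == reg$idx$P) env$conc_P_ex else env$conc_N_ex
    if (conc > 0) feed[sp] <- TRUE
  }
  present <- present | feed
  repeat {
    changed <- FALSE
    for (j in seq_len(nrow(ch))) {
      active <- switch(ch$kind[j],
        reaction = {
          r <- c(ch$r1[j], ch$r2[j])
          all(present[r[!is.na(r)]])
        },
        influx = TRUE, # handled via feed, products == species
        efflux = FALSE, # removes only
        uptake_int = present[reg$idx$Laq] && present[reg$idx$Lmem],
        release_int = present[reg$idx$Lmem],
        uptake_ext = TRUE, release_ext = FALSE)
      if (!active) next
      s <- network$stoich[[j]]
      prod <- s$idx[s$del > 0]
      if (length(prod) && any(!present[prod])) {
        present[prod] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  present
}

#' Options for the deterministic engine
#'
#' @param rtol relative tolerance of the stiff solver. The default 1e-6 is
#'   chosen jointly with \code{atol}: division times and compositions agree
#'   to 5 significant digits with much tighter settings, while tighter
#'   tolerances make the solver stall on the fastest lipid-exchange
#'   relaxation (~ms) during some post-division restarts.
#' @param atol absolute tolerance on counts (molecules); the volume
#'   component gets \code{atol * 1e-24} since V_C is of order 1e-19 L.
#' @param t_cap_days per-generation integration cap; exceeding it flags the
#'   generation as \code{timeout}.
#' @param n_record trajectory samples requested per generation (the solver
#'   additionally returns the exact event time).
#' @param maxsteps solver step limit per generation.
#' @return List of options.
#' @export
det_options <- function(rtol = 1e-6, atol = 1e-2, t_cap_days = 500,
                        n_record = 240, maxsteps = 1e6) {
  list(rtol = rtol, atol = atol, t_cap_days = t_cap_days,
       n_record = n_record, maxsteps = maxsteps)
}

#' Integrate one generation of the deterministic lineage
#'
#' Integrates the stiff ODE system from a vesicle state until the reduced
#' surface reaches the division threshold \code{2^(1/3)(1+eta)} (divide),
#' drops below \code{1 - epsilon} (burst), or the time cap is exceeded
#' (timeout). On division, the molecular content and volume are halved and
#' one daughter is returned.
#'
#' @param state intact [vesicle_state()].
#' @param network [build_reaction_network()].
#' @param env,geom,consts model parameters.
#' @param opts [det_options()].
#' @return List with \code{state} (daughter or final state), \code{stats}
#'   (one-row data frame: generation, event, delta_t_days, rho_nm, genome
#'   composition fractions) and \code{traj} (data frame t, V_C, S_mu, phi).
#' @export
integrate_generation <- function(state, network, env = environment_spec(),
                                 geom = geometry_params(),
                                 consts = physical_constants(),
                                 opts = det_options()) {
  stopifnot(identical(state$status, "intact"))
  reg <- network$registry
  nsp <- reg$n_species
  xptr <- .compile_network(network, env, geom, consts)
  iL <- reg$idx$Lmem
  alpha_half <- .nm2_to_dm2(geom$alpha_L) / 2
  thr_div <- 2^(1 / 3) * (1 + geom$eta)
  thr_burst <- 1 - geom$epsilon

  mask <- as.integer(.reachable_mask(network, state$counts, env))
  func <- function(t, y, p) list(rc_det_rhs(xptr, y, mask))
  rootfunc <- function(t, y, p) {
    phi <- alpha_half * y[iL] / (36 * pi * y[nsp + 1]^2)^(1 / 3)
    c(phi - thr_div, phi - thr_burst)
  }
  y0 <- c(state$counts, state$V_C)
  t_cap <- opts$t_cap_days * .DAY
  times <- seq(0, t_cap, length.out = opts$n_record)
  out <- deSolve::lsodar(y0, times, func, parms = NULL,
                         rtol = opts$rtol,
                         atol = c(rep(opts$atol, nsp), opts$atol * 1e-24),
                         rootfunc = rootfunc, maxsteps = opts$maxsteps)
  tend <- out[nrow(out), 1]
  yend <- out[nrow(out), -1]
  Vend <- unname(yend[nsp + 1])
  Send <- membrane_surface(yend[iL], geom$alpha_L)
  phiend <- reduced_surface(Send, Vend)
  event <- if (phiend >= thr_div - 1e-6) "divide"
           else if (phiend <= thr_burst + 1e-6) "burst" else "timeout"

  traj <- data.frame(t = out[, 1], V_C = out[, nsp + 2],
                     S_mu = membrane_surface(out[, iL + 1], geom$alpha_L))
  traj$phi <- reduced_surface(traj$S_mu, traj$V_C)

  mother <- vesicle_state(setNames(pmax(yend[seq_len(nsp)], 0),
                                   reg$species$id),
                          Vend, state$generation, state$lineage_id,
                          t_birth = state$t_birth)
  tg <- tally_genome(mother, reg)
  tot <- sum(tg$totals)
  comp <- if (tot > 0) tg$totals / tot else tg$totals * 0
  stats <- data.frame(generation = state$generation + 1L, event = event,
                      delta_t_days = tend / .DAY,
                      rho_nm = .dm_to_nm((3 * (Vend / 2) / (4 * pi))^(1 / 3)),
                      f_R_P = comp[["R_P"]], f_cR_P = comp[["cR_P"]],
                      f_R_L = comp[["R_L"]], f_cR_L = comp[["cR_L"]],
                      stringsAsFactors = FALSE)
  next_state <- switch(event,
    divide = {
      d <- partition_at_division(mother, reg, "halve", geom, consts,
                                 check = FALSE)[[1]]
      d$t_birth <- state$t_birth + tend
      d$lineage_id <- state$lineage_id
      d
    },
    burst = { mother$status <- "broken"; mother },
    timeout = mother)
  list(state = next_state, stats = stats, traj = traj)
}

#' Run a deterministic lineage over generations
#'
#' Chains [integrate_generation()]: at each division the content is halved
#' and one daughter is followed. Stops early on burst or timeout.
#'
#' @inheritParams integrate_generation
#' @param n_generations number of generations to attempt (>= 1).
#' @param keep_trajectory also return the per-generation trajectories
#'   (t, V_C, S_mu, phi with a generation column).
#' @return List with \code{stats} (one row per generation), \code{state}
#'   (final state) and optionally \code{traj}.
#' @examples
#' \donttest{
#' reg <- build_species_registry(100, 100)
#' net <- build_reaction_network(reg)
#' st <- make_initial_state(reg, N_0 = 100)
#' lin <- run_lineage(st, net, n_generations = 3)
#' lin$stats
#' }
#' @export
run_lineage <- function(state, network, env = environment_spec(),
                        geom = geometry_params(),
                        consts = physical_constants(),
                        n_generations = 20, opts = det_options(),
                        keep_trajectory = TRUE) {
  stopifnot(n_generations >= 1)
  stats <- NULL; trajs <- NULL
  for (g in seq_len(n_generations)) {
    res <- integrate_generation(state, network, env, geom, consts, opts)
    stats <- rbind(stats, res$stats)
    if (keep_trajectory) {
      res$traj$generation <- res$stats$generation
      res$traj$t <- res$traj$t + state$t_birth
      trajs <- rbind(trajs, res$traj)
    }
    state <- res$state
    if (res$stats$event != "divide") break
  }
  out <- list(stats = stats, state = state)
  if (keep_trajectory) out$traj <- trajs
  out
}

#' Growth control coefficient gamma
#'
#' \code{gamma = (dV_C/dt / V_C) / (dS_mu/dt / S_mu)}: the ratio of relative
#' volume to relative surface growth rates, computed by centred finite
#' differences of log V_C and log S_mu. Synchronised (stationary) growth has
#' \code{gamma = 1}; \code{gamma > 1} leads towards osmotic burst,
#' \code{gamma < 1} towards shrinking divisions. Samples where the surface
#' is locally constant are masked (NA).
#'
#' @param traj data frame with columns \code{t}, \code{V_C}, \code{S_mu}
#'   (at least 3 rows).
#' @return Data frame \code{t}, \code{gamma} (first/last samples dropped).
#' @export
growth_control_coefficient <- function(traj) {
  if (nrow(traj) < 3) stop("need at least 3 trajectory samples")
  i <- 2:(nrow(traj) - 1)
  dt <- traj$t[i + 1] - traj$t[i - 1]
  dlv <- (log(traj$V_C[i + 1]) - log(traj$V_C[i - 1])) / dt
  dls <- (log(traj$S_mu[i + 1]) - log(traj$S_mu[i - 1])) / dt
  gamma <- ifelse(dls != 0, dlv / dls, NA_real_)
  data.frame(t = traj$t[i], gamma = gamma)
}
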