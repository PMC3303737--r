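# Stochastic engine: Gillespie direct method over individual vesicles, with
# instantaneous osmotic volume rebalance after every event, binomial
# partitioning at division, and an optional hybrid accelerator.
#
# Hybrid mode (acceleration = "hybrid"): channels flagged fast (membrane
# transport, lipid exchange, lipid synthesis) whose propensity exceeds
# hybrid_threshold are advanced by Poisson leaps with Cao-style step
# selection; all RNA channels stay exact, their firing times drawn by
# accumulating the slow hazard across leaps. The internal aqueous lipid pool
# (~tens of molecules churning at ~1e4 events/s against the membrane) is
# held at its quasi-steady value so that the equilibrium churn does not set
# the step size; its net flux into the membrane is preserved. With
# hybrid_threshold = Inf every channel is handled exactly and the engine
# reduces to the direct method.

#' Options for the stochastic engine
#'
#' @param seed optional integer; when non-NULL, \code{set.seed(seed)} is
#'   called at the start of [run_population()] so the run is fully
#'   reproducible.
#' @param keep_daughter_policy which daughter a population run follows after
#'   a division: \code{"random"} (fair coin) or \code{"first"}.
#' @param max_generations stop following a vesicle after this many divisions.
#' @param max_sim_time_days per-vesicle simulated time horizon.
#' @param acceleration \code{"hybrid"} (default) or \code{"exact"}.
#' @param hybrid_threshold propensity (events/s) above which a fast-flagged
#'   channel is leapt; \code{Inf} forces exact simulation of everything.
#' @param eps_leap leap accuracy parameter (bound on the relative change of
#'   any species per leap).
#' @param leap_g_min absolute change (molecules) a sparse species may
#'   undergo per leap when its total leap flux is slow (< 1 event/s);
#'   sparse species with fast fluxes always use the conservative
#'   one-molecule floor, where a larger floor would bias the dynamics
#'   through propensity staleness (the hybrid-vs-exact agreement tests
#'   gate this choice).
#' @param dt_max hard cap on a single leap, s.
#' @param record_dt trajectory sampling interval, s (0 = no trajectory).
#' @param max_steps safety cap on engine steps per episode.
#' @return List of options.
#' @export
ssa_options <- function(seed = NULL,
                        keep_daughter_policy = c("random", "first"),
                        max_generations = 25, max_sim_time_days = 600,
                        acceleration = c("hybrid", "exact"),
                        hybrid_threshold = 0, eps_leap = 0.03,
                        leap_g_min = 10, dt_max = 2000, record_dt = 0,
                        max_steps = 5e8) {
  list(seed = seed,
       keep_daughter_policy = match.arg(keep_daughter_policy),
       max_generations = max_generations,
       max_sim_time_days = max_sim_time_days,
       acceleration = match.arg(acceleration),
       hybrid_threshold = hybrid_threshold, eps_leap = eps_leap,
       leap_g_min = leap_g_min, dt_max = dt_max, record_dt = record_dt,
       max_steps = max_steps)
}

#' One step of the Gillespie direct method (reference implementation)
#'
#' Draws the waiting time \code{tau ~ Exp(a0)} and the firing channel with
#' probability proportional to its propensity. This is the plain R reference
#' path used for validation; production simulation goes through the
#' compiled engine in [simulate_vesicle()].
#'
#' @inheritParams propensities
#' @return List with \code{channel} (index into the channel table; NA if
#'   the system is quiescent), \code{tau} (s; Inf if quiescent) and the
#'   propensity vector \code{a}.
#' @export
direct_method_step <- function(network, state, env = environment_spec(),
                               geom = geometry_params(),
                               consts = physical_constants()) {
  a <- propensities(network, state, env, geom, consts)
  a0 <- sum(a)
  if (a0 <= 0) return(list(channel = NA_integer_, tau = Inf, a = a))
  tau <- rexp(1, rate = a0)
  j <- sample.int(length(a), 1, prob = a)
  list(channel = j, tau = tau, a = a)
}

#' Apply one event and rebalance the volume
#'
#' Applies the stoichiometry of a channel to the integer counts and resets
#' the core volume through the osmotic identity (instantaneous water flux).
#' Membrane-only events change \code{n_L_mu} without affecting the volume.
#'
#' @param state [vesicle_state()].
#' @param network [build_reaction_network()].
#' @param channel channel index (as returned by [direct_method_step()]).
#' @param env,consts model parameters.
#' @return The updated [vesicle_state()].
#' @export
apply_event_and_rebalance <- function(state, network, channel,
                                      env = environment_spec(),
                                      consts = physical_constants()) {
  s <- network$stoich[[channel]]
  n <- state$counts
  n[s$idx] <- n[s$idx] + s$del
  if (any(n < 0))
    stop("internal consistency error: event drove a count negative")
  state$counts <- n
  state$V_C <- osmotic_volume(n, env$C_T_E, network$registry, consts)
  state
}

#' Simulate one vesicle until division, burst or timeout
#'
#' Runs the stochastic engine from a state. On division the mother content
#' is partitioned binomially and both daughters are returned; on burst the
#' vesicle is marked broken and retains its identity ("a flat bilayer") but
#' undergoes no further events.
#'
#' @param state intact [vesicle_state()] (counts are rounded to integers).
#' @param network,env,geom,consts model specification.
#' @param opts [ssa_options()].
#' @param t_max_days override for the time horizon (defaults to
#'   \code{opts$max_sim_time_days}).
#' @param xptr optional pre-compiled network (internal use).
#' @return List: \code{fate} ("divide", "burst" or "timeout"), \code{t}
#'   (end time, s), \code{state} (mother at division / final state),
#'   \code{daughters} (list of two, divisions only), \code{traj} (matrix
#'   t, V_C, S_mu, phi if \code{record_dt > 0}), \code{steps}.
#' @export
simulate_vesicle <- function(state, network, env = environment_spec(),
                             geom = geometry_params(),
                             consts = physical_constants(),
                             opts = ssa_options(), t_max_days = NULL,
                             xptr = NULL) {
  stopifnot(identical(state$status, "intact"))
  if (is.null(xptr)) xptr <- .compile_network(network, env, geom, consts)
  reg <- network$registry
  counts <- round(state$counts)
  t_max <- state$t_birth +
    (if (is.null(t_max_days)) opts$max_sim_time_days else t_max_days) * .DAY
  res <- rc_ssa(xptr, counts, state$t_birth, t_max,
                identical(opts$acceleration, "hybrid"),
                opts$hybrid_threshold, opts$eps_leap, opts$leap_g_min,
                opts$dt_max, opts$record_dt, opts$max_steps)
  if (res$fate == 3)
    stop("stochastic engine exceeded max_steps = ", opts$max_steps)
  fate <- c("timeout", "divide", "burst")[res$fate + 1]
  end <- vesicle_state(setNames(res$counts, reg$species$id), res$V,
                       state$generation, state$lineage_id,
                       status = if (fate == "burst") "broken" else "intact",
                       t_birth = state$t_birth)
  out <- list(fate = fate, t = res$t, state = end,
              steps = c(exact = res$steps_exact, leap = res$steps_leap))
  if (opts$record_dt > 0) {
    colnames(res$traj) <- c("t", "V_C", "S_mu", "phi")
    out$traj <- res$traj
  }
  if (fate == "divide") {
    mother <- end
    mother$status <- "intact"
    d <- partition_at_division(mother, reg, "binomial", geom, consts,
                               env = env, check = FALSE)
    d[[1]]$t_birth <- d[[2]]$t_birth <- res$t
    out$daughters <- d
  }
  out
}
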