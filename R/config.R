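# YAML run configuration: flat sections mirroring the model parameter names.

.CONFIG_SCHEMA <- list(
  kinetics = c("k_SS", "k_S", "k_RatS", "k_RatSS", "k_NTP", "k_L",
               "k_in", "k_out", "P_P", "P_NTP", "P_W", "P_S", "P_aq"),
  geometry = c("alpha_L", "epsilon", "eta"),
  constants = c("N_A", "v_aq"),
  environment = c("conc_P_ex", "conc_N_ex", "conc_I_ex", "conc_W_ex",
                  "conc_L_ex"),
  initial = c("N_0", "r_0", "L_P", "L_L"),
  engine = c("mode", "generations", "seed", "acceleration",
             "hybrid_threshold", "t_cap_days", "max_sim_time_days",
             "n_runs", "vesicles_per_run"))

#' Default run configuration
#'
#' All kinetic defaults, the optimal external conditions
#' (\code{[N_ex] = [P_ex] = 1e-2 M}, \code{[I_ex] = 0.3 M}), 100-nt
#' ribozymes, \code{N_0 = 100} dimers and a 50 nm founder.
#'
#' @return Nested named list (sections kinetics, geometry, constants,
#'   environment, initial, engine).
#' @export
default_config <- function() {
  p <- kinetic_parameters(); g <- geometry_params(); k <- physical_constants()
  list(kinetics = unclass(p),
       geometry = unclass(g),
       constants = unclass(k),
       environment = list(conc_P_ex = 1e-2, conc_N_ex = 1e-2,
                          conc_I_ex = 0.3, conc_W_ex = 0,
                          conc_L_ex = lipid_exchange_equilibrium(p, g)),
       initial = list(N_0 = 100, r_0 = 50, L_P = 100, L_L = 100),
       engine = list(mode = "deterministic", generations = 20, seed = 1,
                     acceleration = "hybrid", hybrid_threshold = 0,
                     t_cap_days = 500, max_sim_time_days = 600,
                     n_runs = 4, vesicles_per_run = 10))
}

#' Load a run configuration from YAML
#'
#' Unknown sections or keys are rejected with an error naming the offender;
#' omitted keys take the defaults of [default_config()]. Negative kinetic or
#' concentration values are rejected at model-object construction.
#'
#' @param path YAML file (an empty file yields the full default config).
#' @return Validated nested configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  bad <- setdiff(names(user), names(.CONFIG_SCHEMA))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (sec in names(user)) {
    badk <- setdiff(names(user[[sec]]), .CONFIG_SCHEMA[[sec]])
    if (length(badk)) stop("unknown key(s) in section '", sec, "': ",
                           paste(badk, collapse = ", "))
  }
  cfg <- default_config()
  for (sec in names(user)) cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
  # eager validation of the numeric sections
  do.call(kinetic_parameters, cfg$kinetics)
  do.call(geometry_params, cfg$geometry)
  do.call(physical_constants, cfg$constants)
  do.call(environment_spec, c(cfg$environment,
                              list(params = do.call(kinetic_parameters,
                                                    cfg$kinetics),
                                   geom = do.call(geometry_params,
                                                  cfg$geometry))))
  cfg
}

#' Save a configuration to YAML
#'
#' @param cfg configuration list (as from [load_config()]).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Instantiate model objects from a configuration
#'
#' @param cfg configuration list.
#' @return List with \code{params}, \code{geom}, \code{consts}, \code{env},
#'   \code{registry}, \code{network}, \code{state} (the founder vesicle).
#' @export
build_from_config <- function(cfg) {
  params <- do.call(kinetic_parameters, cfg$kinetics)
  geom <- do.call(geometry_params, cfg$geometry)
  consts <- do.call(physical_constants, cfg$constants)
  env <- do.call(environment_spec,
                 c(cfg$environment, list(params = params, geom = geom)))
  registry <- build_species_registry(cfg$initial$L_P, cfg$initial$L_L)
  network <- build_reaction_network(registry, params)
  state <- make_initial_state(registry, env, geom, consts,
                              N_0 = cfg$initial$N_0, r_0 = cfg$initial$r_0)
  list(params = params, geom = geom, consts = consts, env = env,
       registry = registry, network = network, state = state)
}
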