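# Vesicle geometry, osmotic volume, stability window and division.

#' Membrane surface from lipid count
#'
#' \code{S_mu = alpha_L * n_L_mu / 2}; the factor 1/2 accounts for the two
#' leaflets of the bilayer.
#'
#' @param n_L_mu number of membrane lipids (>= 0).
#' @param alpha_L lipid head area, nm^2.
#' @return Surface in dm^2.
#' @examples
#' membrane_surface(2.094e5) # ~3.14e-12 dm^2, a 50 nm sphere
#' @export
membrane_surface <- function(n_L_mu, alpha_L = 0.3) {
  if (any(n_L_mu < 0)) stop("membrane lipid count must be >= 0")
  .nm2_to_dm2(alpha_L) * n_L_mu / 2
}

#' Reduced surface
#'
#' The ratio between the actual membrane surface and the area of the sphere
#' that would exactly wrap the current core volume:
#' \code{phi = S_mu / (36 pi V_C^2)^(1/3)}. A sphere has \code{phi = 1};
#' swollen vesicles have \code{phi < 1}, deflated ones \code{phi > 1}.
#'
#' @param S_mu membrane surface, dm^2 (> 0).
#' @param V_C core volume, L (> 0).
#' @return phi (dimensionless).
#' @export
reduced_surface <- function(S_mu, V_C) {
  if (any(S_mu <= 0) || any(V_C <= 0))
    stop("reduced_surface needs positive surface and volume")
  S_mu / (36 * pi * V_C^2)^(1 / 3)
}

#' Osmotically balanced core volume
#'
#' In the stochastic engine the water flux is treated as instantaneous: after
#' every event the core volume is reset so that the internal osmolarity
#' equals the external one, \code{V_C = sum(aqueous counts) / (N_A C_T_E)}.
#' Membrane lipids do not count.
#'
#' @param counts named species counts (a full registry vector, or any vector
#'   of aqueous counts when \code{registry} is \code{NULL}).
#' @param C_T_E total external osmolarity, M (> 0).
#' @param registry optional [build_species_registry()]; when supplied, only
#'   osmotically active species are summed.
#' @param consts [physical_constants()].
#' @return Volume in L.
#' @export
osmotic_volume <- function(counts, C_T_E, registry = NULL,
                           consts = physical_constants()) {
  if (!isTRUE(C_T_E > 0)) stop("C_T_E must be > 0")
  tot <- if (is.null(registry)) sum(counts)
         else sum(counts[registry$species$osmotic])
  if (!isTRUE(tot > 0))
    stop("degenerate state: vesicle has no osmotic content")
  tot / (consts$N_A * C_T_E)
}

#' Stability window check
#'
#' Vesicles are stable for \code{(1 - epsilon) <= phi <= 2^(1/3)(1 + eta)}.
#' Below the window the membrane is osmotically overstretched and the
#' vesicle bursts; at or above the upper bound it can split into two equal
#' spherical daughters. Ties: exactly \code{2^(1/3)(1+eta)} divides; exactly
#' \code{1 - epsilon} is still stable (burst requires a strict drop below).
#'
#' @param phi reduced surface.
#' @param epsilon osmotic tolerance.
#' @param eta dividing tolerance.
#' @return One of \code{"stable"}, \code{"burst"}, \code{"divide"}
#'   (vectorised over \code{phi}).
#' @export
stability_check <- function(phi, epsilon = 0.21, eta = 0) {
  out <- ifelse(phi < 1 - epsilon, "burst",
                ifelse(phi >= 2^(1 / 3) * (1 + eta), "divide", "stable"))
  out
}

#' Vesicle state
#'
#' The state of one vesicle: aqueous molecule counts plus the membrane lipid
#' count (one named vector over the registry), the core volume, and lineage
#' metadata.
#'
#' @param counts named numeric vector over \code{registry$species$id}
#'   (integers in stochastic mode, non-negative reals in deterministic mode).
#' @param V_C core volume, L.
#' @param generation generation index (0 = founder).
#' @param lineage_id identifier string.
#' @param status \code{"intact"} or \code{"broken"}.
#' @param t_birth birth time, s.
#' @return An object of class \code{vesicle_state}.
#' @export
vesicle_state <- function(counts, V_C, generation = 0L, lineage_id = "v1",
                          status = "intact", t_birth = 0) {
  if (any(counts < 0)) stop("negative species count")
  if (identical(status, "intact") && !isTRUE(V_C > 0))
    stop("V_C must be > 0 while intact")
  structure(list(counts = counts, V_C = V_C,
                 generation = as.integer(generation),
                 lineage_id = lineage_id, status = status,
                 t_birth = t_birth), class = "vesicle_state")
}

#' @export
print.vesicle_state <- function(x, ...) {
  cat(sprintf("<vesicle %s> gen %d, %s, V_C = %.4g L, %d species tracked\n",
              x$lineage_id, x$generation, x$status, x$V_C, length(x$counts)))
  invisible(x)
}

#' Isotonic initial state
#'
#' Builds a spherical vesicle of radius \code{r_0} containing \code{N_0}
#' dimers of each gene (plus any \code{extra_counts}), with the inert buffer
#' B adjusted so the interior is exactly isotonic with the environment
#' (\code{phi = 1}, \code{C_T_C = C_T_E}). All substrates, waste and aqueous
#' lipid start at zero inside.
#'
#' @param registry [build_species_registry()].
#' @param env [environment_spec()].
#' @param geom [geometry_params()].
#' @param consts [physical_constants()].
#' @param N_0 initial count of each of the two dimers.
#' @param r_0 initial radius, nm.
#' @param extra_counts optional named vector of additional initial counts
#'   (e.g. \code{c(R_L = 1)} for a self-producing vesicle).
#' @param lineage_id identifier.
#' @return A [vesicle_state()].
#' @examples
#' reg <- build_species_registry(100, 100)
#' st <- make_initial_state(reg, N_0 = 100)
#' @export
make_initial_state <- function(registry, env = environment_spec(),
                               geom = geometry_params(),
                               consts = physical_constants(),
                               N_0 = 0, r_0 = 50, extra_counts = NULL,
                               lineage_id = "v1") {
  if (!isTRUE(r_0 > 0)) stop("r_0 must be > 0")
  if (!isTRUE(N_0 >= 0)) stop("N_0 must be >= 0")
  r <- .nm_to_dm(r_0)
  V <- 4 / 3 * pi * r^3
  n_L <- 2 * 4 * pi * r^2 / .nm2_to_dm2(geom$alpha_L)
  counts <- setNames(numeric(registry$n_species), registry$species$id)
  counts[registry$idx$dimers] <- N_0
  if (!is.null(extra_counts)) {
    if (is.null(names(extra_counts)) ||
        !all(names(extra_counts) %in% registry$species$id))
      stop("extra_counts must be named by registry species ids")
    counts[names(extra_counts)] <- counts[names(extra_counts)] + extra_counts
  }
  counts[registry$idx$Lmem] <- n_L
  target <- env$C_T_E * consts$N_A * V
  others <- sum(counts[registry$species$osmotic])
  B <- target - others
  if (B < 0)
    stop("infeasible isotonicity: genome exceeds the osmotic budget ",
         "(required B < 0)")
  counts[registry$idx$B] <- B
  vesicle_state(counts, V, lineage_id = lineage_id)
}

#' Partition a dividing vesicle into two daughters
#'
#' Membrane lipids and volume are split exactly in half in both modes (two
#' equal spheres). Aqueous content: \code{"halve"} divides every count by
#' two (deterministic engine); \code{"binomial"} sends each molecule to a
#' daughter with probability 1/2, independently per species (stochastic
#' engine). Dimers and elongation complexes partition as single units. When
#' \code{env} is supplied, daughter volumes are re-derived from the osmotic
#' identity.
#'
#' @param state a [vesicle_state()] flagged as dividing (see \code{check}).
#' @param registry [build_species_registry()].
#' @param mode \code{"halve"} or \code{"binomial"}.
#' @param geom,consts,env model parameters; \code{env = NULL} splits the
#'   volume exactly in half instead of rebalancing.
#' @param check verify that the state satisfies the division condition
#'   (\code{phi >= 2^(1/3)(1+eta)}); calling on a non-dividing state is a
#'   logic error.
#' @return List of two [vesicle_state()] daughters.
#' @export
partition_at_division <- function(state, registry,
                                  mode = c("halve", "binomial"),
                                  geom = geometry_params(),
                                  consts = physical_constants(),
                                  env = NULL, check = TRUE) {
  mode <- match.arg(mode)
  if (check) {
    S <- membrane_surface(state$counts[registry$idx$Lmem], geom$alpha_L)
    phi <- reduced_surface(S, state$V_C)
    if (phi < 2^(1 / 3) * (1 + geom$eta) - 1e-9)
      stop("partition_at_division called on a non-dividing state (phi = ",
           signif(phi, 6), ")")
  }
  n <- state$counts
  iL <- registry$idx$Lmem
  if (mode == "halve") {
    nA <- n / 2
    nB <- n / 2
  } else {
    nn <- round(n)
    nA <- setNames(rbinom(length(nn), nn, 0.5), names(nn))
    # membrane and any remainder lipid split deterministically in half
    nA[iL] <- floor(nn[iL] / 2) + rbinom(1, nn[iL] %% 2, 0.5)
    nB <- nn - nA
    nA <- as.numeric(nA); nB <- as.numeric(nB)
    names(nA) <- names(nB) <- names(nn)
  }
  VA <- VB <- state$V_C / 2
  if (!is.null(env)) {
    VA <- osmotic_volume(nA, env$C_T_E, registry, consts)
    VB <- osmotic_volume(nB, env$C_T_E, registry, consts)
  }
  g <- state$generation + 1L
  list(vesicle_state(nA, VA, g, paste0(state$lineage_id, ".A"),
                     t_birth = state$t_birth),
       vesicle_state(nB, VB, g, paste0(state$lineage_id, ".B"),
                     t_birth = state$t_birth))
}
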