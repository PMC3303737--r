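#' Kinetic parameters of the Ribocell model
#'
#' Container for the rate constants and membrane permeabilities of the
#' minimal-cell network, with room-temperature oleic-acid defaults. Units
#' are the conventional laboratory ones; conversion to the internal
#' dm/litre system happens when a network is compiled for simulation.
#'
#' @param k_SS dimer formation rate, 1/(M s). Association of a ribozyme with
#'   its complementary strand.
#' @param k_S dimer dissociation rate, 1/s.
#' @param k_RatS polymerase-template complex formation rate, 1/(M s).
#' @param k_RatSS dissociation rate of the completed complex into polymerase
#'   plus product duplex, 1/s.
#' @param k_NTP per-nucleotide addition rate during template-directed
#'   transcription, 1/(M s).
#' @param k_L catalytic precursor-to-lipid conversion rate, 1/(M s).
#' @param k_in membrane lipid uptake coefficient: uptake propensity is
#'   \code{k_in * S_mu * [L]} (events/s) with the membrane surface S_mu in
#'   dm^2 and the aqueous lipid concentration in M.
#' @param k_out membrane lipid release coefficient: release propensity is
#'   \code{k_out * n_L_mu} (events/s), i.e. 1/s per membrane lipid.
#' @param P_P membrane permeability to the lipid precursor, cm/s.
#' @param P_NTP membrane permeability to activated nucleotides, cm/s.
#' @param P_W membrane permeability to the polymerisation by-product W, cm/s
#'   (0: W is assumed charged and trapped; its accumulation drives osmotic
#'   volume growth).
#' @param P_S membrane permeability to RNA strands, cm/s (0: membranes are
#'   impermeable to genetic material).
#' @param P_aq membrane permeability to water, cm/s.
#'
#' @return An object of class \code{kinetic_parameters} (a validated list).
#' @examples
#' kinetic_parameters()
#' kinetic_parameters(k_SS = 8.8e4) # weaker dimerisation
#' @export
kinetic_parameters <- function(k_SS = 8.8e6, k_S = 2.2e-6,
                               k_RatS = 5.32e5, k_RatSS = 9.9e-3,
                               k_NTP = 0.113, k_L = 1.7e3,
                               k_in = 7.6e19, k_out = 7.6e-2,
                               P_P = 4.2e-9, P_NTP = 1.9e-11,
                               P_W = 0, P_S = 0, P_aq = 1.0e-3) {
  p <- list(k_SS = k_SS, k_S = k_S, k_RatS = k_RatS, k_RatSS = k_RatSS,
            k_NTP = k_NTP, k_L = k_L, k_in = k_in, k_out = k_out,
            P_P = P_P, P_NTP = P_NTP, P_W = P_W, P_S = P_S, P_aq = P_aq)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("kinetic parameter '", nm, "' must be a single non-negative number")
  }
  structure(p, class = "kinetic_parameters")
}

#' Physical constants
#'
#' @param N_A Avogadro number, 1/mol.
#' @param v_aq molar volume of water, L/mol.
#' @return An object of class \code{physical_constants}.
#' @export
physical_constants <- function(N_A = 6.02214e23, v_aq = 0.018) {
  if (!isTRUE(v_aq > 0)) stop("v_aq must be > 0")
  if (!isTRUE(N_A > 0)) stop("N_A must be > 0")
  structure(list(N_A = N_A, v_aq = v_aq), class = "physical_constants")
}

#' Vesicle geometry and stability parameters
#'
#' @param alpha_L amphiphile head area, nm^2. The bilayer surface is
#'   \code{S_mu = alpha_L * n_L_mu / 2}.
#' @param epsilon osmotic tolerance (dimensionless): the vesicle bursts when
#'   the reduced surface drops below \code{1 - epsilon}.
#' @param eta dividing tolerance (dimensionless): division fires at
#'   \code{phi >= 2^(1/3) * (1 + eta)}.
#' @return An object of class \code{geometry_params}.
#' @export
geometry_params <- function(alpha_L = 0.3, epsilon = 0.21, eta = 0) {
  if (!isTRUE(alpha_L > 0)) stop("alpha_L must be > 0")
  if (!isTRUE(epsilon > 0 && epsilon < 1)) stop("epsilon must be in (0, 1)")
  if (!isTRUE(eta >= 0)) stop("eta must be >= 0")
  structure(list(alpha_L = alpha_L, epsilon = epsilon, eta = eta),
            class = "geometry_params")
}

#' Equilibrium aqueous lipid concentration of the exchange channels
#'
#' Balance of single-lipid uptake (\code{k_in * S_mu * [L]}) against release
#' (\code{k_out * n_L_mu}) with \code{S_mu = alpha_L * n_L_mu / 2} gives the
#' concentration at which a membrane neither grows nor shrinks:
#' \code{[L]_eq = 2 k_out / (alpha_L k_in)} (about 6.67e-5 M for the oleic
#' defaults).
#'
#' @param params [kinetic_parameters()].
#' @param geom [geometry_params()].
#' @return Equilibrium concentration, M.
#' @export
lipid_exchange_equilibrium <- function(params = kinetic_parameters(),
                                       geom = geometry_params()) {
  2 * params$k_out / (.nm2_to_dm2(geom$alpha_L) * params$k_in)
}

#' External environment (CSTR approximation)
#'
#' Fixed external concentrations; the reactor is assumed continuously fed so
#' that they never change (continuous stirred tank reactor approximation).
#' The by-product W is absent outside by assumption. The external aqueous
#' lipid concentration defaults to the exchange equilibrium value so that an
#' inert membrane neither grows nor shrinks.
#'
#' @param conc_P_ex external lipid precursor concentration, M.
#' @param conc_N_ex external concentration of each of the four nucleotide
#'   pools, M (all four are set equal).
#' @param conc_I_ex external concentration of the inert osmotic buffer, M.
#' @param conc_W_ex external by-product concentration; must be 0.
#' @param conc_L_ex external aqueous lipid concentration, M; \code{NULL}
#'   means the exchange equilibrium value for \code{params}/\code{geom}.
#'   The reservoir is assumed saturated at this value so membranes neither
#'   dissolve nor grow from outside; it contributes to the external
#'   osmolarity but drives no net channel (membrane lipid exchange operates
#'   against the vesicle core).
#' @param params,geom used only to derive the default \code{conc_L_ex}.
#' @return An object of class \code{environment_spec} with the derived total
#'   external osmolarity \code{C_T_E} (the four nucleotide pools all count).
#' @examples
#' env <- environment_spec()
#' env$C_T_E # ~0.35 M at the optimal conditions
#' @export
environment_spec <- function(conc_P_ex = 1e-2, conc_N_ex = 1e-2,
                             conc_I_ex = 0.3, conc_W_ex = 0,
                             conc_L_ex = NULL,
                             params = kinetic_parameters(),
                             geom = geometry_params()) {
  if (is.null(conc_L_ex)) conc_L_ex <- lipid_exchange_equilibrium(params, geom)
  e <- list(conc_P_ex = conc_P_ex, conc_N_ex = conc_N_ex,
            conc_I_ex = conc_I_ex, conc_W_ex = conc_W_ex,
            conc_L_ex = conc_L_ex)
  for (nm in names(e)) {
    v <- e[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("environment concentration '", nm,
           "' must be a single non-negative number")
  }
  if (e$conc_W_ex != 0) stop("conc_W_ex must be 0 (no external by-product)")
  e$C_T_E <- e$conc_I_ex + e$conc_P_ex + 4 * e$conc_N_ex + e$conc_W_ex +
    e$conc_L_ex
  structure(e, class = "environment_spec")
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Ribocell kinetic parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.environment_spec <- function(x, ...) {
  cat("External environment (CSTR, fixed):\n")
  for (nm in names(x)) cat(sprintf("  %-10s %g M\n", nm, x[[nm]]))
  invisible(x)
}
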