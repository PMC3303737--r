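# Reaction network assembly.
#
# Internal chemistry (mass action):
#   (1) S + cS <-> S.cS                 k_SS / k_S, both gene pairs
#   (2) R_P + S -> RP@S_0               k_RatS, S any free monomeric strand
#       RP@S_j + NTP_b -> RP@S_{j+1}+W  k_NTP, j = 0..L-1
#       RP@S_L -> R_P + S.cS            k_RatSS (product duplex released)
#   (3) R_L + P -> R_L + L_aq           k_L (catalyst conserved)
# Only free monomers act as catalysts or templates; strands inside dimers
# and complexes are inactive.
#
# Membrane channels: passive permeation of P and the four NTP pools (split
# into unidirectional influx/efflux), and lipid exchange with the vesicle
# core: uptake k_in * S_mu * [L_aq], release k_out * n_L_mu.

#' Build the Ribocell reaction network
#'
#' Enumerates every reaction and transport channel over a species registry.
#' Each channel carries both a deterministic mass-action rate law and a
#' stochastic propensity (see [propensities()]); the two agree to first
#' order at large copy numbers. Template-directed elongation consumes one
#' nucleotide pool per step, chosen by the template's (random) base sequence:
#' the assignment is drawn once from the current RNG when the network is
#' built, so wrap the call in \code{set.seed()} for a reproducible network.
#' Since the self-template initiation channel \code{R_P + R_P} is
#' homo-bimolecular, its propensity uses ordered-pair counting n(n-1).
#'
#' @param registry a [build_species_registry()] object.
#' @param params [kinetic_parameters()].
#' @param ntp_assignment optional list (named by template strand) of integer
#'   vectors in 1..4 giving the nucleotide pool consumed at each elongation
#'   step; \code{NULL} draws a uniform random assignment.
#' @return An object of class \code{reaction_network}.
#' @examples
#' reg <- build_species_registry(100, 100)
#' net <- build_reaction_network(reg)
#' net$n_internal # 413 internal reactions
#' @export
build_reaction_network <- function(registry, params = kinetic_parameters(),
                                   ntp_assignment = NULL) {
  stopifnot(inherits(registry, "species_registry"))
  stopifnot(inherits(params, "kinetic_parameters"))
  ix <- registry$idx
  L <- registry$L

  if (is.null(ntp_assignment)) {
    ntp_assignment <- lapply(L, function(l) sample.int(4L, l, replace = TRUE))
    names(ntp_assignment) <- names(L)
  }
  for (s in names(L)) {
    v <- ntp_assignment[[s]]
    if (length(v) != L[[s]] || any(!v %in% 1:4))
      stop("ntp_assignment for ", s, " must be length ", L[[s]], " in 1..4")
  }

  name <- character(0); kind <- character(0); k <- numeric(0)
  M <- integer(0); r1 <- integer(0); r2 <- integer(0); homo <- logical(0)
  sp <- integer(0); leap <- logical(0)
  st <- list()  # per-channel stoichiometry: named list(idx=, del=)

  add <- function(nm, kd, kk, mm = NA_integer_, a = NA_integer_,
                  b = NA_integer_, hm = FALSE, species = NA_integer_,
                  lp = FALSE, sidx = integer(0), sdel = numeric(0)) {
    name <<- c(name, nm); kind <<- c(kind, kd); k <<- c(k, kk)
    M <<- c(M, mm); r1 <<- c(r1, a); r2 <<- c(r2, b); homo <<- c(homo, hm)
    sp <<- c(sp, species); leap <<- c(leap, lp)
    st[[length(st) + 1]] <<- list(idx = as.integer(sidx),
                                  del = as.numeric(sdel))
  }

  mono <- ix$monomers
  # (1) reversible dimerisation
  for (pair in list(c("R_P", "cR_P"), c("R_L", "cR_L"))) {
    d <- ix$dimers[[.DIMER_OF[[pair[1]]]]]
    add(paste0("assoc:", .DIMER_OF[[pair[1]]]), "reaction", params$k_SS, 2L,
        mono[[pair[1]]], mono[[pair[2]]],
        sidx = c(mono[[pair[1]]], mono[[pair[2]]], d), sdel = c(-1, -1, 1))
    add(paste0("dissoc:", .DIMER_OF[[pair[1]]]), "reaction", params$k_S, 1L,
        d, sidx = c(d, mono[[pair[1]]], mono[[pair[2]]]), sdel = c(-1, 1, 1))
  }
  # (2) transcription: initiation, elongation ladder, release
  for (s in .STRANDS) {
    cp <- ix$cplx[[s]]
    add(paste0("init:", s), "reaction", params$k_RatS, 2L,
        mono[["R_P"]], mono[[s]], hm = identical(s, "R_P"),
        sidx = c(mono[["R_P"]], mono[[s]], cp[1]),
        sdel = if (identical(s, "R_P")) c(-2, 0, 1) else c(-1, -1, 1))
    for (j in seq_len(L[[s]])) {  # step j-1 -> j
      b <- ix$ntp[ntp_assignment[[s]][j]]
      add(sprintf("elong:%s_%d", s, j), "reaction", params$k_NTP, 2L,
          cp[j], b, sidx = c(cp[j], b, cp[j + 1], ix$W),
          sdel = c(-1, -1, 1, 1))
    }
    add(paste0("release:", s), "reaction", params$k_RatSS, 1L,
        cp[L[[s]] + 1],
        sidx = c(cp[L[[s]] + 1], mono[["R_P"]], ix$dimers[[.DIMER_OF[[s]]]]),
        sdel = c(-1, 1, 1))
  }
  # (3) catalysed lipid synthesis (catalyst R_L conserved)
  add("synth:lipid", "reaction", params$k_L, 2L, mono[["R_L"]], ix$P,
      lp = TRUE, sidx = c(ix$P, ix$Laq), sdel = c(-1, 1))
  n_internal <- length(name)

  # passive permeation (only species with nonzero permeability get channels)
  perm <- function(nm, species, P_cm) {
    if (P_cm <= 0) return(invisible())
    kdm <- .cm_per_s_to_dm(P_cm)
    add(paste0("influx:", nm), "influx", kdm, species = species, lp = TRUE,
        sidx = species, sdel = 1)
    add(paste0("efflux:", nm), "efflux", kdm, species = species, lp = TRUE,
        sidx = species, sdel = -1)
  }
  perm("P", ix$P, params$P_P)
  for (b in 1:4) perm(sprintf("NTP_%d", b), ix$ntp[b], params$P_NTP)
  if (params$P_W > 0) perm("W", ix$W, params$P_W)

  # lipid exchange against the internal aqueous solution. The membrane is
  # taken to equilibrate only with the vesicle core: with the external
  # reservoir clamped at the exchange-equilibrium concentration, external
  # uptake and release channels would cancel in the mean but inject an
  # unbounded critical random walk into the membrane count (empty vesicles
  # would spuriously divide or burst within days); exchanging with the
  # finite internal pool keeps the membrane slaved to the lipid inventory,
  # whose only source is catalysed synthesis.
  add("lipid:uptake_int", "uptake_int", params$k_in, lp = TRUE,
      sidx = c(ix$Laq, ix$Lmem), sdel = c(-1, 1))
  add("lipid:release_int", "release_int", params$k_out, lp = TRUE,
      sidx = c(ix$Lmem, ix$Laq), sdel = c(-1, 1))

  channels <- data.frame(name = name, kind = kind, k = k, M = M,
                         r1 = r1, r2 = r2, homo = homo, species = sp,
                         leapable = leap, stringsAsFactors = FALSE)
  structure(list(registry = registry, params = params, channels = channels,
                 stoich = st, ntp_assignment = ntp_assignment,
                 n_internal = n_internal,
                 n_channels = nrow(channels)),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Ribocell reaction network:", x$n_channels, "channels\n")
  cat("  internal reactions:", x$n_internal, "\n")
  print(table(x$channels$kind))
  invisible(x)
}

#' Dump a network description to JSON
#'
#' Writes species (id, role, osmotic flag, strand census) and channels
#' (name, kind, rate constant, molecularity, stoichiometry) for inspection
#' and golden-file tests.
#'
#' @param network a [build_reaction_network()] object.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
network_to_json <- function(network, path) {
  reg <- network$registry
  ids <- reg$species$id
  chans <- lapply(seq_len(network$n_channels), function(j) {
    s <- network$stoich[[j]]
    ch <- network$channels[j, ]
    list(name = ch$name, kind = ch$kind, k = ch$k,
         M = if (is.na(ch$M)) NULL else ch$M,
         stoich = setNames(as.list(s$del), ids[s$idx]))
  })
  obj <- list(species = cbind(reg$species,
                              as.data.frame(reg$strands,
                                            row.names = seq_along(ids))),
              channels = chans)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
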