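# Species registry: enumerates every chemical species of the Ribocell.
#
# Strand bookkeeping convention: each species carries a census over the four
# strand types (R_P, cR_P, R_L, cR_L). An elongation complex R_P@S_j counts
# its polymerase and its template; the nascent chain counts as a strand only
# once complete (j = L), since a partial chain is not yet a functional
# strand.

.STRANDS <- c("R_P", "cR_P", "R_L", "cR_L")
.COMPLEMENT <- c(R_P = "cR_P", cR_P = "R_P", R_L = "cR_L", cR_L = "R_L")
.DIMER_OF <- c(R_P = "R_P.cR_P", cR_P = "R_P.cR_P",
               R_L = "R_L.cR_L", cR_L = "R_L.cR_L")

#' Build the species registry
#'
#' Enumerates the full species set for given ribozyme lengths: the four RNA
#' monomers, the two duplex dimers, the ladder of polymerase-template
#' elongation complexes \code{R_P@S_j} (j = 0..L for each of the four
#' monomeric templates S), the four activated-nucleotide pools, the
#' by-product W, the lipid precursor P, the aqueous lipid, the inert osmotic
#' buffer B and the membrane lipid. All aqueous species are osmotically
#' active; the membrane lipid is the single non-osmotic species.
#'
#' @param L_P length of the polymerase ribozyme (and its complement), nt.
#' @param L_L length of the lipase ribozyme (and its complement), nt.
#'   Both lengths must be at least 20, the minimum size for a folded
#'   (catalytically plausible) RNA structure.
#' @return An object of class \code{species_registry}: species table,
#'   per-species strand census matrix, and index helpers.
#' @examples
#' reg <- build_species_registry(100, 100)
#' reg$n_species # 419
#' @export
build_species_registry <- function(L_P = 100, L_L = 100) {
  if (!isTRUE(L_P >= 20) || !isTRUE(L_L >= 20))
    stop("ribozyme lengths must be >= 20 nt (minimum folded RNA)")
  L_P <- as.integer(L_P); L_L <- as.integer(L_L)
  L <- c(R_P = L_P, cR_P = L_P, R_L = L_L, cR_L = L_L)

  ids <- character(0); roles <- character(0)
  add <- function(id, role) {
    ids <<- c(ids, id); roles <<- c(roles, role)
  }
  for (s in .STRANDS) add(s, "rna_monomer")
  add("R_P.cR_P", "rna_dimer"); add("R_L.cR_L", "rna_dimer")
  cplx <- list()
  for (s in .STRANDS) {
    nm <- sprintf("RP@%s_%d", s, 0:L[[s]])
    cplx[[s]] <- length(ids) + seq_along(nm)
    for (x in nm) add(x, "rna_complex")
  }
  for (b in 1:4) add(sprintf("NTP_%d", b), "ntp")
  add("W", "waste"); add("P", "precursor"); add("L_aq", "lipid_aqueous")
  add("B", "inert"); add("L_mem", "lipid_membrane")

  n <- length(ids)
  osmotic <- roles != "lipid_membrane"

  strands <- matrix(0L, n, 4, dimnames = list(ids, .STRANDS))
  for (s in .STRANDS) strands[s, s] <- 1L
  strands["R_P.cR_P", c("R_P", "cR_P")] <- 1L
  strands["R_L.cR_L", c("R_L", "cR_L")] <- 1L
  for (s in .STRANDS) {
    idx <- cplx[[s]]
    for (j in 0:L[[s]]) {
      i <- idx[j + 1]
      strands[i, "R_P"] <- strands[i, "R_P"] + 1L  # the bound polymerase
      strands[i, s] <- strands[i, s] + 1L          # the template
      if (j == L[[s]])                             # completed nascent strand
        strands[i, .COMPLEMENT[[s]]] <- strands[i, .COMPLEMENT[[s]]] + 1L
    }
  }

  idx <- list(
    monomers = setNames(match(.STRANDS, ids), .STRANDS),
    dimers = setNames(match(c("R_P.cR_P", "R_L.cR_L"), ids),
                      c("R_P.cR_P", "R_L.cR_L")),
    cplx = cplx,
    ntp = match(sprintf("NTP_%d", 1:4), ids),
    W = match("W", ids), P = match("P", ids), Laq = match("L_aq", ids),
    B = match("B", ids), Lmem = match("L_mem", ids))

  structure(list(
    species = data.frame(id = ids, role = roles, osmotic = osmotic,
                         stringsAsFactors = FALSE),
    strands = strands, idx = idx, L = L,
    n_species = n), class = "species_registry")
}

#' @export
print.species_registry <- function(x, ...) {
  cat("Ribocell species registry:", x$n_species, "species",
      sprintf("(%d aqueous), ribozyme lengths L_P = %d, L_L = %d nt\n",
              sum(x$species$osmotic), x$L[["R_P"]], x$L[["R_L"]]))
  print(table(x$species$role))
  invisible(x)
}
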