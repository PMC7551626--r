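#' Neutral monoisotopic mass of a peptide structure
#'
#' The three topologies differ only in the terminal chemistry added to the
#' residue-mass sum:
#' \describe{
#'   \item{linear-acid}{sum of residues + H2O (conventional peptide).}
#'   \item{linear-aldehyde}{sum of residues + 2H (C-terminal -CHO replaces
#'     -COOH; the reductase-released open-chain form).}
#'   \item{cyclic-imine}{sum of residues + 2H - H2O, i.e. sum - O
#'     (head-to-tail Schiff base; cyclization of the aldehyde loses water).}
#' }
#'
#' @param structure A [peptide_structure()].
#' @param registry A [monomer_registry()].
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(structure, registry = monomer_registry()) {
  stopifnot(inherits(structure, "peptide_structure"))
  k <- registry$constants
  rsum <- sum(vapply(structure$residues, residue_mass, numeric(1),
                     registry = registry))
  switch(structure$topology,
    "linear-acid"     = rsum + k[["H2O"]],
    "linear-aldehyde" = rsum + 2 * k[["H"]],
    "cyclic-imine"    = rsum + 2 * k[["H"]] - k[["H2O"]]
  )
}

#' Precursor m/z of a peptide structure
#'
#' \eqn{(M + z \cdot m_p) / z} for a protonated species. All published
#' nostocyclopeptide ions are singly protonated; higher charges are accepted
#' for generality.
#'
#' @inheritParams neutral_mass
#' @param charge Positive integer charge (default 1).
#' @return Exact m/z in Da; use [nominal_mz()] for the unit-resolution value.
#' @export
precursor_mz <- function(structure, charge = 1L,
                         registry = monomer_registry()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("charge must be a positive integer")
  (neutral_mass(structure, registry) +
     charge * registry$constants[["proton"]]) / charge
}
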