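#' Monoisotopic mass constants
#'
#' Named vector of the monoisotopic masses (Da) used throughout the package:
#' the proton, hydrogen atom, oxygen atom, and the water, ammonia, NH2 and
#' carbon-monoxide neutral-loss masses. All fragment arithmetic is
#' monoisotopic; unit-resolution instruments report nominal m/z values that
#' round from monoisotopic, not average, masses.
#'
#' @format Named numeric vector with elements \code{proton}, \code{H},
#'   \code{O}, \code{H2O}, \code{NH3}, \code{NH2}, \code{CO}, and
#'   \code{immonium_offset} (the residue-to-immonium shift, \eqn{-CO + H}).
#' @export
MASS_CONSTANTS <- c(
  proton = 1.00728,
  H      = 1.00783,
  O      = 15.99491,
  H2O    = 18.01056,
  NH3    = 17.02655,
  NH2    = 16.01872,
  CO     = 27.99491,
  immonium_offset = 26.98763  # CO - proton: immonium = acylium - CO exactly
)

# monoisotopic atomic masses for formula-derived residue masses
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

#' Parse an elemental formula string
#'
#' Accepts formulas over the elements C, H, N, O, S written in Hill-like
#' notation, e.g. \code{"C6H11NO"} or \code{"C5H8N2O2"}.
#'
#' @param formula Character scalar.
#' @return Named integer vector of element counts (C, H, N, O, S).
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  m <- gregexpr("([CHNOS])([0-9]*)", formula, perl = TRUE)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula) || length(tokens) == 0L)
    stop("cannot parse formula: ", formula)
  for (tok in tokens) {
    el <- substr(tok, 1L, 1L)
    n <- if (nchar(tok) > 1L) as.integer(substr(tok, 2L, nchar(tok))) else 1L
    counts[el] <- counts[el] + n
  }
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Character formula string or named count vector as returned
#'   by [parse_formula()].
#' @return Monoisotopic mass in Da.
#' @export
formula_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

# residue (= amino acid minus water) elemental formulas of the building
# blocks observed in nostocyclopeptides; MePro = 4-methylproline,
# HSe = homoserine
.BUILTIN_MONOMERS <- list(
  Gly   = "C2H3NO",
  Ser   = "C3H5NO2",
  Pro   = "C5H7NO",
  Val   = "C5H9NO",
  Ile   = "C6H11NO",
  Leu   = "C6H11NO",
  Gln   = "C5H8N2O2",
  MePro = "C6H9NO",
  Tyr   = "C9H9NO2",
  Phe   = "C9H9NO",
  HSe   = "C4H7NO2"
)

#' Build a monomer registry
#'
#' A registry maps residue tokens (e.g. \code{"Tyr"}, \code{"MePro"}) to
#' monomers carrying an elemental formula and a formula-derived monoisotopic
#' residue mass. The default registry ships with the eleven residues found in
#' nostocyclopeptide structures, including the nonproteinogenic
#' 4-methylproline (\code{MePro}) and homoserine (\code{HSe}). Ile and Leu
#' are registered as distinct monomers with identical mass; their
#' MS-indistinguishability is handled at the candidate-ranking stage, not
#' here.
#'
#' @param extra_tsv Optional path to a TSV with columns \code{name},
#'   \code{formula} and optionally \code{aliases} (comma-separated), loaded
#'   additively over the built-in table.
#' @return An object of class \code{monomer_registry}.
#' @export
monomer_registry <- function(extra_tsv = NULL) {
  reg <- list(monomers = list(), constants = MASS_CONSTANTS)
  class(reg) <- "monomer_registry"
  for (nm in names(.BUILTIN_MONOMERS))
    reg <- register_monomer(reg, nm, .BUILTIN_MONOMERS[[nm]])
  if (!is.null(extra_tsv)) reg <- load_monomer_tsv(reg, extra_tsv)
  reg
}

#' Register a monomer
#'
#' @param registry A [monomer_registry()].
#' @param name Residue token (case-sensitive, unique within the registry).
#' @param formula Elemental formula string over C/H/N/O/S.
#' @param aliases Optional character vector of alternative tokens.
#' @return The updated registry.
#' @export
register_monomer <- function(registry, name, formula, aliases = character()) {
  stopifnot(inherits(registry, "monomer_registry"))
  if (name %in% names(registry$monomers))
    stop("monomer already registered: ", name)
  counts <- parse_formula(formula)
  if (counts["C"] < 1L || counts["N"] < 1L)
    stop("monomer formula must contain at least one C and one N: ", name)
  mass <- formula_mass(counts)
  if (mass <= 0) stop("non-positive residue mass for ", name)
  registry$monomers[[name]] <- list(
    name = name, formula = counts, residue_mass = mass, aliases = aliases
  )
  registry
}

#' Load additional monomers from a TSV file
#'
#' @param registry A [monomer_registry()].
#' @param path TSV with columns \code{name}, \code{formula}, optional
#'   \code{aliases}.
#' @return The updated registry.
#' @export
load_monomer_tsv <- function(registry, path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "formula") %in% names(tab)))
    stop("monomer TSV needs columns 'name' and 'formula'")
  for (i in seq_len(nrow(tab))) {
    aliases <- character()
    if ("aliases" %in% names(tab) && nzchar(tab$aliases[i]))
      aliases <- trimws(strsplit(tab$aliases[i], ",")[[1]])
    registry <- register_monomer(registry, tab$name[i], tab$formula[i], aliases)
  }
  registry
}

# resolve a token (name or alias) to a monomer, or fail loudly
.get_monomer <- function(registry, name) {
  stopifnot(inherits(registry, "monomer_registry"))
  mon <- registry$monomers[[name]]
  if (is.null(mon)) {
    for (m in registry$monomers)
      if (name %in% m$aliases) return(m)
    stop("unknown monomer: ", name)
  }
  mon
}

#' Monoisotopic residue mass of a registered monomer
#'
#' @param name Residue token.
#' @param registry A [monomer_registry()].
#' @return Residue mass in Da.
#' @export
residue_mass <- function(name, registry = monomer_registry()) {
  .get_monomer(registry, name)$residue_mass
}

#' Round an m/z value to its nominal (unit-resolution) integer
#'
#' Rounds half away from zero, the convention that reproduces published
#' unit-resolution ion tables from monoisotopic arithmetic.
#'
#' @param mz Numeric vector of m/z values.
#' @return Integer vector.
#' @export
nominal_mz <- function(mz) as.integer(sign(mz) * floor(abs(mz) + 0.5))

#' Immonium ion m/z of a residue
#'
#' The immonium cation of a residue is its acylium ion minus CO: residue
#' mass minus 26.98763 Da, e.g. nominal 70 for Pro, 84 for MePro and 136 for
#' Tyr.
#'
#' @inheritParams residue_mass
#' @return Exact immonium m/z in Da; apply [nominal_mz()] for the integer.
#' @export
immonium_mz <- function(name, registry = monomer_registry()) {
  residue_mass(name, registry) - registry$constants[["immonium_offset"]]
}

#' Diagnostic (residue-characteristic) ions of a residue
#'
#' Returns the low-mass diagnostic set used in manual spectrum reading: the
#' acylium ion (residue + proton), the immonium ion, the immonium minus
#' ammonia, and the residue minus NH2 plus proton. For Gln this reproduces
#' the characteristic nominal triplet 129/101/84 plus 113; for Tyr it
#' includes nominal 148 ([Tyr-NH2]).
#'
#' @inheritParams residue_mass
#' @return data.frame with columns \code{label}, \code{mz}, \code{nominal}.
#' @export
related_ions <- function(name, registry = monomer_registry()) {
  rm <- residue_mass(name, registry)
  k <- registry$constants
  mz <- c(
    rm + k[["proton"]],                          # acylium
    rm - k[["immonium_offset"]],                 # immonium
    rm - k[["immonium_offset"]] - k[["NH3"]],    # immonium - NH3
    rm - k[["NH2"]] + k[["proton"]]              # residue - NH2
  )
  data.frame(
    label = c(
      sprintf("[%s+H]", name),
      sprintf("%s immonium", name),
      sprintf("%s immonium-NH3", name),
      sprintf("[%s-NH2]", name)
    ),
    mz = mz,
    nominal = nominal_mz(mz),
    stringsAsFactors = FALSE
  )
}

#' @export
print.monomer_registry <- function(x, ...) {
  cat("monomer_registry with", length(x$monomers), "monomers:\n")
  for (m in x$monomers)
    cat(sprintf("  %-6s %-10s %10.5f Da\n", m$name,
                paste0(names(m$formula)[m$formula > 0],
                       ifelse(m$formula[m$formula > 0] > 1,
                              m$formula[m$formula > 0], ""), collapse = ""),
                m$residue_mass))
  invisible(x)
}
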