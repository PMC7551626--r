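#' Peptide structure with topology
#'
#' A peptide structure is an ordered residue list plus one of three
#' topologies: \code{"linear-acid"} (free carboxyl C-terminus),
#' \code{"linear-aldehyde"} (the reductively released open-chain form with a
#' C-terminal -CHO), or \code{"cyclic-imine"} (the head-to-tail macrocycle
#' formed when the C-terminal aldehyde condenses with the N-terminal amine,
#' losing water).
#'
#' @param residues Character vector of residue tokens, in sequence order.
#' @param topology One of \code{"linear-acid"}, \code{"linear-aldehyde"},
#'   \code{"cyclic-imine"}.
#' @param name Optional label (e.g. \code{"Ncp-A1"}).
#' @param registry A [monomer_registry()] used to validate the tokens.
#' @return Object of class \code{peptide_structure}.
#' @export
peptide_structure <- function(residues, topology, name = NULL,
                              registry = monomer_registry()) {
  topology <- match.arg(topology,
                        c("linear-acid", "linear-aldehyde", "cyclic-imine"))
  if (length(residues) < 1L) stop("residue list is empty")
  if (topology == "cyclic-imine" && length(residues) < 2L)
    stop("a cyclic imine needs at least 2 residues")
  for (r in residues) .get_monomer(registry, r)  # errors on unknown tokens
  structure(
    list(residues = as.character(residues), topology = topology, name = name),
    class = "peptide_structure"
  )
}

#' Parse a structure string
#'
#' Understands the field notation used for nostocyclopeptides:
#' \code{"cyclo[Tyr+Gly+Gln+Ile+Ser+MePro+Leu]"} for the cyclic imine, and a
#' bare \code{"+"}-joined residue list for linear forms. Linear forms need a
#' C-terminus chemistry; the default is \code{"aldehyde"} (the open-chain
#' congeners of cyclic imines are peptide aldehydes) and a warning is issued
#' when the default is silently used, because free-acid linear peptides
#' (such as proteolytic hexapeptide fragments) must be parsed with
#' \code{terminus = "acid"}.
#'
#' @param text Structure string.
#' @param terminus \code{"aldehyde"} or \code{"acid"}; only used for linear
#'   input.
#' @param name Optional label attached to the structure.
#' @param registry A [monomer_registry()].
#' @param warn_default_terminus Warn when a linear structure is parsed with
#'   the defaulted terminus (default TRUE).
#' @return A [peptide_structure()].
#' @export
parse_structure <- function(text, terminus = c("aldehyde", "acid"),
                            name = NULL, registry = monomer_registry(),
                            warn_default_terminus = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  terminus_missing <- missing(terminus)
  terminus <- match.arg(terminus)
  txt <- trimws(text)
  if (!nzchar(txt)) stop("empty structure string")
  cyclic <- grepl("^cyclo\\[", txt)
  if (cyclic) {
    if (!grepl("\\]$", txt)) stop("unbalanced brackets in structure: ", text)
    inner <- sub("^cyclo\\[", "", sub("\\]$", "", txt))
  } else {
    if (grepl("[\\[\\]]", txt)) stop("unexpected bracket in structure: ", text)
    inner <- txt
  }
  tokens <- trimws(strsplit(inner, "+", fixed = TRUE)[[1]])
  if (length(tokens) == 0L || any(!nzchar(tokens)))
    stop("malformed residue list in structure: ", text)
  topology <- if (cyclic) "cyclic-imine"
              else if (terminus == "aldehyde") "linear-aldehyde"
              else "linear-acid"
  if (!cyclic && terminus_missing && warn_default_terminus)
    warning("linear structure parsed with default terminus = 'aldehyde'; ",
            "pass terminus = 'acid' for free-acid peptides")
  peptide_structure(tokens, topology, name = name, registry = registry)
}

#' Render a structure back to its canonical string
#'
#' @param structure A [peptide_structure()].
#' @return Character scalar; \code{render(parse(s))} round-trips for the
#'   canonical notation.
#' @export
render_structure <- function(structure) {
  stopifnot(inherits(structure, "peptide_structure"))
  body <- paste(structure$residues, collapse = "+")
  if (structure$topology == "cyclic-imine") paste0("cyclo[", body, "]") else body
}

#' @export
print.peptide_structure <- function(x, ...) {
  cat(sprintf("%s (%s, %d residues)%s\n", render_structure(x), x$topology,
              length(x$residues),
              if (!is.null(x$name)) paste0(" [", x$name, "]") else ""))
  invisible(x)
}

#' Nostocyclopeptide structures detected in the study strain
#'
#' The ten nostocyclopeptides (Ncps) characterized from \emph{Nostoc
#' edaphicum} CCNP1411 plus Ncp-M1 (from \emph{Nostoc} sp. XSPORK 13A), as
#' structure strings with their topologies. Ncp-E4-L is the single free-acid
#' linear hexapeptide; all other linear forms are peptide aldehydes.
#'
#' @param registry A [monomer_registry()].
#' @param include_m1 Include the foreign-strain Ncp-M1 scaffold (default
#'   TRUE).
#' @return Named list of [peptide_structure()] objects.
#' @export
ncp_structures <- function(registry = monomer_registry(), include_m1 = TRUE) {
  spec <- list(
    "Ncp-A1"   = list("cyclo[Tyr+Gly+Gln+Ile+Ser+MePro+Leu]", NA),
    "Ncp-A1-L" = list("Tyr+Gly+Gln+Ile+Ser+MePro+Leu", "aldehyde"),
    "Ncp-A2"   = list("cyclo[Tyr+Gly+Gln+Ile+Ser+MePro+Phe]", NA),
    "Ncp-A2-L" = list("Tyr+Gly+Gln+Ile+Ser+MePro+Phe", "aldehyde"),
    "Ncp-E1"   = list("cyclo[Tyr+Gly+Gln+Ile+Ser+Pro+Phe]", NA),
    "Ncp-E1-L" = list("Tyr+Gly+Gln+Ile+Ser+Pro+Phe", "aldehyde"),
    "Ncp-E2"   = list("cyclo[Tyr+Gly+Gln+Ile+Ser+Pro+Leu]", NA),
    "Ncp-E2-L" = list("Tyr+Gly+Gln+Ile+Ser+Pro+Leu", "aldehyde"),
    "Ncp-E3"   = list("cyclo[Tyr+Gly+Gln+Val+Ser+MePro+Leu]", NA),
    "Ncp-E4-L" = list("Tyr+Gly+Gln+Ile+Ser+MePro", "acid"),
    "Ncp-M1"   = list("cyclo[Tyr+Tyr+HSe+Pro+Val+MePro+Tyr]", NA)
  )
  if (!include_m1) spec$`Ncp-M1` <- NULL
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    if (is.na(s[[2]]))
      parse_structure(s[[1]], name = nm, registry = registry)
    else
      parse_structure(s[[1]], terminus = s[[2]], name = nm,
                      registry = registry)
  })
  names(out) <- names(spec)
  out
}
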