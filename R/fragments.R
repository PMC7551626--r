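#' Fragment enumeration configuration
#'
#' Controls which ion families are generated and how deep the neutral-loss
#' combinatorics go. The defaults reproduce the ion families seen in
#' unit-resolution CID spectra of nostocyclopeptides: b/y series, internal
#' acylium fragments, ring-opened spans, residue losses off the precursor,
#' immonium/diagnostic ions, and up to two combined neutral losses (H2O may
#' occur twice; NH3 and CO at most once).
#'
#' @param max_combined_losses Maximum number of combined neutral losses per
#'   ion (default 2).
#' @param residue_loss_k Composite residue losses cover up to this many
#'   consecutive residues (default 2).
#' @param include_a Emit a ions (b - CO) explicitly; identical species also
#'   arise as b with a CO loss and are de-duplicated (default TRUE).
#' @param include_internal Emit internal acylium fragments (default TRUE).
#' @param include_diagnostics Emit immonium/diagnostic ions per distinct
#'   residue (default TRUE).
#' @param include_precursor Emit the precursor ion (default TRUE).
#' @param include_residue_loss Emit residue-loss ions (default TRUE).
#' @return Object of class \code{fragment_config}.
#' @export
fragment_config <- function(max_combined_losses = 2L,
                            residue_loss_k = 2L,
                            include_a = TRUE,
                            include_internal = TRUE,
                            include_diagnostics = TRUE,
                            include_precursor = TRUE,
                            include_residue_loss = TRUE) {
  stopifnot(max_combined_losses >= 0L, residue_loss_k >= 0L)
  structure(
    list(max_combined_losses = as.integer(max_combined_losses),
         residue_loss_k = as.integer(residue_loss_k),
         include_a = include_a,
         include_internal = include_internal,
         include_diagnostics = include_diagnostics,
         include_precursor = include_precursor,
         include_residue_loss = include_residue_loss),
    class = "fragment_config"
  )
}

# kind priority used for deterministic ordering and matching tie-breaks:
# b > y > a > internal > residue-loss > precursor-loss > diagnostic;
# the intact precursor outranks everything.
.kind_priority <- function(kind, n_losses) {
  base <- c(precursor = 6, b = 1, y = 2, a = 3, internal = 4,
            "residue-loss" = 5, immonium = 7, diagnostic = 7)
  p <- unname(base[kind])
  p[kind == "precursor" & n_losses == 0L] <- 0
  p
}

.empty_fragments <- function() {
  data.frame(kind = character(), start = integer(), length = integer(),
             residues = character(), label = character(),
             losses = character(), n_losses = integer(),
             mz = numeric(), nominal = integer(), stringsAsFactors = FALSE)
}

.fragment_row <- function(kind, start, length, residues, label, mz) {
  data.frame(kind = kind, start = as.integer(start),
             length = as.integer(length),
             residues = residues, label = label, losses = "",
             n_losses = 0L, mz = mz, nominal = nominal_mz(mz),
             stringsAsFactors = FALSE)
}

# ring-aware span token extraction: positions wrap modulo n
.span_positions <- function(start, length, n) ((start - 1L + seq_len(length) - 1L) %% n) + 1L

#' Apply neutral-loss combinatorics to fragment ions
#'
#' Generates loss variants subtracting multisets over \{H2O (at most twice),
#' NH3 (at most once), CO (at most once)\} with at most
#' \code{config$max_combined_losses} combined losses. Only ions without
#' existing losses are expanded; immonium/diagnostic ions are never expanded.
#'
#' @param ions Fragment data.frame as produced by the enumeration functions.
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return data.frame of the loss variants only (possibly zero rows).
#' @export
apply_neutral_losses <- function(ions, config = fragment_config(),
                                 registry = monomer_registry()) {
  k <- registry$constants
  eligible <- ions[ions$n_losses == 0L &
                     ions$kind %in% c("b", "y", "internal",
                                      "precursor", "residue-loss"), ,
                   drop = FALSE]
  max_l <- config$max_combined_losses
  if (max_l == 0L || nrow(eligible) == 0L) return(.empty_fragments())
  combos <- expand.grid(h2o = 0:2, nh3 = 0:1, co = 0:1)
  combos$total <- combos$h2o + combos$nh3 + combos$co
  combos <- combos[combos$total >= 1L & combos$total <= max_l, , drop = FALSE]
  out <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    loss_mass <- cb$h2o * k[["H2O"]] + cb$nh3 * k[["NH3"]] + cb$co * k[["CO"]]
    parts <- c(
      if (cb$h2o == 1) "H2O" else if (cb$h2o == 2) "2H2O",
      if (cb$nh3 == 1) "NH3",
      if (cb$co == 1) "CO"
    )
    loss_str <- paste(parts, collapse = "+")
    suffix <- paste0("-", parts, collapse = "")
    v <- eligible
    v$mz <- v$mz - loss_mass
    v$nominal <- nominal_mz(v$mz)
    v$losses <- loss_str
    v$n_losses <- as.integer(cb$total)
    v$label <- sub("\\]$", paste0(suffix, "]"), v$label)
    v[v$mz > 0, , drop = FALSE]
  })
  do.call(rbind, out)
}

#' Residue-loss ions off the precursor
#'
#' Ions of the form [M+H - X] where X is a residue's topology-effective
#' mass: the plain residue for interior or N-terminal positions, residue +
#' 2H when X is the aldehyde-bearing terminal residue of a linear aldehyde,
#' residue + H2O for the acid terminus, and residue - O when X is the
#' imine-carbon residue (position n) of a cyclic imine. Composite losses of
#' up to \code{config$residue_loss_k} consecutive residues are included:
#' N-terminal runs for linear structures, any contiguous ring run for cyclic
#' ones.
#'
#' @param structure A [peptide_structure()].
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return Fragment data.frame of kind \code{"residue-loss"}.
#' @export
residue_loss_ions <- function(structure, config = fragment_config(),
                              registry = monomer_registry()) {
  stopifnot(inherits(structure, "peptide_structure"))
  k <- registry$constants
  res <- structure$residues
  n <- length(res)
  masses <- vapply(res, residue_mass, numeric(1), registry = registry)
  prec <- precursor_mz(structure, 1L, registry)
  cyclic <- structure$topology == "cyclic-imine"
  topo <- structure$topology

  runs <- list()
  # single-residue losses at every position
  for (i in seq_len(n)) runs[[length(runs) + 1L]] <- c(i, 1L)
  # composite losses of consecutive residues
  if (config$residue_loss_k >= 2L && n >= 2L) {
    if (cyclic) {
      for (len in 2:min(config$residue_loss_k, n - 1L))
        for (s in seq_len(n)) runs[[length(runs) + 1L]] <- c(s, len)
    } else {
      for (len in 2:min(config$residue_loss_k, n - 1L))
        runs[[length(runs) + 1L]] <- c(1L, len)
    }
  }

  rows <- lapply(runs, function(r) {
    s <- r[1]; len <- r[2]
    pos <- .span_positions(s, len, n)
    eff <- sum(masses[pos])
    if (cyclic) {
      if (n %in% pos) eff <- eff - k[["O"]]
    } else if (n %in% pos) {
      eff <- eff + if (topo == "linear-aldehyde") 2 * k[["H"]] else k[["H2O"]]
    }
    mz <- prec - eff
    if (mz <= 0) return(NULL)
    lost <- paste(res[pos], collapse = "+")
    label <- if (len == 1L) sprintf("[M+H-%s]", lost)
             else sprintf("[M+H-(%s)]", lost)
    # the surviving ion is the complement span; contiguous complements are
    # recorded with their span so equivalent b/y species de-duplicate
    comp_pos <- setdiff(seq_len(n), pos)
    contiguous <- FALSE
    comp_start <- NA_integer_
    if (length(comp_pos) > 0L) {
      if (cyclic) {
        comp_start <- ((s + len - 1L) %% n) + 1L
        contiguous <- TRUE
      } else if (all(diff(comp_pos) == 1L)) {
        comp_start <- comp_pos[1]
        contiguous <- TRUE
      }
    }
    tokens <- if (contiguous)
      paste(res[.span_positions(comp_start, n - len, n)], collapse = "+")
    else paste(res[comp_pos], collapse = "+")
    .fragment_row("residue-loss", if (contiguous) comp_start else NA_integer_,
                  n - len, tokens, label, mz)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(.empty_fragments())
  do.call(rbind, rows)
}

.diagnostic_ions <- function(structure, registry) {
  res <- unique(structure$residues)
  rows <- lapply(res, function(r) {
    tab <- related_ions(r, registry)
    kinds <- c("diagnostic", "immonium", "diagnostic", "diagnostic")
    data.frame(kind = kinds, start = NA_integer_, length = 1L,
               residues = r, label = tab$label, losses = "", n_losses = 0L,
               mz = tab$mz, nominal = tab$nominal, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# order deterministically and drop rows that describe the same species:
# same residue composition, same span start and same m/z (1e-4 Da)
.finalize_fragments <- function(frags) {
  if (nrow(frags) == 0L) return(frags)
  pri <- .kind_priority(frags$kind, frags$n_losses)
  ord <- order(pri, frags$n_losses, ifelse(is.na(frags$start), 0L, frags$start),
               frags$length, frags$mz)
  frags <- frags[ord, , drop = FALSE]
  key <- paste(sprintf("%.4f", frags$mz),
               vapply(strsplit(frags$residues, "+", fixed = TRUE),
                      function(t) paste(sort(t), collapse = "+"), character(1)),
               ifelse(is.na(frags$start), "x", frags$start))
  frags <- frags[!duplicated(key), , drop = FALSE]
  rownames(frags) <- NULL
  frags
}

.assemble <- function(base, structure, config, registry) {
  parts <- list(base)
  if (config$include_residue_loss)
    parts[[length(parts) + 1L]] <- residue_loss_ions(structure, config, registry)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  pool <- if (length(parts)) do.call(rbind, parts) else .empty_fragments()
  losses <- apply_neutral_losses(pool, config, registry)
  if (config$include_diagnostics)
    parts[[length(parts) + 1L]] <- .diagnostic_ions(structure, registry)
  .finalize_fragments(rbind(do.call(rbind, parts), losses))
}

#' Theoretical fragment ions of a linear peptide
#'
#' Enumerates the b series (prefix acylium ions, \eqn{b_i = \sum_{1..i} +
#' proton}), the y series with the structure's C-terminal chemistry
#' (\eqn{y_j = \sum_{n-j+1..n} + terminus + proton}, terminus = H2O for the
#' acid and 2H for the aldehyde), a ions (b - CO), internal acylium
#' fragments, residue-loss ions, neutral-loss variants and
#' immonium/diagnostic ions, per the configuration. \eqn{b_n} is not emitted
#' (it duplicates precursor-derived species).
#'
#' @param structure A linear [peptide_structure()].
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return data.frame with columns kind, start, length, residues, label,
#'   losses, n_losses, mz, nominal.
#' @export
linear_fragments <- function(structure, config = fragment_config(),
                             registry = monomer_registry()) {
  stopifnot(inherits(structure, "peptide_structure"))
  if (structure$topology == "cyclic-imine")
    stop("cyclic structure: use cyclic_fragments()")
  k <- registry$constants
  res <- structure$residues
  n <- length(res)
  masses <- vapply(res, residue_mass, numeric(1), registry = registry)
  terminus <- if (structure$topology == "linear-aldehyde") 2 * k[["H"]]
              else k[["H2O"]]
  rows <- list()
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {                                   # b series
      mz <- sum(masses[1:i]) + k[["proton"]]
      rows[[length(rows) + 1L]] <- .fragment_row(
        "b", 1L, i, paste(res[1:i], collapse = "+"),
        sprintf("[%s+H]", paste(res[1:i], collapse = "+")), mz)
    }
    for (j in 1:(n - 1L)) {                                   # y series
      pos <- (n - j + 1L):n
      mz <- sum(masses[pos]) + terminus + k[["proton"]]
      lab <- if (structure$topology == "linear-aldehyde")
        sprintf("[%s+2H]", paste(res[pos], collapse = "+"))
      else sprintf("[%s+H2O+H]", paste(res[pos], collapse = "+"))
      rows[[length(rows) + 1L]] <- .fragment_row(
        "y", n - j + 1L, j, paste(res[pos], collapse = "+"), lab, mz)
    }
    if (config$include_a) {
      for (i in 1:(n - 1L)) {                                 # a = b - CO
        mz <- sum(masses[1:i]) + k[["proton"]] - k[["CO"]]
        rows[[length(rows) + 1L]] <- .fragment_row(
          "a", 1L, i, paste(res[1:i], collapse = "+"),
          sprintf("[%s+H-CO]", paste(res[1:i], collapse = "+")), mz)
      }
    }
  }
  if (config$include_internal && n >= 3L) {
    for (i in 2:(n - 1L)) for (j in i:(n - 1L)) {             # internal acylium
      mz <- sum(masses[i:j]) + k[["proton"]]
      rows[[length(rows) + 1L]] <- .fragment_row(
        "internal", i, j - i + 1L, paste(res[i:j], collapse = "+"),
        sprintf("[%s+H]", paste(res[i:j], collapse = "+")), mz)
    }
  }
  if (config$include_precursor) {
    rows[[length(rows) + 1L]] <- .fragment_row(
      "precursor", 1L, n, paste(res, collapse = "+"), "[M+H]",
      precursor_mz(structure, 1L, registry))
  }
  .assemble(do.call(rbind, rows), structure, config, registry)
}

#' Theoretical fragment ions of a cyclic imine
#'
#' Ring opening of a head-to-tail cyclic imine under CID produces b-type
#' (acylium) ions: every contiguous ring span of length 1..n-1 gives
#' \eqn{\sum span + proton}, with one oxygen (15.99491 Da) subtracted when
#' the span contains residue n, whose carbonyl carbon is the imine CH. The
#' full-ring span is the precursor. Residue-loss, neutral-loss and
#' immonium/diagnostic ions are added per the configuration.
#'
#' @param structure A cyclic-imine [peptide_structure()].
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return data.frame as for [linear_fragments()].
#' @export
cyclic_fragments <- function(structure, config = fragment_config(),
                             registry = monomer_registry()) {
  stopifnot(inherits(structure, "peptide_structure"))
  if (structure$topology != "cyclic-imine")
    stop("linear structure: use linear_fragments()")
  k <- registry$constants
  res <- structure$residues
  n <- length(res)
  masses <- vapply(res, residue_mass, numeric(1), registry = registry)
  rows <- list()
  for (len in 1:(n - 1L)) for (s in seq_len(n)) {
    pos <- .span_positions(s, len, n)
    mz <- sum(masses[pos]) + k[["proton"]]
    if (n %in% pos) mz <- mz - k[["O"]]
    rows[[length(rows) + 1L]] <- .fragment_row(
      "b", s, len, paste(res[pos], collapse = "+"),
      sprintf("[%s+H]", paste(res[pos], collapse = "+")), mz)
  }
  if (config$include_precursor) {
    rows[[length(rows) + 1L]] <- .fragment_row(
      "precursor", 1L, n, paste(res, collapse = "+"), "[M+H]",
      precursor_mz(structure, 1L, registry))
  }
  .assemble(do.call(rbind, rows), structure, config, registry)
}

#' Theoretical fragment ions, dispatched on topology
#'
#' @inheritParams linear_fragments
#' @return data.frame as for [linear_fragments()].
#' @export
fragment_ions <- function(structure, config = fragment_config(),
                          registry = monomer_registry()) {
  if (structure$topology == "cyclic-imine")
    cyclic_fragments(structure, config, registry)
  else linear_fragments(structure, config, registry)
}

#' Residue tokens encoded in a fragment label
#'
#' Inverse of the labeling convention: extracts the residue composition from
#' a label such as \code{"[Tyr+Gly+Gln+H-CO]"} or \code{"[M+H-(Tyr+Gly)]"}.
#' For precursor-derived labels the composition is the loss complement and
#' \code{NA} is returned (composition equals the full structure minus the
#' named losses).
#'
#' @param label Character vector of labels.
#' @return List of character vectors of residue tokens (NA for
#'   precursor-derived labels).
#' @export
label_tokens <- function(label) {
  lapply(label, function(l) {
    if (grepl("^\\[M\\+H", l)) return(NA_character_)
    if (grepl(" immonium", l)) return(sub(" immonium.*$", "", l))
    body <- sub("^\\[", "", sub("\\]$", "", l))
    body <- sub("(-(2?H2O|NH3|CO|NH2))+$", "", body)
    toks <- strsplit(body, "+", fixed = TRUE)[[1]]
    toks[!toks %in% c("H", "2H", "H2O")]
  })
}

#' Write a theoretical-ion table to TSV
#'
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
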