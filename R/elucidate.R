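#' Candidate template over variable positions
#'
#' Describes a combinatorial family of candidate structures: per-position
#' residue sets plus the allowed topologies. Nostocyclopeptides vary mainly
#' at positions 4, 6 and 7 of a conserved heptapeptide scaffold, giving the
#' default template Tyr-Gly-Gln-\{Ile,Val\}-Ser-\{MePro,Pro\}-\{Leu,Phe\}
#' in both the linear-aldehyde and cyclic-imine topologies (16 candidates).
#'
#' @param positions List of character vectors, one per residue position.
#' @param topologies Character vector of allowed topologies.
#' @return Object of class \code{candidate_template}.
#' @export
candidate_template <- function(positions,
                               topologies = c("linear-aldehyde",
                                              "cyclic-imine")) {
  stopifnot(is.list(positions), length(positions) >= 1L)
  if (any(vapply(positions, length, integer(1)) == 0L))
    stop("every position set must be non-empty")
  topologies <- match.arg(topologies,
                          c("linear-acid", "linear-aldehyde", "cyclic-imine"),
                          several.ok = TRUE)
  structure(list(positions = positions, topologies = topologies),
            class = "candidate_template")
}

#' The default nostocyclopeptide candidate template
#'
#' @return A [candidate_template()] with pos4 in \{Ile, Val\}, pos6 in
#'   \{MePro, Pro\}, pos7 in \{Leu, Phe\}, both open-chain aldehyde and
#'   cyclic-imine topologies.
#' @export
ncp_template <- function() {
  candidate_template(
    positions = list("Tyr", "Gly", "Gln", c("Ile", "Val"), "Ser",
                     c("MePro", "Pro"), c("Leu", "Phe")),
    topologies = c("linear-aldehyde", "cyclic-imine")
  )
}

#' Enumerate candidate structures from a template
#'
#' Cartesian product of the per-position residue sets and the allowed
#' topologies, in deterministic order (topologies outermost, then positions
#' with the last position varying fastest).
#'
#' @param template A [candidate_template()].
#' @param registry A [monomer_registry()].
#' @return List of [peptide_structure()] objects.
#' @export
enumerate_candidates <- function(template, registry = monomer_registry()) {
  stopifnot(inherits(template, "candidate_template"))
  grids <- rev(template$positions)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  combos <- combos[, rev(seq_along(grids)), drop = FALSE]
  out <- list()
  for (topo in template$topologies) {
    for (i in seq_len(nrow(combos))) {
      res <- as.character(unlist(combos[i, ]))
      out[[length(out) + 1L]] <- peptide_structure(res, topo,
                                                   registry = registry)
    }
  }
  out
}

# canonical residue string under Ile/Leu mass equivalence
.xle_key <- function(structure) {
  res <- structure$residues
  res[res %in% c("Ile", "Leu")] <- "Xle"
  paste(structure$topology, paste(res, collapse = "+"))
}

#' Rank candidate structures against an observed spectrum
#'
#' Each candidate is annotated via the spectrum matcher and candidates are
#' sorted by explained-intensity fraction (descending), then explained-peak
#' fraction (descending), then fewer theoretical ions, then lexicographic
#' residue string. Because Ile and Leu are isobaric and indistinguishable at
#' unit resolution, candidates differing only by Ile/Leu swaps may be
#' collapsed into equivalence classes.
#'
#' @param spec A [ms_spectrum()].
#' @param candidates List of [peptide_structure()] objects (or a
#'   [candidate_template()], which is enumerated first).
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @param tolerance Matching tolerance in Da.
#' @param collapse_xle Collapse Ile/Leu-equivalent candidates into classes
#'   (default TRUE).
#' @return Object of class \code{candidate_ranking}: a data.frame
#'   \code{table} with one row per candidate in rank order (rank, structure,
#'   topology, score_intensity, score_count, n_theory, explained, class_id)
#'   and the list of candidate structures in the same order.
#' @export
rank_candidates <- function(spec, candidates, config = fragment_config(),
                            registry = monomer_registry(), tolerance = 0.5,
                            collapse_xle = TRUE) {
  if (inherits(candidates, "candidate_template"))
    candidates <- enumerate_candidates(candidates, registry)
  if (length(candidates) == 0L) stop("empty candidate list")
  ann <- lapply(candidates, function(s)
    annotate(spec, s, config, registry, tolerance)$match)
  tab <- data.frame(
    structure = vapply(candidates, render_structure, character(1)),
    topology = vapply(candidates, function(s) s$topology, character(1)),
    score_intensity = vapply(ann, function(m) m$score_intensity, numeric(1)),
    score_count = vapply(ann, function(m) m$score_count, numeric(1)),
    n_theory = vapply(ann, function(m) m$n_theory, integer(1)),
    explained = vapply(ann, function(m) nrow(m$assignments), integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(-tab$score_intensity, -tab$score_count, tab$n_theory,
               tab$structure)
  tab <- tab[ord, , drop = FALSE]
  candidates <- candidates[ord]
  ann <- ann[ord]
  keys <- vapply(candidates, .xle_key, character(1))
  if (collapse_xle) {
    class_id <- integer(length(keys))
    seen <- character()
    for (i in seq_along(keys)) {
      j <- match(keys[i], seen)
      if (is.na(j)) { seen <- c(seen, keys[i]); j <- length(seen) }
      class_id[i] <- j
    }
  } else class_id <- seq_along(keys)
  tab$class_id <- class_id
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tied <- duplicated(tab[, c("score_intensity", "score_count")]) |
    duplicated(tab[, c("score_intensity", "score_count")], fromLast = TRUE)
  tab$tied <- tied
  structure(list(table = tab, candidates = candidates, matches = ann,
                 collapse_xle = collapse_xle),
            class = "candidate_ranking")
}

#' @export
print.candidate_ranking <- function(x, ...) {
  cat("candidate_ranking over", nrow(x$table), "candidates\n")
  print(utils::head(x$table[, c("rank", "structure", "topology",
                                "score_intensity", "score_count",
                                "class_id")], 8))
  invisible(x)
}

#' Members of the top-ranked equivalence class
#'
#' @param ranking A [rank_candidates()] result.
#' @return data.frame of rows belonging to the first-ranked class.
#' @export
top_class <- function(ranking) {
  stopifnot(inherits(ranking, "candidate_ranking"))
  ranking$table[ranking$table$class_id == ranking$table$class_id[1], ,
                drop = FALSE]
}

#' Homologous fragment m/z shifts between two structures
#'
#' For two structures of equal length and topology, pairs each fragment of A
#' with the homologous fragment of B (same kind, span and losses) and
#' reports the m/z shift. A single residue substitution shifts every
#' fragment whose span contains the substituted position by the residue-mass
#' difference (e.g. MePro to Pro: -14.0157 Da on every such fragment).
#'
#' @param structure_a,structure_b [peptide_structure()] objects of equal
#'   length and topology.
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return data.frame with columns kind, start, length, label_a, label_b,
#'   mz_a, mz_b, shift, nominal_shift.
#' @export
mass_shift_check <- function(structure_a, structure_b,
                             config = fragment_config(),
                             registry = monomer_registry()) {
  stopifnot(inherits(structure_a, "peptide_structure"),
            inherits(structure_b, "peptide_structure"))
  if (length(structure_a$residues) != length(structure_b$residues))
    stop("structures differ in length")
  if (structure_a$topology != structure_b$topology)
    stop("structures differ in topology")
  fa <- fragment_ions(structure_a, config, registry)
  fb <- fragment_ions(structure_b, config, registry)
  # only span-bearing ions are positionally homologous; immonium/diagnostic
  # ions and non-contiguous residue losses carry no span
  fa <- fa[!is.na(fa$start) & !fa$kind %in% c("immonium", "diagnostic"), ,
           drop = FALSE]
  fb <- fb[!is.na(fb$start) & !fb$kind %in% c("immonium", "diagnostic"), ,
           drop = FALSE]
  key <- function(f) paste(f$kind, f$start, f$length, f$losses)
  fa$k <- key(fa); fb$k <- key(fb)
  fa <- fa[!duplicated(fa$k), , drop = FALSE]
  fb <- fb[!duplicated(fb$k), , drop = FALSE]
  m <- match(fa$k, fb$k)
  ok <- !is.na(m)
  out <- data.frame(
    kind = fa$kind[ok], start = fa$start[ok], length = fa$length[ok],
    label_a = fa$label[ok], label_b = fb$label[m[ok]],
    mz_a = fa$mz[ok], mz_b = fb$mz[m[ok]],
    stringsAsFactors = FALSE
  )
  out$shift <- out$mz_b - out$mz_a
  out$nominal_shift <- nominal_mz(out$mz_b) - nominal_mz(out$mz_a)
  out
}

#' Write a candidate ranking as TSV
#'
#' @param ranking A [rank_candidates()] result.
#' @param path Output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(ranking$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
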