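#' A-domain binding-pocket signature
#'
#' The specificity-conferring code of an NRPS adenylation domain: the nine
#' binding-pocket residues at GrsA (gramicidin S synthetase phenylalanine
#' activating domain) positions 235, 236, 239, 278, 299, 301, 322, 330 and
#' 331, written as a 9-letter uppercase string.
#'
#' @param residues 9-character uppercase string over the 20-letter amino
#'   acid alphabet.
#' @param module_name Optional module label (e.g. \code{"NcpB2"}).
#' @return Object of class \code{adomain_signature}.
#' @export
adomain_signature <- function(residues, module_name = "") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(trimws(residues))
  if (nchar(residues) != 9L)
    stop("signature must have exactly 9 residues, got ", nchar(residues))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]{9}$", residues))
    stop("signature contains non-amino-acid letters: ", residues)
  structure(list(module_name = module_name, residues = residues),
            class = "adomain_signature")
}

#' GrsA positions of the nine signature residues
#' @return Integer vector of length 9.
#' @export
grsa_positions <- function() c(235L, 236L, 239L, 278L, 299L, 301L, 322L,
                               330L, 331L)

.as_signature <- function(x) {
  if (inherits(x, "adomain_signature")) x else adomain_signature(x)
}

#' Identity fraction between two signatures
#'
#' Plain position-wise identity over the nine binding-pocket residues. The
#' nonribosomal code is a lookup, not a learned model, so no substitution
#' matrix is applied by default; a matrix can be supplied for weighted
#' scoring.
#'
#' @param a,b Signatures (strings or [adomain_signature()] objects).
#' @param matrix Optional 20x20 substitution matrix with dimnames over the
#'   amino-acid alphabet; when supplied the score is the normalized matrix
#'   similarity instead of the identity fraction.
#' @return Similarity in [0, 1].
#' @export
signature_similarity <- function(a, b, matrix = NULL) {
  a <- .as_signature(a); b <- .as_signature(b)
  ca <- strsplit(a$residues, "")[[1]]
  cb <- strsplit(b$residues, "")[[1]]
  if (is.null(matrix)) return(sum(ca == cb) / 9)
  raw <- sum(vapply(seq_len(9), function(i) matrix[ca[i], cb[i]], numeric(1)))
  self_a <- sum(vapply(ca, function(x) matrix[x, x], numeric(1)))
  self_b <- sum(vapply(cb, function(x) matrix[x, x], numeric(1)))
  max(0, raw / max(self_a, self_b))
}

#' Load a reference code table
#'
#' Reads a TSV of (module, signature, substrate, brackets, source) rows.
#' With no path, the packaged table is loaded: the seven adenylation-domain
#' signatures of the nostocyclopeptide synthetase modules NcpA1-NcpB4 with
#' their proposed substrates. The \code{brackets} column lists GrsA
#' positions at which the strain's residue differs from the ATCC 53789
#' reference synthetase.
#'
#' @param path Optional TSV path; users can extend the packaged table with
#'   further published codes.
#' @return Object of class \code{reference_code} (a data.frame).
#' @export
ncp_reference_code <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "adomain_reference.tsv",
                        package = "ncptools", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("module", "signature", "substrate")
  if (!all(need %in% names(tab)))
    stop("reference TSV needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab[, c("signature", "substrate")]))
    stop("duplicate (signature, substrate) pair in reference code")
  for (s in tab$signature) adomain_signature(s)  # validate
  class(tab) <- c("reference_code", "data.frame")
  tab
}

#' Predict the substrate of an A domain from its signature
#'
#' Ranks reference entries by signature identity and reports the top
#' matches. Ties are ordered alphabetically by substrate label for
#' determinism. An exact signature match returns similarity 1.0.
#'
#' @param query Signature (string or [adomain_signature()]).
#' @param reference A [ncp_reference_code()] table.
#' @param top_k Number of entries to report (default 3).
#' @param matrix Optional substitution matrix passed to
#'   [signature_similarity()].
#' @return Object of class \code{substrate_prediction}: data.frame with
#'   columns module, substrate, similarity, sorted by similarity descending.
#' @export
predict_substrate <- function(query, reference = ncp_reference_code(),
                              top_k = 3L, matrix = NULL) {
  if (nrow(reference) == 0L) stop("empty reference code")
  query <- .as_signature(query)
  sim <- vapply(reference$signature, function(s)
    signature_similarity(query, s, matrix), numeric(1))
  out <- data.frame(module = reference$module,
                    substrate = reference$substrate,
                    similarity = unname(sim), stringsAsFactors = FALSE)
  out <- out[order(-out$similarity, out$substrate, out$module), ,
             drop = FALSE]
  out <- utils::head(out, top_k)
  rownames(out) <- NULL
  attr(out, "query") <- query$residues
  class(out) <- c("substrate_prediction", "data.frame")
  out
}

#' Positions at which a signature differs from a comparison signature
#'
#' Reports the GrsA positions of mismatching columns, e.g. to check that a
#' strain's signatures differ from a reference synthetase exactly at the
#' positions annotated as inconsistent.
#'
#' @param a,b Signatures (strings or [adomain_signature()] objects).
#' @return Integer vector of GrsA positions (subset of [grsa_positions()]).
#' @export
signature_mismatch_positions <- function(a, b) {
  a <- .as_signature(a); b <- .as_signature(b)
  ca <- strsplit(a$residues, "")[[1]]
  cb <- strsplit(b$residues, "")[[1]]
  grsa_positions()[ca != cb]
}
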