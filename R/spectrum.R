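#' Construct a spectrum object
#'
#' A centroided positive-mode MS/MS spectrum: a peak list (m/z, intensity)
#' plus optional precursor m/z, retention time and source identifier. Peaks
#' are sorted ascending by m/z on ingestion.
#'
#' @param mz Numeric vector of peak m/z values (Da).
#' @param intensity Numeric vector of non-negative intensities (recycled
#'   unit intensities if missing).
#' @param precursor_mz Optional precursor m/z.
#' @param retention_time Optional retention time (minutes).
#' @param source_id Identifier string.
#' @return Object of class \code{spectrum}.
#' @export
ms_spectrum <- function(mz, intensity = NULL, precursor_mz = NULL,
                        retention_time = NULL, source_id = "") {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  ord <- order(mz)
  structure(
    list(peaks = data.frame(mz = as.numeric(mz)[ord],
                            intensity = as.numeric(intensity)[ord]),
         precursor_mz = precursor_mz, retention_time = retention_time,
         source_id = source_id),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("spectrum '%s': %d peaks", x$source_id, nrow(x$peaks)))
  if (!is.null(x$precursor_mz))
    cat(sprintf(", precursor m/z %.4f", x$precursor_mz))
  cat("\n")
  invisible(x)
}

#' Read a two-column peak list
#'
#' Whitespace- or comma-separated text with m/z in the first column and an
#' optional intensity in the second (defaulting to 1).
#'
#' @param path File path.
#' @param source_id Identifier (defaults to the file name).
#' @return A [ms_spectrum()].
#' @export
read_peaklist <- function(path, source_id = basename(path)) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,\t ]+")
  mz <- vapply(fields, function(f) as.numeric(f[1]), numeric(1))
  int <- vapply(fields, function(f)
    if (length(f) >= 2L) as.numeric(f[2]) else 1, numeric(1))
  if (anyNA(mz) || anyNA(int)) stop("malformed peak list: ", path)
  ms_spectrum(mz, int, source_id = source_id)
}

#' Read spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: BEGIN IONS / END IONS blocks with
#' PEPMASS, optional TITLE and RTINSECONDS headers, and m/z-intensity peak
#' rows.
#'
#' @param path File path.
#' @return List of [ms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  out <- list()
  in_block <- FALSE
  mz <- int <- numeric()
  pep <- rt <- NULL
  title <- ""
  for (l in lines) {
    if (l == "BEGIN IONS") {
      in_block <- TRUE; mz <- int <- numeric(); pep <- rt <- NULL; title <- ""
    } else if (l == "END IONS") {
      out[[length(out) + 1L]] <- ms_spectrum(mz, int, precursor_mz = pep,
                                          retention_time = rt,
                                          source_id = title)
      in_block <- FALSE
    } else if (in_block && nzchar(l)) {
      if (grepl("^TITLE=", l)) title <- sub("^TITLE=", "", l)
      else if (grepl("^PEPMASS=", l))
        pep <- as.numeric(strsplit(sub("^PEPMASS=", "", l), " ")[[1]][1])
      else if (grepl("^RTINSECONDS=", l))
        rt <- as.numeric(sub("^RTINSECONDS=", "", l)) / 60
      else if (grepl("^[0-9]", l)) {
        f <- strsplit(l, "[\t ]+")[[1]]
        mz <- c(mz, as.numeric(f[1]))
        int <- c(int, if (length(f) >= 2L) as.numeric(f[2]) else 1)
      }
    }
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra A [ms_spectrum()] or list of them.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(sp$source_id))
      writeLines(paste0("TITLE=", sp$source_id), con)
    if (!is.null(sp$precursor_mz))
      writeLines(sprintf("PEPMASS=%.5f", sp$precursor_mz), con)
    if (!is.null(sp$retention_time))
      writeLines(sprintf("RTINSECONDS=%.2f", sp$retention_time * 60), con)
    writeLines(sprintf("%.5f %.3f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Match observed peaks to theoretical fragment ions
#'
#' Greedy one-to-one assignment in ascending absolute m/z error; ties are
#' broken by fewer neutral losses, then ion-kind priority (b > y > a >
#' internal > residue-loss > precursor-loss > diagnostic), then lower span
#' start. Each peak is explained by at most one theoretical ion and each
#' theoretical ion is consumed at most once.
#'
#' @param spec A [ms_spectrum()].
#' @param theoretical Fragment data.frame (from [fragment_ions()] etc.).
#' @param tolerance Matching tolerance in Da (default 0.5, suiting
#'   unit-resolution ion-trap spectra).
#' @return Object of class \code{match_result} with elements
#'   \code{assignments} (peak index, theory index, label, kind, delta),
#'   \code{unexplained} (peak indices), \code{score_intensity} (explained
#'   intensity fraction) and \code{score_count} (explained peak fraction).
#' @export
match_peaks <- function(spec, theoretical, tolerance = 0.5) {
  stopifnot(inherits(spec, "spectrum"), tolerance > 0)
  peaks <- spec$peaks
  if (nrow(peaks) == 0L) stop("empty spectrum")
  empty_assign <- data.frame(peak = integer(), theory = integer(),
                             peak_mz = numeric(), theory_mz = numeric(),
                             label = character(), kind = character(),
                             delta = numeric(), stringsAsFactors = FALSE)
  if (is.null(theoretical) || nrow(theoretical) == 0L) {
    res <- list(assignments = empty_assign,
                unexplained = seq_len(nrow(peaks)),
                score_intensity = 0, score_count = 0, n_theory = 0L)
    class(res) <- "match_result"
    return(res)
  }
  # candidate (peak, ion) pairs within tolerance
  cand <- list()
  pri <- .kind_priority(theoretical$kind, theoretical$n_losses)
  for (p in seq_len(nrow(peaks))) {
    d <- theoretical$mz - peaks$mz[p]
    hit <- which(abs(d) <= tolerance)
    if (length(hit))
      cand[[length(cand) + 1L]] <- data.frame(
        peak = p, theory = hit, delta = d[hit], adelta = abs(d[hit]),
        n_losses = theoretical$n_losses[hit], pri = pri[hit],
        start = ifelse(is.na(theoretical$start[hit]), .Machine$integer.max,
                       theoretical$start[hit]))
  }
  assigned <- empty_assign
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$adelta, cand$n_losses, cand$pri, cand$start,
                       cand$peak, cand$theory), , drop = FALSE]
    peak_used <- rep(FALSE, nrow(peaks))
    theory_used <- rep(FALSE, nrow(theoretical))
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      p <- cand$peak[i]; t <- cand$theory[i]
      if (!peak_used[p] && !theory_used[t]) {
        peak_used[p] <- TRUE; theory_used[t] <- TRUE; keep[i] <- TRUE
      }
    }
    cd <- cand[keep, , drop = FALSE]
    if (nrow(cd)) {
      assigned <- data.frame(
        peak = cd$peak, theory = cd$theory,
        peak_mz = peaks$mz[cd$peak], theory_mz = theoretical$mz[cd$theory],
        label = theoretical$label[cd$theory],
        kind = theoretical$kind[cd$theory],
        delta = cd$delta, stringsAsFactors = FALSE)
      assigned <- assigned[order(assigned$peak), , drop = FALSE]
      rownames(assigned) <- NULL
    }
  }
  total_int <- sum(peaks$intensity)
  expl_int <- sum(peaks$intensity[assigned$peak])
  res <- list(
    assignments = assigned,
    unexplained = setdiff(seq_len(nrow(peaks)), assigned$peak),
    score_intensity = if (total_int > 0) expl_int / total_int else 0,
    score_count = nrow(assigned) / nrow(peaks),
    n_theory = nrow(theoretical)
  )
  class(res) <- "match_result"
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "match_result: %d/%d peaks explained (count %.3f, intensity %.3f)\n",
    nrow(x$assignments), nrow(x$assignments) + length(x$unexplained),
    x$score_count, x$score_intensity))
  invisible(x)
}

#' Annotate a spectrum against a candidate structure
#'
#' Convenience composition: generate the theoretical ions for the structure
#' (dispatched on topology), match them against the observed peaks, and
#' return a per-peak annotation table.
#'
#' @param spec A [ms_spectrum()].
#' @param structure A [peptide_structure()].
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @param tolerance Matching tolerance in Da.
#' @return List with \code{table} (per-peak data.frame: mz, intensity,
#'   label, kind, theory_mz, delta) and \code{match} (the
#'   \code{match_result}).
#' @export
annotate <- function(spec, structure, config = fragment_config(),
                     registry = monomer_registry(), tolerance = 0.5) {
  theory <- fragment_ions(structure, config, registry)
  m <- match_peaks(spec, theory, tolerance)
  tab <- data.frame(mz = spec$peaks$mz, intensity = spec$peaks$intensity,
                    label = NA_character_, kind = NA_character_,
                    theory_mz = NA_real_, delta = NA_real_,
                    stringsAsFactors = FALSE)
  if (nrow(m$assignments)) {
    tab$label[m$assignments$peak] <- m$assignments$label
    tab$kind[m$assignments$peak] <- m$assignments$kind
    tab$theory_mz[m$assignments$peak] <- m$assignments$theory_mz
    tab$delta[m$assignments$peak] <- m$assignments$delta
  }
  list(table = tab, match = m)
}

#' Cyclic:linear content ratio
#'
#' Expresses the cyclic form's signal as a percentage of the linear peptide
#' aldehyde's signal, the metric used to describe how far macrocyclization
#' has proceeded in vivo (values range from under 10\% to over 90\%
#' depending on the congener and extraction).
#'
#' @param intensity_cyclic Non-negative cyclic-form intensity.
#' @param intensity_linear Positive linear-form intensity.
#' @return Percentage (100 x cyclic / linear).
#' @export
cyclic_linear_ratio <- function(intensity_cyclic, intensity_linear) {
  if (!is.numeric(intensity_linear) || intensity_linear <= 0)
    stop("linear intensity must be positive")
  if (!is.numeric(intensity_cyclic) || intensity_cyclic < 0)
    stop("cyclic intensity must be non-negative")
  100 * intensity_cyclic / intensity_linear
}

#' Write an annotation table as TSV or JSON
#'
#' @param annotation Result of [annotate()].
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_annotation <- function(annotation, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- annotation$table
  if (format == "tsv") {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    rows <- lapply(seq_len(nrow(tab)), function(i) {
      r <- as.list(tab[i, ])
      r[vapply(r, function(v) is.na(v), logical(1))] <- NULL
      r
    })
    writeLines(.to_json(rows), path)
  }
  invisible(path)
}

# tiny JSON serializer for list/vector trees (avoids a hard dependency in
# the package namespace; scripts may use jsonlite directly)
.to_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.list(x)) {
    if (!is.null(names(x)) && all(nzchar(names(x)))) {
      paste0("{", paste(sprintf("\"%s\":%s", names(x),
                                vapply(x, .to_json, character(1))),
                        collapse = ","), "}")
    } else {
      paste0("[", paste(vapply(x, .to_json, character(1)), collapse = ","),
             "]")
    }
  } else if (is.character(x)) {
    if (length(x) == 1L) sprintf("\"%s\"", gsub("\"", "\\\\\"", x))
    else .to_json(as.list(x))
  } else if (length(x) == 1L) {
    if (is.na(x)) "null" else format(x, digits = 15)
  } else .to_json(as.list(x))
}
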