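#' Simulation parameters for synthetic CID spectra
#'
#' A declared noise model for unit-resolution ion-trap product-ion spectra:
#' theoretical ions survive with probability 1 - dropout, m/z values receive
#' Gaussian jitter, intensities are log-normal with a multiplicative boost
#' for ions derived from the two C-terminal residues (which dominate real
#' nostocyclopeptide spectra), and uniform decoy peaks are added over the
#' instrument's product-ion range (50-1000 m/z) with intensities drawn from
#' the lower quartile of the peak-intensity distribution.
#'
#' @param seed Integer RNG seed. The default 1411 (the producing strain's
#'   collection number) is arbitrary; every stochastic entry point requires
#'   a seed.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (default 0.1).
#' @param dropout_prob Per-ion dropout probability (default 0.2).
#' @param n_decoys Number of uniform decoy peaks (default 5).
#' @param decoy_mz_range Decoy m/z range (default c(50, 1000)).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   (defaults log(1e4) and 1).
#' @param cterm_boost Multiplicative intensity boost for ions whose span
#'   lies within the two C-terminal residues (default 5).
#' @return Object of class \code{simulation_params}.
#' @export
simulation_params <- function(seed = 1411L,
                              mz_jitter_sd = 0.1,
                              dropout_prob = 0.2,
                              n_decoys = 5L,
                              decoy_mz_range = c(50, 1000),
                              intensity_meanlog = log(1e4),
                              intensity_sdlog = 1,
                              cterm_boost = 5) {
  stopifnot(mz_jitter_sd >= 0, dropout_prob >= 0, dropout_prob <= 1,
            n_decoys >= 0, length(decoy_mz_range) == 2L,
            decoy_mz_range[1] < decoy_mz_range[2],
            intensity_sdlog >= 0, cterm_boost > 0)
  structure(
    list(seed = as.integer(seed), mz_jitter_sd = mz_jitter_sd,
         dropout_prob = dropout_prob, n_decoys = as.integer(n_decoys),
         decoy_mz_range = as.numeric(decoy_mz_range),
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog, cterm_boost = cterm_boost),
    class = "simulation_params"
  )
}

# does the ion's span lie entirely within the two C-terminal residues?
.is_cterm_ion <- function(frags, n) {
  cterm <- c(n - 1L, n)
  vapply(seq_len(nrow(frags)), function(i) {
    s <- frags$start[i]; len <- frags$length[i]
    if (is.na(s) || len > 2L || frags$kind[i] == "precursor") return(FALSE)
    all(.span_positions(s, len, n) %in% cterm)
  }, logical(1))
}

#' Simulate a CID spectrum from a known structure
#'
#' Generates the theoretical ion table for the structure, retains each ion
#' with probability 1 - dropout, perturbs m/z by Normal(0, sd), draws
#' log-normal intensities (boosted for C-terminal two-residue ions), and
#' appends uniform decoy peaks. Fully reproducible from the seed.
#'
#' @param structure A [peptide_structure()].
#' @param params A [simulation_params()].
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return A [ms_spectrum()].
#' @export
simulate_spectrum <- function(structure, params = simulation_params(),
                              config = fragment_config(),
                              registry = monomer_registry()) {
  stopifnot(inherits(params, "simulation_params"))
  theory <- fragment_ions(structure, config, registry)
  n <- length(structure$residues)
  withr::with_seed(params$seed, {
    keep <- stats::runif(nrow(theory)) >= params$dropout_prob
    kept <- theory[keep, , drop = FALSE]
    mz <- kept$mz + stats::rnorm(nrow(kept), 0, params$mz_jitter_sd)
    intensity <- stats::rlnorm(nrow(kept), params$intensity_meanlog,
                               params$intensity_sdlog)
    boost <- .is_cterm_ion(kept, n)
    intensity[boost] <- intensity[boost] * params$cterm_boost
    if (params$n_decoys > 0L) {
      dmz <- stats::runif(params$n_decoys, params$decoy_mz_range[1],
                          params$decoy_mz_range[2])
      # decoy intensities sit in the lower quartile of the real-peak model
      dint <- stats::rlnorm(
        params$n_decoys,
        params$intensity_meanlog +
          stats::qnorm(0.25) * params$intensity_sdlog,
        params$intensity_sdlog)
      mz <- c(mz, dmz)
      intensity <- c(intensity, dint)
    }
  })
  ms_spectrum(mz, intensity,
           precursor_mz = precursor_mz(structure, 1L, registry),
           source_id = sprintf("%s|seed=%d",
                               if (is.null(structure$name))
                                 render_structure(structure)
                               else structure$name,
                               params$seed))
}

#' Noiseless simulation parameters
#'
#' Convenience constructor for the noiseless limit: no dropout, no jitter,
#' no decoys. The resulting peak list is exactly the theoretical m/z
#' multiset.
#'
#' @param seed Integer seed (still required; intensities remain stochastic
#'   unless \code{unit_intensity}).
#' @param unit_intensity Use unit intensities instead of log-normal draws
#'   (default TRUE).
#' @return A [simulation_params()].
#' @export
noiseless_params <- function(seed = 1411L, unit_intensity = TRUE) {
  p <- simulation_params(seed = seed, mz_jitter_sd = 0, dropout_prob = 0,
                         n_decoys = 0L)
  if (unit_intensity) {
    p$intensity_sdlog <- 0
    p$intensity_meanlog <- 0
    p$cterm_boost <- 1
  }
  p
}

#' Generate a benchmark fixture set
#'
#' Writes one simulated MGF spectrum per structure plus a truth table TSV
#' (file, name, structure, topology, precursor m/z, per-structure seed).
#' Per-structure seeds are derived deterministically from the base seed, so
#' the same seed yields byte-identical fixtures.
#'
#' @param structures Non-empty list of [peptide_structure()] objects.
#' @param params A [simulation_params()].
#' @param dir Output directory (created if needed).
#' @param config A [fragment_config()].
#' @param registry A [monomer_registry()].
#' @return Invisibly, the truth table data.frame.
#' @export
generate_benchmark <- function(structures, params = simulation_params(),
                               dir, config = fragment_config(),
                               registry = monomer_registry()) {
  if (length(structures) == 0L) stop("empty structure list")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    nm <- if (!is.null(s$name)) s$name else sprintf("structure_%02d", i)
    p <- params
    p$seed <- params$seed + i - 1L
    sp <- simulate_spectrum(s, p, config, registry)
    file <- file.path(dir, paste0(gsub("[^A-Za-z0-9_-]", "_", nm), ".mgf"))
    write_mgf(sp, file)
    data.frame(file = basename(file), name = nm,
               structure = render_structure(s), topology = s$topology,
               precursor_mz = precursor_mz(s, 1L, registry),
               seed = p$seed, stringsAsFactors = FALSE)
  })
  truth <- do.call(rbind, rows)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}

#' Load configuration from a YAML file
#'
#' Reads a YAML file whose top-level keys mirror the [fragment_config()] and
#' [simulation_params()] field names under \code{fragment} and
#' \code{simulation}.
#'
#' @param path YAML file path.
#' @return List with elements \code{fragment} (a \code{fragment_config})
#'   and \code{simulation} (a \code{simulation_params}); missing sections
#'   get defaults.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  frag <- do.call(fragment_config, y$fragment %||% list())
  sim <- do.call(simulation_params, y$simulation %||% list())
  list(fragment = frag, simulation = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
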