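# Independent oracles used across the suite. These deliberately avoid the
# package's own enumeration/matching code paths.

# IUPAC monoisotopic atomic masses, written out independently of the
# package's internal table
ORACLE_ATOM <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)

oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z])([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  sum(vapply(toks, function(t) {
    el <- substr(t, 1, 1)
    n <- if (nchar(t) > 1) as.integer(substring(t, 2)) else 1L
    ORACLE_ATOM[[el]] * n
  }, numeric(1)))
}

# residue masses recomputed from scratch for the oracle enumerator
ORACLE_RESIDUE <- c(
  Gly = oracle_formula_mass("C2H3NO"),
  Ser = oracle_formula_mass("C3H5NO2"),
  Pro = oracle_formula_mass("C5H7NO"),
  Val = oracle_formula_mass("C5H9NO"),
  Ile = oracle_formula_mass("C6H11NO"),
  Leu = oracle_formula_mass("C6H11NO"),
  Gln = oracle_formula_mass("C5H8N2O2"),
  MePro = oracle_formula_mass("C6H9NO"),
  Tyr = oracle_formula_mass("C9H9NO2"),
  Phe = oracle_formula_mass("C9H9NO"),
  HSe = oracle_formula_mass("C4H7NO2")
)

O_PROTON <- 1.00728
O_H <- 1.00783
O_O <- 15.99491
O_H2O <- 18.01056

# brute-force enumeration of plain fragment m/z values: every contiguous
# subsequence with terminal chemistry applied by first principles
oracle_linear_mz <- function(residues, terminus = c("aldehyde", "acid")) {
  terminus <- match.arg(terminus)
  tadd <- if (terminus == "aldehyde") 2 * O_H else O_H2O
  n <- length(residues)
  m <- ORACLE_RESIDUE[residues]
  out <- numeric()
  for (i in seq_len(n)) for (j in i:n) {
    if (i == 1 && j == n) next          # full span handled as precursor
    mass <- sum(m[i:j]) + O_PROTON
    if (j == n) mass <- mass + tadd     # suffix keeps the C-terminus
    out <- c(out, mass)
  }
  sort(out)
}

oracle_cyclic_mz <- function(residues) {
  n <- length(residues)
  m <- ORACLE_RESIDUE[residues]
  out <- numeric()
  for (s in seq_len(n)) for (len in seq_len(n - 1)) {
    pos <- ((s - 1 + seq_len(len) - 1) %% n) + 1
    mass <- sum(m[pos]) + O_PROTON
    if (n %in% pos) mass <- mass - O_O  # span crosses the imine carbon
    out <- c(out, mass)
  }
  sort(out)
}

# exhaustive maximum-cardinality, minimum-total-|delta| peak/ion matching
# by recursion over peaks; small instances only
oracle_best_matching <- function(peak_mz, theory_mz, tolerance) {
  np <- length(peak_mz)
  best <- list(count = -1L, cost = Inf)
  recurse <- function(p, used, count, cost) {
    if (p > np) {
      if (count > best$count ||
          (count == best$count && cost < best$cost))
        best <<- list(count = count, cost = cost)
      return(invisible())
    }
    cand <- which(!used & abs(theory_mz - peak_mz[p]) <= tolerance)
    for (t in cand) {
      used[t] <- TRUE
      recurse(p + 1L, used, count + 1L,
              cost + abs(theory_mz[t] - peak_mz[p]))
      used[t] <- FALSE
    }
    recurse(p + 1L, used, count, cost)  # leave peak unexplained
  }
  recurse(1L, rep(FALSE, length(theory_mz)), 0L, 0)
  best
}

# random test structures over the registry alphabet
random_structure <- function(n, topology, seed) {
  withr::with_seed(seed, {
    res <- sample(names(ORACLE_RESIDUE), n, replace = TRUE)
  })
  peptide_structure(res, topology)
}

# published unit-resolution ion lists (product-ion spectra captions);
# nominal m/z values keyed by the structure they characterize
published_ions <- function(which) {
  switch(which,
    e1l = c(795, 777, 759, 646, 614, 575, 549, 531, 462, 349, 334, 247,
            229, 201, 148, 136, 129, 101, 84, 70),
    e4l = c(549, 531, 521, 462, 434, 349, 329, 312, 221, 193, 148, 136,
            129, 101, 86, 84),          # terminus-independent entries
    e1 = c(777, 759, 741, 690, 672, 662, 646, 628, 575, 549, 480, 462,
           444, 434, 392, 352, 316, 298, 229, 201, 158, 132, 70),
    stop("unknown ion list")
  )
}

extdata <- function(f) system.file("extdata", f, package = "ncptools",
                                   mustWork = TRUE)
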