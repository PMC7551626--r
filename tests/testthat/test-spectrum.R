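reg <- monomer_registry()
ncps <- ncp_structures(reg)

test_that("peak matching follows tolerance and one-to-one assignment", {
  theory <- data.frame(kind = "b", start = 1L, length = 5L,
                       residues = "Tyr+Gly+Gln+Ile+Ser",
                       label = "[Tyr+Gly+Gln+Ile+Ser+H]", losses = "",
                       n_losses = 0L, mz = 549.27, nominal = 549L,
                       stringsAsFactors = FALSE)
  m <- match_peaks(ms_spectrum(c(549.0, 999.0)), theory, tolerance = 0.5)
  expect_identical(nrow(m$assignments), 1L)
  expect_equal(m$score_count, 0.5)
  m2 <- match_peaks(ms_spectrum(548.4), theory, tolerance = 0.5)
  expect_identical(nrow(m2$assignments), 0L)  # |delta| = 0.87 > 0.5
  expect_error(match_peaks(ms_spectrum(numeric()), theory), "empty spectrum")
  m3 <- match_peaks(ms_spectrum(100), theory[0, , drop = FALSE])
  expect_equal(m3$score_count, 0)
  expect_equal(m3$score_intensity, 0)
})

test_that("a spectrum of a structure's own ions self-matches completely", {
  th <- fragment_ions(ncps[["Ncp-A1"]], registry = reg)
  sp <- ms_spectrum(th$mz)
  m <- match_peaks(sp, th, tolerance = 0.5)
  expect_equal(m$score_count, 1.0)
  expect_equal(m$score_intensity, 1.0)
})

test_that("scores are invariant under peak reordering and intensity scaling", {
  th <- fragment_ions(ncps[["Ncp-E1-L"]], registry = reg)
  mz <- published_ions("e1l")
  int <- seq_along(mz) * 10
  base <- match_peaks(ms_spectrum(mz, int), th)
  perm <- withr::with_seed(3, sample(seq_along(mz)))
  shuffled <- match_peaks(ms_spectrum(mz[perm], int[perm]), th)
  scaled <- match_peaks(ms_spectrum(mz, int * 1e3), th)
  expect_equal(shuffled$score_count, base$score_count)
  expect_equal(shuffled$score_intensity, base$score_intensity)
  expect_equal(scaled$score_intensity, base$score_intensity)
})

test_that("shrinking the tolerance never increases the explained fraction", {
  th <- fragment_ions(ncps[["Ncp-E1"]], registry = reg)
  sp <- withr::with_seed(11, ms_spectrum(runif(40, 50, 1000)))
  tols <- c(1.0, 0.5, 0.25, 0.1, 0.02)
  counts <- vapply(tols, function(t) match_peaks(sp, th, t)$score_count,
                   numeric(1))
  expect_true(all(diff(counts) <= 1e-12))
})

test_that("greedy assignment attains the exhaustive optimum on spaced peaks", {
  for (seed in 1:5) {
    inst <- withr::with_seed(seed, {
      theory_mz <- sort(runif(20, 100, 900))
      # peaks spaced > 2x tolerance so stars in the match graph are disjoint
      pk <- sort(sample(seq(100, 900, by = 2.5), 8)) +
        runif(8, -0.4, 0.4)
      list(theory_mz = theory_mz, pk = pk)
    })
    th <- data.frame(kind = "b", start = 1L, length = 1L, residues = "Gly",
                     label = "[Gly+H]", losses = "", n_losses = 0L,
                     mz = inst$theory_mz, nominal = nominal_mz(inst$theory_mz),
                     stringsAsFactors = FALSE)
    m <- match_peaks(ms_spectrum(inst$pk), th, tolerance = 0.5)
    best <- oracle_best_matching(inst$pk, inst$theory_mz, 0.5)
    expect_identical(nrow(m$assignments), best$count, info = paste("seed", seed))
  }
})

test_that("annotation reproduces the published labels for the open-chain heptapeptide", {
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  ann <- annotate(sp, ncps[["Ncp-E1-L"]], registry = reg)
  tab <- ann$table
  expect_identical(tab$label[tab$mz == 549], "[Tyr+Gly+Gln+Ile+Ser+H]")
  expect_identical(tab$label[tab$mz == 136], "Tyr immonium")
  expect_identical(tab$label[tab$mz == 795], "[M+H]")
  expect_gte(ann$match$score_count, 0.95)
  # an unrelated dipeptide explains almost nothing of the same spectrum
  gg <- peptide_structure(c("Gly", "Gly"), "linear-aldehyde", registry = reg)
  expect_lt(annotate(sp, gg, registry = reg)$match$score_count, 0.2)
})

test_that("cyclic:linear content ratio is plain percentage arithmetic", {
  expect_equal(cyclic_linear_ratio(91.7, 100), 91.7)
  expect_equal(cyclic_linear_ratio(0, 100), 0)
  expect_equal(cyclic_linear_ratio(50, 200), 25)
  expect_error(cyclic_linear_ratio(10, 0), "positive")
  expect_error(cyclic_linear_ratio(-1, 10), "non-negative")
})

test_that("peak-list and MGF files round-trip", {
  sp <- simulate_spectrum(ncps[["Ncp-A1"]], simulation_params(seed = 5),
                          registry = reg)
  mgf <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(sp, mgf)
  back <- read_mgf(mgf)[[1]]
  expect_equal(back$peaks$mz, sp$peaks$mz, tolerance = 1e-5)
  expect_equal(back$precursor_mz, sp$precursor_mz, tolerance = 1e-5)
  expect_identical(back$source_id, sp$source_id)

  txt <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "100.5,200", "250.25 30"), txt)
  sp2 <- read_peaklist(txt)
  expect_equal(sp2$peaks$mz, c(100.5, 250.25))
  expect_equal(sp2$peaks$intensity, c(200, 30))
})

test_that("annotation tables serialize to TSV and JSON", {
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  ann <- annotate(sp, ncps[["Ncp-E1-L"]], registry = reg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, tsv, "tsv")
  expect_identical(nrow(utils::read.delim(tsv)), nrow(ann$table))
  js <- withr::local_tempfile(fileext = ".json")
  write_annotation(ann, js, "json")
  expect_match(readLines(js), "\"label\":", all = FALSE)
})
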