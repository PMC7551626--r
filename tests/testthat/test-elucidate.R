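reg <- monomer_registry()
ncps <- ncp_structures(reg)

test_that("template enumeration is the cartesian product in stable order", {
  cands <- enumerate_candidates(ncp_template(), reg)
  expect_length(cands, 16L)
  expect_identical(anyDuplicated(vapply(cands, render_structure,
                                        character(1))), 0L)
  single <- candidate_template(list("Tyr", "Gly"),
                               topologies = "linear-aldehyde")
  expect_length(enumerate_candidates(single, reg), 1L)
  expect_error(candidate_template(list("Tyr", character())), "non-empty")
})

test_that("the published open-chain peak list ranks its own structure first", {
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  rk <- rank_candidates(sp, ncp_template(), registry = reg)
  top <- top_class(rk)
  expect_identical(top$topology[1], "linear-aldehyde")
  expect_identical(top$structure[1], "Tyr+Gly+Gln+Ile+Ser+Pro+Phe")
})

test_that("the published cyclic peak list ranks the macrocycle first", {
  sp <- read_peaklist(extdata("ncp_e1_ions.txt"))
  rk <- rank_candidates(sp, ncp_template(), registry = reg)
  expect_identical(top_class(rk)$structure[1],
                   "cyclo[Tyr+Gly+Gln+Ile+Ser+Pro+Phe]")
})

test_that("a noiseless spectrum of any candidate ranks that candidate first", {
  cands <- enumerate_candidates(ncp_template(), reg)
  for (i in c(1, 6, 11, 16)) {
    sp <- simulate_spectrum(cands[[i]], noiseless_params(seed = 2),
                            registry = reg)
    rk <- rank_candidates(sp, cands, registry = reg)
    expect_true(render_structure(cands[[i]]) %in% top_class(rk)$structure,
                info = render_structure(cands[[i]]))
  }
})

test_that("ranking is a stable permutation of the candidate set", {
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  cands <- enumerate_candidates(ncp_template(), reg)
  rk1 <- rank_candidates(sp, cands, registry = reg)
  rk2 <- rank_candidates(sp, rev(cands), registry = reg)
  expect_setequal(rk1$table$structure,
                  vapply(cands, render_structure, character(1)))
  expect_identical(rk1$table$structure, rk2$table$structure)
  expect_identical(rk1$table$rank, seq_len(16L))
})

test_that("Ile/Leu swaps collapse into one isobaric equivalence class", {
  tmpl <- candidate_template(
    list("Tyr", "Gly", "Gln", c("Ile", "Leu"), "Ser", "Pro", "Phe"),
    topologies = "linear-aldehyde")
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  rk <- rank_candidates(sp, tmpl, registry = reg, collapse_xle = TRUE)
  expect_identical(nrow(top_class(rk)), 2L)
  expect_identical(length(unique(rk$table$class_id)), 1L)
  rk2 <- rank_candidates(sp, tmpl, registry = reg, collapse_xle = FALSE)
  expect_identical(length(unique(rk2$table$class_id)), 2L)
})

test_that("faint decoy peaks do not change the top-ranked class", {
  sp <- simulate_spectrum(ncps[["Ncp-A1"]], noiseless_params(seed = 4,
                                                             unit_intensity = FALSE),
                          registry = reg)
  rk <- rank_candidates(sp, ncp_template(), registry = reg)
  top0 <- top_class(rk)$structure[1]
  decoys <- withr::with_seed(9, runif(8, 50, 1000))
  total <- sum(sp$peaks$intensity)
  sp2 <- ms_spectrum(c(sp$peaks$mz, decoys),
                  c(sp$peaks$intensity,
                    rep(total * 0.001 / 8, 8)),
                  precursor_mz = sp$precursor_mz)
  rk2 <- rank_candidates(sp2, ncp_template(), registry = reg)
  expect_identical(top_class(rk2)$structure[1], top0)
})

test_that("ranking requires candidates and writes a TSV", {
  sp <- read_peaklist(extdata("ncp_e1l_ions.txt"))
  expect_error(rank_candidates(sp, list(), registry = reg), "empty candidate")
  rk <- rank_candidates(sp, ncp_template(), registry = reg)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(rk, tsv)
  expect_identical(nrow(utils::read.delim(tsv)), 16L)
})
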