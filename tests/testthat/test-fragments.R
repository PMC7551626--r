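reg <- monomer_registry()
ncps <- ncp_structures(reg)
plain_by <- fragment_config(max_combined_losses = 0L, include_a = FALSE,
                            include_internal = FALSE,
                            include_diagnostics = FALSE,
                            include_precursor = FALSE,
                            include_residue_loss = FALSE)

test_that("b, y and internal ions match their published nominal values", {
  e1l <- fragment_ions(ncps[["Ncp-E1-L"]], registry = reg)
  b5 <- e1l[e1l$kind == "b" & e1l$length == 5 & e1l$n_losses == 0, ]
  expect_identical(b5$nominal, 549L)
  expect_identical(b5$label, "[Tyr+Gly+Gln+Ile+Ser+H]")
  y2 <- e1l[e1l$kind == "y" & e1l$length == 2 & e1l$n_losses == 0, ]
  expect_identical(y2$nominal, 247L)
  y3 <- e1l[e1l$kind == "y" & e1l$length == 3 & e1l$n_losses == 0, ]
  expect_identical(y3$label, "[Ser+Pro+Phe+2H]")
  expect_identical(y3$nominal, 334L)

  e4l <- fragment_ions(ncps[["Ncp-E4-L"]], registry = reg)
  b2 <- e4l[e4l$kind == "b" & e4l$length == 2 & e4l$n_losses == 0, ]
  expect_identical(b2$nominal, 221L)
  expect_true(193L %in% e4l$nominal[e4l$losses == "CO"])  # a2 = b2 - CO
  b3 <- e4l[e4l$kind == "b" & e4l$length == 3 & e4l$n_losses == 0, ]
  expect_identical(b3$label, "[Tyr+Gly+Gln+H]")
  # the Ile+Ser+MePro acylium (positions 4-6 of the hexapeptide) arises as
  # the water-loss form of y3, since its span touches the C-terminus
  int <- e4l[e4l$residues == "Ile+Ser+MePro", ]
  acylium <- sum(vapply(c("Ile", "Ser", "MePro"), residue_mass, numeric(1),
                        registry = reg)) + 1.00728
  expect_true(any(abs(int$mz - acylium) < 1e-6))
  expect_true(312L %in% int$nominal)
})

test_that("cyclic ring spans apply the imine -O rule exactly when crossing residue n", {
  e1 <- cyclic_fragments(ncps[["Ncp-E1"]], registry = reg)
  span <- function(s, len) e1[e1$kind == "b" & e1$start == s &
                                e1$length == len & e1$n_losses == 0, ]
  expect_identical(span(7, 4)$nominal, 480L)  # Phe+Tyr+Gly+Gln, crosses imine
  expect_identical(span(4, 3)$nominal, 298L)  # Ile+Ser+Pro, no -O
  expect_identical(span(5, 3)$nominal, 316L)  # Ser+Pro+Phe, -O
  expect_identical(span(6, 2)$nominal, 229L)  # Pro+Phe, -O

  a1 <- cyclic_fragments(ncps[["Ncp-A1"]], registry = reg)
  mepro_leu <- a1[a1$kind == "b" & a1$residues == "MePro+Leu" &
                    a1$n_losses == 0, ]
  expect_identical(mepro_leu$nominal, 209L)
  # full-ring span yields the precursor
  expect_equal(max(a1$mz[a1$kind == "precursor" & a1$n_losses == 0]),
               precursor_mz(ncps[["Ncp-A1"]], 1L, reg), tolerance = 1e-9)
})

test_that("residue-loss ions use topology-effective masses", {
  e1 <- fragment_ions(ncps[["Ncp-E1"]], registry = reg)
  expect_true(690L %in% e1$nominal)  # [M+H-Ser], cyclic
  expect_true(662L %in% e1$nominal)  # [M+H-Pro-H2O]
  expect_true(646L %in% e1$nominal)  # [M+H-Phe]: imine residue, -O applied
  expect_true(575L %in% e1$nominal)  # [M+H-(Ser+Pro)-H2O]

  e1l <- fragment_ions(ncps[["Ncp-E1-L"]], registry = reg)
  expect_true(646L %in% e1l$nominal) # [M+H-Phe]: aldehyde terminus, +2H
  expect_true(575L %in% e1l$nominal) # [M+H-(Tyr+Gly)]
  expect_true(614L %in% e1l$nominal) # [M+H-Tyr-H2O]
})

test_that("neutral-loss combinatorics cover published variants and respect the cap", {
  e1 <- fragment_ions(ncps[["Ncp-E1"]], registry = reg)
  prec_losses <- e1[e1$kind == "precursor" & e1$n_losses > 0, ]
  expect_true(all(c(759L, 741L) %in% prec_losses$nominal))
  e4l <- fragment_ions(ncps[["Ncp-E4-L"]], registry = reg)
  b5v <- e4l[e4l$residues == "Tyr+Gly+Gln+Ile+Ser" & e4l$kind == "b", ]
  expect_true(all(c(531L, 521L) %in% b5v$nominal))
  expect_true(all(e1$n_losses <= 2))
  # zero-loss config generates no variants
  ions <- fragment_ions(ncps[["Ncp-E1"]], plain_by, reg)
  expect_identical(nrow(apply_neutral_losses(ions, plain_by, reg)), 0L)
})

test_that("b/y complementarity holds for both linear terminus chemistries", {
  for (nm in c("Ncp-E1-L", "Ncp-A2-L", "Ncp-E4-L")) {
    s <- ncps[[nm]]
    n <- length(s$residues)
    f <- fragment_ions(s, plain_by, reg)
    prec <- precursor_mz(s, 1L, reg)
    for (i in 1:(n - 1)) {
      b <- f$mz[f$kind == "b" & f$length == i]
      y <- f$mz[f$kind == "y" & f$length == n - i]
      expect_equal(b + y, prec + 1.00728, tolerance = 1e-6,
                   info = paste(nm, i))
    }
  }
})

test_that("b and y series increase monotonically", {
  f <- fragment_ions(ncps[["Ncp-A1-L"]], plain_by, reg)
  b <- f[f$kind == "b", ]
  y <- f[f$kind == "y", ]
  expect_true(all(diff(b$mz[order(b$length)]) > 0))
  expect_true(all(diff(y$mz[order(y$length)]) > 0))
})

test_that("ion counts match the combinatorial oracle", {
  for (n in c(3L, 5L, 7L)) {
    lin <- random_structure(n, "linear-aldehyde", seed = n)
    expect_identical(nrow(fragment_ions(lin, plain_by, reg)), 2L * (n - 1L))
    cyc <- random_structure(n, "cyclic-imine", seed = n + 100)
    expect_identical(nrow(fragment_ions(cyc, plain_by, reg)), n * (n - 1L))
  }
})

test_that("enumeration agrees with the brute-force span oracle", {
  cfg <- fragment_config(max_combined_losses = 0L, include_a = FALSE,
                         include_diagnostics = FALSE,
                         include_precursor = FALSE,
                         include_residue_loss = FALSE)
  for (seed in 1:6) {
    n <- sample(3:7, 1)
    lin <- random_structure(n, "linear-aldehyde", seed)
    got <- sort(fragment_ions(lin, cfg, reg)$mz)
    expect_equal(got, oracle_linear_mz(lin$residues, "aldehyde"),
                 tolerance = 1e-9, info = paste("aldehyde seed", seed))
    acid <- peptide_structure(lin$residues, "linear-acid", registry = reg)
    expect_equal(sort(fragment_ions(acid, cfg, reg)$mz),
                 oracle_linear_mz(acid$residues, "acid"),
                 tolerance = 1e-9, info = paste("acid seed", seed))
    cyc <- random_structure(n, "cyclic-imine", seed + 50)
    expect_equal(sort(fragment_ions(cyc, plain_by, reg)$mz),
                 oracle_cyclic_mz(cyc$residues),
                 tolerance = 1e-9, info = paste("cyclic seed", seed))
  }
})

test_that("topology dispatch rejects the wrong enumerator", {
  expect_error(linear_fragments(ncps[["Ncp-A1"]], registry = reg),
               "cyclic_fragments")
  expect_error(cyclic_fragments(ncps[["Ncp-A1-L"]], registry = reg),
               "linear_fragments")
})

test_that("labels regenerate the span composition when re-parsed", {
  f <- fragment_ions(ncps[["Ncp-E1-L"]], registry = reg)
  spanful <- f[!is.na(f$start) & !f$kind %in%
                 c("immonium", "diagnostic", "precursor", "residue-loss") &
                 !grepl("^\\[M\\+H", f$label), ]
  toks <- label_tokens(spanful$label)
  for (i in seq_len(nrow(spanful)))
    expect_identical(paste(toks[[i]], collapse = "+"), spanful$residues[i])
})

test_that("the homolog mass-shift table localizes single substitutions", {
  shifts <- mass_shift_check(ncps[["Ncp-A1"]], ncps[["Ncp-E2"]],
                             registry = reg)  # MePro6 -> Pro6
  # the published diagnostic pair: [MePro+Leu+H] 209 <-> [Pro+Leu+H] 195
  pair <- shifts[shifts$label_a == "[MePro+Leu+H]" & shifts$kind == "b" &
                   shifts$length == 2, ]
  expect_identical(pair$nominal_shift[1], -14L)
  expect_equal(pair$shift[1], -14.0157, tolerance = 1e-4)
  # every span containing position 6 shifts by -CH2; others are unshifted
  with_sub <- mapply(function(s, l) 6 %in% ((s - 1 + seq_len(l) - 1) %% 7 + 1),
                     shifts$start, shifts$length)
  expect_true(all(abs(shifts$shift[with_sub] + 14.0157) < 1e-3))
  expect_true(all(abs(shifts$shift[!with_sub]) < 1e-9))

  ident <- mass_shift_check(ncps[["Ncp-A1"]], ncps[["Ncp-A1"]],
                            registry = reg)
  expect_true(all(ident$shift == 0))
  # Ile4 -> Val4 shifts the precursor by -14
  e3 <- mass_shift_check(ncps[["Ncp-A1"]], ncps[["Ncp-E3"]], registry = reg)
  expect_identical(e3$nominal_shift[e3$kind == "precursor" &
                                      e3$label_a == "[M+H]"], -14L)
  expect_error(mass_shift_check(ncps[["Ncp-A1"]], ncps[["Ncp-E4-L"]],
                                registry = reg), "length|topology")
})
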