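# Mass model: formula arithmetic, the ADP-ribose species table, peptide
# masses, and theoretical fragment generation.

test_that("monoisotopic masses reproduce tabulated values", {
  expect_equal(monoisotopic_mass("H2O"), 18.010565, tolerance = 1e-5)
  expect_equal(round(monoisotopic_mass("C5H5N5") + proton_mass(), 4),
               136.0618)
  expect_identical(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C2Xx3"), "Xx")
  expect_equal(monoisotopic_mass(c(C = 5, H = 5, N = 5)),
               monoisotopic_mass("C5H5N5"))
})

test_that("the five ADP-ribose loss ions reproduce their printed m/z at 4 d.p.", {
  tab <- adpr_species_table()
  expect_equal(round(tab$adpr$loss_events$ion_mz, 4),
               c(136.0618, 250.0935, 348.0704, 428.0367, 542.0684))
  expect_equal(tab$adpr$loss_events$name,
               c("adenine", "adenosine-H2O", "AMP", "ADP", "ADP-ribose"))
})

test_that("modification species deltas and remainders are consistent", {
  tab <- adpr_species_table()
  expect_equal(tab$adpr$delta_mass, 541.06111, tolerance = 1e-4)
  expect_equal(tab$phosphoribose_gas$delta_mass, 193.99802, tolerance = 1e-4)
  expect_equal(tab$phosphoribose_nudix$delta_mass, 212.00859, tolerance = 1e-4)
  # hydrolysis product = gas-phase remainder + water
  expect_equal(tab$phosphoribose_nudix$delta_mass -
                 tab$phosphoribose_gas$delta_mass,
               monoisotopic_mass("H2O"), tolerance = 1e-6)
  # gas-phase phosphoribose is the AMP-loss remainder of ADPr
  amp_row <- tab$adpr$loss_events[tab$adpr$loss_events$name == "AMP", ]
  expect_equal(amp_row$remainder, tab$phosphoribose_gas$delta_mass,
               tolerance = 1e-6)
  # remainder invariant enforced by the constructor
  expect_error(mod_species("bad", 100, data.frame(
    name = "x", neutral_mass = 50, remainder = 60, ion_mz = 51)),
    "inconsistent")
})

test_that("Lys8 label delta is computed from isotope differences", {
  expect_equal(round(lys8_delta(), 5), 8.01420)
})

test_that("peptide neutral mass sums residues, water, termini and mods", {
  expect_equal(peptide_neutral_mass(modified_peptide("GG")), 132.05349,
               tolerance = 1e-4)
  tab <- adpr_species_table()
  p <- modified_peptide("GG", placements = list(`1` = tab$adpr))
  expect_equal(peptide_neutral_mass(p), 673.11460, tolerance = 1e-4)
  # acetyl and amide terminal deltas
  expect_equal(peptide_neutral_mass(modified_peptide("GG", n_term = "acetyl")) -
                 peptide_neutral_mass(modified_peptide("GG")),
               42.010565, tolerance = 1e-5)
  expect_equal(peptide_neutral_mass(modified_peptide("GG", c_term = "amide")) -
                 peptide_neutral_mass(modified_peptide("GG")),
               -0.984016, tolerance = 1e-5)
  # heavy labels: one K adds the Lys8 delta
  pk <- modified_peptide("GKG", heavy_labels = c(K = lys8_delta()))
  expect_equal(peptide_neutral_mass(pk) -
                 peptide_neutral_mass(modified_peptide("GKG")),
               lys8_delta(), tolerance = 1e-9)
  expect_error(modified_peptide(""), "empty")
  expect_error(modified_peptide("GXG"), "non-canonical")
  expect_error(modified_peptide("GG", placements = list(`5` = tab$adpr)),
               "within")
})

test_that("b/y and c/z ion m/z values follow the standard offsets", {
  f_hcd <- theoretical_fragments(modified_peptide("AK"), "HCD", 1)
  expect_equal(f_hcd$mz[f_hcd$series == "b" & f_hcd$index == 1], 72.04439,
               tolerance = 1e-4)
  expect_equal(f_hcd$mz[f_hcd$series == "y" & f_hcd$index == 1], 147.11280,
               tolerance = 1e-4)
  f_etd <- theoretical_fragments(modified_peptide("AK"), "ETD", 1)
  expect_equal(f_etd$mz[f_etd$series == "c" & f_etd$index == 1], 89.07094,
               tolerance = 1e-4)
  expect_error(theoretical_fragments(modified_peptide("A"), "HCD"), "length")
})

test_that("an ETD z1 ion carries the intact ADP-ribose delta", {
  tab <- adpr_species_table()
  p_mod <- modified_peptide("AS", placements = list(`2` = tab$adpr))
  f_mod <- theoretical_fragments(p_mod, "ETD", 1)
  f_un <- theoretical_fragments(modified_peptide("AS"), "ETD", 1)
  z1_mod <- f_mod$mz[f_mod$series == "z" & f_mod$index == 1]
  z1_un <- f_un$mz[f_un$series == "z" & f_un$index == 1]
  expect_equal(z1_mod - z1_un, 541.06111, tolerance = 1e-4)
  expect_false(any(f_mod$mod_state %in% c("full_loss",
                                          "phosphoribose_remainder")))
})

test_that("HCD emits three loss states plus the diagnostic ion for modified fragments", {
  tab <- adpr_species_table()
  p <- modified_peptide("AS", placements = list(`2` = tab$adpr))
  f <- theoretical_fragments(p, "HCD", 1)
  y1 <- f[f$series == "y" & f$index == 1, ]
  expect_setequal(y1$mod_state,
                  c("intact", "phosphoribose_remainder", "full_loss"))
  expect_equal(y1$mz[y1$mod_state == "intact"] -
                 y1$mz[y1$mod_state == "full_loss"],
               541.06111, tolerance = 1e-4)
  expect_true(any(f$series == "diagnostic" &
                    round(f$mz, 4) == 136.0618))
})

test_that("fragment masses conserve the peptide mass (complementarity)", {
  for (seed in 1:10) {
    seq <- random_st_peptide(sample(6:20, 1), seed)
    p <- modified_peptide(seq)
    m <- peptide_neutral_mass(p)
    n <- nchar(seq)
    f <- theoretical_fragments(p, "HCD", 1)
    b <- f[f$series == "b", ]
    y <- f[f$series == "y", ]
    for (i in seq_len(n - 1)) {
      expect_equal(b$neutral[b$index == i] + y$neutral[y$index == n - i], m,
                   tolerance = 1e-4)
    }
    fe <- theoretical_fragments(p, "ETD", 1)
    cc <- fe[fe$series == "c", ]
    zz <- fe[fe$series == "z", ]
    # c/z offsets sum to +NH3 - NH2 = +H relative to b/y
    for (i in seq_len(n - 1)) {
      expect_equal(cc$neutral[cc$index == i] + zz$neutral[zz$index == n - i],
                   m + 1.007825, tolerance = 1e-4)
    }
  }
})

test_that("subtracting each printed neutral loss from an intact fragment reproduces the reduced state", {
  tab <- adpr_species_table()
  p <- modified_peptide("GGSGGK", placements = list(`3` = tab$adpr))
  f <- theoretical_fragments(p, "HCD", 2)
  amp <- tab$adpr$loss_events$neutral_mass[tab$adpr$loss_events$name == "AMP"]
  full <- tab$adpr$loss_events$neutral_mass[
    tab$adpr$loss_events$name == "ADP-ribose"]
  spans <- f[f$mod_state == "intact", ]
  for (r in seq_len(nrow(spans))) {
    row <- spans[r, ]
    sel <- f$series == row$series & f$index == row$index &
      f$charge == row$charge
    pr <- f$mz[sel & f$mod_state == "phosphoribose_remainder"]
    fl <- f$mz[sel & f$mod_state == "full_loss"]
    expect_equal(row$mz - amp / row$charge, pr, tolerance = 1e-4)
    expect_equal(row$mz - full / row$charge, fl, tolerance = 1e-4)
  }
})

test_that("precursor loss ions cover the five-species ladder", {
  tab <- adpr_species_table()
  p <- modified_peptide("GGSGGK", placements = list(`3` = tab$adpr))
  loss <- precursor_loss_ions(p, 2)
  expect_equal(nrow(loss), 5L)
  m <- peptide_neutral_mass(p)
  expect_equal(loss$mz,
               (m - tab$adpr$loss_events$neutral_mass + 2 * proton_mass()) / 2,
               tolerance = 1e-9)
})
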