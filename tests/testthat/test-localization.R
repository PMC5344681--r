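# Site localization, serine validation, and confidence filtering.

test_that("the H3 synthetic peptide localizes to S10 with high probability", {
  p <- h3_peptide(10L)
  s <- simulate_etd(p, 3, zero_noise())
  loc <- localization_probabilities(s, p, candidate_residues = "ST",
                                    protein_start = 1L)
  expect_equal(loc$best_site, 10L)
  expect_equal(loc$best_protein_site, 10L)
  expect_identical(loc$best_residue, "S")
  expect_gt(loc$probabilities[match(10L, loc$candidate_sites)], 0.9)
  v <- validate_serine_site(loc, s, p)
  expect_true(v$pass)
  expect_length(v$reasons, 0L)
})

test_that("the PARP-1 peptide's third serine maps to protein coordinate 507", {
  p <- parp1_peptide(14L)
  s <- simulate_etd(p, 4, zero_noise())
  loc <- localization_probabilities(s, p, candidate_residues = "ST",
                                    protein_start = 494L)
  expect_equal(loc$best_protein_site, 507L)
  expect_gt(max(loc$probabilities), 0.9)
})

test_that("probabilities always normalize and with no evidence are uniform", {
  p <- h3_peptide(10L)
  # empty spectrum: no evidence at all
  empty <- new_spectrum("e", precursor_mz(p, 3), 3, "ETD")
  loc <- localization_probabilities(empty, p, "ST")
  k <- length(loc$candidate_sites)
  expect_equal(sum(loc$probabilities), 1, tolerance = 1e-9)
  expect_equal(loc$probabilities, rep(1 / k, k), tolerance = 1e-9)
  # normalization under noise, across several simulated spectra
  for (seed in 1:5) {
    s <- simulate_etd(p, 3, noise_model(fragment_dropout_prob = 0.3,
                                        mz_jitter_ppm = 5, seed = seed))
    l2 <- localization_probabilities(s, p, "ST")
    expect_equal(sum(l2$probabilities), 1, tolerance = 1e-9)
    expect_true(all(l2$probabilities >= 0 & l2$probabilities <= 1))
  }
  expect_error(localization_probabilities(empty, modified_peptide("GGAGG"),
                                          "ST", species = .species_tab$adpr),
               "no candidate")
})

test_that("full-loss-only evidence yields uniform probabilities and fails validation", {
  p <- h3_peptide(10L)
  f <- theoretical_fragments(p, "HCD", 1)
  fl <- f[f$mod_state %in% c("full_loss", "unmodified"), ]
  s <- new_spectrum("fl", precursor_mz(p, 2), 2, "HCD", fl$mz,
                    rep(100, nrow(fl)))
  loc <- localization_probabilities(s, p, "ST")
  k <- length(loc$candidate_sites)
  expect_equal(loc$probabilities, rep(1 / k, k), tolerance = 1e-9)
  # single-serine peptide: best site is serine but the evidence is void
  p1 <- modified_peptide("GGAGSAGGK",
                         placements = list(`5` = .species_tab$adpr))
  f1 <- theoretical_fragments(p1, "HCD", 1)
  fl1 <- f1[f1$mod_state %in% c("full_loss", "unmodified"), ]
  s1 <- new_spectrum("fl1", precursor_mz(p1, 2), 2, "HCD", fl1$mz,
                     rep(100, nrow(fl1)))
  loc1 <- localization_probabilities(s1, p1, "S")
  v <- validate_serine_site(loc1, s1, p1)
  expect_false(v$pass)
  expect_true("no intact/phosphoribose evidence" %in% v$reasons)
})

test_that("an empty spectrum fails every validation clause", {
  p1 <- modified_peptide("GGAGSAGGK",
                         placements = list(`5` = .species_tab$adpr))
  s <- new_spectrum("e", precursor_mz(p1, 2), 2, "ETD")
  loc <- localization_probabilities(s, p1, "S")
  v <- validate_serine_site(loc, s, p1)
  expect_false(v$pass)
  expect_true("no intact/phosphoribose evidence" %in% v$reasons)
  expect_true(any(grepl("site-determining", v$reasons)))
})

test_that("validation errors when the best site is not a serine", {
  p <- modified_peptide("GGTGGK", placements = list(`3` = .species_tab$adpr))
  s <- simulate_etd(p, 2, zero_noise())
  loc <- localization_probabilities(s, p, "ST")
  expect_identical(loc$best_residue, "T")
  expect_error(validate_serine_site(loc, s, p), "not a serine")
})

test_that("site-determining ions discriminate adjacent candidate sites", {
  p <- h3_peptide(10L)
  s <- simulate_etd(p, 3, zero_noise())
  sdi <- site_determining_ions(s, p, 10L, 11L)
  expect_gte(sdi$count_a, 1L)
  expect_equal(sdi$count_b, 0L)
  expect_error(site_determining_ions(s, p, 10L, 10L), "differ")
  # empty spectrum has no site-determining evidence
  empty <- new_spectrum("e", precursor_mz(p, 3), 3, "ETD")
  sdi0 <- site_determining_ions(empty, p, 10L, 11L)
  expect_equal(sdi0$count_a, 0L)
  # full-loss-only HCD evidence never counts
  f <- theoretical_fragments(p, "HCD", 1)
  fl <- f[f$mod_state %in% c("full_loss", "unmodified"), ]
  sfl <- new_spectrum("fl", precursor_mz(p, 2), 2, "HCD", fl$mz,
                      rep(100, nrow(fl)))
  sdif <- site_determining_ions(sfl, p, 10L, 11L)
  expect_equal(sdif$count_a, 0L)
  expect_equal(sdif$count_b, 0L)
})

test_that("removing a site-determining ion never increases the true site's advantage", {
  p <- h3_peptide(10L)
  s <- simulate_etd(p, 3, zero_noise())
  loc_full <- localization_probabilities(s, p, "ST")
  i10 <- match(10L, loc_full$candidate_sites)
  adv_full <- loc_full$probabilities[i10] - max(loc_full$probabilities[-i10])
  sdi <- site_determining_ions(s, p, 10L, 11L)
  drop_mz <- sdi$ions_a$mz[sdi$ions_a$matched][1]
  s2 <- s
  s2$peaks <- s2$peaks[abs(s2$peaks$mz - drop_mz) > 1e-6, ]
  loc_less <- localization_probabilities(s2, p, "ST")
  adv_less <- loc_less$probabilities[i10] - max(loc_less$probabilities[-i10])
  expect_lte(adv_less, adv_full + 1e-12)
})

test_that("confidence filtering applies the score, ppm and probability thresholds", {
  df <- data.frame(
    peptide = c("A", "B", "C", "D"),
    score = c(50, 50, 5, 50),
    precursor_error_ppm = c(1, 3.5, 1, -1),
    localization_prob = c(0.95, 0.95, 0.95, 0.85))
  out <- filter_confident(df)
  expect_equal(out$peptide, "A")   # B: 3.5 ppm; C: low score; D: low prob
  expect_equal(nrow(filter_confident(df[0, ])), 0L)
})

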