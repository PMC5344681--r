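# Search engine: preprocessing, diagnostic trigger, PSM scoring, and both
# search modes.

test_that("windowed top-N filtering keeps the configured number per window", {
  mz <- c(seq(100, 148, by = 2), seq(210, 218, by = 2))  # 25 + 5 peaks
  s <- new_spectrum("w", 500, 2, "HCD", mz, seq_along(mz))
  out <- preprocess_spectrum(s, top_n = 20)
  expect_equal(sum(out$peaks$mz < 200), 20L)
  expect_equal(sum(out$peaks$mz >= 200), 5L)
  expect_false(is.unsorted(out$peaks$mz))
  # windows are filtered independently
  s2 <- new_spectrum("w2", 500, 2, "HCD",
                     c(seq(100, 121, by = 1), seq(210, 214, by = 1)),
                     c(22:1, 5:1))
  out2 <- preprocess_spectrum(s2, top_n = 20)
  expect_equal(sum(out2$peaks$mz < 200), 20L)
  expect_equal(sum(out2$peaks$mz >= 200), 5L)
  expect_error(preprocess_spectrum(s, top_n = 0), "top_n")
})

test_that("diagnostic-ion detection respects tolerance and intensity floor", {
  target <- adenine_diagnostic_mz()
  s <- new_spectrum("d", 500, 2, "HCD", c(target, 500), c(1000, 100))
  r <- detect_diagnostic_ion(s)
  expect_true(r$present)
  expect_equal(r$intensity_rank, 1L)
  empty <- new_spectrum("e", 500, 2, "HCD")
  expect_false(detect_diagnostic_ion(empty)$present)
  # 50 ppm off with a 10 ppm tolerance
  off <- new_spectrum("o", 500, 2, "HCD", 136.0686, 1000)
  expect_false(detect_diagnostic_ion(off, tol_ppm = 10)$present)
  # low-intensity peak below the relative floor
  weak <- new_spectrum("wk", 500, 2, "HCD", c(target, 500), c(1, 1000))
  expect_false(detect_diagnostic_ion(weak, min_relative_intensity = 0.05)$present)
  etd <- new_spectrum("z", 500, 3, "ETD", target, 100)
  expect_error(detect_diagnostic_ion(etd), "ETD")
})

test_that("the ETD trigger requires both the diagnostic ion and multiple charge", {
  target <- adenine_diagnostic_mz()
  hit <- new_spectrum("t", 500, 3, "HCD", target, 1000)
  expect_true(acquisition_decision(hit))
  single <- new_spectrum("t1", 500, 1, "HCD", target, 1000)
  expect_false(acquisition_decision(single))
  miss <- new_spectrum("t2", 500, 3, "HCD", 400, 1000)
  expect_false(acquisition_decision(miss))
})

test_that("the PSM score is matched count plus matched intensity fraction", {
  theo <- data.frame(mz = c(200, 300, 400, 500))
  full <- new_spectrum("f", 600, 2, "HCD", theo$mz, rep(100, 4))
  sc <- score_psm(full, theo, 20)
  expect_equal(sc$score, 4 + 1.0)
  disjoint <- new_spectrum("d", 600, 2, "HCD", c(250, 350), c(10, 10))
  expect_equal(score_psm(disjoint, theo, 20)$score, 0)
  # half the ions matched carrying half the intensity
  half <- new_spectrum("h", 600, 2, "HCD", c(200, 300, 610, 620),
                       rep(100, 4))
  sc2 <- score_psm(half, theo, 20)
  expect_equal(sc2$score, 2 + 0.5)
  expect_error(score_psm(full, theo[0, , drop = FALSE], 20), "non-empty")
})

test_that("adding a matched peak never decreases the score", {
  theo <- data.frame(mz = seq(200, 650, by = 50))
  set.seed(42)
  for (k in 1:5) {
    sub <- sort(sample(nrow(theo), 5))
    s_small <- new_spectrum("a", 700, 2, "HCD", theo$mz[sub], rep(50, 5))
    extra <- setdiff(seq_len(nrow(theo)), sub)[1]
    s_big <- new_spectrum("b", 700, 2, "HCD", theo$mz[c(sub, extra)],
                          rep(50, 6))
    expect_gte(score_psm(s_big, theo, 20)$score,
               score_psm(s_small, theo, 20)$score)
  }
})

test_that("localization-free search generates exactly two hypotheses per candidate", {
  db <- decoy_database("MGWAETKLNSDVKQPFHYRAGSLEIKTVNDR", n_decoys = 3)
  pep <- modified_peptide("LNSDVK", c_term_labile_mod = .species_tab$adpr)
  s <- simulate_hcd(pep, 2, zero_noise())
  res <- search_localization_free(list(s), db)
  counts <- attr(res, "hypothesis_count")
  expect_equal(counts$hypotheses, 2L * counts$candidates)
  # empty inputs
  empty <- search_localization_free(list(), db)
  expect_equal(nrow(empty), 0L)
  none <- search_localization_free(list(s),
                                   data.frame(accession = character(0),
                                              sequence = character(0)))
  expect_equal(nrow(none), 0L)
})

test_that("localization-free search recovers a labile-ADPr peptide from a decoy database", {
  target <- "MGWAETKLNSDVKQPFHYRAGSLEIKTVNDR"
  db <- decoy_database(target, n_decoys = 9)
  pep <- modified_peptide("LNSDVK", c_term_labile_mod = .species_tab$adpr)
  s <- simulate_hcd(pep, 2, zero_noise())
  res <- search_localization_free(list(s), db)
  top <- res[res$rank == 1, ]
  expect_equal(top$peptide, "LNSDVK")
  expect_true(top$is_adpr_hypothesis)
  # the unmodified form of the same peptide is recovered without the tag
  s_un <- simulate_hcd(modified_peptide("LNSDVK"), 2, zero_noise())
  res_un <- search_localization_free(list(s_un), db)
  top_un <- res_un[res_un$rank == 1, ]
  expect_equal(top_un$peptide, "LNSDVK")
  expect_false(top_un$is_adpr_hypothesis)
})

test_that("variable-mod placement enumeration counts hypotheses correctly", {
  expect_length(adprms:::enumerate_placements("GGSGG", "S", 1), 2L)
  expect_length(adprms:::enumerate_placements("GSTGY", "STY", 1), 4L)
  expect_length(adprms:::enumerate_placements("GSTGY", "STY", 2), 7L)
  expect_length(adprms:::enumerate_placements("GGGGG", "STY", 1), 1L)
})

test_that("variable-mod ETD search places ADPr on the correct serine", {
  # a tryptic PARP-1-like peptide: mod on the serine at position 4
  target <- "MSEVKAAPRGKSGAALSKKSKGQVKEEGINKSEKRMKGGALK"
  db <- decoy_database(target, n_decoys = 5)
  pep <- modified_peptide("SGAALSKK",
                          placements = list(`6` = .species_tab$adpr))
  s <- simulate_etd(pep, 3, zero_noise())
  res <- search_variable_mod(list(s), db,
                             search_params("variable_mod"),
                             digest_params(max_missed_cleavages = 5,
                                           min_length = 6))
  top <- res[res$rank == 1, ]
  expect_equal(top$peptide, "SGAALSKK")
  expect_equal(top$mod_sites, "6")
  expect_true(top$is_adpr_hypothesis)
})

test_that("precursor isotope mis-assignment is corrected up to the configured offset", {
  target <- "MGWAETKLNSDVKQPFHYRAGSLEIKTVNDR"
  db <- decoy_database(target, n_decoys = 3)
  pep <- modified_peptide("LNSDVK", c_term_labile_mod = .species_tab$adpr)
  for (k in 0:3) {
    s <- simulate_hcd(pep, 2, zero_noise())
    s$precursor_mz <- s$precursor_mz + k * isotope_spacing() / 2
    res <- search_localization_free(list(s), db)
    top <- res[res$rank == 1, ]
    expect_equal(top$peptide, "LNSDVK")
    expect_equal(top$isotope_offset, k)
    expect_lt(abs(top$precursor_error_ppm), 10)
  }
  # beyond the allowed offset the precursor no longer matches
  s4 <- simulate_hcd(pep, 2, zero_noise())
  s4$precursor_mz <- s4$precursor_mz + 4 * isotope_spacing() / 2
  res4 <- search_localization_free(list(s4), db)
  expect_false("LNSDVK" %in% res4$peptide[res4$rank == 1 &
                                            res4$is_adpr_hypothesis])
})

test_that("variable-mod best placement equals brute-force enumeration on short peptides", {
  params <- search_params("variable_mod")
  for (seed in 1:8) {
    len <- sample(8:12, 1)
    seqs <- random_st_peptide(len, 100 + seed)
    sites <- which(strsplit(seqs, "")[[1]] %in%
                     strsplit(params$allowed_mod_residues, "")[[1]])
    set.seed(200 + seed)
    true_site <- sample1(sites)
    pep <- modified_peptide(seqs, placements = stats::setNames(
      list(params$species), true_site))
    s <- simulate_etd(pep, 3, noise_model(fragment_dropout_prob = 0.1,
                                          mz_jitter_ppm = 3,
                                          seed = 300 + seed))
    # brute force: rescore every single-placement hypothesis directly
    brute <- vapply(sites, function(site) {
      hyp <- modified_peptide(seqs, placements = stats::setNames(
        list(params$species), site))
      frags <- theoretical_fragments(hyp, "ETD", max_charge = 2)
      score_psm(s, frags, params$fragment_tol_ppm)$score
    }, numeric(1))
    best_brute <- sites[which.max(brute)]
    db <- data.frame(accession = "T", sequence = seqs)
    res <- search_variable_mod(list(s), db, params,
                               digest_params(max_missed_cleavages = 0,
                                             min_length = 6))
    top <- res[res$rank == 1 & res$n_mods == 1, ][1, ]
    expect_equal(as.integer(top$mod_sites), best_brute)
  }
})
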