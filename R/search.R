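# Peptide-spectrum matching. Two search modes mirror the two analysis
# strategies: a variable-modification search (ADPr or phosphoribose placed on
# a configurable residue set) and a localization-free search in which the
# modifier is an entirely labile C-terminal mass tag, so every candidate
# peptide generates exactly two hypotheses -- with and without the modifier.

#' Search parameters
#'
#' Defaults depend on the mode, following the two parameterizations used for
#' this kind of data: variable-modification searches use 4.5 ppm precursor /
#' 20 ppm fragment tolerances; localization-free searches use 10 ppm for both
#' with precursor isotope assignment allowed to be off by up to 3.
#'
#' @param mode `"variable_mod"` or `"localization_free"`.
#' @param precursor_tol_ppm,fragment_tol_ppm Mass tolerances, ppm.
#' @param isotope_offset_max Maximum precursor isotope mis-assignment (in
#'   13C-12C units) corrected during precursor matching.
#' @param max_charge Maximum precursor charge considered.
#' @param top_peaks_per_100da Peaks retained per 100 Da window before scoring.
#' @param allowed_mod_residues Residues eligible for a placed modification
#'   (variable-modification mode).
#' @param max_var_mods_per_peptide Maximum placed modifications per peptide.
#' @param max_hypotheses_per_peptide Combinatorial cap; peptides exceeding it
#'   are skipped with a warning.
#' @param species The [mod_species()] searched (default ADP-ribose).
#' @return An object of class `search_params`.
#' @export
search_params <- function(mode = c("variable_mod", "localization_free"),
                          precursor_tol_ppm = NULL, fragment_tol_ppm = NULL,
                          isotope_offset_max = NULL, max_charge = 7L,
                          top_peaks_per_100da = 20L,
                          allowed_mod_residues = "DEKRSTCYNQHM",
                          max_var_mods_per_peptide = 1L,
                          max_hypotheses_per_peptide = 200L,
                          species = adpr_species_table()$adpr) {
  mode <- match.arg(mode)
  if (mode == "variable_mod") {
    precursor_tol_ppm <- precursor_tol_ppm %||% 4.5
    fragment_tol_ppm <- fragment_tol_ppm %||% 20
    isotope_offset_max <- isotope_offset_max %||% 0L
  } else {
    precursor_tol_ppm <- precursor_tol_ppm %||% 10
    fragment_tol_ppm <- fragment_tol_ppm %||% 10
    isotope_offset_max <- isotope_offset_max %||% 3L
  }
  stopifnot(precursor_tol_ppm > 0, fragment_tol_ppm > 0,
            isotope_offset_max >= 0, inherits(species, "mod_species"))
  structure(list(mode = mode, precursor_tol_ppm = precursor_tol_ppm,
                 fragment_tol_ppm = fragment_tol_ppm,
                 isotope_offset_max = as.integer(isotope_offset_max),
                 max_charge = as.integer(max_charge),
                 top_peaks_per_100da = as.integer(top_peaks_per_100da),
                 allowed_mod_residues = allowed_mod_residues,
                 max_var_mods_per_peptide = as.integer(max_var_mods_per_peptide),
                 max_hypotheses_per_peptide = as.integer(max_hypotheses_per_peptide),
                 species = species),
            class = "search_params")
}

# Greedy nearest-first matching of theoretical m/z values to observed peaks.
# Each theoretical ion matches at most one peak and each peak is used at most
# once; candidate pairs are accepted in order of increasing |ppm error|,
# which makes the assignment deterministic.
match_peaks <- function(theo_mz, peaks, tol_ppm) {
  n_theo <- length(theo_mz)
  if (n_theo == 0L || nrow(peaks) == 0L)
    return(list(theo_peak = rep(NA_integer_, n_theo)))
  pairs_t <- integer(0); pairs_p <- integer(0); pairs_e <- numeric(0)
  mzv <- peaks$mz
  for (t in seq_len(n_theo)) {
    tol <- theo_mz[t] * tol_ppm * 1e-6
    lo <- findInterval(theo_mz[t] - tol, mzv) + 1L
    hi <- findInterval(theo_mz[t] + tol, mzv)
    if (hi >= lo) {
      idx <- lo:hi
      pairs_t <- c(pairs_t, rep(t, length(idx)))
      pairs_p <- c(pairs_p, idx)
      pairs_e <- c(pairs_e, abs(mzv[idx] - theo_mz[t]) / theo_mz[t])
    }
  }
  assign <- rep(NA_integer_, n_theo)
  if (length(pairs_t)) {
    used_peak <- logical(nrow(peaks))
    for (k in order(pairs_e, pairs_t, pairs_p)) {
      t <- pairs_t[k]; pkt <- pairs_p[k]
      if (is.na(assign[t]) && !used_peak[pkt]) {
        assign[t] <- pkt
        used_peak[pkt] <- TRUE
      }
    }
  }
  list(theo_peak = assign)
}

#' Score a peptide-spectrum match
#'
#' Morpheus-convention score: the number of matched theoretical product ions
#' plus the fraction of total spectrum intensity carried by the matched
#' peaks. Each theoretical ion is matched to at most one peak (nearest within
#' tolerance) and each peak is used at most once.
#'
#' @param s A [new_spectrum()].
#' @param fragments `data.frame` of theoretical ions with an `mz` column (as
#'   from [theoretical_fragments()]).
#' @param fragment_tol_ppm Fragment tolerance, ppm.
#' @return List with `score`, `matched_peak_count`,
#'   `matched_intensity_fraction`, and `matched` (peak index per theoretical
#'   ion, NA when unmatched).
#' @export
score_psm <- function(s, fragments, fragment_tol_ppm = 20) {
  stopifnot(inherits(s, "spectrum"))
  if (nrow(fragments) == 0L) stop("fragments must be non-empty")
  m <- match_peaks(fragments$mz, s$peaks, fragment_tol_ppm)
  matched <- !is.na(m$theo_peak)
  count <- sum(matched)
  total <- sum(s$peaks$intensity)
  frac <- if (total > 0 && count > 0)
    sum(s$peaks$intensity[unique(m$theo_peak[matched])]) / total else 0
  list(score = count + frac, matched_peak_count = count,
       matched_intensity_fraction = frac, matched = m$theo_peak)
}

# Precursor match against a hypothesis neutral mass with isotope-offset
# correction. Returns NULL when outside tolerance for all offsets, else the
# best (offset, ppm error).
.precursor_match <- function(obs_neutral, hyp_neutral, tol_ppm, iso_max) {
  offs <- 0:iso_max
  err <- obs_neutral - hyp_neutral - offs * isotope_spacing()
  ppm <- err / hyp_neutral * 1e6
  ok <- abs(ppm) <= tol_ppm
  if (!any(ok)) return(NULL)
  k <- which(ok)[which.min(abs(ppm[ok]))]
  list(offset = offs[k], ppm = ppm[k])
}

.digest_candidates <- function(proteins, dparams) {
  stopifnot(is.data.frame(proteins),
            all(c("accession", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L)
    return(data.frame(peptide = character(0), accession = character(0),
                      start = integer(0)))
  cand <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    d <- digest(proteins$sequence[i], dparams)
    if (!nrow(d)) return(NULL)
    d$accession <- proteins$accession[i]
    d
  }))
  if (is.null(cand))
    return(data.frame(peptide = character(0), accession = character(0),
                      start = integer(0)))
  # one entry per unique sequence; first (accession, start) kept
  cand <- cand[order(cand$accession, cand$start), , drop = FALSE]
  cand <- cand[!duplicated(cand$peptide), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

.rank_psms <- function(df) {
  if (!nrow(df)) return(df)
  o <- order(-df$score, abs(df$precursor_error_ppm), df$n_mods, df$peptide)
  df <- df[o, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

.empty_psm_df <- function() {
  data.frame(title = character(0), peptide = character(0),
             accession = character(0), start = integer(0),
             n_mods = integer(0), mod_sites = character(0),
             is_adpr_hypothesis = logical(0), score = numeric(0),
             matched_peak_count = integer(0),
             matched_intensity_fraction = numeric(0),
             precursor_error_ppm = numeric(0), isotope_offset = integer(0),
             mode = character(0), rank = integer(0))
}

.score_hypothesis <- function(spec, pep, frags, params, pm, cand_row,
                              mod_sites, is_adpr) {
  sc <- score_psm(spec, frags, params$fragment_tol_ppm)
  data.frame(title = spec$title, peptide = pep$sequence,
             accession = cand_row$accession, start = cand_row$start,
             n_mods = length(pep$placements) +
               as.integer(!is.null(pep$c_term_labile_mod)),
             mod_sites = mod_sites, is_adpr_hypothesis = is_adpr,
             score = sc$score, matched_peak_count = sc$matched_peak_count,
             matched_intensity_fraction = sc$matched_intensity_fraction,
             precursor_error_ppm = pm$ppm, isotope_offset = pm$offset,
             mode = spec$mode, rank = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Localization-free search
#'
#' Models the modifier as an entirely labile C-terminal mass tag: for every
#' digested candidate peptide exactly two hypotheses are generated -- one
#' without the modifier and one in which the modifier contributes its mass to
#' the precursor (and to the precursor neutral-loss series on HCD spectra)
#' but not to backbone fragment masses. Precursor matching allows isotope
#' offsets `0..isotope_offset_max`.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param proteins `data.frame` with columns `accession`, `sequence` (as from
#'   [read_fasta()]).
#' @param params A [search_params()] with `mode = "localization_free"`.
#' @param dparams A [digest_params()]; defaults to the Morpheus-style
#'   parameterization (3 missed cleavages, no proline rule, min length 6).
#' @return `data.frame` of scored hypotheses per spectrum, ranked (rank 1 =
#'   best) with runner-ups retained. Attribute `hypothesis_count` records,
#'   per spectrum, the number of candidate peptides and generated hypotheses
#'   (always exactly two per candidate).
#' @export
search_localization_free <- function(spectra, proteins,
                                     params = search_params("localization_free"),
                                     dparams = digest_params(max_missed_cleavages = 3L)) {
  stopifnot(params$mode == "localization_free")
  cand <- .digest_candidates(proteins, dparams)
  counters <- data.frame(title = character(0), candidates = integer(0),
                         hypotheses = integer(0))
  out <- list()
  for (spec in spectra) {
    spec_f <- preprocess_spectrum(spec, params$top_peaks_per_100da)
    obs_neutral <- (spec$precursor_mz - proton_mass()) * spec$precursor_charge
    n_hyp <- 0L
    rows <- list()
    for (ci in seq_len(nrow(cand))) {
      pep_unmod <- modified_peptide(cand$peptide[ci])
      pep_mod <- modified_peptide(cand$peptide[ci],
                                  c_term_labile_mod = params$species)
      n_hyp <- n_hyp + 2L
      for (hyp in list(list(p = pep_unmod, adpr = FALSE),
                       list(p = pep_mod, adpr = TRUE))) {
        pm <- .precursor_match(obs_neutral, peptide_neutral_mass(hyp$p),
                               params$precursor_tol_ppm,
                               params$isotope_offset_max)
        if (is.null(pm)) next
        frags <- theoretical_fragments(
          hyp$p, spec$mode, max_charge = .fragment_charges(spec$precursor_charge),
          include_diagnostic = FALSE)
        if (hyp$adpr && spec$mode == "HCD") {
          loss <- precursor_loss_ions(hyp$p, spec$precursor_charge)
          if (nrow(loss)) {
            frags <- rbind(frags, data.frame(
              series = "precursor_loss", index = NA_integer_, charge =
                spec$precursor_charge, mod_state = "full_loss",
              neutral = NA_real_, mz = loss$mz))
          }
        }
        rows[[length(rows) + 1L]] <- .score_hypothesis(
          spec_f, hyp$p, frags, params, pm, cand[ci, ],
          if (hyp$adpr) "C-term(labile)" else "", hyp$adpr)
      }
    }
    counters <- rbind(counters, data.frame(title = spec$title,
                                           candidates = nrow(cand),
                                           hypotheses = n_hyp))
    if (length(rows)) out[[length(out) + 1L]] <- .rank_psms(do.call(rbind, rows))
  }
  res <- if (length(out)) do.call(rbind, out) else .empty_psm_df()
  attr(res, "hypothesis_count") <- counters
  res
}

# All placement combinations of up to max_mods modifications on the allowed
# residues of a peptide; returns a list of integer index vectors (the empty
# vector = unmodified hypothesis).
enumerate_placements <- function(sequence, allowed_residues, max_mods) {
  sites <- residue_positions(sequence, allowed_residues)
  out <- list(integer(0))
  if (max_mods >= 1L && length(sites)) {
    for (k in seq_len(min(max_mods, length(sites)))) {
      cmb <- if (length(sites) == 1L) list(sites) else
        utils::combn(sites, k, simplify = FALSE)
      out <- c(out, cmb)
    }
  }
  out
}

#' Variable-modification search
#'
#' Enumerates modification placements on the allowed residues (up to
#' `max_var_mods_per_peptide` per peptide) for every digested candidate
#' peptide. ETD hypotheses are matched against intact-state c/z ions only;
#' HCD hypotheses include the modification loss states and diagnostic ions.
#'
#' @inheritParams search_localization_free
#' @param params A [search_params()] with `mode = "variable_mod"`.
#' @param dparams A [digest_params()]; defaults to the MaxQuant-style
#'   parameterization (5 missed cleavages, min length 6).
#' @return Ranked PSM `data.frame` as for [search_localization_free()].
#' @export
search_variable_mod <- function(spectra, proteins,
                                params = search_params("variable_mod"),
                                dparams = digest_params()) {
  stopifnot(params$mode == "variable_mod")
  cand <- .digest_candidates(proteins, dparams)
  # precompute unmodified neutral masses and placement sets once
  base_mass <- vapply(cand$peptide, function(s)
    peptide_neutral_mass(modified_peptide(s)), numeric(1), USE.NAMES = FALSE)
  placement_sets <- lapply(cand$peptide, function(s) {
    pl <- enumerate_placements(s, params$allowed_mod_residues,
                               params$max_var_mods_per_peptide)
    if (length(pl) > params$max_hypotheses_per_peptide) {
      warning("skipping peptide ", s, ": ", length(pl),
              " placement hypotheses exceed the cap of ",
              params$max_hypotheses_per_peptide)
      return(NULL)
    }
    pl
  })
  delta <- params$species$delta_mass
  out <- list()
  for (spec in spectra) {
    spec_f <- preprocess_spectrum(spec, params$top_peaks_per_100da)
    obs_neutral <- (spec$precursor_mz - proton_mass()) * spec$precursor_charge
    rows <- list()
    for (ci in seq_len(nrow(cand))) {
      placements <- placement_sets[[ci]]
      if (is.null(placements)) next
      # cheap per-mod-count precursor screen before building any hypothesis
      ks <- sort(unique(lengths(placements)))
      pm_by_k <- lapply(ks, function(k)
        .precursor_match(obs_neutral, base_mass[ci] + k * delta,
                         params$precursor_tol_ppm,
                         params$isotope_offset_max))
      names(pm_by_k) <- as.character(ks)
      if (all(vapply(pm_by_k, is.null, logical(1)))) next
      for (pl in placements) {
        pm <- pm_by_k[[as.character(length(pl))]]
        if (is.null(pm)) next
        pep <- if (length(pl)) {
          modified_peptide(cand$peptide[ci], placements = stats::setNames(
            rep(list(params$species), length(pl)), pl))
        } else modified_peptide(cand$peptide[ci])
        frags <- theoretical_fragments(
          pep, spec$mode, max_charge = .fragment_charges(spec$precursor_charge))
        rows[[length(rows) + 1L]] <- .score_hypothesis(
          spec_f, pep, frags, params, pm, cand[ci, ],
          paste(pl, collapse = ","), length(pl) > 0L)
      }
    }
    if (length(rows)) out[[length(out) + 1L]] <- .rank_psms(do.call(rbind, rows))
  }
  if (length(out)) do.call(rbind, out) else .empty_psm_df()
}
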