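# Site localization and serine validation. Evidence is restricted to
# modification-carrying fragment states (intact or phosphoribose remainder):
# an unmodified-looking fragment cannot be distinguished from complete loss
# of the modifier during fragmentation, so such ions are disregarded.

# Evidence fragments for a placement: modification-carrying states only.
.evidence_fragments <- function(pep, mode, max_charge) {
  frags <- theoretical_fragments(
    pep, mode, max_charge = max_charge,
    hcd_states = c("intact", "phosphoribose_remainder"),
    include_diagnostic = FALSE)
  frags[frags$mod_state %in% c("intact", "phosphoribose_remainder"), ,
        drop = FALSE]
}

.place_at <- function(base_pep, site, species) {
  modified_peptide(base_pep$sequence, n_term = base_pep$n_term,
                   c_term = base_pep$c_term,
                   placements = stats::setNames(list(species), site),
                   heavy_labels = base_pep$heavy_labels)
}

#' Site localization probabilities for a modified peptide
#'
#' Rescores every placement of the modification on a candidate residue and
#' converts placement scores to probabilities on a log scale (a softmax:
#' probability of site i is exp(s_i) normalized over candidates, computed
#' relative to the best score for numerical stability -- the same family of
#' probabilities that binomial PTM-score engines report). The placement
#' score is the number of matched evidence ions minus the number of
#' predicted-but-absent ones, plus the matched intensity fraction. Only
#' modification-carrying fragment ions (intact or phosphoribose-remainder
#' states) count as evidence; fragments showing complete loss of the modifier
#' are disregarded, so a spectrum containing only full-loss evidence yields
#' uniform probabilities.
#'
#' @param spectrum A [new_spectrum()] (ETD or HCD).
#' @param peptide A [modified_peptide()] carrying exactly one placed
#'   modification, or an unplaced template plus `species`.
#' @param candidate_residues Residue letters considered as candidate sites,
#'   e.g. `"ST"`.
#' @param fragment_tol_ppm Fragment tolerance, ppm.
#' @param species The [mod_species()] being localized; defaults to the
#'   species placed on `peptide`.
#' @param protein_start Optional 1-based protein coordinate of the peptide's
#'   first residue; enables protein-coordinate site reporting.
#' @return An object of class `site_localization`: list with
#'   `candidate_sites` (peptide-local indices), `protein_sites`,
#'   `probabilities` (summing to 1), `scores`, `best_site`,
#'   `best_protein_site`, `best_residue`, `n_site_determining_ions` and
#'   `mode`.
#' @export
localization_probabilities <- function(spectrum, peptide,
                                       candidate_residues = "ST",
                                       fragment_tol_ppm = 20,
                                       species = NULL,
                                       protein_start = NA_integer_) {
  stopifnot(inherits(spectrum, "spectrum"),
            inherits(peptide, "modified_peptide"))
  if (is.null(species)) {
    if (!length(peptide$placements))
      stop("peptide carries no placed modification and no species was given")
    species <- peptide$placements[[1]]
  }
  sites <- residue_positions(peptide$sequence, candidate_residues)
  if (!length(sites))
    stop("no candidate residues (", candidate_residues, ") in peptide ",
         peptide$sequence)
  max_charge <- .fragment_charges(spectrum$precursor_charge)

  # Placement score: matched evidence ions minus predicted-but-absent
  # evidence ions, plus the matched intensity fraction. An expected
  # modification-carrying ion that is missing argues against a placement
  # just as a matched one argues for it; for single-site placements the
  # number of predicted evidence ions is identical across candidate sites,
  # so a spectrum without discriminating evidence scores all sites equally.
  scores <- vapply(sites, function(s) {
    frags <- .evidence_fragments(.place_at(peptide, s, species),
                                 spectrum$mode, max_charge)
    if (!nrow(frags)) return(0)
    sc <- score_psm(spectrum, frags, fragment_tol_ppm)
    2 * sc$matched_peak_count - nrow(frags) + sc$matched_intensity_fraction
  }, numeric(1))

  probs <- exp(scores - max(scores))
  probs <- probs / sum(probs)
  best_i <- which.max(probs)                 # ties: lowest index
  best_site <- sites[best_i]

  n_sdi <- vapply(seq_along(sites), function(i) {
    if (length(sites) == 1L) {
      frags <- .evidence_fragments(.place_at(peptide, sites[i], species),
                                   spectrum$mode, max_charge)
      return(score_psm(spectrum, frags, fragment_tol_ppm)$matched_peak_count)
    }
    others <- setdiff(seq_along(sites), i)
    other <- others[which.max(probs[others])]
    sdi <- site_determining_ions(spectrum, peptide, sites[i], sites[other],
                                 species = species,
                                 fragment_tol_ppm = fragment_tol_ppm)
    sdi$count_a
  }, integer(1))

  chars <- strsplit(peptide$sequence, "", fixed = TRUE)[[1]]
  structure(list(
    sequence = peptide$sequence,
    candidate_sites = sites,
    protein_sites = if (!is.na(protein_start)) protein_start + sites - 1L
                    else rep(NA_integer_, length(sites)),
    residues = chars[sites],
    probabilities = probs,
    scores = scores,
    best_site = best_site,
    best_protein_site = if (!is.na(protein_start))
      protein_start + best_site - 1L else NA_integer_,
    best_residue = chars[best_site],
    n_site_determining_ions = n_sdi,
    mode = spectrum$mode,
    species = species$name
  ), class = "site_localization")
}

#' @export
print.site_localization <- function(x, ...) {
  cat(sprintf("<site_localization %s: best %s%d (p=%.3f, %d site-determining ions)>\n",
              x$sequence, x$best_residue, x$best_site,
              x$probabilities[match(x$best_site, x$candidate_sites)],
              x$n_site_determining_ions[match(x$best_site, x$candidate_sites)]))
  invisible(x)
}

#' Site-determining ions between two candidate placements
#'
#' Counts matched fragment ions whose theoretical m/z differs between the two
#' placements and which carry the modification (intact or
#' phosphoribose-remainder state only). Full-loss and unmodified fragments
#' never count: they cannot distinguish an original lack of modification from
#' complete loss during fragmentation.
#'
#' @param spectrum A [new_spectrum()].
#' @param peptide Template [modified_peptide()].
#' @param site_a,site_b Two distinct candidate residue indices.
#' @param species The [mod_species()] placed.
#' @param fragment_tol_ppm Fragment tolerance, ppm.
#' @param min_relative_intensity Only matched peaks with at least this
#'   fraction of the base-peak intensity are counted.
#' @return List with `count_a`, `count_b`, and ion tables `ions_a`, `ions_b`
#'   (`data.frame` incl. matched peak intensity).
#' @export
site_determining_ions <- function(spectrum, peptide, site_a, site_b,
                                  species = NULL, fragment_tol_ppm = 20,
                                  min_relative_intensity = 0) {
  if (site_a == site_b) stop("the two placements must differ")
  if (is.null(species)) {
    if (!length(peptide$placements))
      stop("no species given and peptide carries none")
    species <- peptide$placements[[1]]
  }
  max_charge <- .fragment_charges(spectrum$precursor_charge)
  base <- if (nrow(spectrum$peaks)) max(spectrum$peaks$intensity) else 0

  side <- function(this_site, other_site) {
    fa <- .evidence_fragments(.place_at(peptide, this_site, species),
                              spectrum$mode, max_charge)
    fb_all <- theoretical_fragments(
      .place_at(peptide, other_site, species), spectrum$mode,
      max_charge = max_charge,
      hcd_states = c("intact", "phosphoribose_remainder"),
      include_diagnostic = FALSE)
    if (!nrow(fa)) return(list(count = 0L, ions = fa))
    key <- function(d) paste(d$series, d$index, d$charge, d$mod_state)
    other_mz <- fb_all$mz[match(key(fa), key(fb_all))]
    differs <- is.na(other_mz) |
      abs(other_mz - fa$mz) > fa$mz * fragment_tol_ppm * 1e-6
    fa <- fa[differs, , drop = FALSE]
    if (!nrow(fa)) return(list(count = 0L, ions = fa))
    m <- match_peaks(fa$mz, spectrum$peaks, fragment_tol_ppm)
    fa$peak_intensity <- ifelse(is.na(m$theo_peak), 0,
                                spectrum$peaks$intensity[m$theo_peak])
    fa$matched <- !is.na(m$theo_peak) &
      fa$peak_intensity >= min_relative_intensity * base
    list(count = sum(fa$matched), ions = fa)
  }

  a <- side(site_a, site_b)
  b <- side(site_b, site_a)
  list(count_a = as.integer(a$count), count_b = as.integer(b$count),
       ions_a = a$ions, ions_b = b$ions)
}

#' Validation thresholds for confident site calls
#'
#' @param min_psm_score Minimum peptide-spectrum match score (calibrated on
#'   the synthetic suite so that noiseless true matches pass and
#'   shuffled-sequence matches fail).
#' @param max_abs_ppm Maximum absolute precursor mass deviation, ppm.
#' @param min_localization_prob Minimum localization probability.
#' @param min_site_determining_ions Minimum number of high-intensity
#'   site-determining ions ("multiple" operationalized as 2).
#' @param min_relative_intensity Fraction of the base peak an ion must reach
#'   to count as high-intensity.
#' @return An object of class `validation_thresholds`.
#' @export
validation_thresholds <- function(min_psm_score = 10,
                                  max_abs_ppm = 3,
                                  min_localization_prob = 0.9,
                                  min_site_determining_ions = 2L,
                                  min_relative_intensity = 0.05) {
  stopifnot(min_psm_score > 0, max_abs_ppm > 0, min_localization_prob > 0,
            min_site_determining_ions > 0, min_relative_intensity > 0)
  structure(list(min_psm_score = min_psm_score, max_abs_ppm = max_abs_ppm,
                 min_localization_prob = min_localization_prob,
                 min_site_determining_ions = as.integer(min_site_determining_ions),
                 min_relative_intensity = min_relative_intensity),
            class = "validation_thresholds")
}

#' Validate a serine site call
#'
#' A serine site passes when (a) at least one matched fragment in the intact
#' or phosphoribose-remainder state pinpoints the serine against the best
#' alternative placement, (b) at least `min_site_determining_ions` such ions
#' reach `min_relative_intensity` of the base peak, and (c) the localization
#' probability reaches `min_localization_prob`. Failure reasons enumerate the
#' violated clauses.
#'
#' @param loc A [localization_probabilities()] result whose best site is a
#'   serine (otherwise an error).
#' @param spectrum The spectrum the localization was computed from.
#' @param thresholds A [validation_thresholds()].
#' @param peptide The template [modified_peptide()] (unplaced or placed).
#' @param species The [mod_species()]; defaults to the one on `peptide`.
#' @return List with `pass` (flag) and `reasons` (character vector of reason
#'   codes, empty on pass).
#' @export
validate_serine_site <- function(loc, spectrum, peptide,
                                 thresholds = validation_thresholds(),
                                 species = NULL) {
  stopifnot(inherits(loc, "site_localization"))
  if (loc$best_residue != "S")
    stop("best site is not a serine (", loc$best_residue, loc$best_site, ")")
  if (is.null(species)) {
    species <- if (length(peptide$placements)) peptide$placements[[1]] else
      adpr_species_table()$adpr
  }
  i <- match(loc$best_site, loc$candidate_sites)
  reasons <- character(0)

  if (loc$n_site_determining_ions[i] < 1L)
    reasons <- c(reasons, "no intact/phosphoribose evidence")

  hi_count <- if (length(loc$candidate_sites) == 1L) {
    loc$n_site_determining_ions[i]
  } else {
    others <- setdiff(seq_along(loc$candidate_sites), i)
    other <- others[which.max(loc$probabilities[others])]
    sdi <- site_determining_ions(
      spectrum, peptide, loc$best_site, loc$candidate_sites[other],
      species = species,
      min_relative_intensity = thresholds$min_relative_intensity)
    sdi$count_a
  }
  if (hi_count < thresholds$min_site_determining_ions)
    reasons <- c(reasons, "insufficient high-intensity site-determining ions")

  if (loc$probabilities[i] < thresholds$min_localization_prob)
    reasons <- c(reasons, "localization probability below threshold")

  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Filter confident site calls
#'
#' Retains entries with PSM score at or above `min_psm_score`, absolute
#' precursor deviation strictly below `max_abs_ppm`, and localization
#' probability strictly above `min_localization_prob`; output ordering is
#' deterministic (descending score, then peptide).
#'
#' @param df `data.frame` with columns `score`, `precursor_error_ppm`,
#'   `localization_prob` (and any others, carried through).
#' @param thresholds A [validation_thresholds()].
#' @return The retained rows.
#' @export
filter_confident <- function(df, thresholds = validation_thresholds()) {
  stopifnot(all(c("score", "precursor_error_ppm", "localization_prob") %in%
                  names(df)))
  if (!nrow(df)) return(df)
  keep <- df$score >= thresholds$min_psm_score &
    abs(df$precursor_error_ppm) < thresholds$max_abs_ppm &
    df$localization_prob > thresholds$min_localization_prob
  out <- df[keep, , drop = FALSE]
  if (nrow(out)) {
    out <- out[order(-out$score, out$peptide), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
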