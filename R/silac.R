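# SILAC Lys8 quantification: heavy/light pair arithmetic with explicit
# single-channel states. When one channel shows no signal the ratio is
# undefined and the state is propagated rather than capping at an arbitrary
# number.

#' Construct a SILAC isotope pair
#'
#' @param light_intensity,heavy_intensity Summed channel intensities (>= 0).
#' @param peptide Peptide identifier (sequence string), optional.
#' @return An object of class `isotope_pair` with a `state` of `"both"`,
#'   `"heavy_only"`, `"light_only"` or `"neither"`.
#' @export
isotope_pair <- function(light_intensity, heavy_intensity, peptide = NA_character_) {
  if (light_intensity < 0 || heavy_intensity < 0)
    stop("intensities must be non-negative")
  state <- if (light_intensity > 0 && heavy_intensity > 0) "both"
  else if (heavy_intensity > 0) "heavy_only"
  else if (light_intensity > 0) "light_only"
  else "neither"
  structure(list(peptide = peptide, light_intensity = light_intensity,
                 heavy_intensity = heavy_intensity, state = state),
            class = "isotope_pair")
}

#' Expected heavy-channel m/z shift for a Lys8-labeled peptide
#'
#' @param p A [modified_peptide()].
#' @param charge Precursor charge (>= 1).
#' @return Cluster spacing in Th: (number of K x 8.01420) / charge. A
#'   lysine-free peptide returns 0 with a warning (the channels coincide).
#' @export
expected_heavy_shift <- function(p, charge) {
  stopifnot(inherits(p, "modified_peptide"), charge >= 1)
  n_k <- sum(strsplit(p$sequence, "", fixed = TRUE)[[1]] == "K")
  if (n_k == 0L)
    warning("peptide contains no lysine; heavy shift is 0")
  n_k * lys8_delta() / charge
}

#' Heavy/light ratio of an isotope pair
#'
#' @param pair An [isotope_pair()].
#' @return List with `ratio` (H/L; NA when undefined), `log2_ratio`, and
#'   `state`. Single-channel pairs give an undefined ratio with the state
#'   propagated: the ratio calculation is impossible when no signal was
#'   detected in one channel.
#' @export
compute_ratio <- function(pair) {
  stopifnot(inherits(pair, "isotope_pair"))
  if (pair$state == "both") {
    r <- pair$heavy_intensity / pair$light_intensity
    list(ratio = r, log2_ratio = log2(r), state = "both")
  } else {
    list(ratio = NA_real_, log2_ratio = NA_real_, state = pair$state)
  }
}

#' Ratio-versus-intensity table
#'
#' One row per pair; single-channel rows are flagged by state and never
#' dropped. Total intensity is light + heavy.
#'
#' @param pairs List of [isotope_pair()] objects.
#' @return `data.frame` with columns `peptide`, `state`, `light_intensity`,
#'   `heavy_intensity`, `total_intensity`, `ratio`, `log2_ratio`.
#' @export
ratio_intensity_table <- function(pairs) {
  rows <- lapply(pairs, function(pr) {
    stopifnot(inherits(pr, "isotope_pair"))
    r <- compute_ratio(pr)
    data.frame(peptide = pr$peptide, state = r$state,
               light_intensity = pr$light_intensity,
               heavy_intensity = pr$heavy_intensity,
               total_intensity = pr$light_intensity + pr$heavy_intensity,
               ratio = r$ratio, log2_ratio = r$log2_ratio,
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide = character(0), state = character(0),
               light_intensity = numeric(0), heavy_intensity = numeric(0),
               total_intensity = numeric(0), ratio = numeric(0),
               log2_ratio = numeric(0))
}

#' Extract an isotope pair from a simulated MS1 pair
#'
#' Channel intensities are summed over the simulated isotopologue peaks,
#' which is robust to jitter on any single peak.
#'
#' @param sim Output of [simulate_silac_ms1_pair()].
#' @param max_labeled_k Pairs whose peptide contains more than this many
#'   lysines are rejected with an error (the labeled-residue cap).
#' @return An [isotope_pair()].
#' @export
extract_silac_pair <- function(sim, max_labeled_k = 7L) {
  stopifnot(is.list(sim), all(c("light", "heavy") %in% names(sim)))
  pep <- sim$ground_truth$peptide$sequence
  n_k <- sum(strsplit(pep, "", fixed = TRUE)[[1]] == "K")
  if (n_k > max_labeled_k)
    stop("peptide ", pep, " exceeds the maximum of ", max_labeled_k,
         " labeled lysines")
  isotope_pair(sum(sim$light$intensity), sum(sim$heavy$intensity),
               peptide = pep)
}
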