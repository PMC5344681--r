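# Synthetic-data generator: ETD/HCD MS2 spectra with ground-truth annotation
# and SILAC Lys8 MS1 isotope pairs, fully deterministic under a seed.

#' Noise model for synthetic spectra
#'
#' @param fragment_dropout_prob Probability that a true fragment peak is
#'   dropped, in \[0, 1\].
#' @param mz_jitter_ppm Standard deviation of multiplicative m/z jitter, ppm.
#' @param intensity_cv Coefficient of variation of multiplicative intensity
#'   noise.
#' @param n_noise_peaks Number of uniformly placed noise peaks added.
#' @param noise_mz_range Two-element (lo, hi) m/z range of noise peaks, Th.
#' @param seed Integer seed; identical seed + inputs give identical output.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(fragment_dropout_prob = 0, mz_jitter_ppm = 0,
                        intensity_cv = 0, n_noise_peaks = 0L,
                        noise_mz_range = c(150, 2000), seed = 1L) {
  stopifnot(fragment_dropout_prob >= 0, fragment_dropout_prob <= 1,
            mz_jitter_ppm >= 0, intensity_cv >= 0, n_noise_peaks >= 0,
            length(noise_mz_range) == 2L,
            noise_mz_range[1] < noise_mz_range[2])
  structure(list(fragment_dropout_prob = fragment_dropout_prob,
                 mz_jitter_ppm = mz_jitter_ppm,
                 intensity_cv = intensity_cv,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = as.numeric(noise_mz_range),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Guard band (ppm) within which synthetic noise peaks may not approach a
# surviving true fragment peak.
.NOISE_GUARD_PPM <- 30

# Apply dropout / jitter / intensity noise / noise peaks to annotated peaks.
# `peaks` needs columns mz, intensity; extra columns are kept for annotation.
apply_noise <- function(peaks, noise, seed_offset = 0L) {
  stopifnot(inherits(noise, "noise_model"))
  with_seed(noise$seed + seed_offset, {
    if (nrow(peaks) && noise$fragment_dropout_prob > 0) {
      keep <- stats::runif(nrow(peaks)) >= noise$fragment_dropout_prob
      peaks <- peaks[keep, , drop = FALSE]
    }
    if (nrow(peaks) && noise$mz_jitter_ppm > 0) {
      peaks$mz <- peaks$mz *
        (1 + stats::rnorm(nrow(peaks)) * noise$mz_jitter_ppm * 1e-6)
    }
    if (nrow(peaks) && noise$intensity_cv > 0) {
      peaks$intensity <- peaks$intensity *
        pmax(0.01, 1 + stats::rnorm(nrow(peaks)) * noise$intensity_cv)
    }
    if (noise$n_noise_peaks > 0L) {
      base <- if (nrow(peaks)) stats::median(peaks$intensity) else 100
      draw_clear <- function(n) {
        out <- numeric(0)
        tries <- 0L
        while (length(out) < n && tries < 50L) {
          cand <- stats::runif(n - length(out), noise$noise_mz_range[1],
                               noise$noise_mz_range[2])
          if (nrow(peaks)) {
            ok <- vapply(cand, function(x)
              all(abs(peaks$mz - x) > x * .NOISE_GUARD_PPM * 1e-6), logical(1))
            cand <- cand[ok]
          }
          out <- c(out, cand)
          tries <- tries + 1L
        }
        out
      }
      nz <- draw_clear(noise$n_noise_peaks)
      if (length(nz)) {
        noise_df <- peaks[0, , drop = FALSE]
        noise_df[seq_along(nz), "mz"] <- nz
        noise_df$intensity <- stats::runif(length(nz), 0.01, 0.3) * base
        if ("annotation" %in% names(noise_df)) noise_df$annotation <- "noise"
        peaks <- rbind(peaks, noise_df)
      }
    }
    peaks <- peaks[order(peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
    peaks
  })
}

# Fragment charge states emitted for a precursor charge: 1+, plus 2+ when the
# precursor is at least 3+.
.fragment_charges <- function(precursor_charge) {
  if (precursor_charge >= 3L) 2L else 1L
}

.spectrum_from_fragments <- function(p, frags, precursor_charge, mode, noise,
                                     title, base_intensity,
                                     extra_peaks = NULL) {
  peaks <- data.frame(mz = frags$mz,
                      intensity = rep(base_intensity, nrow(frags)),
                      annotation = paste0(frags$series,
                                          ifelse(is.na(frags$index), "",
                                                 frags$index),
                                          "/", frags$mod_state, "/",
                                          frags$charge, "+"),
                      stringsAsFactors = FALSE)
  if (!is.null(extra_peaks)) peaks <- rbind(peaks, extra_peaks)
  peaks <- apply_noise(peaks, noise)
  s <- new_spectrum(title, precursor_mz(p, precursor_charge),
                    precursor_charge, mode,
                    mz = peaks$mz, intensity = peaks$intensity)
  class(s) <- c("synthetic_spectrum", class(s))
  s$ground_truth <- list(
    peptide = p,
    sites = as.integer(names(p$placements)),
    labile_c_term = !is.null(p$c_term_labile_mod),
    mode = mode)
  s
}

#' Simulate an ETD spectrum
#'
#' Produces the complete c/z fragment ladder of the peptide (1+, and also 2+
#' for precursors of charge >= 3), every modification-spanning fragment in the
#' intact state only, then applies the noise model. With an all-zero noise
#' model the exact theoretical ladder is returned.
#'
#' @param p A [modified_peptide()].
#' @param precursor_charge Precursor charge, >= 2 (only multiply charged
#'   precursors are selected for ETD).
#' @param noise A [noise_model()].
#' @param base_intensity Intensity assigned to each true fragment peak before
#'   noise.
#' @param title Spectrum title; autogenerated when NULL.
#' @return A `synthetic_spectrum` (a [new_spectrum()] with a `ground_truth`
#'   element; the search and localization code paths never consult it).
#' @export
simulate_etd <- function(p, precursor_charge, noise = noise_model(),
                         base_intensity = 100, title = NULL) {
  if (precursor_charge < 2L)
    stop("ETD is only triggered for multiply-charged precursors (charge >= 2)")
  frags <- theoretical_fragments(p, "ETD",
                                 max_charge = .fragment_charges(precursor_charge))
  title <- title %||% sprintf("sim_etd_%s_z%d", p$sequence, precursor_charge)
  .spectrum_from_fragments(p, frags, precursor_charge, "ETD", noise, title,
                           base_intensity)
}

#' Simulate an HCD spectrum
#'
#' Produces the b/y ladder; fragments spanning a placed modification appear in
#' all three states (intact, phosphoribose remainder, full loss). If the
#' peptide carries ADP-ribose (placed or as a labile C-terminal tag), the
#' adenine diagnostic ion is added with an intensity in the top decile of the
#' spectrum, and the precursor neutral-loss ladder of the species is included.
#' A peptide with a labile C-terminal modifier yields backbone fragments
#' without the modifier mass (complete loss), per the labile model.
#'
#' @inheritParams simulate_etd
#' @param precursor_charge Precursor charge, >= 1.
#' @param diagnostic_boost Multiple of the base fragment intensity given to
#'   the diagnostic ion (keeps it "among the strongest fragment ion signals").
#' @export
simulate_hcd <- function(p, precursor_charge, noise = noise_model(),
                         base_intensity = 100, diagnostic_boost = 1.5,
                         title = NULL) {
  stopifnot(precursor_charge >= 1L)
  frags <- theoretical_fragments(p, "HCD",
                                 max_charge = .fragment_charges(precursor_charge),
                                 include_diagnostic = FALSE)
  extra <- NULL
  modified <- length(p$placements) > 0L || !is.null(p$c_term_labile_mod)
  if (modified) {
    species <- if (length(p$placements)) p$placements else
      list(p$c_term_labile_mod)
    diag_mz <- unique(unlist(lapply(species, function(s) s$diagnostic_ions)))
    loss <- precursor_loss_ions(p, precursor_charge)
    extra <- data.frame(mz = numeric(0), intensity = numeric(0),
                        annotation = character(0))
    if (nrow(loss)) {
      extra <- rbind(extra, data.frame(
        mz = loss$mz, intensity = rep(base_intensity, nrow(loss)),
        annotation = paste0("precursor-", loss$loss)))
    }
    if (length(diag_mz)) {
      extra <- rbind(extra, data.frame(
        mz = diag_mz,
        intensity = rep(diagnostic_boost * base_intensity, length(diag_mz)),
        annotation = "diagnostic"))
    }
  }
  title <- title %||% sprintf("sim_hcd_%s_z%d", p$sequence, precursor_charge)
  .spectrum_from_fragments(p, frags, precursor_charge, "HCD", noise, title,
                           base_intensity, extra_peaks = extra)
}

#' Simulate a SILAC Lys8 MS1 isotope pair
#'
#' Emits simplified light and heavy isotope clusters (three isotopologue
#' peaks each, relative 1 : 0.6 : 0.3) separated by
#' (number of K x 8.01420) / charge Th, with a heavy/light intensity ratio of
#' `true_ratio_H_over_L` before noise. A ratio of 0 yields a light-only
#' cluster and `Inf` a heavy-only cluster, emulating single-channel cases in
#' which no signal is detected in one condition.
#'
#' @param p A [modified_peptide()] (light form; the heavy channel adds the
#'   Lys8 delta per lysine).
#' @param true_ratio_H_over_L Heavy/light intensity ratio, >= 0 or `Inf`.
#' @param charge Precursor charge, >= 1.
#' @param noise A [noise_model()].
#' @param base_intensity Monoisotopic light-channel intensity before scaling.
#' @return List with `light` and `heavy` peak data.frames (`mz`, `intensity`),
#'   `spacing_th`, and `ground_truth`.
#' @export
simulate_silac_ms1_pair <- function(p, true_ratio_H_over_L, charge,
                                    noise = noise_model(),
                                    base_intensity = 1000) {
  stopifnot(inherits(p, "modified_peptide"), charge >= 1L,
            true_ratio_H_over_L >= 0)
  n_k <- sum(strsplit(p$sequence, "", fixed = TRUE)[[1]] == "K")
  if (n_k == 0L)
    warning("peptide contains no lysine: heavy and light channels coincide")
  spacing <- n_k * lys8_delta() / charge
  iso_rel <- c(1, 0.6, 0.3)
  mono <- precursor_mz(p, charge)
  cluster <- function(mz0, scale) {
    if (scale <= 0) return(data.frame(mz = numeric(0), intensity = numeric(0)))
    data.frame(mz = mz0 + (seq_along(iso_rel) - 1L) * isotope_spacing() / charge,
               intensity = base_intensity * scale * iso_rel)
  }
  light_scale <- if (is.infinite(true_ratio_H_over_L)) 0 else 1
  heavy_scale <- if (is.infinite(true_ratio_H_over_L)) 1 else
    true_ratio_H_over_L
  light <- cluster(mono, light_scale)
  heavy <- cluster(mono + spacing, heavy_scale)
  light <- apply_noise(light, noise, seed_offset = 0L)
  heavy <- apply_noise(heavy, noise, seed_offset = 1L)
  list(light = light, heavy = heavy, spacing_th = spacing,
       ground_truth = list(peptide = p, true_ratio = true_ratio_H_over_L,
                           charge = charge, n_k = n_k))
}
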