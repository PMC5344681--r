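# Pipeline configuration: one nested structure holding digestion, search,
# validation and noise parameters plus the modification-species selection.
# Round-trips losslessly through YAML.

#' Default pipeline configuration
#'
#' Defaults follow the analysis parameterizations used for this kind of
#' data: the variable-modification search uses 4.5 ppm precursor / 20 ppm
#' fragment tolerances with up to 5 missed cleavages; the localization-free
#' search uses 10/10 ppm, up to 3 missed cleavages and precursor isotope
#' offsets up to 3; minimum peptide length 6; top 20 peaks per 100 Da;
#' confident sites require < 3 ppm deviation and localization probability
#' above 0.9.
#'
#' @param seed Integer master seed; every stochastic step derives from it.
#' @param species_choice `"adpr"`, `"phosphoribose_gas"` (the gas-phase
#'   AMP-loss remainder) or `"phosphoribose_nudix"` (the hydrolysis product,
#'   which carries an extra water).
#' @param overrides Named list of fields to override (nested lists merge).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, species_choice = "adpr",
                            overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    species_choice = species_choice,
    digestion_variable_mod = list(max_missed_cleavages = 5L, min_length = 6L,
                                  proline_rule = FALSE),
    digestion_localization_free = list(max_missed_cleavages = 3L,
                                       min_length = 6L, proline_rule = FALSE),
    search_variable_mod = list(precursor_tol_ppm = 4.5, fragment_tol_ppm = 20,
                               isotope_offset_max = 0L, max_charge = 7L,
                               top_peaks_per_100da = 20L,
                               allowed_mod_residues = "DEKRSTCYNQHM",
                               max_var_mods_per_peptide = 1L),
    search_localization_free = list(precursor_tol_ppm = 10,
                                    fragment_tol_ppm = 10,
                                    isotope_offset_max = 3L, max_charge = 7L,
                                    top_peaks_per_100da = 20L),
    validation = list(min_psm_score = 10, max_abs_ppm = 3,
                      min_localization_prob = 0.9,
                      min_site_determining_ions = 2L,
                      min_relative_intensity = 0.05),
    noise = list(fragment_dropout_prob = 0, mz_jitter_ppm = 0,
                 intensity_cv = 0, n_noise_peaks = 0L,
                 noise_mz_range = c(150, 2000))
  )
  for (k in names(overrides)) {
    if (is.list(overrides[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], overrides[[k]])
    else cfg[[k]] <- overrides[[k]]
  }
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' Validate a pipeline configuration
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly-checked; invalid values raise an error naming the
#'   offending field.
#' @export
validate_config <- function(cfg) {
  check <- function(cond, field, msg)
    if (!cond) stop("invalid config field '", field, "': ", msg)
  check(cfg$species_choice %in% c("adpr", "phosphoribose_gas",
                                  "phosphoribose_nudix"),
        "species_choice", "must be adpr, phosphoribose_gas or phosphoribose_nudix")
  for (d in c("digestion_variable_mod", "digestion_localization_free")) {
    check(cfg[[d]]$max_missed_cleavages >= 0, paste0(d, "$max_missed_cleavages"),
          "must be >= 0")
    check(cfg[[d]]$min_length >= 1, paste0(d, "$min_length"), "must be >= 1")
  }
  for (s in c("search_variable_mod", "search_localization_free")) {
    check(cfg[[s]]$precursor_tol_ppm > 0, paste0(s, "$precursor_tol_ppm"),
          "must be > 0")
    check(cfg[[s]]$fragment_tol_ppm > 0, paste0(s, "$fragment_tol_ppm"),
          "must be > 0")
    check(cfg[[s]]$isotope_offset_max >= 0, paste0(s, "$isotope_offset_max"),
          "must be >= 0")
  }
  check(cfg$validation$min_localization_prob > 0 &&
          cfg$validation$min_localization_prob <= 1,
        "validation$min_localization_prob", "must be in (0, 1]")
  check(cfg$noise$fragment_dropout_prob >= 0 &&
          cfg$noise$fragment_dropout_prob <= 1,
        "noise$fragment_dropout_prob", "must be in [0, 1]")
  cfg
}

#' Resolve the configured modification species
#'
#' @param cfg A `pipeline_config`.
#' @return The corresponding [mod_species()].
#' @export
config_species <- function(cfg) {
  tab <- adpr_species_table()
  switch(cfg$species_choice,
         adpr = tab$adpr,
         phosphoribose_gas = tab$phosphoribose_gas,
         phosphoribose_nudix = tab$phosphoribose_nudix)
}

#' Read / write a pipeline configuration
#'
#' @param path YAML file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  pipeline_config(seed = raw$seed %||% 1L,
                  species_choice = raw$species_choice %||% "adpr",
                  overrides = raw[setdiff(names(raw),
                                          c("seed", "species_choice"))])
}

#' @rdname read_config
#' @param cfg A `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Helpers translating config sections to parameter objects.
config_digest_params <- function(cfg, which = c("variable_mod",
                                                "localization_free")) {
  which <- match.arg(which)
  d <- cfg[[paste0("digestion_", which)]]
  digest_params(d$max_missed_cleavages, d$min_length, d$proline_rule)
}

config_search_params <- function(cfg, which = c("variable_mod",
                                                "localization_free")) {
  which <- match.arg(which)
  s <- cfg[[paste0("search_", which)]]
  search_params(mode = which,
                precursor_tol_ppm = s$precursor_tol_ppm,
                fragment_tol_ppm = s$fragment_tol_ppm,
                isotope_offset_max = s$isotope_offset_max,
                max_charge = s$max_charge,
                top_peaks_per_100da = s$top_peaks_per_100da,
                allowed_mod_residues = s$allowed_mod_residues %||%
                  "DEKRSTCYNQHM",
                max_var_mods_per_peptide = s$max_var_mods_per_peptide %||% 1L,
                species = config_species(cfg))
}

config_noise_model <- function(cfg, seed_offset = 0L) {
  n <- cfg$noise
  noise_model(n$fragment_dropout_prob, n$mz_jitter_ppm, n$intensity_cv,
              n$n_noise_peaks, unlist(n$noise_mz_range),
              seed = cfg$seed + seed_offset)
}

config_thresholds <- function(cfg) {
  v <- cfg$validation
  validation_thresholds(v$min_psm_score, v$max_abs_ppm,
                        v$min_localization_prob,
                        v$min_site_determining_ions,
                        v$min_relative_intensity)
}
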