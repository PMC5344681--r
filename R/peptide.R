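# Modified peptides: sequence + terminal groups + per-residue modification
# placements (or a labile C-terminal mass tag) + SILAC heavy labels.

#' Construct a modified peptide
#'
#' @param sequence Upper-case amino-acid string over the 20 canonical residues.
#' @param n_term `"free"` or `"acetyl"` (+42.01057 Da).
#' @param c_term `"free"` (acid) or `"amide"` (-0.98402 Da).
#' @param placements Named list mapping 1-based residue index (as the list
#'   name) to a [mod_species()]; or NULL.
#' @param c_term_labile_mod Optional [mod_species()] carried as an entirely
#'   labile C-terminal mass tag (localization-free searching): it contributes
#'   to the precursor mass but not to backbone fragment masses. Mutually
#'   exclusive with `placements`.
#' @param heavy_labels Named numeric vector mapping a residue letter to a mass
#'   delta applied at every occurrence, e.g. `c(K = lys8_delta())`.
#' @return An object of class `modified_peptide`.
#' @examples
#' sp <- adpr_species_table()
#' p <- modified_peptide("ARTKQTARKSTGGKAPRKQLAGGA", n_term = "acetyl",
#'                       c_term = "amide", placements = list(`10` = sp$adpr))
#' peptide_neutral_mass(p)
#' @export
modified_peptide <- function(sequence, n_term = c("free", "acetyl"),
                             c_term = c("free", "amide"),
                             placements = NULL, c_term_labile_mod = NULL,
                             heavy_labels = NULL) {
  n_term <- match.arg(n_term)
  c_term <- match.arg(c_term)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty peptide sequence")
  residues <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(residues), names(.RESIDUE_MASS_TABLE))
  if (length(bad))
    stop("non-canonical residue(s): ", paste(bad, collapse = ", "))
  n <- length(residues)
  if (!is.null(placements)) {
    if (length(placements)) {
      idx <- as.integer(names(placements))
      if (any(is.na(idx)) || any(idx < 1L) || any(idx > n))
        stop("placement indices must lie within [1, ", n, "]")
      if (anyDuplicated(idx)) stop("duplicate placement indices")
      ok <- vapply(placements, inherits, logical(1), what = "mod_species")
      if (!all(ok)) stop("placements must be mod_species objects")
    }
    if (!is.null(c_term_labile_mod) && length(placements))
      stop("a peptide has either placements or a C-terminal labile modifier, never both")
  }
  if (!is.null(c_term_labile_mod) &&
      !inherits(c_term_labile_mod, "mod_species"))
    stop("c_term_labile_mod must be a mod_species")
  if (!is.null(heavy_labels)) {
    stopifnot(is.numeric(heavy_labels), !is.null(names(heavy_labels)))
  }
  structure(list(sequence = sequence, n_term = n_term, c_term = c_term,
                 placements = placements %||% list(),
                 c_term_labile_mod = c_term_labile_mod,
                 heavy_labels = heavy_labels),
            class = "modified_peptide")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.modified_peptide <- function(x, ...) {
  mods <- if (length(x$placements)) {
    paste(vapply(seq_along(x$placements), function(i) {
      sprintf("%s@%s", x$placements[[i]]$name, names(x$placements)[i])
    }, character(1)), collapse = ", ")
  } else if (!is.null(x$c_term_labile_mod)) {
    paste0(x$c_term_labile_mod$name, "@C-term (labile)")
  } else "none"
  cat(sprintf("<modified_peptide %s [%s/%s] mods: %s>\n",
              x$sequence, x$n_term, x$c_term, mods))
  invisible(x)
}

# Per-residue mass vector including heavy labels and placed modification
# deltas; used by both the precursor mass and the fragment generator.
.residue_mass_vector <- function(p, include_placements = TRUE) {
  residues <- strsplit(p$sequence, "", fixed = TRUE)[[1]]
  m <- .RESIDUE_MASS_TABLE[residues]
  if (!is.null(p$heavy_labels)) {
    hit <- residues %in% names(p$heavy_labels)
    m[hit] <- m[hit] + p$heavy_labels[residues[hit]]
  }
  if (include_placements && length(p$placements)) {
    idx <- as.integer(names(p$placements))
    m[idx] <- m[idx] + vapply(p$placements, function(s) s$delta_mass,
                              numeric(1))
  }
  unname(m)
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus water, terminal-group deltas, placed
#' modification deltas, any labile C-terminal modifier, and heavy-label deltas.
#'
#' @param p A [modified_peptide()].
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass(modified_peptide("GG"))  # 132.05349
#' @export
peptide_neutral_mass <- function(p) {
  stopifnot(inherits(p, "modified_peptide"))
  m <- sum(.residue_mass_vector(p)) + .MASS_H2O +
    .NTERM_DELTA[[p$n_term]] + .CTERM_DELTA[[p$c_term]]
  if (!is.null(p$c_term_labile_mod)) m <- m + p$c_term_labile_mod$delta_mass
  m
}

#' Precursor m/z of a peptide at a given charge
#'
#' @param p A [modified_peptide()].
#' @param charge Positive integer charge state.
#' @return m/z in Th.
#' @export
precursor_mz <- function(p, charge) {
  stopifnot(charge >= 1)
  (peptide_neutral_mass(p) + charge * proton_mass()) / charge
}

# Indices of residues matching a candidate set, e.g. "ST".
residue_positions <- function(sequence, residues) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  which(chars %in% strsplit(residues, "", fixed = TRUE)[[1]])
}
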