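# Monoisotopic mass arithmetic. The atomic mass table is pinned here, once,
# to >= 5 decimals (NIST/CODATA); everything downstream derives from it.

.ATOMIC_MASS <- c(
  H = 1.0078250319,
  C = 12.0,
  N = 14.0030740052,
  O = 15.9949146221,
  P = 30.97376151,
  S = 31.97207069
)

.PROTON_MASS <- 1.007276467
.C13_DELTA   <- 1.0033548378   # 13C - 12C
.N15_DELTA   <- 0.9970348893   # 15N - 14N

.MASS_H2O <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]
.MASS_NH3 <- 3 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["N"]]
.MASS_NH2 <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["N"]]

# Terminal-group deltas relative to a free amine / free acid backbone.
.NTERM_DELTA <- c(free = 0, acetyl = 2 * .ATOMIC_MASS[["C"]] +
                    2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]])
.CTERM_DELTA <- c(free = 0, amide = .MASS_NH2 - .ATOMIC_MASS[["H"]] -
                    .ATOMIC_MASS[["O"]])

#' Parse an element formula
#'
#' Accepts either a Hill-style formula string such as `"C5H5N5"` or a named
#' numeric vector of element counts. Counts must be non-negative integers.
#'
#' @param formula A formula string or named numeric vector.
#' @return A named integer vector of element counts.
#' @examples
#' parse_formula("C10H14N5O7P")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("numeric formulas must be fully named by element symbol")
    counts <- formula
  } else if (is.character(formula) && length(formula) == 1L) {
    if (!nzchar(formula)) return(setNames(integer(0), character(0)))
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (sum(nchar(tokens)) != nchar(formula))
      stop("malformed element formula: ", formula)
    sym <- sub("[0-9]*$", "", tokens)
    num <- sub("^[A-Z][a-z]?", "", tokens)
    counts <- ifelse(nzchar(num), as.numeric(num), 1)
    names(counts) <- sym
    counts <- tapply(counts, names(counts), sum)
    counts <- setNames(as.numeric(counts), names(counts))
  } else {
    stop("formula must be a string or a named numeric vector")
  }
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("element counts must be non-negative integers")
  setNames(as.integer(counts), names(counts))
}

#' Monoisotopic mass of an element formula
#'
#' @param formula A formula string (e.g. `"C5H5N5"`) or a named vector of
#'   element counts. The empty formula has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")              # 18.01056
#' monoisotopic_mass("C5H5N5") + proton_mass()  # protonated adenine, 136.0618
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

#' @describeIn monoisotopic_mass Mass of the proton, Da.
#' @export
proton_mass <- function() .PROTON_MASS

#' @describeIn monoisotopic_mass The C12/C13 isotopologue spacing, Da.
#' @export
isotope_spacing <- function() .C13_DELTA

#' Mass shift of the SILAC Lys8 label
#'
#' Six 12C -> 13C plus two 14N -> 15N substitutions on lysine; computed from
#' the isotope mass differences rather than hard-coded.
#'
#' @return Mass delta in Da (8.01420).
#' @export
lys8_delta <- function() 6 * .C13_DELTA + 2 * .N15_DELTA

# Residue elemental compositions (monomer residues, i.e. minus water).
.RESIDUE_FORMULA <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

#' Monoisotopic residue masses of the 20 canonical amino acids
#'
#' @return Named numeric vector of residue (monomer) masses in Da, derived
#'   from elemental compositions.
#' @export
residue_masses <- function() .RESIDUE_MASS_TABLE

.RESIDUE_MASS_TABLE <- vapply(.RESIDUE_FORMULA, function(f) {
  sum(.ATOMIC_MASS[names(f)] * f)
}, numeric(1))
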