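# Theoretical fragment-ion generation. ETD yields c/z ions that preserve the
# modification; HCD yields b/y ions in up to three modification states
# (intact, phosphoribose remainder after AMP loss, complete loss) plus the
# species' low-mass diagnostic ions.

.C_OFFSET <- .MASS_NH3                      # c = b + NH3
.Z_OFFSET <- -.MASS_NH2                     # z-dot = y - NH2 (radical z ion)

#' Theoretical fragment ions of a modified peptide
#'
#' For ETD only c and z(dot) ions are produced and every fragment spanning a
#' placed modification is emitted exclusively in the intact state (ETD
#' preserves the ADP-ribose--serine linkage). For HCD, b and y ions are
#' produced; fragments spanning a placed modification are emitted in the
#' requested loss states, and the placed species' diagnostic ions are appended
#' as standalone entries (series `"diagnostic"`). A labile C-terminal modifier
#' is ignored here by construction: it contributes to the precursor, never to
#' backbone fragments.
#'
#' @param p A [modified_peptide()] of length >= 2.
#' @param mode `"HCD"` or `"ETD"`.
#' @param max_charge Fragments are emitted at charges `1..max_charge`.
#' @param hcd_states Which modification states to emit for HCD fragments that
#'   span a placed modification. The phosphoribose-remainder state is only
#'   produced for species with an AMP loss event.
#' @param include_diagnostic Append diagnostic-ion entries for HCD spectra of
#'   modified peptides.
#' @return `data.frame` with columns `series` (b/y/c/z/diagnostic), `index`,
#'   `charge`, `mod_state` (unmodified/intact/phosphoribose_remainder/
#'   full_loss/diagnostic), `neutral` and `mz`.
#' @examples
#' frags <- theoretical_fragments(modified_peptide("AK"), "HCD", 1)
#' subset(frags, series == "b" & index == 1)$mz   # 72.04439
#' @export
theoretical_fragments <- function(p, mode = c("HCD", "ETD"), max_charge = 1L,
                                  hcd_states = c("intact",
                                                 "phosphoribose_remainder",
                                                 "full_loss"),
                                  include_diagnostic = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "modified_peptide"), max_charge >= 1L)
  hcd_states <- match.arg(hcd_states, several.ok = TRUE)
  n <- nchar(p$sequence)
  if (n < 2) stop("peptide must have length >= 2 for fragmentation")

  res_mass <- .residue_mass_vector(p, include_placements = FALSE)
  delta <- numeric(n)        # placed modification delta per residue
  amp_loss <- numeric(n)     # mass removed in the phosphoribose state
  has_amp <- logical(n)
  if (length(p$placements)) {
    idx <- as.integer(names(p$placements))
    for (k in seq_along(idx)) {
      sp <- p$placements[[k]]
      delta[idx[k]] <- delta[idx[k]] + sp$delta_mass
      amp_row <- sp$loss_events[sp$loss_events$name == "AMP", , drop = FALSE]
      if (nrow(amp_row)) {
        amp_loss[idx[k]] <- amp_row$neutral_mass[1]
        has_amp[idx[k]] <- TRUE
      }
    }
  }

  pre_res <- cumsum(res_mass)          # residues 1..i
  pre_mod <- cumsum(delta)
  pre_amp <- cumsum(amp_loss)
  pre_n   <- cumsum(delta > 0)
  tot_res <- pre_res[n]

  i <- seq_len(n - 1L)                 # prefix fragment index
  j <- i                               # suffix fragment index (count from C)

  prefix_neutral <- pre_res[i] + .NTERM_DELTA[[p$n_term]]
  prefix_moddelta <- pre_mod[i]
  prefix_amp <- pre_amp[i]
  prefix_spans <- pre_n[i] > 0

  suffix_neutral <- (tot_res - pre_res[n - j]) + .MASS_H2O +
    .CTERM_DELTA[[p$c_term]]
  suffix_moddelta <- pre_mod[n] - pre_mod[n - j]
  suffix_amp <- pre_amp[n] - pre_amp[n - j]
  suffix_spans <- (pre_n[n] - pre_n[n - j]) > 0

  emit <- function(series, index, base_neutral, moddelta, ampneutral, spans) {
    # one row-block per state
    rows <- list()
    states <- if (mode == "ETD") "intact" else hcd_states
    add <- function(state, neutral, which) {
      if (!any(which)) return()
      rows[[length(rows) + 1L]] <<- data.frame(
        series = series, index = index[which], state = state,
        neutral = neutral[which], stringsAsFactors = FALSE)
    }
    add("unmodified", base_neutral, !spans)
    if ("intact" %in% states)
      add("intact", base_neutral + moddelta, spans)
    if (mode == "HCD" && "phosphoribose_remainder" %in% hcd_states)
      add("phosphoribose_remainder", base_neutral + moddelta - ampneutral,
          spans & ampneutral > 0)
    if (mode == "HCD" && "full_loss" %in% hcd_states)
      add("full_loss", base_neutral, spans)
    do.call(rbind, rows)
  }

  if (mode == "ETD") {
    blocks <- rbind(
      emit("c", i, prefix_neutral + .C_OFFSET, prefix_moddelta, prefix_amp,
           prefix_spans),
      emit("z", j, suffix_neutral + .Z_OFFSET, suffix_moddelta, suffix_amp,
           suffix_spans))
  } else {
    blocks <- rbind(
      emit("b", i, prefix_neutral, prefix_moddelta, prefix_amp, prefix_spans),
      emit("y", j, suffix_neutral, suffix_moddelta, suffix_amp, suffix_spans))
  }
  names(blocks)[names(blocks) == "state"] <- "mod_state"

  charges <- seq_len(max_charge)
  out <- do.call(rbind, lapply(charges, function(ch) {
    b <- blocks
    b$charge <- ch
    b$mz <- (b$neutral + ch * .PROTON_MASS) / ch
    b
  }))

  if (mode == "HCD" && include_diagnostic && length(p$placements)) {
    diag_mz <- unique(unlist(lapply(p$placements,
                                    function(s) s$diagnostic_ions)))
    if (length(diag_mz)) {
      out <- rbind(out, data.frame(
        series = "diagnostic", index = NA_integer_, mod_state = "diagnostic",
        neutral = diag_mz - .PROTON_MASS, charge = 1L, mz = diag_mz,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out[, c("series", "index", "charge", "mod_state", "neutral", "mz")]
}

#' Precursor neutral-loss ion m/z values for a modified precursor
#'
#' For each neutral-loss event of the placed (or labile C-terminal) species,
#' the m/z of the intact precursor minus the lost neutral, at the precursor
#' charge. These peaks accompany HCD spectra of ADP-ribosylated peptides.
#'
#' @param p A [modified_peptide()] carrying a modification.
#' @param charge Precursor charge state.
#' @return `data.frame` with columns `loss` and `mz`.
#' @export
precursor_loss_ions <- function(p, charge) {
  species <- if (length(p$placements)) {
    p$placements
  } else if (!is.null(p$c_term_labile_mod)) {
    list(p$c_term_labile_mod)
  } else return(data.frame(loss = character(0), mz = numeric(0)))
  m <- peptide_neutral_mass(p)
  losses <- unique(do.call(rbind, lapply(species, function(s)
    s$loss_events[, c("name", "neutral_mass")])))
  if (is.null(losses) || !nrow(losses))
    return(data.frame(loss = character(0), mz = numeric(0)))
  data.frame(loss = losses$name,
             mz = (m - losses$neutral_mass + charge * .PROTON_MASS) / charge,
             stringsAsFactors = FALSE)
}
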