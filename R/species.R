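# The ADP-ribose modification species model: mass deltas, staged neutral
# losses, and the low-mass diagnostic ions seen in HCD.

#' Construct a modification species
#'
#' A modification species is a residue mass delta together with its neutral
#' loss events and the diagnostic ions it produces under HCD. Each loss event
#' records the lost neutral species and the delta that remains on the peptide
#' afterwards; the constructor enforces remainder = delta - loss to 1e-4 Da.
#'
#' @param name Identifier, e.g. `"ADPr"`.
#' @param delta_mass Mass added to the modified residue, Da (> 0).
#' @param loss_events `data.frame` with columns `name`, `neutral_mass`,
#'   `remainder`, `ion_mz` (the protonated m/z of the lost species), or NULL.
#' @param diagnostic_ions Numeric vector of m/z values expected in HCD.
#' @return An object of class `mod_species`.
#' @export
mod_species <- function(name, delta_mass, loss_events = NULL,
                        diagnostic_ions = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(delta_mass) || length(delta_mass) != 1L || delta_mass <= 0)
    stop("delta_mass must be a single positive number")
  if (is.null(loss_events)) {
    loss_events <- data.frame(name = character(0), neutral_mass = numeric(0),
                              remainder = numeric(0), ion_mz = numeric(0))
  }
  stopifnot(all(c("name", "neutral_mass", "remainder", "ion_mz") %in%
                  names(loss_events)))
  bad <- abs(loss_events$remainder - (delta_mass - loss_events$neutral_mass)) > 1e-4
  if (any(bad))
    stop("loss event remainder inconsistent with delta - loss for: ",
         paste(loss_events$name[bad], collapse = ", "))
  structure(list(name = name, delta_mass = delta_mass,
                 loss_events = loss_events,
                 diagnostic_ions = diagnostic_ions),
            class = "mod_species")
}

#' @export
print.mod_species <- function(x, ...) {
  cat(sprintf("<mod_species %s: +%.5f Da, %d loss event(s), %d diagnostic ion(s)>\n",
              x$name, x$delta_mass, nrow(x$loss_events),
              length(x$diagnostic_ions)))
  invisible(x)
}

#' ADP-ribose modification species table
#'
#' Builds, from elemental compositions alone, the ADP-ribose (ADPr) species
#' (+541.06111 Da) with its five staged neutral losses -- adenine,
#' adenosine minus water, AMP, ADP and the complete ADP-ribose -- whose
#' protonated m/z values are the familiar diagnostic/loss ions at 136.0618,
#' 250.0935, 348.0704, 428.0367 and 542.0684. Two phosphoribose species are
#' also returned: the gas-phase remainder left on a peptide after AMP loss
#' (+193.99802 Da) and the Nudix-hydrolysis product, which carries an extra
#' water (+212.00859 Da). Protonated adenine is the HCD diagnostic ion of the
#' ADPr species.
#'
#' @return Named list of `mod_species`: `adpr`, `phosphoribose_gas`,
#'   `phosphoribose_nudix`.
#' @examples
#' tab <- adpr_species_table()
#' tab$adpr$delta_mass                     # 541.06111
#' tab$adpr$loss_events$ion_mz             # the five printed ion m/z values
#' @export
adpr_species_table <- function() {
  adenine   <- monoisotopic_mass("C5H5N5")
  adenosine_h2o <- monoisotopic_mass("C10H11N5O3")
  amp       <- monoisotopic_mass("C10H14N5O7P")
  adp       <- monoisotopic_mass("C10H15N5O10P2")
  adpr      <- monoisotopic_mass("C15H21N5O13P2")
  losses <- data.frame(
    name = c("adenine", "adenosine-H2O", "AMP", "ADP", "ADP-ribose"),
    neutral_mass = c(adenine, adenosine_h2o, amp, adp, adpr),
    stringsAsFactors = FALSE
  )
  losses$remainder <- adpr - losses$neutral_mass
  losses$ion_mz <- losses$neutral_mass + proton_mass()

  pr_gas <- adpr - amp
  pr_nudix <- pr_gas + monoisotopic_mass("H2O")

  list(
    adpr = mod_species("ADPr", adpr, losses,
                       diagnostic_ions = adenine + proton_mass()),
    phosphoribose_gas = mod_species(
      "phosphoribose-gas", pr_gas,
      data.frame(name = "phosphoribose", neutral_mass = pr_gas, remainder = 0,
                 ion_mz = pr_gas + proton_mass())),
    phosphoribose_nudix = mod_species(
      "phosphoribose-nudix", pr_nudix,
      data.frame(name = "phosphoribose", neutral_mass = pr_nudix,
                 remainder = 0, ion_mz = pr_nudix + proton_mass()))
  )
}

#' m/z of the protonated adenine diagnostic ion
#'
#' @return 136.0618 (4 d.p.), from the composition C5H5N5 plus a proton.
#' @export
adenine_diagnostic_mz <- function() {
  monoisotopic_mass("C5H5N5") + proton_mass()
}
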