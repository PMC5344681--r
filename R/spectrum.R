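# Centroided spectrum container and acquisition-side operations: windowed
# top-N peak filtering, adenine diagnostic-ion detection, and the
# product-ion-trigger decision that re-isolates a precursor for ETD.

#' Construct a centroided spectrum
#'
#' @param title Spectrum identifier.
#' @param precursor_mz Precursor m/z in Th.
#' @param precursor_charge Positive integer charge.
#' @param mode `"HCD"` or `"ETD"`.
#' @param mz,intensity Numeric peak vectors of equal length; stored sorted by
#'   m/z. Intensities must be non-negative.
#' @return An object of class `spectrum`: a list with a `peaks` data.frame.
#' @export
new_spectrum <- function(title, precursor_mz, precursor_charge,
                         mode = c("HCD", "ETD"), mz = numeric(0),
                         intensity = numeric(0)) {
  mode <- match.arg(mode)
  stopifnot(length(mz) == length(intensity), precursor_charge >= 1,
            precursor_mz > 0)
  if (any(intensity < 0)) stop("intensities must be >= 0")
  o <- order(mz)
  structure(list(title = as.character(title),
                 precursor_mz = precursor_mz,
                 precursor_charge = as.integer(precursor_charge),
                 mode = mode,
                 peaks = data.frame(mz = mz[o], intensity = intensity[o])),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum '%s' %s z=%d prec=%.4f, %d peaks>\n", x$title,
              x$mode, x$precursor_charge, x$precursor_mz, nrow(x$peaks)))
  invisible(x)
}

#' Windowed top-N peak filtering
#'
#' Within each consecutive 100-Da window, starting at the spectrum's lowest
#' m/z, only the `top_n` most intense peaks are retained (FTMS "top peaks per
#' 100 Da"). Peak order by m/z is preserved.
#'
#' @param s A [new_spectrum()].
#' @param top_n Peaks retained per window (default 20).
#' @param window_da Window width in Da.
#' @return The filtered spectrum.
#' @export
preprocess_spectrum <- function(s, top_n = 20L, window_da = 100) {
  stopifnot(inherits(s, "spectrum"))
  if (top_n < 1) stop("top_n must be >= 1")
  pk <- s$peaks
  if (nrow(pk) == 0L) return(s)
  win <- floor((pk$mz - pk$mz[1]) / window_da)
  keep <- unlist(lapply(split(seq_len(nrow(pk)), win), function(ix) {
    if (length(ix) <= top_n) return(ix)
    ix[order(pk$intensity[ix], decreasing = TRUE)[seq_len(top_n)]]
  }), use.names = FALSE)
  keep <- sort(keep)
  s$peaks <- pk[keep, , drop = FALSE]
  rownames(s$peaks) <- NULL
  s
}

#' Detect the adenine diagnostic ion in an HCD spectrum
#'
#' Looks for a peak within `tol_ppm` of protonated adenine (136.0618) whose
#' intensity is at least `min_relative_intensity` of the base peak. ETD input
#' is an error: the diagnostic ion is not generated in the ETD reaction.
#'
#' @param s An HCD [new_spectrum()].
#' @param tol_ppm Mass tolerance in ppm.
#' @param min_relative_intensity Fraction of the base-peak intensity the
#'   diagnostic peak must reach to count as present.
#' @return List with `present` (flag) and `intensity_rank` (1 = most intense
#'   peak; NA when absent).
#' @export
detect_diagnostic_ion <- function(s, tol_ppm = 10, min_relative_intensity = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  if (s$mode != "HCD")
    stop("diagnostic-ion detection requires an HCD spectrum; ",
         "ETD spectra do not contain the adenine diagnostic ion")
  target <- adenine_diagnostic_mz()
  pk <- s$peaks
  if (nrow(pk) == 0L) return(list(present = FALSE, intensity_rank = NA_integer_))
  within <- abs(pk$mz - target) <= target * tol_ppm * 1e-6
  if (!any(within)) return(list(present = FALSE, intensity_rank = NA_integer_))
  cand <- which(within)[which.max(pk$intensity[within])]
  base <- max(pk$intensity)
  if (pk$intensity[cand] < min_relative_intensity * base)
    return(list(present = FALSE, intensity_rank = NA_integer_))
  rank <- sum(pk$intensity > pk$intensity[cand]) + 1L
  list(present = TRUE, intensity_rank = as.integer(rank))
}

#' Diagnostic-ion product trigger decision
#'
#' Emulates the acquisition decision tree: upon detection of an intense
#' adenine diagnostic peak in the HCD scan of a multiply-charged precursor,
#' that precursor is immediately re-isolated and subjected to ETD. Singly
#' charged precursors never trigger.
#'
#' @inheritParams detect_diagnostic_ion
#' @return Logical: whether an ETD scan would be triggered.
#' @export
acquisition_decision <- function(s, tol_ppm = 10, min_relative_intensity = 0.05) {
  stopifnot(inherits(s, "spectrum"))
  if (s$precursor_charge < 2L) return(FALSE)
  detect_diagnostic_ion(s, tol_ppm, min_relative_intensity)$present
}
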