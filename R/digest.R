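# In-silico tryptic digestion. Two parameterizations are used in practice:
# a MaxQuant-style search (5 missed cleavages, min length 6 -- the partial
# FASP protocol yields long multi-missed-cleavage peptides) and a
# Morpheus-style search (3 missed cleavages, no proline rule).

#' Digestion parameters
#'
#' @param max_missed_cleavages Maximum internal cleavage sites per peptide.
#' @param min_length Minimum peptide length retained.
#' @param proline_rule If TRUE, cleavage after K/R is suppressed when the next
#'   residue is proline.
#' @param clip_nterm_met If TRUE, additionally consider the protein with its
#'   initiator methionine removed. Off by default.
#' @return An object of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 5L, min_length = 6L,
                          proline_rule = FALSE, clip_nterm_met = FALSE) {
  stopifnot(max_missed_cleavages >= 0, min_length >= 1)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 proline_rule = isTRUE(proline_rule),
                 clip_nterm_met = isTRUE(clip_nterm_met)),
            class = "digest_params")
}

#' Tryptic digest of a protein sequence
#'
#' Cleaves after K or R (optionally suppressed before proline) and returns
#' all contiguous products with at most `max_missed_cleavages` internal
#' cleavage sites and length >= `min_length`, each with its 1-based start
#' coordinate in the protein.
#'
#' @param protein Amino-acid string over the canonical residues.
#' @param params A [digest_params()].
#' @return `data.frame` with columns `peptide`, `start`, `missed_cleavages`.
#' @examples
#' digest("AKCKR", digest_params(max_missed_cleavages = 0, min_length = 1))
#' @export
digest <- function(protein, params = digest_params()) {
  stopifnot(inherits(params, "digest_params"))
  if (!is.character(protein) || length(protein) != 1L || !nzchar(protein))
    stop("protein must be a non-empty amino-acid string")
  residues <- strsplit(protein, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(residues), names(.RESIDUE_MASS_TABLE))
  if (length(bad))
    stop("non-canonical residue(s) in protein: ", paste(bad, collapse = ", "))

  digest_one <- function(seq_chars, offset) {
    n <- length(seq_chars)
    cut_after <- which(seq_chars %in% c("K", "R"))
    if (params$proline_rule)
      cut_after <- cut_after[!(cut_after < n & seq_chars[cut_after + 1L] == "P")]
    cut_after <- cut_after[cut_after < n]
    bounds <- c(0L, cut_after, n)            # peptide i spans bounds[i]+1..bounds[i+1]
    m <- length(bounds) - 1L
    out <- vector("list", 0L)
    for (a in seq_len(m)) {
      for (b in a:min(m, a + params$max_missed_cleavages)) {
        from <- bounds[a] + 1L
        to <- bounds[b + 1L]
        if (to - from + 1L < params$min_length) next
        out[[length(out) + 1L]] <- data.frame(
          peptide = paste(seq_chars[from:to], collapse = ""),
          start = from + offset,
          missed_cleavages = b - a,
          stringsAsFactors = FALSE)
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(peptide = character(0), start = integer(0),
                 missed_cleavages = integer(0))
  }

  res <- digest_one(residues, 0L)
  if (params$clip_nterm_met && residues[1] == "M" && length(residues) > 1L)
    res <- rbind(res, digest_one(residues[-1], 1L))
  res <- res[!duplicated(res[, c("peptide", "start")]), , drop = FALSE]
  res <- res[order(res$start, nchar(res$peptide)), , drop = FALSE]
  rownames(res) <- NULL
  res
}
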