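# Standard-format I/O: FASTA (via Biostrings), MGF peak lists, and TSV
# tables. All tables are UTF-8, tab-separated, header row, '.' decimal.

#' Read protein sequences from FASTA
#'
#' Sequences are upper-cased; stop characters (`*`) are stripped with a
#' warning. The accession is the first whitespace-delimited token of the
#' header, the rest is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return `data.frame` with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("no FASTA records in ", path)
  headers <- names(set)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(grepl("*", seqs, fixed = TRUE))) {
    warning("stripping '*' stop characters from sequence(s)")
    seqs <- gsub("*", "", seqs, fixed = TRUE)
  }
  data.frame(accession = accession, description = description,
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins `data.frame` with columns `accession`, `sequence` and
#'   optionally `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  names(set) <- trimws(paste(proteins$accession, desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Supports the dialect: `BEGIN IONS`/`END IONS` blocks with `TITLE`,
#' `PEPMASS` (m/z and optional intensity), signed `CHARGE` (e.g. `3+`), an
#' optional `MODE` extension key (HCD/ETD; defaults to HCD), and `mz
#' intensity` peak lines.
#'
#' @param path Path to an MGF file.
#' @return List of [new_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  block_no <- 0L
  while (i <= n) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      block_no <- block_no + 1L
      title <- sprintf("block_%d", block_no)
      pepmass <- NA_real_
      charge <- 1L
      mode <- "HCD"
      mz <- numeric(0); intensity <- numeric(0)
      ended <- FALSE
      i <- i + 1L
      while (i <= n) {
        line <- trimws(lines[i])
        if (line == "END IONS") { ended <- TRUE; break }
        if (grepl("^TITLE=", line)) {
          title <- sub("^TITLE=", "", line)
        } else if (grepl("^PEPMASS=", line)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", line),
                                         "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", line)) {
          cs <- sub("^CHARGE=", "", line)
          sign <- if (grepl("-", cs, fixed = TRUE)) -1L else 1L
          charge <- sign * as.integer(gsub("[^0-9]", "", cs))
        } else if (grepl("^MODE=", line)) {
          mode <- sub("^MODE=", "", line)
        } else if (grepl("^[0-9]", line)) {
          parts <- strsplit(line, "\\s+")[[1]]
          mz <- c(mz, as.numeric(parts[1]))
          intensity <- c(intensity, if (length(parts) > 1)
            as.numeric(parts[2]) else 0)
        }
        i <- i + 1L
      }
      if (!ended)
        stop("MGF block '", title, "' has no END IONS")
      if (is.na(pepmass))
        stop("MGF block '", title, "' is missing PEPMASS")
      spectra[[length(spectra) + 1L]] <-
        new_spectrum(title, pepmass, abs(charge), mode, mz, intensity)
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to MGF
#'
#' Writes precursor m/z to 6 decimals and peak m/z to 4 decimals, so a write
#' followed by a read is the identity within that precision.
#'
#' @param spectra List of [new_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum"))
    writeLines(c(
      "BEGIN IONS",
      paste0("TITLE=", s$title),
      sprintf("PEPMASS=%.6f", s$precursor_mz),
      sprintf("CHARGE=%d+", s$precursor_charge),
      paste0("MODE=", s$mode),
      sprintf("%.4f %.4f", s$peaks$mz, s$peaks$intensity),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Ground-truth sidecar for synthetic spectra
#'
#' @param spectra List of `synthetic_spectrum` objects.
#' @return `data.frame` with columns `title`, `peptide`, `sites`, `mode`.
#' @export
ground_truth_table <- function(spectra) {
  rows <- lapply(spectra, function(s) {
    gt <- s$ground_truth
    data.frame(title = s$title, peptide = gt$peptide$sequence,
               sites = paste(gt$sites, collapse = ","),
               mode = gt$mode, stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(title = character(0), peptide = character(0),
               sites = character(0), mode = character(0))
}
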