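Package: adprms
Title: Mass-Spectrometric Discovery and Localization of Serine ADP-Ribosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and localizing serine ADP-ribosylation
    (S-ADPr) sites from tandem mass spectra. Provides monoisotopic mass
    arithmetic and the ADP-ribose neutral-loss/diagnostic-ion species model,
    in-silico tryptic digestion, a seedable synthetic-spectrum generator for
    ETD/HCD fragmentation and SILAC Lys8 MS1 pairs, peptide-spectrum matching
    in localization-free (labile C-terminal modifier) and variable-modification
    modes, diagnostic-ion-triggered acquisition simulation, site localization
    with serine-specific validation rules, SILAC heavy/light ratio
    quantification with explicit single-channel states, and downstream
    N-terminal residue frequency and basic-residue motif statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'masses.R'
    'species.R'
    'peptide.R'
    'fragments.R'
    'digest.R'
    'spectrum.R'
    'simulate.R'
    'search.R'
    'localize.R'
    'silac.R'
    'enrichment.R'
    'io.R'
    'config.R'
    'pipeline.R'
    'cli.R'
    'adprms-package.R'
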