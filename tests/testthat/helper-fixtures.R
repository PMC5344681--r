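# Fixture builders shared across test files. Everything is generated in code
# under explicit seeds; no binary fixtures.

.species_tab <- adpr_species_table()

# Random protein sequence over the 20 canonical residues.
random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(names(residue_masses()), n, replace = TRUE), collapse = "")
}

# Random tryptic-looking peptide: no internal K/R, C-terminal K or R, at
# least two S/T candidate sites, one serine guaranteed.
random_st_peptide <- function(len, seed) {
  set.seed(seed)
  alphabet <- setdiff(names(residue_masses()), c("K", "R"))
  chars <- sample(alphabet, len - 1L, replace = TRUE)
  pos <- sample(len - 1L, 2L)
  chars[pos[1]] <- "S"
  chars[pos[2]] <- sample(c("S", "T"), 1L)
  paste(c(chars, sample(c("K", "R"), 1L)), collapse = "")
}

# The two synthetic peptides printed for this system: histone H3 residues
# 1-21 and the PARP-1 automodification-region residues 494-524, each with an
# acetylated N terminus, amidated C terminus and a GGA linker.
h3_peptide <- function(adpr_site = 10L) {
  placements <- if (!is.null(adpr_site))
    stats::setNames(list(.species_tab$adpr), adpr_site) else NULL
  modified_peptide("ARTKQTARKSTGGKAPRKQLAGGA", n_term = "acetyl",
                   c_term = "amide", placements = placements)
}

parp1_wt_sequence <- function() "APRGKSGAALSKKSKGQVKEEGINKSEKRMKGGA"
parp1_mut_sequence <- function() "APRGKAGAALSKKAKGQVKEEGINKAEKRMKGGA"

parp1_peptide <- function(adpr_site = 14L) {
  placements <- if (!is.null(adpr_site))
    stats::setNames(list(.species_tab$adpr), adpr_site) else NULL
  modified_peptide(parp1_wt_sequence(), n_term = "acetyl", c_term = "amide",
                   placements = placements)
}

# Small decoy-spiked database around a target protein sequence.
decoy_database <- function(target, n_decoys = 9L, seed = 99L) {
  decoys <- vapply(seq_len(n_decoys), function(i)
    random_protein(40L, seed + i), character(1))
  data.frame(accession = c("TARGET", paste0("DEC", seq_len(n_decoys))),
             sequence = c(target, decoys), stringsAsFactors = FALSE)
}

zero_noise <- function(seed = 1L) noise_model(seed = seed)

# sample() treats a scalar first argument as 1:n; this always samples from
# the given set.
sample1 <- function(x) x[sample(length(x), 1L)]
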