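---
title: "Localizing serine ADP-ribosylation sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing serine ADP-ribosylation sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adprms)
```

## The problem

ADP-ribosylation attaches an ADP-ribose group (+541.06111 Da) to protein
residues; on serine it is written by PARP-1/PARP-2 in complex with HPF1 and
marks histones, PARP-1 itself and many chromatin regulators. Two physical
facts shape any site-mapping pipeline. Under collisional fragmentation
(HCD) the modifier is highly labile: product ions appear with the intact
mass, with a phosphoribose remainder after AMP loss, or with the modifier
gone entirely, and the ejected species show up as low-mass ions — adenine
at m/z 136.0618 being a reliable diagnostic of a modified precursor. Under
electron-transfer dissociation (ETD) the serine–ADP-ribose bond survives,
so c/z ions carry the modification and can pin it to a single residue.
`adprms` models both regimes and the acquisition logic that connects them
(screen by HCD, trigger ETD on the adenine ion for multiply charged
precursors).

## Mass model

All masses derive from one pinned table of monoisotopic atomic masses
(≥ 5 decimals). The ADP-ribose species is built from the composition
C15H21N5O13P2; its five neutral-loss events (adenine, adenosine − H₂O,
AMP, ADP, complete ADP-ribose) reproduce the familiar protonated ion
values 136.0618 / 250.0935 / 348.0704 / 428.0367 / 542.0684 at four
decimals. The printed values are interpreted as [M+H]⁺ of the lost
species — all five match protonated-species masses exactly — so the
neutral loss applied to fragments is the printed value minus a proton.

Two phosphoribose variants are provided and selectable by configuration,
because "phosphoribosylation" can mean either of two masses: the gas-phase
remainder left after AMP loss (+193.99802 Da) or the product of Nudix
hydrolase treatment, which hydrolyzes ADP-ribose/poly-ADP-ribose to a
ribose-phosphate and therefore carries an extra water (+212.00859 Da).
Both are exposed; the default search species is intact ADP-ribose.

Fragment conventions: b/y for HCD, c/z for ETD with c = b + NH₃ and
z• = y − NH₂ (radical z, singly protonated baseline). The SILAC Lys8 delta
is computed as 6 × (¹³C−¹²C) + 2 × (¹⁵N−¹⁴N) = 8.01420 Da, never
hard-coded. Fragments are emitted at 1+, plus 2+ when the precursor is at
least 3+.

## Digestion

Trypsin cleaves after K/R; the proline rule is off by default (matching
the localization-free search engine's convention) and available as a flag.
Two parameterizations are bundled: up to 5 missed cleavages with minimum
length 6 for the variable-modification search — many missed cleavages
because brief "partial FASP" digestion deliberately produces long,
ETD-friendly peptides whose Lys/Arg-rich stretches would otherwise be cut
away — and up to 3 missed cleavages for the localization-free search.
The initiator methionine is not clipped by default (configurable);
I and L are distinct throughout; coordinates are 1-based and closed, so
site labels read S499-style.

## Synthetic data generator

The generator is the package's study-condition definition, not a
convenience: searches and localization are exercised against spectra whose
ground truth is known and never consulted by the analysis code path.

* **ETD**: the complete c/z ladder, modification-spanning fragments in the
  intact state only; charge ≥ 2 required (only multiply charged precursors
  are selected for ETD).
* **HCD**: the b/y ladder with all three modification states for spanning
  fragments, the precursor neutral-loss ladder of the placed species, and
  the adenine diagnostic ion placed in the top decile of peak intensities
  — operationalizing "typically among the strongest fragment ion signals"
  (a boost factor of 1.5 over the base fragment intensity by default).
* **SILAC MS1**: three isotopologue peaks per channel (relative
  1 : 0.6 : 0.3), heavy cluster shifted by (#K × 8.01420)/z; the intensity
  ratio is exact before noise, and ratios of 0/∞ produce single-channel
  clusters to emulate conditions in which one background shows no signal.

The noise model applies fragment dropout (Bernoulli), m/z jitter
(multiplicative Gaussian, ppm), intensity noise (CV), and uniform noise
peaks that are kept ≥ 30 ppm away from surviving true fragments so that a
noise peak never silently stands in for an annotated ion. All draws happen
under the model's seed; identical seed and inputs give identical spectra.

Because the base intensity profile is flat and synthetic, passing tests
demonstrate the correctness of the arithmetic, matching, ranking and
probability logic — not robustness to real chromatographic or instrument
effects (co-isolation, charge-reduced ETD species, isotope envelope fine
structure, intensity-dependent mass error), which the generator does not
emulate.

## Searching

Spectra are first reduced to the top 20 peaks per 100 Da window (FTMS
convention; configurable). PSMs are scored with the Morpheus convention:
matched theoretical-ion count plus the fraction of total spectrum
intensity carried by matched peaks; each theoretical ion matches at most
one peak (nearest within tolerance, greedily by ppm error) and each peak
is used once. Absolute score values are engine-specific; the pipeline
depends only on rankings and on thresholds calibrated against this
package's own synthetic suite.

Two search modes:

* **Variable modification** (default tolerances 4.5 ppm precursor / 20 ppm
  fragment): placements are enumerated on the residue set DEKRSTCYNQHM up
  to one modification per peptide by default, with a combinatorial cap
  (200 hypotheses) above which a peptide is skipped with a warning. ETD
  hypotheses score intact-only fragments; HCD hypotheses include the loss
  states and diagnostic ions.
* **Localization-free** (10/10 ppm, isotope offset up to 3): the modifier
  is an entirely labile C-terminal mass tag. It contributes to the
  precursor mass and to the precursor neutral-loss series, but not to
  backbone fragment masses — the only reading under which each candidate
  peptide generates exactly two hypotheses (with and without the
  modifier), which is what collapses the combinatorial search space. The
  implementation counts generated hypotheses and the two-per-candidate
  contract is asserted in the tests.

Precursor isotope mis-assignment is corrected by trying offsets
0..k × 1.00335 Da and keeping the smallest residual error. Ties between
equal-scoring hypotheses break deterministically: smaller |ppm error|,
then fewer modifications, then lexicographic peptide.

No FDR/decoy machinery is included: confidence here is threshold-based
(score, ppm, localization probability), mirroring the validation-driven
style of analysis this package supports.

## Localization probabilities

Only modification-carrying fragment states — intact or phosphoribose
remainder — count as localization evidence. A fragment that looks
unmodified cannot be distinguished from one that lost the modifier
completely during fragmentation, so such ions are disregarded; a spectrum
containing only full-loss evidence therefore yields exactly uniform
probabilities.

Each candidate placement is scored as

  s_i = (matched evidence ions) − (predicted-but-absent evidence ions)
        + (matched intensity fraction)

and probabilities are the softmax of these scores. Two properties drove
this choice. First, an expected intact-state ion that is *absent* argues
against a placement as strongly as a matched one argues for it; counting
only matches lets a wrong adjacent placement ride on the shared ladder.
Second, linear normalization of count-like scores cannot express high
confidence when candidates share most of their ladder (with four
candidates the correct site tops out near 0.3–0.6 no matter how complete
the evidence), whereas the softmax is the probability family that
PTM-score engines (binomial log-scores) effectively report, and it
reaches the conventional 0.9 reporting threshold exactly when the
discriminating ions are present. For single-placement peptides the number
of predicted evidence ions is the same for every candidate site (n − 1
ions per c/z series pair and charge), so a spectrum with no discriminating
evidence gives all sites equal scores and uniform probabilities — the
desired degenerate behavior. The probability definition is deliberately
not identical to any specific engine's localization score; the 0.9
threshold is applied to it as a convention.

Site-determining ions between two placements are the matched,
modification-carrying ions whose theoretical m/z differs between the
placements. A serine call passes validation only if (a) at least one
intact/phosphoribose ion pinpoints the serine against the best competing
site, (b) at least 2 such ions reach 5% of the base-peak intensity
("multiple high-intensity ions", both knobs configurable), and (c) the
localization probability is at least 0.9. Confident-site filtering further
requires PSM score ≥ 10 and |precursor error| < 3 ppm. The score floor of
10 is calibrated on the synthetic suite such that every zero-noise true
PSM of a minimum-length peptide passes (a length-6 peptide has 10 backbone
ions at 1+, scoring ≥ 11 when complete) while shuffled-sequence matches
score far below it; engine scores are not portable across software, so a
portable replacement threshold has to be calibrated in-repo.

## SILAC quantification

Channel intensities are summed over the simulated isotopologues (robust to
single-peak jitter), and H/L ratios are only computed when both channels
have signal; single-channel pairs are reported with an explicit state
(`heavy_only`, `light_only`, `neither`) rather than a capped ratio,
because a ratio against zero signal is undefined, not large. A
labeled-residue cap (7 lysines by default) mirrors the search-side limit
on labeled amino acids. The ratio-versus-intensity table keeps one row per
pair, never dropping single-channel entries, so downstream scatterplots
can display them distinctly.

## Downstream statistics

The N-terminal frequency table counts the first residue of unique peptides
in a modified and an unmodified set and reports per-residue relative
occurrence as a pseudocounted frequency ratio, (f_mod + 1/20)/(f_unmod +
1/20). Frequencies (not raw counts) are compared so the two sets need not
be the same size, and the 1/20 pseudocount keeps ratios finite when a
residue class is empty — the zero-handling is otherwise unspecified in
this kind of figure. Serine-ADP-ribosylated peptides are expected to show
serine over-represented at position 1: the motif places a basic residue
before the modified serine, and basic residues are tryptic cleavage sites,
so the serine starts the fully cleaved peptide. The motif summary flags,
per validated site, whether the preceding protein residue is K/R.

## Numerical and degenerate-input choices

* Atomic masses pinned in one source file; acceptance-style comparisons at
  4 decimal places; internal consistency checks at 1e-4 Da.
* Peak matching is greedy nearest-first by relative error, deterministic
  under ties by theoretical-ion order.
* Probability ties (e.g. all-uniform) resolve to the lowest candidate
  index; outputs are deterministically ordered everywhere.
* Empty spectra, empty peptide sets, empty databases and zero-intensity
  channels all return well-defined empty/uniform/NA results or precise
  errors (empty protein, non-canonical residue, missing PEPMASS, block
  without END IONS, position out of range), never silent misbehavior.
* Noise peaks are re-drawn (up to a bounded number of rounds) rather than
  clipped, so their distribution stays uniform over the allowed region.

## Problem sizes

The bundled checks run at desk scale, chosen so the full suite completes
in well under a minute of compute on one core: property sweeps over tens
of random peptides (lengths 6–25), best-site recovery over 200 simulated
noisy ETD spectra (20% fragment dropout, 5 ppm jitter, fixed seed grid,
≥ 95% required), SILAC ratio recovery over 100 seeds at 5% intensity CV
(median within 5%), brute-force placement-equivalence on peptides of at
most 12 residues, and a seed-determinism check that runs the demo pipeline
twice and compares outputs byte for byte.

## Limitations

* The generator's intensity model is flat/synthetic; scores and
  probabilities on real spectra will differ in scale, and the calibrated
  score floor (10) is meaningful only relative to this package's scoring.
* Dataset-scale results from the original biological studies (hundreds of
  sites from public raw data, fold-changes of specific histone marks)
  require external raw files and are out of scope here; the package
  reproduces the *method* at synthetic scale.
* No FDR estimation, no retention-time or XIC-level quantification, no
  a/x internal fragments, no poly-ADP-ribose chain modeling, no vendor
  raw-file reading (MGF is the sole spectrum format).
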