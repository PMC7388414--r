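---
title: "Reconstructing and validating mature venom toxins: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and validating mature venom toxins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomtox)
```

## The problem

Spider venoms are dominated by cysteine-rich peptides (CRPs), disulfide-
stabilised toxins of typically 3–9 kDa, alongside short linear peptides
below 1.5 kDa. Toxins are translated as precursors (signal peptide +
propeptide + mature peptide) and secreted in the mature, disulfide-bonded
form, so neither the transcript nor a database entry tells you what
molecule is actually in the venom. The experimental strategy this package
supports is: digest venom aliquots with five different proteases, identify
the cleaved peptides by LC-MS/MS, reconstruct each mature toxin from
overlapping fragments, and then confirm that the *intact* mature molecule
— at its disulfide-corrected monoisotopic mass — is present in the native
(undigested) precursor-ion map. Validated toxins are then quantified
(Hi3), profiled physicochemically, and screened for candidate
antimicrobial/anticancer activity using external predictor scores.

`venomtox` implements everything downstream of the vendor software: it
consumes sequences (FASTA), peptide-identification tables and precursor-ion
lists (TSV), and external predictor scores (TSV). Raw spectra, peak
picking, PSM scoring, FDR control and the predictors themselves are out of
scope and treated as inputs.

## Mass model

The neutral monoisotopic mass of a peptide is

$$ M = \sum_i m(\mathrm{res}_i) + m_{\mathrm{H_2O}}
       - 2\,n_{SS}\, m_{\mathrm{H}} + \sum_j \Delta_j $$

with residue masses from the standard IUPAC elemental masses, water
18.010565 Da, hydrogen 1.0078250319 Da, and one −2H correction per
disulfide bond ($n_{SS}$ bonds, each oxidising two Cys thiols). The
modification catalog is fixed: carbamidomethyl (+57.021464, Cys, fixed in
digest context only — native aliquots are never alkylated, so native
mature masses take no carbamidomethyl), Met oxidation (+15.994915),
Asn/Gln deamidation (+0.984016), N-terminal acetylation (+42.010565), and
C-terminal amidation (−0.984016), which is applied only when annotated on
a toxin record, never inferred. Ions are decharged as
$M = z\,(m/z - m_{\mathrm{proton}})$ with $m_{\mathrm{proton}} =
1.00727646$ Da.

Two entries of the packaged reference table deserve comment. The reported
mass of U2-TRTX-Ar1a (4876.02 Da) corresponds to the des-Gly, C-terminally
amidated form of the printed sequence: the C-terminal Gly of the precursor
is the amide donor of a peptidylglycine α-amidating conversion, an enzyme
of which was detected in the same venom. The reported mass of U1-TRTX-Ar1b
(3920.58 Da) corresponds to the N-terminally acetylated form. The table
therefore carries a `mass_sequence` and `modifications` pair describing
the molecular form behind each reported mass. One short peptide, VLPPLKF,
is reported at 812.40 Da while every standard mass basis gives 812.52 Da
(≈140 ppm); this is recorded as a flagged discrepancy (`mass_discrepant`)
and deliberately not forced to agree.

## Digestion

Five enzymes, each a data-driven rule (side, targets, blockers):

| enzyme | cleaves | blocked by |
|---|---|---|
| trypsin | after K, R | next residue P |
| chymotrypsin | after F, W, Y, L | next residue P |
| Glu-C | after E and D | — |
| Asp-N | before D | — |
| thermolysin | before I, L, V, A, M, F | — |

Where the underlying study reports only enzyme names, conventional
specificities are assumed and documented as assumptions: proline blocking
is applied to trypsin and chymotrypsin only; chymotrypsin is used without
the low-efficiency M/H targets; thermolysin is not proline-blocked. Glu-C
cleaves after both E and D because the Glu-C aliquot was digested in
phosphate buffer, which broadens the specificity; `enzyme_catalog(glu_c =
"E")` restores the E-only rule.

`digest()` enumerates fully specific peptides spanning at most
`max_missed` internal cleavage sites (default 2) and, with
`max_nonspecific = 1` (default), adds semi-specific peptides in which
exactly one terminus is truncated to a non-boundary position — matching
the identification settings "maximum of one nonspecific cleavage, maximum
of two missed cleavages". The implementation is constructive (built from
the cleavage-site vector); the test suite checks it against an independent
brute-force oracle that filters all substrings by the specificity
predicate.

## Assembly: coverage and the consensus N-terminus

`build_coverage()` tallies per-residue depth and, per start position, the
set of distinct enzymes with a peptide starting there. The mature
N-terminus is called by `consensus_n_terminus()` at the smallest start
supported by at least two distinct enzymes (configurable); the native,
undigested channel counts as its own enzyme because it is an independent
observation. A mature span counts as *fully sequenced*
(`is_fully_sequenced()`) only when consecutive fragments overlap by at
least one residue: merely abutting peptides cannot exclude an insertion at
the junction, so overlap — not just coverage — is required. The minimum
overlap of one residue is itself an assumption (no value is established in
the field); it is the weakest requirement that still chains fragments.
`compare_maturation()` reports the signed offset between a predicted
maturation start (from an external signal/propeptide predictor) and the
observed consensus start, with the N-terminal extension sequence when the
observed form is longer, e.g. the two-residue `NR` extension seen for one
of the reference toxins.

## Native-ion validation

The native precursor-ion map is filtered at 5.0e5 intensity — *strictly
below* is excluded, so an ion at exactly the threshold is kept, following
the wording of the filtering rule. Redundant observations of one species
(across runs and charge states) are then merged by single-linkage
clustering of decharged neutral masses at 10 ppm; single linkage is chosen
precisely because it transitively merges the charge-state series of one
molecule. Merging (intensity-summed) is the default rather than the
discard convention so no signal is lost; `mode = "exclude"` reproduces the
keep-most-intense behaviour. Ions with unknown charge cannot be decharged
and pass through as flagged singletons that can never carry a validation.

A candidate toxin is validated when (i) some cluster's neutral mass lies
within 10 ppm of the toxin's theoretical mass — ppm is computed against
the theoretical mass; flipping the reference changes results by
≪ 0.01 ppm at this scale —, (ii) the matching cluster contains at least
one ion with charge in the +2..+9 ladder (unassigned and +1 ions were
never fragmented upstream, so they cannot carry a validation on their
own), and (iii) the consensus sequence is MS/MS-supported
(`require_msms = TRUE`). The worked example in the README rebuilds the
18-toxin reference set through `run_pipeline()` from a native map built at
their theoretical ladders.

## Physicochemical profiling

Net charge is the Henderson–Hasselbalch sum
$\sum_{\mathrm{basic}} (1+10^{pH-pK_a})^{-1} -
 \sum_{\mathrm{acidic}} (1+10^{pK_a-pH})^{-1}$
over N-terminus, C-terminus and the K/R/H/D/E/C/Y side chains. For
disulfide-bonded CRPs, Cys is excluded from both charge and composition —
engaged thiols cannot titrate, and the reference composition percentages
are only consistent with Cys-free denominators. The default pKa set
(N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5,
Y 10.1) was chosen because it reproduces all four reference net charges at
pH 7.4 (+5.94, +6.0, −0.96, −0.95) within rounding *and* the two reported
isoelectric points (10.60, 10.52); a Lehninger-style alternative is
selectable by name. The charge curve uses the 0–14 pH grid in 0.5 steps
(29 points) and is monotonically decreasing by construction, which makes
the pI the unique root; it is found by bisection to |charge| < 1e-4 and
reported to 2 decimals.

Composition classes are fixed alphabets — tiny {A,C,G,S,T}, small
{A,C,D,G,N,P,S,T,V}, aliphatic {A,I,L,V}, aromatic {F,H,W,Y}, hydrophobic
{A,C,F,G,I,L,M,P,V,W,Y}, hydrophilic {D,E,H,K,N,Q,R,S,T}, charged
{D,E,H,K,R}, cationic {H,K,R}, anionic {D,E} — that reproduce every cell
of the reference composition table. Hydrophobic/hydrophilic partition the
alphabet, so their counts always sum to the considered length, and
charged = cationic + anionic (His belongs to both charged and cationic).
Percentages are half-up rounded to one decimal, matching the reference
presentation (base R's `round()` is banker's rounding and would differ on
exact halves).

## Hi3 quantification

A protein's abundance in a run is the mean intensity of its three most
intense peptides (all of them when fewer than three). Proteins are
retained when identified with ≥ 3 distinct peptides in ≥ 2 replicates;
the mean Hi3 is taken over the replicates where the protein was detected,
because a missing protein under data-independent acquisition is not a
zero. Relative abundances are percentages over the retained proteins only;
filtered-out proteins stay in the report flagged rather than silently
dropped. Whether the reference NI column is a replicate mean or a
reference-run value is not established; the mean is used and documented.

## Screening rules

Both rules are strict threshold rules on external predictor scores:
an antimicrobial activity is significant when its score is > 0.8, and a
peptide is labelled ACP only when the random-forest *and* SVM anticancer
scores are both > 0.5 (consensus). Missing scores yield `not-evaluated`.
The rules are monotone: raising a score can never turn a positive verdict
negative.

## Synthetic data: what it emulates and what it does not

`synthetic_config()` defaults describe the study-like conditions used in
all recovery tests: 7 CRPs (30–62 residues, 6–10 Cys, masses constrained
to 3–9 kDa) and 7 short hydrophobic peptides (< 1.5 kDa); precursors with
signal peptide and an Arg-terminated propeptide so the mature start is
well defined; five-enzyme digests at ≤ 2 missed cleavages and ≤ 1
nonspecific terminus with 15% per-peptide dropout; per-toxin native ions
at 2–9 charge states with ≤ 5 ppm m/z jitter (half the matching
tolerance) and log-normal intensities (meanlog 15, sdlog 1.5, so roughly
a tenth of ions fall below the 5.0e5 filter and exercise it); and 50 decoy
ions kept ≥ 50 ppm (5× tolerance) from every true mass so decoys are
unambiguous negatives. CRP residue usage is sampled with elevated K/R —
a qualitative, not fitted, imitation of cationic venom CRPs.

The generator does **not** simulate MS/MS fragment spectra, chromatography,
isotope envelopes, charge-state misassignment, or homologous proteoform
families; passing recovery tests therefore demonstrates the correctness of
the downstream logic under the stated noise model, not identification
performance on real spectra. Determinism is by integer-seeded generation:
the same config always yields the same truth, evidence and ion map; the
three stages draw from seed, seed+1, seed+2 so they are individually
reproducible regardless of call order.

The recovery acceptance check runs 20 replicates (seeds 1–20, 14 toxins
each, the default conditions above) and requires validation sensitivity
≥ 0.95 with zero validations from decoy-only maps; these problem sizes
keep the whole suite fast while giving ~280 toxin-level trials.

## Numerical choices and degenerate inputs

* Intensity threshold boundary: kept at exactly 5.0e5 (strict-less
  exclusion).
* Clustering: 1-D single linkage implemented as a sorted-gap scan;
  the cluster mass is the unweighted mean of member masses.
* Hi3 ties: peptides sorted by (intensity desc, sequence asc); ties do not
  change the mean but make the selected set deterministic.
* Bisection: interval [0, 14], stop at |charge| < 1e-4 or width < 1e-8;
  undefined pI (no basic or no acidic group after exclusions) returns `NA`
  rather than a number.
* Empty inputs: empty ion tables produce empty cluster sets and zero
  validations with a warning; empty sequences, out-of-bounds evidence and
  non-physical m/z are rejected with informative errors.
* Coordinates: residue positions are 1-based inclusive everywhere in
  reports; cleavage positions are inter-residue 0..L internally, with 0
  and L implicit.

## Known limitations

* Disulfide connectivity is a count-based mass correction; pairing
  topology is not modelled.
* Shared-peptide (proteoform) quantification is out of scope; peptides are
  assumed pre-assigned to proteins upstream.
* The reported masses in the reference table are observed values for some
  entries; theory is matched to 60 ppm rather than forced, and one entry
  (VLPPLKF) remains genuinely discrepant.
* The pKa set is a calibration choice; absolute charges shift between
  published scales even though curves remain monotone.
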