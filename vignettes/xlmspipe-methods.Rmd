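---
title: "Methods: identifying isotope-coded, cleavable crosslinks with xlmspipe"
author: "xlmspipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying isotope-coded, cleavable crosslinks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlmspipe)
```

# The problem

Chemical crosslinking mass spectrometry (XL-MS) captures residue-residue
proximities by covalently bridging lysines that sit within the reagent's
reach, digesting the proteins, and identifying the bridged peptide pairs
from MS2 spectra. On a proteome-wide scale this is hard for two reasons:
crosslinked peptides are rare relative to linear peptides, and the
candidate space of peptide *pairs* grows quadratically with the database.
`xlmspipe` implements the computational side of a workflow built around a
crosslinker with three exploitable properties:

* **isotopic coding** — the reagent is applied as a 1:1 mixture of a light
  and a heavy (8-deuterium) form, so every crosslinked species appears in
  MS1 as a co-eluting doublet spaced by a fixed mass delta;
* **gas-phase cleavability** — CID breaks the crosslinker at defined
  bonds, leaving a *short-arm* or *long-arm* remnant on each peptide and
  producing up to four diagnostic product ions per inter-peptide link;
* **affinity enrichability** — a biotin tag permits enrichment upstream
  (wet-lab; outside this package's scope).

The pipeline detects the MS1 doublets, converts them into targeted
acquisition lists, generates or imports crosslink peptide-spectrum matches
(PSMs), annotates every PSM with the crosslinker-specific evidence, and
feeds the result to a semi-supervised target-decoy rescorer that estimates
q-values and filters at 2% FDR. Accepted PSMs are aggregated to unique
residue-pair links and protein-protein interactions (PPIs), and validated
against C-alpha distances in structural models.

# The label mass delta

The light/heavy mass difference is derived, not configured:

```{r}
isotopicMassDelta(8)
```

Eight deuterium positions times the 2H-1H monoisotopic mass difference
give 8.0502 Da. Everything that keys on the delta — doublet detection,
heavy/light candidate enumeration, partner corroboration — uses this
derived value.

# Crosslinker model and its placeholder masses

A `CrosslinkerSpec` records spacer mass, short/long arm remnant masses, a
cleavage mass-balance constant, dead-end quench adducts, the label-site
split across arms, and the maximum C-alpha span (38 Angstrom). The
validity method enforces two conservation laws: `short + long == spacer +
adjustment` and `labelDelta == nSites * (m(2H) - m(1H))` within 0.5 mDa.

The exact spacer and arm masses of the commercial reagent are not public,
so the default object carries *placeholder* values (spacer 500, arms
200/300, adjustment 0) that satisfy the conservation laws; they are
adequate for simulation and for testing every algorithm, and real analyses
supply the true masses through `crosslinkerSpec()` or a YAML config
(`readCrosslinkerConfig()`). The arm label split defaults to 4/4, so a
complementary cleavage-product pair of a heavy species is shifted by the
full label delta — a property the tests verify exactly.

Dead-end (quenched) species use adduct masses for hydrolysis (+18.0106)
and ammonium quenching (+17.0265). CID of a dead-end can break either
cleavable bond, so its signature is the ion pair {peptide+short arm,
peptide+long arm}. A loop-link's cleavage merely opens the ring without a
mass change, so no mass-shifted diagnostic ion exists and the package
defines its signature as empty.

# MS1 doublet detection

Deconvoluted persistent features (neutral monoisotopic mass, charge, RT
extent, intensities — the output of standard deconvolution tools, read by
`readKronik()`) are paired by `findDoubletPairs()` under four criteria,
all boundaries inclusive:

| criterion | default | unit |
|---|---|---|
| mass delta | 8.0502 +/- 0.01 | Da |
| heavy - light apex RT | [-0.4, +0.05] | min |
| abs log2(H/L summed intensity) | <= 2 | — |
| per-feature maximum intensity | >= 25000 | counts |

The asymmetric RT window reflects deuterated species eluting slightly
earlier than their hydrogen counterparts on reversed phase. A second
preset ("pipeline") replaces the last two criteria with a relative
summed-intensity difference bound of 20%, defined as |H - L| / mean(H, L);
the definition of "relative difference" was an open choice and the
symmetric mean-normalized form was chosen so the criterion is invariant to
swapping the partners. The acquisition-evaluation preset is the default.

`pairMultiplets()` resolves the accepted-pair relation into disjoint
chains of up to four members (doublet/triplet/quadruplet: species carrying
more than one crosslinker). Where a feature pairs with several candidates,
the conflict is settled greedily by smallest absolute mass error, then
smallest absolute RT delta, with mass-based tie-breaks so the outcome is
deterministic and invariant to input order; chains longer than four split
greedily from the light end. An exhaustive O(n^2) oracle reproduces the
accepted-pair set exactly in the test suite.

Inclusion lists (`buildInclusionList()`) emit one entry per member — both
light and heavy partners — of every multiplet of charge 3 or greater
(charge-2 precursors are excluded because crosslinked peptides at +2
fragment poorly and linear peptides dominate there), with m/z computed at
proton mass 1.007276 and RT windows padded by 0.5 min by default (a value
chosen to cover apex drift between runs; configurable).

# The toy crosslink matcher

The package is designed to *ingest* results of a dedicated crosslink
search engine (`readKojak()` maps a Kojak-style table onto the PSM
schema). For self-contained operation on synthetic or small data it also
ships a deliberately simple matcher:

* candidate species (inter/intra pairs, loops, dead-ends; light and heavy;
  all reactive-site placements) are enumerated from a peptide index within
  10 ppm of the precursor, using a sorted-mass two-pointer scan;
* theoretical singly charged b/y ions are generated with the partner
  peptide plus spacer treated as a fixed modification on the linked
  residue; loop-links omit ions that would cleave inside the bridged
  region;
* the match count over theoretical ions is scored as -log10 of a binomial
  tail with per-ion null probability p = n_peaks * 2 * tol / span,
  fragment tolerance 0.02 Da;
* the best candidate is kept with the score gap to the runner-up; ties
  break by matched fraction, then lexicographic species key, so results
  are deterministic.

Only precursor charges +3 to +7 are searched. Reactive sites are lysines
plus protein N-termini; a C-terminal lysine remains linkable. The matcher
makes no claim of sensitivity on real data — it exists so that every
downstream stage is testable end to end without external software.

# Feature annotation and the PIN schema

Each PSM is annotated with:

* **MS2 cleavage evidence** (`annotateCleavage()`): presence and intensity
  of the 4 predicted cleavage products (2 for dead-ends) over charges 1 to
  precursor charge - 1, inclusive tolerance;
* **MS1 multiplet evidence** (`attachMs1Evidence()`): the PSM is linked to
  a multiplet member by mass (10 ppm) and RT containment, nearest mass
  winning; the heavy/light intensity ratio, partner RT delta, an
  isotope-pattern-match flag (cosine >= 0.95 between the observed envelope,
  when the feature table carries one, and a Poisson-averagine prediction
  with lambda = 4.7e-4 per Da), and an MS1/MS2 label-agreement flag (PSM
  label vs the member's position in the multiplet);
* **meta-features** (`computeMetaFeatures()`): partner corroboration — a
  second PSM with the identical peptide pair and sites, opposite label,
  and a precursor gap of one label delta.

`buildPinTable()` lays these out as a fixed 41-dimension feature block
between the identification columns (SpecId, Label, ScanNr ... Peptide,
Proteins). Missing evidence is always encoded as 0 with a paired
missing-evidence indicator set to 1, so the schema is identical whatever
evidence exists; any NaN is a hard error. The 41-name list
(`pinFeatureNames()`) is this package's documented reconstruction of the
feature families named above — search scores and ranks, precursor
diagnostics, spectrum summaries, peptide properties, link-type indicators,
MS1/MS2/meta evidence, and indicators.

# Semi-supervised rescoring and FDR

`tdcQvalues()` implements the conservative (d+1)/t target-decoy estimator:
sort by score, estimate FDR at each target threshold, monotonize from the
bottom; decoys inherit the q-value of the next better target.

`semiSupervisedRescore()` is a cross-validated iterative linear rescorer:
standardize features (constant columns dropped), pick the single feature
and sign that maximizes targets at q <= 0.01 as the initial direction,
then per fold (3 by default) iterate (10 rounds): label targets at
q <= 0.01 under the current score as positives and all decoys as
negatives, refit a ridge-regularized least-squares discriminant
(lambda = 1), and finally score the held-out fold with the trained
direction. Held-out scores are normalized per fold (decoy median zero,
unit standard deviation) before merging; q-values come from the merged
scores. The ridge direction was chosen over a hinge-loss SVM for
closed-form stability at small n; at the separations typical of this
problem the two give nearly identical rankings. Cross-validation keeps
held-out decoys and held-out false targets exchangeable — the property
the FDR estimate rests on. With fewer than 20 targets or decoys the
rescorer falls back to the initial single-feature ranking.

Filtering (`filterAtFdr()`) accepts q <= threshold inclusively and by
default re-estimates q within each link-type stratum (inter, intra, loop,
single as separate tables), because score distributions differ
systematically between link types; a pooled mode exists. The working
threshold is 2%.

`aggregateLinks()` collapses accepted PSMs to unique residue pairs in
canonical order (protein group ambiguity flagged, never double counted),
and `aggregatePpis()` rolls links up to protein pairs with per-fraction
PSM tallies.

# Structure validation

`mapLinksToStructure()` computes Euclidean C-alpha distances using author
chain ids and residue numbering (PDB and mmCIF via bio3d; no sequence
realignment — links are expected to be in the model's numbering). When an
accession maps to several equivalent chains, all chain-pair combinations
are evaluated and the *minimum* distance is reported, generalizing the
homodimer convention of drawing only the shortest copy of a constraint.
Residues without a C-alpha are reported separately with a reason.
`randomPairDistanceBaseline()` draws uniform random residue pairs
(optionally restricted to lysines and chain N-termini) as the null
distribution, with 2-Angstrom histogram bins. A link is `withinSpan` when
its distance is at most the crosslinker's 38 Angstrom maximum.

# The synthetic-data generator

`simulateGroundTruth()` draws random proteins (uniform residue
frequencies with lysine boosted to 8% and arginine 5%, guaranteeing
linkable sites and tryptic behaviour) and plants requested numbers of
inter/intra/loop/dead-end species on *internal* lysines of tryptic
peptides with up to 2 missed cleavages — mirroring the chemistry, where a
crosslinked lysine blocks trypsin. `emitMs1FeatureTable()` produces
light/heavy feature pairs satisfying every pairing criterion (RT offset
uniform in [-0.35, 0.02] min, log2 ratio normal(0, 0.5) truncated at 1.8,
log-normal intensities above the floor, heavy-mass jitter within +/- 4
mDa), optionally breaking exactly one named criterion per violating pair,
plus unpaired noise features whose masses are kept out of the pairing
window of any other feature. `emitMs2Spectra()` writes one spectrum per
species and label with b/y ions subsampled at a chosen coverage, cleavage
products at a chosen probability, optional noise peaks, and decoy-like
false spectra whose precursors sit near, but not on, true species masses.
Outputs serialize as FASTA, feature TSV, mzML (minimal but valid;
uncompressed arrays) or a binary-free JSON spectra format, and a
ground-truth JSON.

`simulatePsmFeatures()` skips the spectrum level and draws an annotated
PIN table directly: true targets carry signal in the search score
(normal(2.2, 1) vs normal(0, 1)) and in the crosslinker-specific evidence
(cleavage products Binomial(4, 0.75) vs (4, 0.08); corroboration 0.7 vs
0.03; MS1 evidence present 90% vs 20%), while false targets and decoys
are drawn from one common null — exchangeable by construction. This is
the instrument for calibration studies: accepting at q <= 0.02 and
comparing against the known labels measures the empirical false-discovery
proportion, and comparing accepted counts against a score-only baseline
measures the value of the crosslinker-specific evidence.

What the generator does *not* emulate: chromatographic peak shape and RT
prediction, isotope envelopes beyond the pattern flag's needs, chimeric
spectra, fraction chemistry (fraction labels are tags), and realistic
score correlation structure between features. Passing tests on synthetic
data therefore demonstrate the correctness and calibration of the
algorithms under their stated assumptions, not sensitivity on real
instrument data.

# Numerical choices and problem sizes

* All criterion boundaries are inclusive, with a 1e-9 epsilon so floating
  arithmetic cannot flip a boundary case.
* Monoisotopic residue masses at 8 decimals; cysteine carries fixed
  carbamidomethylation; proton 1.007276; water 18.0105647.
* Tryptic digestion applies the proline rule by default. Decoy shuffling
  deliberately uses strict K/R boundaries (no proline exception): every
  internal residue of a fully cleaved peptide is then non-K/R, so
  permuting them provably preserves all cleavage positions, peptide
  lengths, compositions and C-termini. Missed-cleavage peptides in the
  search inherit the shuffled composition.
* Shuffles retry up to 10 times to avoid decoy == target where at least
  two distinct shuffleable residues exist (homopolymeric segments pass
  through).
* The test suite and acceptance script run at desk scale: closed-loop
  datasets of ~56 planted species across 6 proteins (~120 spectra),
  calibration sets of 500 true / 5000 false / 5000 decoy PSMs over 20
  seeds, and oracle sweeps over 100 random feature sets of up to 500
  features. These sizes were chosen so each property is measured with
  useful Monte-Carlo precision while the whole suite stays interactive.

# Known limitations

* The internal matcher scores singly charged b/y ions only (no higher
  fragment charges, no ETD/EThcD ion types, no chimeric handling).
* The mzML reader supports the uncompressed encodings the writer emits.
* Structure mapping requires author-numbering agreement; no
  Needleman-Wunsch remapping is attempted.
* Protein-level FDR is out of scope; q-values are at the PSM level,
  filtered per link type.
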