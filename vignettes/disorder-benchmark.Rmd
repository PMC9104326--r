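---
title: "Benchmarking structure-derived disorder predictors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking structure-derived disorder predictors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disbench)
```

## The problem

Predicted protein structures carry a per-residue confidence score — the
pLDDT, on a 0–100 scale, stored in the B-factor field of the deposited
model. Intrinsically disordered regions (IDRs) have no fixed native
structure, and structure predictors behave characteristically on them:
confidence collapses, while the modelled geometry may still show
(spurious or transient) secondary structure. This package implements and
benchmarks the two natural ways of reading disorder out of a predicted
structure:

* **tpLD** — the continuous disorder score $s_i = 1 - \mathrm{pLDDT}_i/100$,
  so $s_i \in [0,1]$ with 1 fully disordered;
* **pLDn** — the binary predictor calling residue $i$ ordered iff
  $\mathrm{pLDDT}_i \ge n$, with $n$ chosen to maximise the Matthews
  correlation coefficient (MCC) against a reference set;
* **DSSPp** — the naive structure rule: residues assigned by the
  Kabsch–Sander algorithm to helices (H/G/I), strands/bridges (E/B) or
  hydrogen-bonded turns (T) are ordered; bends (S) and coil (−) are
  disordered.

The benchmark asks which rule better recovers reference disorder
annotations, residue by residue.

## Reference sets

Two reference variants are built from interval annotations:

* **DisProt-style**: residues inside any disorder interval are labelled 1;
  *every other residue is labelled 0*, including residues about which
  nothing is known. This inflates the apparent error of any predictor on
  genuinely uncertain residues.
* **DisProt-PDB-style**: only residues with either a disorder annotation
  or structural (PDB) coverage are evaluated. A residue that is both
  annotated disordered and covered by a structure is labelled
  **disordered** (annotation wins); covered-but-unannotated residues are
  ordered; everything else is masked and excluded from every metric.

Masking, conflict resolution and the "unannotated = ordered" rule are the
exact construction rules of the two sets; the package applies them
per-residue and records provenance (`disprot` / `pdb` / `none`) so the
masking logic is auditable. When a structure's length disagrees with its
annotation the protein is truncated to the shorter length with a warning
(the conservative choice; mismatches are logged, never silently
reconciled). Proteins with zero evaluated residues are dropped from
pooled metrics, again with a warning.

## Metrics

The positive class is *disordered* throughout, and all threshold-free
metrics are pooled over evaluated residues (the CAID convention), while
RMSD is computed per protein:

* **ROC/AUC** — the ROC polygon over all distinct score thresholds;
  AUC by trapezoidal integration, which equals pairwise concordance with
  ties counted one half. The test suite asserts this equivalence against
  a brute-force pairwise oracle on random instances.
* **Precision–recall / Fmax** — the maximum F1 over thresholds. The
  call-everything bound $2p/(1+p)$ at prevalence $p$ is a floor.
* **MCC** — with the conventional value 0 when a denominator factor
  vanishes while both classes are present, and *undefined* (`NA`) for a
  single-class reference: the two degenerate cases mean different things
  and are kept distinct.
* **Per-protein RMSD** — $\sqrt{\tfrac1m \sum_i (v_i - w_i)^2}$ over the
  $m$ evaluated residues of one protein. For binary vectors this is the
  root of the normalised Hamming distance; two independent fair coins give
  $\sqrt{1/2} \approx 0.707$, the "random predictor" level.
* **Bootstrap summaries** — means and standard errors from resampling
  with replacement: 10,000 resamples of size 60 at the protein level and
  10,000 of size 500 at the residue level. All draws derive from one
  run-level seed and restore the caller's RNG state.

Threshold selection sweeps integer $n \in \{0,\dots,100\}$ (confidence
scores are reported to two decimals, but named thresholds are integers)
and breaks ties toward the smallest $n$, i.e. toward calling fewer
residues disordered at the margin; users preferring the opposite
convention can read the full `mcc_by_n` table from the search result.
Combining dataset-specific thresholds uses the arithmetic mean with
half-up rounding — exact for an even pair like (76, 68) → 72, and only
the rounding rule for user-supplied odd sums.

## The Kabsch–Sander module

The secondary-structure dependency is implemented from scratch. Amide
hydrogens are rebuilt at $N_i + \widehat{(C_{i-1} - O_{i-1})}$ (1 Å from
N along the preceding carbonyl direction); prolines and segment-start
residues are donor-incapable. The hydrogen-bond energy is the
electrostatic model

$$E = 27.888\left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}} -
\frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

with a bond recorded when $E < -0.5$. Distances are clamped below at
0.5 Å so malformed input cannot produce singularities (real geometry never
approaches the clamp). Chain breaks are declared when the peptide C–N
distance exceeds 2.5 Å. n-turns ($n = 3,4,5$) are CO($i$)→NH($i{+}n$)
bonds; two consecutive n-turns start a minimal helix covering residues
$i..i{+}n{-}1$; parallel/antiparallel bridge patterns yield B, bridges
linked into ladders yield E; residues inside an n-turn get T; a CA
pseudo-angle above 70° gives the bend S; classes resolve with priority
H > E/B > G > I > T > S. Chains shorter than 5 residues are returned as
all-coil with a warning.

Two deliberate simplifications: the classic 8-class alphabet is used (no
polyproline-II class — the analyses here only consume the 4-class
reduction, whose categories predate it), and β-bulge linking of ladders
is omitted (it affects edge residues of imperfect sheets; the test suite
requires ≥95% residue-level agreement with an independent reference DSSP
implementation over a generated 50-chain suite, and the ideal-geometry
chains used here agree exactly). Bends and coil both reduce to C and are
the two classes DSSPp calls disordered — they are exactly the classes
that are *not* hydrogen-bond stabilised.

## The synthetic cohort generator

The generator defines the study conditions; every test and the
acceptance script run against it, and its defaults were fixed once:

* 200 proteins of 80–300 residues; disordered fraction 0.35 (disorder
  benchmark cohorts are strongly disorder-enriched relative to the
  proteome);
* two-state Markov segment process with mean disordered-segment length 30
  residues (ordered segments get the complementary mean so the stationary
  fraction is exact) — disorder occurs in runs, as in real IDRs, rather
  than i.i.d.;
* confidence: ordered residues $\sim N(85, 8)$, disordered
  $\sim N(45, 12)$, clamped to $[0,100]$ and smoothed with a 5-residue
  moving average to emulate the spatial correlation of real confidence
  profiles. For the unsmoothed equal-sd process the tpLD score is
  binormal with theoretical AUC $\Phi(d'/\sqrt2)$,
  $d' = (\mu_o - \mu_d)/\sigma$ — the calibration the acceptance tests
  check at $d' \in \{0.5, 1, 2, 4\}$;
* coverage: per-residue Bernoulli, 0.9 for ordered and 0.2 for disordered
  residues, runs merged into intervals — structural coverage is biased
  toward ordered regions, which is what makes the DisProt-PDB masking
  non-trivial;
* discordance knobs: `transient_helix_rate = 0.2` turns a contiguous
  fifth of each disordered segment into (low-confidence) helix, and
  `confident_coil_rate = 0.1` turns ordered residues into coil. These
  operationalise the observation that confidence and geometry disagree —
  a helix can be transient and a coil can be confidently placed — and
  they are the mechanism that separates DSSPp from pLDn in the benchmark.
  With both at zero, DSSPp reproduces the labels exactly by construction.
* emulated external predictors: binormal score models with configurable
  theoretical AUC, squashed into $[0,1]$ by a logistic map
  (rank-preserving, hence AUC-preserving), with binary calls at the
  equal-error threshold.

Backbone geometry is built from ideal internal coordinates (N–CA 1.458 Å,
CA–C 1.525 Å, C–N 1.329 Å, standard angles) by sequential torsion
placement: helices at (−57°, −47°), strands at (−139°, 135°), coil
torsions drawn uniformly from three allowed Ramachandran basins with a
steric guard (non-adjacent CA–CA < 2 Å triggers regeneration, at most 100
times). Antiparallel strand pairs are built as two chains with the second
rigid-fitted to hydrogen-bond register by least squares on the ideal
O···N distances.

What the generator does **not** emulate: real amino-acid sequences (chains
are polyalanine), side chains, the error modes of any particular structure
predictor beyond the two knobs, or inter-protein correlation in
annotation quality. Passing tests therefore demonstrate the correctness
and calibration of the pipeline's machinery, not the field performance of
any predictor on real proteins; the package accepts real structure files,
interval tables and CAID prediction files through the same interfaces
when such data are available.

## Secondary-structure codons

The codon at residue $i$ is the triplet of reduced classes at
$(i{-}1, i, i{+}1)$; termini carry no codon (no padding symbol is
invented), codons never span proteins, and a chain of length $L$ yields
exactly $\max(L-2, 0)$ codons. Per-class and per-codon confidence
distributions report the mean (with the residue-level bootstrap),
skewness, a histogram (default bin width 0.5 pLDDT units), the fraction
of values below pLDDT 50, and a Gaussian KDE with Scott's-rule bandwidth
($\sigma n^{-1/5}$) on a 512-point grid without boundary reflection.
Bimodality is declared when the KDE has two local maxima of comparable
mass separated by at least 10 pLDDT units — this turns the qualitative
"coil confidence is bimodal" observation into an assertable property.
Codons observed fewer than 25 times are flagged low-support rather than
suppressed. `pldnorm` min–max-normalises confidence per contiguous
segment (a cohort-wide normalisation would wash out local structure);
propensity relationships are fitted as a line or as a power law
$y = ax^b$ by least squares in log–log space, dropping non-positive
points with a warning.

## Numerical and design choices

* Interval tables are 1-based inclusive (the annotation convention);
  internal arrays are plain R vectors; conversion happens only at I/O
  boundaries.
* Structure files are read through `bio3d` (PDB and mmCIF through one
  code path; confidence always from the B-factor field, CA atom first,
  mean over backbone atoms as fallback); writing uses fixed-column PDB
  records with two-decimal B-factors, and a round-trip preserves
  coordinates to 3 decimals and confidence to 2.
* Protein-class cutoffs default to >0.90 (highly disordered) and <0.10
  (highly ordered) with strict inequalities; both are arguments, since
  published figure captions and text disagree between 0.90 and 0.95.
* Disorder-content histograms default to bin width 0.05 on $[0,1]$ (a
  literal caption value of 0.5 would put the whole distribution in two
  bins); configurable.
* The MCC sweep pools residues across proteins (the CAID convention);
  per-protein metrics remain available through the per-protein RMSD and
  content tables.
* All randomness (generator, bootstraps, emulated predictors) descends
  from explicit integer seeds; seeded helpers save and restore the
  caller's RNG state.

## Problem sizes

The default cohort (200 proteins, ~37k residues) runs the full benchmark
in a few seconds. The test suite uses cohorts of 40–200 proteins,
binormal calibrations at ~24k residues per separation level, a 50-chain
geometry suite checked against the reference DSSP implementation, and
10⁴-residue closed-form checks; these sizes make every statistical
tolerance (3 standard errors, ±0.02 AUC, ±1 threshold unit) comfortably
testable while keeping a full run under a minute.

## Known limitations

* The Kabsch–Sander implementation omits β-bulges and the PPII class;
  against real, irregular structures agreement with a reference DSSP will
  be below the exact agreement seen on ideal geometry.
* Author residue numbering is assumed to match annotation numbering;
  length mismatches are truncated with a warning, not remapped.
* Multi-model (NMR-style) structure files are not supported; only the
  first model/altloc is read.
* The generator's two-state confidence model cannot reproduce every real
  confidence pathology (e.g. domain-boundary dips in long linkers); the
  discordance knobs are a deliberate, minimal mechanism.
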