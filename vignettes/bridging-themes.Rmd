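---
title: "Bridging themes and the beta-trefoil-like motif: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridging themes and the beta-trefoil-like motif: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trefoilthemes)
```

This vignette explains the models behind the package: what each stage
assumes, the parameters that matter and why their defaults are what
they are, what the synthetic-data generators emulate (and what they do
not), and the numerical choices made where the design was genuinely
open.

## The scientific question

The β-trefoil fold is a pseudo-threefold-symmetric all-β architecture
whose repetitive unit is a four-β-strand motif of roughly 40–50
residues carrying an absolutely conserved buried water. Whole-fold
comparisons find almost no relatives, which has been read as evidence
that the fold arose *de novo*. The analysis implemented here asks the
question at the level of *segments* instead: do four-strand fragments
of β-trefoil domains recur, detectably, inside other evolutionary
lineages (bridging themes), and does the minimal structural signature
of the fold — two strands, a loop, and the water that stitches their
backbones together — occur outside the lineage (β-trefoil-like, βTL,
motifs)?

## Sequence track

### Windows and profiles

A master domain's MSA is first filtered: a row is kept when its
non-gap overlap with the master columns is at least 90% of the
master's length **and** its identity to the master over mutually
aligned columns is at least 30% (both inclusive). These two cutoffs
control, respectively, fragment rows that would misestimate
insert/delete transitions, and rows so remote that column homology is
doubtful. β-strands on the master come either from a user-supplied
H/E/C string or from `assign_ss()` (below); maximal runs of E of
length ≥ 2 are numbered, and a window of `k = 4` consecutive strands —
the repetitive β-trefoil unit — slides one strand at a time
(strands 1–4, 2–5, …), so `n` strands yield `n − 3` windows. The MSA
restricted to a window's columns becomes a profile HMM:

* match columns: non-gap fraction ≥ 0.5;
* sequence weights: Henikoff position-based, normalized to sum to 1
  (duplicated rows collapse exactly to one observation);
* emissions: `(weighted counts + α·background)/(total + α)` with a
  single background-proportional pseudocount `α = 0.5` — simpler than
  Dirichlet mixtures and adequate at the scale of tens of rows;
* insert emissions: the background (Robinson–Robinson frequencies;
  uniform 1/20 available);
* transitions: observed per-row state paths with Laplace `α`.

### Local scoring and E-values

Scoring is local, mirroring the situation of a sub-domain segment
embedded in a longer chain: a path enters at any match state at any
sequence position (probability `1/(M·L)`, uniform over both) and exits
after any match state (`1/M`); flanking residues are scored by the
background and cancel in the log-odds. The entry convention matters:
uniform entry over match states alone over-counts start positions and
background sequences then score *above* zero on average; with the
`1/(M·L)` entry the path ensemble is a probability subdensity and the
expected background score is ≤ 0, which the tests verify by sampling.
The forward score is computed in log space with exact log-sum-exp (a
compiled kernel); Viterbi uses the same model with a deterministic
match > insert > delete tie-break, and its path provides the
residue-level alignment used downstream for strand associations and
segment RMSDs.

E-values are calibrated per profile by simulation: 200 i.i.d.
background sequences of the database's median length are scored, the
scores fitted to a Gumbel distribution by the method of moments, and
`E(s) = N·(1 − exp(−exp(−λ(s − μ))))` for a database of `N` targets.
This plays the role of the per-domain ("conditional") E-value of
standard profile search tools; the package's E-value is per sequence,
a deliberate approximation that is conservative for the small,
single-domain-like targets used here. Hits require `E < 10⁻³`
(strict) and targets in the query's own X-group (6) are excluded.

### The shuffle/EVD confirmation

Each hit is confirmed independently of the HMM machinery: the master
window sequence and the target are realigned by Smith–Waterman
(BLOSUM62, affine gaps; a gap of length `l` costs `11 + (l − 1)·1`),
the target is shuffled 1000 times by composition-preserving
Fisher–Yates, each shuffle realigned, the null scores fitted to a
Gumbel by moments, and the observed score converted to
`p = 1 − exp(−exp(−λ(s − μ)))`. Only the subject is shuffled by
default — shuffling one side preserves the composition pairing of the
null while halving the variance sources; a `both` switch exists.
Moments rather than maximum likelihood: at 1000 draws the moment fit
recovers λ to within a few percent (verified by simulation), and it
is closed-form and unconditionally stable. Under the null the p-value
is approximately uniform; the acceptance suite checks that the
fraction below 0.05 over 500 replicates lies in [0.02, 0.09], the
slack reflecting the moment fit's mild tail bias.

### Counting objects

Hits aggregate into: a bipartite network with one edge per (query
F-group, target X-group) pair; unique-theme counts, where a theme is
a *profile* with ≥ 1 hit into a lineage (multiple hits by one profile
collapse — overlapping windows deliberately remain distinct themes,
matching the operational definition; an optional merge mode is out of
scope); deduplicated F-group pair associations; strand associations,
emitted when ≥ 3 aligned residue pairs fall into one query strand and
one target strand simultaneously (fewer invites single-residue
artifacts); and metamorphism statistics — the median segment RMSD
over hits with coordinates and the fraction strictly below 2.5 Å.

## Structure track

### Secondary structure from backbone hydrogen bonds

`assign_ss()` is a reduced DSSP-style assigner: the Kabsch–Sander
electrostatic energy
`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol with a
bond below −0.5, amide H placed 1 Å from N opposite the preceding
carbonyl; a residue is strand when it participates in at least one
parallel or antiparallel bridge pair, helix when inside two
consecutive i→i+4 turns. The full torsional/geometric STRIDE-style
refinements are omitted: for idealized or well-resolved inputs the
electrostatic term alone recovers the designed secondary structure at
≥ 95% of residues (tested), and users with pre-computed assignments
can bypass the assigner entirely. The chain's first residue has no
amide H, so an N-terminal strand residue is undetectable in
principle; this accounts for the two mismatching residues on the
generator's 45-residue structure.

### The TM-score search

The search motif is discontinuous (two ordered segments; for the
reference query, 18 + 11 = 29 residues). Candidate placements are all
gapless threadings of the segments onto the target (order preserved,
non-negative inter-segment gap); the best few seeds are refined by
alternating superposition on close pairs with monotone dynamic
programming on the score matrix `1/(1 + (d_ij/d0)²)` until the
mapping is stable (≤ 20 rounds). The score is the TM-score normalized
to the *motif* length, `d0 = 1.24·(L − 15)^{1/3} − 1.8` Å floored at
0.5; normalizing to the motif makes scores comparable across targets
of any size, and `TM > 0.5` is the conventional same-fold threshold.
This is a simplified TM-align: it forgoes secondary-structure-assisted
seeding and fragment heuristics, which on hard, twisted targets can
cost a point or two of TM — the reason the worked-example comparison
carries a ±0.02 band.

### Water, clamp, dry

`find_water_motif()` is distance-only: a water qualifies when
backbone N/O atoms of at least three distinct residues lie within
3.0 Å (listed partners extend to 3.5 Å). No angular terms: water
hydrogens are absent from crystal structures, and the hallmark
geometry is unambiguous at these distances. Partner context comes
from the secondary structure (E → strand, else loop); the canonical
signature is {strand, strand, loop}. The hydrophobic clamp tests the
two strand partners: both must be A/V/L/I/M/F/W/Y/C with side chains
in contact — minimal heavy-atom distance ≤ 5.0 Å when atoms beyond
CB are present, else a CB–CB proxy at 6.5 Å. The doubly
hydrogen-bonded pair that binds the water has CB–CB near 8 Å in ideal
sheet geometry, so real clamps close at the γ/δ level, which is why
the generator models CG/CD atoms for those residues. A motif is
*dry* only when both conditions hold: no qualifying water on the
mapped residues **and** ≥ 1 proline at a mapped donor position
(proline's backbone nitrogen cannot donate); absent both, the site is
merely incomplete.

## The synthetic data

The generators define the study conditions; they are first-class,
tested code.

**Sequence scenarios.** A donor master (120 residues, drawn from the
Robinson background) natively carries the 30-residue theme annotated
with four strands of 6 residues; a recipient master in another
lineage receives the theme mutated at rate 0.3; families of 20
members form around each master by i.i.d. substitutions at rate 0.15
(uniform over the 19 alternatives — identity is the only property the
search depends on, so no rate matrix); two decoy families are drawn
independently. Indels are excluded by default, keeping MSA columns
trivially defined, as the protocol's MSAs arrive pre-aligned. Truth
records every (window, recipient) pair whose window overlaps the
planted segment by at least half the theme length. What this does
*not* emulate: real families have phylogenetic correlation, indel
structure, and composition bias; passing recovery tests therefore
demonstrates the machinery's correctness and calibration, not its
sensitivity on remote natural homologs.

**Structures.** A 45-residue chain: strands 1–7, 12–18, 22–28, 39–45
in an antiparallel sheet, hairpin turns of 4 and 3 residues, and a
10-residue loop between strands 3 and 4 routed past the β1/β2 end.
Strands are built from ideal peptide internal coordinates at
antiparallel-sheet torsions (−139°/+135°); a fully extended
(−120°/+120°) template was tried first and rejected because its amide
H points back along the chain and no placement then yields genuine
Kabsch–Sander bonds. Each strand is placed against its neighbor by
optimizing its rigid transform *and* its uniform (φ, ψ) — a few
degrees of freedom real sheets use — against explicit bond-energy
targets plus backbone/CB clash hinges. Turns and the loop are routed
by spring relaxation (consecutive CA distances stiffly held at
3.8 ± 0.1 Å, clearance hinges against everything already placed); the
water pocket is located by a deterministic grid search as the point
within hydrogen-bond reach of the designated β1/β2 partners that is
farthest from all other backbone N/O, and the loop's middle residue
is anchored so its N donates the third bond. The whole construction
is deterministic (fixed initializations, no RNG) and cached per
session (~30 s once). `noise_sigma` is the RMS *total* atomic
displacement (per-axis σ/√3): under this definition 0.5 Å noise
leaves the 29-residue motif at TM ≈ 0.85, comfortably above
threshold, whereas a per-axis reading of the same number would drag
expected TM to ~0.65. The dry variant omits the water and sets both
backbone donor positions to proline.

## Degenerate inputs and tie-breaks

Ragged alignments, all-gap masters, out-of-range windows, themes
longer than hosts, chains missing backbone atoms, structures without
waters, sub-3-point superpositions, and zero-variance calibration
nulls all fail fast with specific errors (or return empty results
where the contract says so). Viterbi ties prefer match over insert
over delete; `kabsch()` corrects reflections so rotations are always
proper; E-value and p-value formulas are evaluated in the saturating
tail without overflow.

## Problem sizes

The test suite and `scripts/acceptance.R` run entirely on synthetic
data at the following sizes, chosen to exercise every stage at full
protocol settings while remaining desk-scale: 50 (tests) or 30
(script) scenario seeds for recall, 500 replicates × 200 shuffles for
null calibration, 10⁵ samples for Gumbel recovery, 200 oracle cases
per scoring kernel, and 10-seed panels for the structural search.

## Known limitations

* The E-value is per-sequence, not a per-domain envelope
  decomposition; on long multi-domain targets it is conservative.
* The TM search is a simplified TM-align (±0.02 expected on hard
  cases); sequence-order-independent alignment is not attempted.
* `assign_ss()` has no π/3₁₀-helix discrimination or β-bulge
  annotation, and cannot label chain-terminal donors.
* The generators do not model indels, phylogeny, side chains beyond
  CB (CG/CD only for the clamp pair), or crystallographic artifacts.
* The database-scale counts of the original study (thousands of hits
  across dozens of lineages) require the full domain classification
  and deep alignments and are out of scope; the counting operations
  are validated on planted scenarios and toy tables instead.
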