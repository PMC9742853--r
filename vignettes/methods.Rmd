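---
title: "Methods: structural triage of missense variants with varstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural triage of missense variants with varstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varstab)
```

## The problem

A missense variant replaces one amino acid of a protein with another.
Whether that matters clinically depends on more than the identity of the
exchanged residues: the variant may destabilise the fold (a change in the
free energy of folding, ddG = dG_mutant - dG_wildtype, with positive
values destabilising), it may sit next to a ligand, an interface or a
phosphorylation site, it may create or destroy a short linear motif, and
nearby common variants in healthy populations can argue against a
destabilisation mechanism. `varstab` implements this triage as an offline
pipeline: model selection, two-tier ddG estimation, structural
neighbourhood annotation, motif scanning, and the benchmarking/survey
statistics around them. All external resources (structure repositories,
population and clinical variant databases, PTM compendia, motif
libraries) are replaced by file-based inputs, and a fixture module
generates synthetic versions of every input with known ground truth.

## Model selection

Candidates come from a JSON manifest, each with a kind (`experimental`,
`homology`, `predicted`, `user`), the sequence positions it covers and
its quality metrics. The hierarchy is deterministic:

1. covering experimental structures, best (lowest) resolution first;
2. else covering homology models with template identity >= 20% (lower
   identity is *excluded* outright), best identity first; a QMEAN below
   -2 only raises `LOW_QMEAN`;
3. else a covering predicted model; per-residue confidence below 70 at
   the target site raises `LOW_PLDDT_AT_SITE`;
4. else no structure: sequence-level analysis still runs, flagged
   `NO_STRUCTURE`.

Ties break by manifest order, so selection is reproducible. With
`require_partners`, a covering homology model that carries partner
chains outranks a single-chain predicted model (predicted monomers
cannot show interfaces), but the identity exclusion always stands.
Identity is exclusionary while QMEAN only warns because a wrong template
gives a wrong fold, whereas a mediocre QMEAN merely dilutes confidence.
The confidence flag is evaluated *at the target position* rather than
globally — a well-predicted site in a partly disordered model is still
usable. User-supplied models bypass the quality gates (warnings are
still recorded): the user explicitly chose them.

## Structure normalisation

All downstream coordinates are 1-based positions in the protein's
sequence. `apply_offset()` renumbers chains (scalar offset or explicit
injective mapping); insertion codes are rejected rather than guessed at.
`strip_solvent()` removes waters and crystallisation additives from an
editable shipped list; metals are kept by default because they can be
functional cofactors. `isolate_target_chain()` renames the chain of
interest to "A", keeps partner chains under distinct labels and records
them in metadata; `detect_interchain_clash()` flags copied template
chains whose heavy atoms come within 2.0 A of the target chain — below
any plausible nonbonded contact distance. Alternate locations keep the
highest-occupancy conformer; hydrogens are ignored on input and never
generated. Conservation scores can be painted into B-factors
(`paint_conservation()`), with a sentinel for unscored residues.

## Two-tier ddG

### Quick estimator

The quick tier is a second-degree equation over two
structure-independent variables — the hydropathy difference dH
(Kyte-Doolittle) and the volume difference dV between wild-type and
mutant residue — and one structure-dependent variable, the relative
solvent accessibility (RSA) of the site:

    ddG_quick = c0 + (1 - RSA) (c1 dH + c2 dV + c3 dV^2)

clamped from above by `cap(RSA) = 4.5 - 3.5 RSA` kcal/mol, so the
estimate saturates at +1 kcal/mol for a fully exposed residue and +4.5
kcal/mol for a fully buried one. Identity substitutions return exactly
zero. RSA is absolute Shrake-Rupley SASA (probe 1.4 A, 92 deterministic
quasi-uniform sphere points per atom) divided by the per-residue
theoretical maximum ASA, clamped to [0, 1]. The coefficients c0..c3 are
not universal constants: they were calibrated once by least squares
against protocol-generated synthetic data (helix sites across a burial
range plus packed-cluster buried sites, protocol values clipped to
[-10, 10] kcal/mol) and shipped in `extdata/quick_coefficients.json`.
The exposed limit is anchored at c0 = 0 — a substitution on a fully
solvated surface should cost nothing in this saturating regime. Users
can supply their own coefficients.

### Repack protocol

The second tier is a deterministic neighbourhood repack over an
in-package empirical pairwise energy. The energy is intentionally
simple, with every term stated in `energy_params()`:

* soft-sphere repulsion `k_rep (r_i + r_j - d)^2` below van der Waals
  contact (k_rep = 10 kcal/(mol A^2));
* a carbon-carbon contact well, depth 0.1 kcal/mol, ramping linearly to
  zero between contact and 6.0 A;
* a hydrogen-bond term between N/O atoms, depth 1.0 kcal/mol over
  2.4-3.5 A;
* screened Coulomb between charged-group representative atoms (Arg CZ,
  Lys NZ +1; Asp CG, Glu CD -1) with a distance-dependent dielectric
  `eps(d) = 4 d` and distances floored at 2 A;
* per-residue reference energies (all zero by default).

Intra-residue pairs and backbone-backbone pairs of sequence-adjacent
residues are excluded (those distances are fixed by covalent geometry).
The backend is pluggable — any replacement must preserve the
identity-zero and determinism properties — but the shipped energy is the
package's own; it is not a re-implementation of any molecular-mechanics
forcefield, and no backbone minimisation is attempted (sidechain-only
repacking; substitutions that require backbone rearrangement will be
overestimated, which is what the display cap is for).

The protocol: residues whose C-beta (C-alpha for glycine) lies within
12 A of the target's C-beta form the neighbourhood. The neighbourhood is
repacked once from the pristine input; from that shared state two
symmetric arms install the wild-type and the mutant residue from ideal
internal-coordinate templates (initial torsions by exhaustive
single-residue grid search) and repack again; `ddG = E_mut - E_wt` with
both arms scored identically. The symmetric-arm construction is what
makes an identity substitution exactly zero — both arms then follow
bit-identical trajectories — which a purely sequential
minimise/mutate/minimise arrangement cannot guarantee.

Repacking itself is a greedy sequential grid search: selection residues
are visited in ascending distance from the target; each visit rebuilds
the sidechain from its ideal template over a torsion grid (chi1, chi2 at
30 degree steps; chi3, chi4 at 120 degree steps; proline's ring is kept
fixed) and keeps the assignment minimising the selection score. Three
corrections, all on by default, address the artefacts of minimising only
a sphere of residues: only pairs touching the neighbourhood are scored
(`score_neighbourhood_only`); sidechains of the outermost 2 A shell are
frozen identically in both arms (`constrain_shell`); and no move that
worsens the total is ever accepted (`reject_worse`), which makes the
per-cycle energy trace non-increasing. Everything is deterministic:
fixed visit order, grid enumerated in ascending lexicographic order, and
ties resolved to the lexicographically smallest torsion vector. Default
two cycles.

Raw values above 10 kcal/mol are displayed as ">10 kcal/mol" with
`capped = TRUE` — beyond that point the sidechain-only model is only
reporting "severe clash", not a quantitative energy. Both arms' models
are returned for inspection, along with a per-cycle energy audit.

## Neighbourhood annotation

Two radii, two rules. The energy neighbourhood uses the C-beta rule at
12 A (above). Annotation joins default to 10 A under the
minimum-heavy-atom rule: annotation reports quote sub-C-beta contact
distances (e.g. a variant "2.0 A away" from a phosphosite), which only
minimum-atom distances can produce. Both radius and rule are arguments.
Each neighbour is joined with every population variant, clinical
variant and PTM at its position, its conservation score and every
overlapping feature interval; partner-chain residues appear with
distances but no joins (annotations are in the target chain's
coordinate system). `ligand_proximity()` reports retained het groups
within the radius with their minimum distances. Summary counts are
recomputed from the joined lists, never cached.

## Motif scanning

Short linear motifs are user-supplied regular expressions over the
amino-acid alphabet (the layout of an ELM classes download; a demo set
ships with the package). `scan_motifs()` reports all matches including
overlapping ones at distinct start positions, via a capture inside a
zero-width lookahead. `motif_delta()` scans wild type and mutant,
restricts to hits overlapping a +/- 25 residue window around the site
(motifs are short; the window only bounds the report, not the match),
and classifies hits by (pattern, span): mutant-only hits are gained,
wild-type-only hits are lost, hits present in both that span the site
are reported unchanged. Back-references are rejected to keep matching
time predictable; anchors are allowed.

## Benchmarking statistics

The metric suite follows standard practice for ddG benchmarks:

* median absolute error, robust to the heavy right tail;
* Tukey fences (k = 1.5, quartiles by linear interpolation) on the
  *error* distribution to exclude outliers before mean absolute error,
  RMSE and Pearson r — the harness can also fence the experimental
  values instead, but errors are the default because that is what the
  excluded metrics are sensitive to;
* confusion tables at 0 and 2 kcal/mol with predictions first rounded
  to one decimal (half away from zero — the convention is stated
  because rounding ties at the threshold decide classifications), class
  = value >= threshold, experimental values classified unrounded;
* the phi coefficient (algebraically the Pearson correlation of the two
  binary indicators, which is also how the tests check it) and the
  concordance fraction (tp + tn)/n.

Two threshold conventions coexist deliberately: the confusion-matrix
classification is ">= threshold", while the cohort-survey notion of a
*destabilising* variant is strictly "> 2 kcal/mol"; each is implemented
where it belongs. The population-rescue filter marks a variant when a
destabilising population variant within 10 A (structural distance) is
seen homozygous at least once or at allele frequency above 5e-4 — a
healthy person tolerating a comparable nearby destabilisation weakens
the destabilisation-pathogenicity hypothesis. `survey()` aggregates
scored cohorts into per-class fractions and pathogenic:benign fold
enrichments per feature category; empty classes are reported as absent
(`NA`), never as zero, and every aggregate is recomputable from the
per-variant rows.

## Synthetic fixtures

The generators are first-class, tested code, and every one is a pure
function of its seed:

* `build_helix()` / `build_extended()`: ideal-geometry backbones (phi
  -57/psi -47 and phi -120/psi 120) built by natural-extension-frame
  placement from standard bond lengths and angles, with template
  sidechains. The helix reproduces textbook geometry (consecutive
  C-alpha distances 3.8 A, rise 1.5 A per residue, i to i+4 N-O
  hydrogen-bond distances around 3.1 A), which the tests assert.
* `build_packed_cluster()`: a target residue caged by a spherical shell
  of inward-pointing residues (default 16 leucines with C-alpha 6.0 A
  from the target). These defaults were chosen at construction time so
  that the fixture's defining contract holds with margin: target RSA
  below 0.05 and a raw Gly to Trp ddG far above the 10 kcal/mol display
  cap. Shell residues sit at non-adjacent sequence positions so no
  covalent-adjacency exclusions apply between them.
* `synth_annotations()`: uniform random positions, log-uniform allele
  frequencies in [1e-6, 1e-2], Poisson homozygote counts, random
  feature intervals and PTM sites, with a ground-truth manifest of the
  generated counts attached.
* `synth_benchmark()`: random substitutions scored by the protocol as
  ground truth, with additive Gaussian noise as the "experimental"
  value. With noise sd 1.0 the median absolute error of a benchmark
  report must recover the half-normal median 0.674 kcal/mol; with noise
  0 it is exactly 0. Gaussian noise is the simplest model supporting
  that recovery test; real thermodynamic datasets have composition
  biases this generator does not attempt to mimic.

What passing on these fixtures shows — and what it does not. The
fixtures exercise geometry, determinism, join correctness, classifier
arithmetic and the protocol's invariants with exact ground truth. They
do not certify accuracy on real proteins: ideal backbones have no
strain, the synthetic energy has no solvation, and benchmark noise is
Gaussian. Benchmarks on experimental datasets require those datasets
and are read through `read_benchmark_table()` when available.

## Numerical choices and degenerate inputs

Quartiles use linear interpolation (R type 7); "Tukey fences" admits
variants, so the choice is stated. Rounding of predictions is half away
from zero at one decimal. The SASA point count (92) makes the two-sphere
test agree with the analytic spherical-cap formula within 2%. The clash
cutoff for copied chains (2.0 A), the torsion grids (30/120 degrees),
the frozen-shell width (2 A) and the +/- 25 residue motif window are
package choices where the method leaves them open; each is a documented
argument. Degenerate inputs have defined behaviour: empty candidate
lists give `NO_STRUCTURE` results rather than exceptions, empty
annotation tables give empty joins, zero-margin confusion tables give
phi = 0 with a `degenerate` attribute, empty survey classes give `NA`
fractions, and batches collect per-item errors without aborting.

## Problem sizes

The shipped test-beds are deliberately desk-scale: helices of 16-40
residues, packed clusters of 17 residues, benchmark sets of 100-200
variants, 1,000-draw statistical oracles. These sizes keep every oracle
(including O(n^2) brute-force scans and exhaustive torsion enumerations)
exact and fast while covering all code paths; nothing in the
implementation depends on them.

## Known limitations

Backbone relaxation is not modelled; severely clashing substitutions
saturate at the display cap rather than converge. The empirical energy
has no explicit solvation or entropy, so its absolute scale is only
loosely comparable to experimental ddG — the calibrated quick tier and
the classification thresholds absorb part of that. Nucleic-acid partner
chains are carried verbatim (kept, clash-checked, never renumbered).
Post-translationally modified residues are not modelled. Motif hits are
not filtered by accessibility or disorder context.
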