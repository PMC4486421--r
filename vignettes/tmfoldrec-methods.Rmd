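---
title: "Statistical-potential threading for transmembrane fold recognition: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical-potential threading for transmembrane fold recognition: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmfoldrec)
```

## The problem

Most transmembrane (TM) protein sequences have no detectable sequence
homologue with a known structure, so homology modelling cannot assign
them a fold. Fold recognition sidesteps sequence similarity: the
membrane-embedded segments of a query are threaded onto every candidate
template structure and an energy function decides which fold the
sequence fits best. Two properties of the membrane environment make a
TM-specific treatment worthwhile: the lipid bilayer is a homogeneous
apolar solvent that can be modelled by a single per-residue contact
term, and membrane topology (which side of the bilayer each loop sits
on) is a hard constraint that can eliminate incompatible templates
before any energy is computed.

## Energy model

A template chain is held in the membrane frame: membrane normal along
z, bilayer core at z = 0, half thickness `half_thickness` (Å; 15 by
default in the synthetic world). For a conformation–sequence pairing
the energy is

$$E = \sum_{i \le j} \varepsilon_{ij}\, n_{ij} \;+\; \sum_i h_i m_i,$$

with $n_{ij}$ the number of unordered residue pairs of amino-acid types
$i, j$ in contact and $m_i$ the number of lipid-exposed residues of
type $i$. The conventions, all tested as exact boundary cases:

* **Contact**: interaction-center distance strictly below 5 Å.
  Interaction centers are C~β~ atoms, C~α~ for glycine. Sequence
  separation must be strictly greater than 4 (so |i−j| = 5 is the first
  counted separation). A pair at exactly 5.0 Å is not a contact.
* **Cross-chain contacts**: for homo-oligomers, each non-identity
  symmetry operator generates an image copy and cross pairs follow the
  same 5 Å rule with *no* separation filter — the image is a different
  molecule. Each (chain residue, image residue) pair is counted once;
  for a C2 dimer the symmetric pair (q, image-of-p) is a genuinely
  distinct contact and is counted as such.
* **Lipid exposure**: a residue counts one lipid contact when at least
  one heavy atom lies inside the slab (boundary inclusive) and has
  positive solvent-accessible surface at probe radius 1.4 Å, computed
  on the full oligomeric coordinate set. The package uses a
  deterministic Fibonacci-lattice surface sampler (92 points per atom);
  the test suite cross-checks burial classification against an
  independent Monte-Carlo sampler. Atoms outside the slab never create
  exposure but still occlude.
* **Nonstandard residues** map to `X` and contribute no terms at all.

With a multiple sequence alignment the profile energy is the mean of
the single-sequence energy over rows, mapped through one common
alignment; gap or `X` characters in a row simply drop that row's terms
at the affected positions. A single-row profile reduces exactly to the
single-sequence energy.

### Unknown neighbors

Hetero-oligomeric templates have neighbor chains whose residue
identities are unknown at threading time. Their interaction centers are
carried as `neighbor_centers` and scored through a z-layer amino-acid
distribution: |z| from 0 to 15 Å is sliced into 1 Å layers and the
per-layer composition of the template set replaces the unknown identity,
so a contact with an unknown neighbor contributes the compositional
expectation of ε at that depth. Contacts between two unknown positions
contribute the double expectation; they are constant per template.
Layers with no observations fall back to the global membrane
composition; neighbor centers with |z| ≥ 15 Å are outside the layered
region and are skipped.

## Potential estimation

The potential is trained by maximum likelihood against shuffled decoys:
for each training chain the native sequence and `decoys_per_native`
uniform permutations of it are threaded onto the same structure, and
the likelihood of the chain is the Boltzmann softmax weight of the
native,

$$\mathcal{L} = \sum_{\text{chains}} \log
  \frac{e^{-E_\text{native}}}{\sum_{k \in \{\text{native}\} \cup \text{decoys}} e^{-E_k}}.$$

Because permutations preserve composition and the structural contact
count, this objective estimates exactly the conditional preference for
the native *arrangement* given the composition; a constant shift of all
ε is unidentifiable and harmless (rankings are shift-invariant, which
the suite asserts).

Numerical choices: Θ initialized at zero; steepest ascent with step
0.1 and backtracking halving, so the objective is non-decreasing across
accepted steps (asserted in the tests); convergence at gradient
max-norm < 1e-6 or `max_iterations`; decoys drawn once per run from the
recorded seed, making the surface fixed and the result reproducible to
the byte. No regularization term is added — the model is kept strictly
physical with a minimal parameter set. A NaN objective aborts with the
iteration number.

## Topology grammar filter

Per-residue region strings over `{1, 2, M, R}` collapse to grammatical
structures (`11111MMMMM22222MMMMM22222MMMMM11111` → `1M2M2M1`). The
similarity of two grammars with equal membrane counts is

$$TS = \frac{\max(N_{11}+N_{22},\; N_{12}+N_{21})}{L - N_M},$$

the `max` making the score invariant to the arbitrary side-1/side-2
labelling. Templates pass at TS strictly above 0.9; re-entrant
templates are discarded whenever the query has no re-entrant region.
Design choices where the formula alone is underdetermined:

* **R tokens** form a third side class that matches only itself, and a
  positional R/side mismatch counts toward neither numerator term.
* **Grammars of unequal length** (possible only through missing
  terminal loops once membrane counts match) are scored incompatible
  rather than gap-aligned. A cut structure whose grammar starts or ends
  with `M` gets a terminal *wildcard* that matches any side and is
  excluded from both numerator and denominator.
* The optional **short-linker filter** (query linker ≤ 5 residues
  aligned to a template loop > 15 residues ⇒ reject) ships off by
  default: the short/long partition is arbitrary and applying it has
  not been observed to help.

## Threading

Membrane segment i of the query is aligned gaplessly to template
segment i at shifts $c_i - 2, \dots, c_i + 2$ with
$c_i = \lfloor (L^{str}_i - L^{qry}_i)/2 \rfloor$ (floor division makes
odd-difference shift sets reproducible). The Cartesian product gives
exactly $5^{NTM}$ alignments — small enough for exhaustive scoring and
exhaustively verified against a naive oracle up to NTM = 4 (625
alignments) in the tests. Up to 10 query residues upstream and
downstream of each segment then fill the template positions flanking
the aligned stretch, so template loop positions are not left void;
flanks truncate at either chain's termini, never overwrite membrane
assignments, and when two segments compete for a position the nearer
one wins (ties to the earlier segment). Template positions that remain
unmapped contribute no terms; flank–flank contacts are counted like any
other. Ties in energy are broken deterministically: first enumerated
alignment within a template, lexicographic template identifier between
templates.

## Reliability of nativeness

Chains with different segment counts live on different energy scales,
so the reduced energy `e = E/NTM` is used. Cumulative distributions of
native and decoy reduced energies are each fitted with
`H = erf(e·a − b)/2 + 0.5` by nonlinear least squares against the
Hazen empirical CDF, `(rank − 0.5)/n` (initialization a = 1,
b = mean(e); degenerate constant samples abort). "Decoy" means the
best-scoring non-native template per query. The score
`H_N/(H_N + H_D)` is computed from log-CDFs
(`H = Φ(√2(ea − b))`), so it reaches its correct limit of 1 deep in
the native tail instead of underflowing to 0/0, and it is clamped below
at 0.5: with the shipped parameters the raw ratio dips marginally under
0.5 above the curve-crossing energy (e ≈ −1.003), a regime where the
prediction is uninformative anyway. The shipped defaults are
a~N~ = 1.380, b~N~ = −2.473, a~D~ = 2.050, b~D~ = −3.145; refitting
with `fit_curves()` is recommended whenever the potential is retrained,
and the jackknife in `run_train()` does so automatically from fold-out
energies.

```{r reliability-curves, fig.width = 6, fig.height = 3.5}
autoplot(default_reliability_model())
```

## The synthetic world, and what it does not show

`make_library()` builds fold classes as idealized α-helical bundles:
1.5 Å rise and 100° twist per residue, C~α~/C~β~ at 2.3/3.4 Å from the
axis, helices alternating up/down and spanning the slab, with region
labels derived from the interaction-center z. Classes differ by the 2D
arrangement of helix axes (line, triangle, permuted line, hub and
spokes, …), chosen so that adjacent-helix interface counts are
comparable across classes — otherwise raw-energy ranking would simply
favor the densest packing regardless of sequence.

Sequences are drawn by Metropolis sampling from a seeded ground-truth
potential. The default `sampling_temperature = 0.3` (in units of the
potential) puts sequences close to the ground state of their own
contact map, emulating the strong optimization of real native membrane
sequences; at temperature 1 the sampled sequences encode their fold
only weakly and even the generating potential cannot rank them
reliably, which is a property of the data, not the algorithm.

Problem sizes used by the shipped experiments (chosen once as the
package's benchmark design):

* **End-to-end benchmark**: the default spec — 4 fold classes, 3
  helices of 20 membrane residues, 15 Å half thickness — with 8 queries
  per class and a fold-class jackknife (a held-out query's class never
  trains the potential it is scored with). The suite requires ≥ 90 %
  native-class recovery and always beating the 1/F random baseline.
* **Parameter recovery**: 40 sequences per class sampled at temperature
  0.6 with 200 decoys per chain and 250 ascent iterations; the suite
  requires Spearman ≥ 0.8 between trained and generating pair energies
  over all 210 entries. The higher temperature is deliberate: at 0.3
  the native/decoy populations are linearly separable and the
  unregularized likelihood direction stops carrying magnitude
  information, so recovery tests need equilibrium-like diversity.

What passing these tests does **not** show about real data: the
synthetic world has a single-residue backbone representation and no
side-chain packing, loops are not modelled geometrically, re-entrant
regions are never generated, lipid exposure is nearly uniform on the
loosely packed bundles, and query sequences are genuine Gibbs samples
of the scoring model family — real sequences are not. Accuracy numbers
from the fixture world therefore validate the machinery (contract
correctness, estimator consistency, ranking logic), not expected
performance on PDB-derived template sets.

## Degenerate inputs and numerics

* Chains must contain at least one membrane segment; membrane-labelled
  residues must sit within `half_thickness` (+1 Å tolerance) of the
  core.
* A non-glycine residue without C~β~ falls back to C~α~ with a warning;
  a residue with neither is rejected.
* Structures without heavy atoms fall back to an
  interaction-center-only exposure test, with a warning.
* MSA rows covering < 20 % of the masked (membrane) positions are
  dropped; the query row never is.
* An empty filtered library yields an explicit no-compatible-fold
  result (CLI exit code 2), never an error.
* Symmetry operators are validated as rigid transforms; the identity is
  always present.

## Known limitations

Gapless threading cannot absorb insertions within a membrane segment;
segment-length mismatches beyond ±2 of the centered shift are simply
not enumerated. The topology filter assumes equal membrane-segment
counts and treats missing terminal loops as wildcards rather than
aligning grammars with gaps. Lipid exposure approximates the
membrane-detection convention (slab-restricted SASA at 1.4 Å) rather
than reimplementing a full membrane-surface algorithm. The trained
potential is identified only up to an additive constant on ε, and lipid
terms are weakly constrained when exposure is nearly uniform across
positions, as it is on loosely packed synthetic bundles.
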