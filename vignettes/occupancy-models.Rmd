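---
title: "Occupancy, jamming and saturation models on the dodecahedral enzyme-core lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy, jamming and saturation models on the dodecahedral enzyme-core lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corelattice)
```

## The system being modelled

The icosahedral core of the fungal pyruvate dehydrogenase complex (PDC) is a
60-subunit cage of E2 catalytic domains.  Its 20 E2 trimers sit at the
vertices of a dodecahedron and are connected by 30 twofold "bridge"
interfaces, each of which provides one hydrophobic pocket that can receive
the short binding helix of the accessory protein PX (the fungal analogue of
E3-binding protein).  The C-terminal core-binding domain of PX trimerizes
inside the core, forming a basket that hangs interior to one E2 trimer and
occupies that trimer's three bridge pockets.  The basket is bulky: two
baskets clash unless their host trimers are separated by at least two
intermediate trimers.

`corelattice` abstracts this to a graph problem.  The core is a 3-regular
lattice (`build_core("icosahedral-60mer")`): vertices are trimer sites with
unit-sphere coordinates, edges are bridge pockets, and the steric constraint
becomes a *minimum graph distance* between occupied vertices
(`exclusion_rule(min_distance)`):

* `min_distance = 3` — volume-occluding trimers (the basket clash rule);
* `min_distance = 2` — non-occluding trimers (each trimer only consumes its
  own three pockets, so occupied sites merely cannot be adjacent);
* `min_distance = 1` — no exclusion (a degenerate reference case).

An octahedral 24-subunit core (`"octahedral-24mer"`, the cube lattice) and
arbitrary user polyhedra (JSON coordinates + edges) are supported by the
same machinery, which makes the group-theoretic code path exercisable on a
second, smaller symmetry.

## Symmetry classification

Physical equivalence of occupancy patterns is equivalence under the *proper*
rotation group of the lattice — order 60 (icosahedral, I) for the
dodecahedron, 24 (octahedral, O) for the cube.  Reflections are excluded
deliberately: the E2 scaffold is chiral (fixed handedness), so a mirror
image of an arrangement is not reachable by any rigid-body motion of a real
particle.  `rotation_group()` constructs the group numerically, by mapping a
reference vertex and one neighbour to every compatible image pair and
completing each to a right-handed orthonormal frame; a candidate matrix is
kept when it permutes the vertex set within 1e-9.  This avoids hand-coded
generators and works unchanged for user polyhedra (an asymmetric polyhedron
yields the trivial group).

`classify()` partitions occupancies into orbits using the canonical form
(lexicographically minimal sorted image over all group elements) and labels
each stabilizer by its element-order census (`point_group_label()`): C1,
cyclic Cn, dihedral Dn, and the polyhedral groups T, O, I.  Under the
occluding rule the dodecahedral lattice admits valid occupancies of sizes
0–4 only (1, 20, 100, 100 and 10 labelled patterns); the ten maximal
patterns are the ten inscribed tetrahedra, which fall into exactly two
rotation classes of orbit size 5 and stabilizer order 12 (point group T).
The two classes are exchanged by the central inversion — they are mirror
counterparts, which is why both must occur and occur with equal probability
under any achiral assembly law.  The package names them `X4S`/`Y4S` in
canonical-key order; which one corresponds to a particular experimentally
reconstructed map is not decidable from the lattice alone, and the package
makes no such claim.

```{r classes}
core <- build_core("icosahedral-60mer")
rule <- exclusion_rule(3)
cls <- configuration_classes(core, rule)
cls[, c("alias", "size", "orbit_size", "stabilizer_order", "point_group", "jammed")]
```

Terminology for the sub-maximal states follows the saturated/suboptimal/
unsaturated distinction: a *jammed* pattern below size 4 admits no further
valid addition (`2S`, the antipodal pair; `3S`), while an *unsaturated*
pattern is an extendable subset of a maximal one (`X3U`/`Y3U`).  The
wording of the source material on this point is internally inconsistent
(it describes the suboptimal two- and three-trimer states as allowing
further additions, while also naming them terminally suboptimal); the
package adopts the blocked-additions reading, since it is the only one
under which "suboptimal" is distinct from "unsaturated" and under which a
sequential-assembly model can terminate below saturation at all.

## Stoichiometry

`stoichiometry_report()` converts geometry into binding bounds, with no
hard-coded counts: monomeric PX (one helix per pocket) saturates all 30
edges — 30 monomers, E2:PX = 2:1; non-occluding trimers reach the maximum
independent set of the dodecahedron graph, 8 trimers = 24 monomers; and
volume-occluding trimers reach 4 trimers = 12 monomers — 60:12 = 5:1.
`literature_ratios()` annotates previously reported ratios against these
modes; the historical 4:1 value (15 monomers) matches none of them and is
flagged as unexplained rather than rationalised.

## The assembly models

**Preformed-core attachment (the naive model).**  Trimers attach
irreversibly one at a time, each step choosing uniformly among the vertices
whose addition keeps the pattern valid, until the pattern jams.  Uniformity
over addable *sites* is the minimal choice given that no attachment measure
is specified by the biology; it is also the assumption under which the
printed headline numbers are reproduced.  `exact_jamming_distribution()`
solves the chain exactly by recursion, memoizing on canonical forms (the
chain's law is rotation-invariant, so one state per orbit suffices — 11
states instead of 231).  The test suite re-derives the same law with a
plain state-space recursion that knows nothing about the group, as an
independent second route.  The exact absorbing law under the occluding
rule is:

```{r exact}
jd <- exact_jamming_distribution(core, rule)
jd$table
```

Each tetrahedral arrangement collects exactly 3/20 = 15% of chains; 10% jam
as the antipodal pair and 60% as a three-trimer suboptimal state, so only
30% of cores saturate.  `simulate_rsa()` is the seeded Monte Carlo
counterpart (single generator seeded once per call, runs drawn
sequentially, so a seed fully determines the output).

**Co-assembly.**  If PX binds while the core is still growing, early
commitments can forestall the suboptimal traps.  `simulate_coassembly()`
adds core vertices in uniformly random order; a vertex becomes *competent*
the moment it and its three neighbours are present (only then do its bridge
pockets exist), binds at that moment with probability `p_bind` if not
sterically excluded, and any remaining opportunities are filled
post-completion exactly as in the preformed-core chain.  `p_bind = 0`
therefore reduces to the naive model, and `p_bind` has no calibrated
biological value — it is the single abstraction of a mechanism for which no
rate measurements exist.  The model exists to establish a *direction*:
binding during growth enriches saturated tetrahedral outcomes above the
30% of the naive model (at `p_bind = 1` the saturation fraction rises to
roughly 0.36 in our simulations), consistent with co-assembly as a
candidate explanation for saturation levels higher than the naive model
predicts.  Competence requiring the full neighbour shell is the weakest
geometry-faithful condition; detachment is excluded throughout because the
naive model is irreversible by construction.

## The synthetic population stage and saturation recovery

Single-particle classification of such mixtures is unreliable at the level
of class *proportions*: marginalized reconstruction can hide sub-symmetric
particles in a broad class, and sub-tetrahedral content tends to reclassify
as tetrahedral under implicit symmetrization.  The package models this at
the label level only.  A particle's true state is `tetrahedral-X`,
`tetrahedral-Y` (together with probability equal to the saturation fraction
*s*, split equally by the mirror symmetry) or `non-tetrahedral` (everything
else — unsaturated and suboptimal interiors are deliberately collapsed,
since the classification being emulated cannot separate them).  The
confusion model has two parameters: `lambda_loss`, the probability a truly
tetrahedral particle is observed as class N, and `eta_gain`, the
probability a non-tetrahedral particle is observed as X or Y (split
equally).  The forward model is

$$ f_X = f_Y = \tfrac{s}{2}(1-\lambda) + \tfrac{1-s}{2}\,\eta,
   \qquad f_N = 1 - 2 f_X . $$

With zero confusion, $s = 0.60$ gives the observed-class split
(0.30, 0.30, 0.40) — the arithmetic link between "~60% of particles
complete" and a ~30/~30/40 classification.

```{r forward}
expected_fractions(0.60)
```

`generate_population()` draws seeded per-particle labels from this model;
`estimate_saturation()` inverts it by maximum likelihood with a
profile-likelihood interval.  Three observed counts carry two degrees of
freedom, so $(s, \lambda, \eta)$ is not jointly identifiable: the confusion
parameters are *fixed inputs* of the estimator, never estimates — mirroring
the underlying caution that class proportions cannot be interpreted without
external validation.  Because no quantitative confusion rates exist, the
defaults are zero and the values used in the recovery tests
($\lambda = 0.2$, $\eta = 0.05$) are illustrative magnitudes, chosen once
as a plausible moderate-loss/small-gain regime and not revisited.  The
generator emulates label statistics only: it does not simulate images,
orientation distributions, or the dependence of confusion on particle
quality, so passing recovery tests demonstrate correctness of the
label-level inversion, not robustness of any real classification pipeline.

## Numerical choices and problem sizes

* Dodecahedron coordinates use the golden-ratio embedding normalised to the
  unit sphere; vertex ids come from a lexicographic sort of coordinates
  rounded to 6 decimals, making canonical forms reproducible across
  platforms.  Adjacency is detected as minimal Euclidean separation within
  a 1e-6 relative tolerance; rotation matrices must permute coordinates
  within 1e-9.  At these scales (exact algebraic coordinates, double
  precision) both tolerances are separated from the signal by many orders
  of magnitude.
* Enumeration uses depth-first extension restricted to ids above the
  current maximum — duplicate-free by construction.  The full valid spaces
  are tiny (231 patterns at `min_distance = 3`, 5 828 at `min_distance =
  2`), so everything downstream of enumeration is exact.
* Exact jamming probabilities are IEEE doubles; the induced error is
  bounded far below the 1e-12 tolerance used when asserting equalities such
  as $P(X4S) = P(Y4S) = 3/20$.
* Simulations in the test suite use 2·10^4–10^5 runs, which puts three
  binomial standard deviations at ≲0.01 on the probabilities being checked;
  the parameter-recovery study uses 500 replicates of 10^4 particles.
  These sizes were chosen so each statistical assertion has comfortable
  resolution while the whole suite stays desk-scale.
* Random sequential attachment and co-assembly consume one seeded base-R
  generator per call with sequential draws, which makes outputs
  byte-reproducible for a given seed without substream bookkeeping.

## Known limitations

The lattice model treats baskets as all-or-nothing vertex occupancies: no
partial pocket engagement, no monomer/trimer mixtures within one particle,
and no energetic scoring — the exclusion rule is a hard constraint.  The
co-assembly model abstracts all kinetics into `p_bind` and says nothing
about mechanism beyond the direction of enrichment.  The confusion model is
label-level and symmetric in X/Y by construction, so it cannot represent a
classifier biased toward one mirror class.  Finally, the X/Y naming of the
mirror classes is an internal convention; mapping it onto specific deposited
reconstructions would require registering real maps, which is outside the
scope of this package.
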