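---
title: "Risk-weighted corridor planning for the inferior clivus: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-weighted corridor planning for the inferior clivus: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliviplan)
```

## The decision problem

Exposing the inferior clivus through a retro-condylar corridor forces a
trade-off: more bone removal and tissue retraction buys operative space, at
the price of injury risk to the medulla, the vertebrobasilar vessels, the
venous sinuses and the lower cranial nerves. `cliviplan` casts that trade-off
as a shortest-path problem on a corridor graph and solves it per subject, so
the *individual* anatomy — not a population average — selects the approach.

## Model

### Anatomy as data

A `label_map` is a 3-D integer array over a regular grid (RAS axes,
millimetres, voxel-center convention: voxel `(i,j,k)` sits at
`origin + (i-1, j-1, k-1) * spacing`). Eight tissue classes are distinguished:
free space (code 0), bone, cerebellum, brainstem, artery, vein, cranial nerve,
other. Finer anatomical identity (e.g. PICA vs AICA vs VA) is deliberately
collapsed to the class level, because the weight model only consumes
class-level volumes.

A `landmark_set` gives named 3-D points in the same frame. The default
corridor system uses eleven, `a`–`k`, placed at parametric anatomical loci
(condyle posterior margin, jugular process, asterion, foramen-magnum rim,
jugular bulb, jugular tubercle apex, hypoglossal canal, jugular foramen,
and three clival target points); their default coordinates are documented
constants in `phantom_landmark_layout()`.

### The corridor graph

Topology is configuration, not code (`schema: 1` YAML): windows are landmark
triples, paths are landmark quadruples with two designated faces as entry and
exit windows, plans are face-adjacent path sequences from the start to the
end window. Validation is total — dangling references, non-face windows,
broken plan adjacency and cyclic path graphs are all rejected with located
errors.

The bundled default satisfies the canonical counts (11 landmarks, 17 windows,
12 paths, 7 plans). Its route system is a braided DAG: an infra-tubercle
trunk through the hypoglossal-canal landmark, a supra-tubercle trunk through
the jugular-foramen landmark, three crossover tetrahedra that exchange
between the trunks, and one dead-end trans-tubercle probe that no complete
plan uses. Exhaustive enumeration of start-to-end routes yields exactly the
seven declared plans, and the enumeration (`enumerate_plans()`) is kept as a
tested oracle for the shortest-path planner. Of the seventeen windows, nine
are entry/exit faces on plan routes; the other eight are named accessory
apertures (condylar fossa, jugular bulb roof, tubercle faces, ...) that
anchor the remaining landmarks — with twelve tetrahedra, twenty-four
entry/exit face slots cannot realize seventeen distinct connected windows, so
a corridor system at these counts necessarily declares some windows that no
route crosses.

### Weights

For a path tetrahedron T and label map L:

- `tissue_volumes_in_tetra(L, T)` counts voxels whose *center* lies in T
  (barycentric test, boundary-inclusive with relative tolerance 1e-9) and
  multiplies by the voxel volume;
- `injury_risk = Σ volume(class) × coeff(class)` over non-space classes;
- `surgical_freedom = volume(space)`;
- `weight = injury_risk − surgical_freedom`, which may be negative and is
  never clamped.

The default coefficients (space 0, bone 1, cerebellum 2, vein 3, artery 4,
cranial nerve 4, brainstem 5, other 1) follow qualitative severity —
brainstem retraction risks respiratory and circulatory compromise, so it
ranks highest; bone costs drilling time and stability rather than neural
injury, so it ranks lowest. They are explicitly assumptions: every report
records the coefficient table used and a YAML override is a first-class
input. Risk and freedom are kept on a single scale (mm³ and weighted mm³) so
the subtraction is well defined; no normalization is applied by default.

### Planner

The optimal plan minimizes the sum of path weights over all start-to-end
routes. Because weights are routinely negative, the classic priority-queue
form of Dijkstra's algorithm is inapplicable; `optimal_plan()` instead
relaxes edges in topological order on the window/path DAG, which is exact for
arbitrary edge weights. The exhaustive enumerator doubles as an oracle: on
the default topology the two agree on 100% of 1000 random weight vectors
(including negative entries) in the acceptance suite. Exact ties are resolved
to the lexicographically smallest plan id — a documented, deterministic rule.

Plans are classified geometrically: all path-tetrahedron centroids more than
δ below the tubercle landmark's superior (z) coordinate → ITA; all more than
δ above → STA; anything straddling or within the band → TTA. δ defaults to
2 mm and is configurable; the superior axis is +z of the RAS frame.

## The synthetic phantom

`generate_phantom()` rasterizes an analytic structure set — ellipsoids,
capsule tubes along polylines, slabs (the occipital plate carries a cylindrical
foramen-magnum hole) — by voxel-center inclusion, painting in fixed
precedence order (bone over artery over vein over nerve over brain over
space), so overlaps resolve deterministically. The default grid is 96³ at
1 mm isotropic: small enough to build in well under a second, fine enough
that 1–2 mm vessels survive voxelization.

The tunable parameters are the variations that actually flip plan selection:

| parameter | default | meaning |
|---|---|---|
| `va_radius_mm` | 2 | VA caliber; 1 hypoplastic, ≥5 grossly dilated |
| `sinus_dominance` | 0.5 | sigmoid/jugular caliber scale, 0–1 |
| `cn11_height_mm` | 0 | superior offset of the CN XI root exit |
| `tubercle_size_mm` | 9 | jugular tubercle radius (TTA's drilling cost) |
| `condyle_size_mm` | 8 | occipital condyle radius |
| `jitter_mm` | 0.5 | seeded Gaussian landmark jitter |

The phantom is a pure function of its parameter list including the seed;
the RNG state of the caller is preserved.

What the phantom does *not* emulate: true patient-derived surface geometry,
left/right pairing within a patient, mass lesions and the deformation they
cause, partial-volume tissue mixtures, and any biomechanical notion of
tissue tolerance. Tests passing on phantoms therefore demonstrate the
*machinery* — volumetry, weighting, search, classification — and the
qualitative anatomy-to-decision coupling, not clinical validity on real
imaging.

### Cohort simulation and the frozen variation distribution

`simulate_cohort()` draws per-subject parameters from a
`variation_distribution()`: VA caliber as a lognormal body (median ≈ 2.2 mm)
with mass points for hypoplasia (p = 0.12 at 1 mm) and dolichoectatic gross
dilation (p = 0.09 at 6.5 mm), Beta(2,2) sinus dominance, and truncated
normals for CN XI height and condyle/tubercle size. Per-subject RNG streams
are derived from the master seed by subject index, so extending a cohort
never reshuffles earlier subjects.

The bundled distribution was calibrated once against the qualitative
behaviour a retro-condylar cohort should show — the infra-tubercle approach
modal, all three approaches represented, frequencies ordered
ITA > TTA > STA — and then frozen. The real-world split (roughly 82/16/2
percent) reflects actual patient anatomy; a desk-scale phantom cohort mirrors
the ordering, not those exact percentages, and the package makes no claim
beyond the ordinal structure.

## Numerical choices

- **Voxel-center inclusion, not partial volume.** Membership of a voxel in a
  tetrahedron is all-or-nothing. This buys exact conservation (the per-class
  volumes sum to voxel volume × inside-center count, tested exactly) and a
  clean Monte-Carlo oracle, at the price of a boundary-layer discretization
  error of order one voxel.
- **Boundary convention.** Centers on a face count as inside (ε = 1e-9
  relative on barycentric coordinates), so adjacent paths double-count a
  shared-face voxel layer. This is accepted: plans are compared under the
  same convention.
- **Degenerate tetrahedra** (coplanar landmarks) contribute zero volumes
  rather than erroring, so pathological landmark placements degrade
  gracefully; `point_in_tetra()` alone treats degeneracy as an error because
  a membership query has no graceful answer.
- **Monte-Carlo comparison.** The volumetry oracle samples 10⁵ uniform points
  per tetrahedron and classifies by nearest voxel. Its sampling error shrinks
  as n^(-1/2) while the voxel-counting boundary error is fixed at
  O(face area × voxel), so the two agree within 3 standard errors only where
  sampling noise dominates: for tissue classes occupying at least 1% of a
  corridor-scale tetrahedron (≥ 5·10⁴ mm³ at 1 mm voxels). Trace classes
  (thin nerves and vessels near a tetra face) are compared with an additional
  one-voxel-layer allowance of 0.2% of the tetra volume. The acceptance suite
  states the comparison in exactly these terms.
- **Fisher exact test.** Two-sided p by the "sum of small p" convention —
  the total probability of all tables with the observed margins whose point
  probability does not exceed the observed one (with a 1e-7 relative slack
  for floating-point-equal tables) — accumulated in log space via `lchoose`,
  so large margins neither overflow nor prematurely underflow. Mid-p and
  doubling conventions give different numbers and are not offered.
- **Spearman interval.** ρ is the Pearson correlation of average ranks; the
  interval is Fisher-z with `se = 1/√(n−3)` and is tagged `"fisher-z"` in the
  result. Published Spearman intervals obtained by other methods (e.g.
  bootstrap) are not directly comparable, and at ρ = ±1 the interval
  degenerates to a point.
- **Tie-breaks** everywhere are lexicographic (plan ids, enumeration order),
  making every pipeline output byte-reproducible from its inputs; reports
  embed tool version, config hash and seed.

## Problem sizes

The test suite runs phantoms at 64³ × 1.5 mm for unit-level properties and at
the full 96³ × 1 mm scale for the end-to-end checks: a 50-subject cohort
screening, a 7-point VA-caliber sweep, 20 Monte-Carlo volumetry pairs at 10⁵
points each, and 1000 random-weight planner-oracle comparisons. These sizes
were chosen so the whole suite completes in well under a minute of compute on
one core while still exercising every full-scale code path.

## Known limitations and open points

- The default topology is a principled stand-in satisfying the canonical
  counts and the under/through/above-tubercle structure; a site-specific
  corridor system (different landmark identities or incidence) can be dropped
  in as YAML without code changes.
- Risk coefficients are ordinal assumptions, not fitted quantities. Ranking
  robustness to coefficient scaling is exact (scaling all coefficients by k
  scales every injury risk by k), but cross-tissue ratios matter and should
  be sensitivity-checked per application (`sensitivity_sweep()` helps).
- Weight compares risk against freedom on one scale with an implicit exchange
  rate of 1; applications weighing maneuverability differently should rescale
  coefficients rather than the freedom term.
- The cohort simulator treats subjects as independent; paired sides of one
  patient are not modelled.
- Test-retest reliability of trainee confidence ratings (the
  `read_trainee_pairs()` / `scripts/trainee_reliability.R` hook) requires the
  externally deposited ratings data; the package validates the ingest path on
  synthetic ratings only.
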