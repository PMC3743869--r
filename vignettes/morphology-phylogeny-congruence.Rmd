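---
title: "Comparing colony morphology with molecular phylogeny: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing colony morphology with molecular phylogeny: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(phylomorph)
```

# The problem

Branching corals of closely related morphospecies overlap both in
corallite-scale characters and in nuclear marker variation, so neither
classical taxonomy nor a single-locus phylogeny cleanly separates them.
`phylomorph` operationalizes a third axis: *whole-colony* morphology,
measured from CT volumes, compared quantitatively against genetic distances
of the same colonies with permutation statistics. This vignette documents
the models, the tunable parameters, the numerical conventions, and the
places where the design was genuinely open — in enough detail that every
number the package produces can be traced to a decision stated here.

# Morphometrics

## From voxels to a medial skeleton

A colony arrives as a binary occupancy grid with per-axis physical spacing
(mm/voxel). CT stacks are strongly anisotropic (an axial pitch of 1.5 mm
against 0.33 mm in-plane is typical), and every distance the package
reports is in mm, never in voxel counts.

1. **Largest component.** Segmentation debris is removed by keeping the
   largest 26-connected foreground component.
2. **Isotropic resampling.** 3D thinning assumes cubic voxels, so the
   volume is resampled to the finest axis pitch. The occupancy is
   interpolated *trilinearly* and thresholded at 0.5, rather than
   replicated slice-wise: nearest-neighbour replication leaves terraced
   surfaces whose notches bite into the distance transform and systematically
   shrink inscribed radii, and whose crease ridges grow spurious skeleton
   branches.
3. **Distance transform.** An exact anisotropic squared Euclidean distance
   transform (separable lower-envelope algorithm, implemented in C++)
   gives, at every foreground voxel, the distance in mm to the nearest
   background voxel center. Twice that value at a medial-axis point is the
   local branch thickness: the inscribed sphere drawn at the medial axis is
   bounded by the branch surface.
4. **Thinning.** The curve skeleton is obtained by directional homotopic
   thinning: repeated sweeps over the six face directions delete *simple*
   voxels (deletion preserves both foreground 26-connectivity and
   background 6-connectivity, checked by the two-condition neighbourhood
   characterization) that are border voxels of the sweep direction, are not
   curve endpoints (more than one foreground neighbour), and sit where the
   object is at least two voxels thick along the sweep axis. The last
   condition stops a one-voxel-thick wall from being consumed lengthwise
   within a single sweep — the failure mode that makes naive sequential
   erosion shorten or destroy tubes. Diagonal one-voxel-thick ribbons,
   which no axis sweep can erode, are peeled by a rim phase whose
   candidates (voxels with at most four foreground neighbours) are frozen
   at the start of each pass so the peel cannot cascade.
5. **Graph extraction.** Skeleton voxels form a graph under 26-adjacency
   with physical edge lengths; its minimum spanning tree removes the
   triangle chords of lattice staircases. A non-tree edge that closes a
   cycle longer than six median branch diameters flags the colony as not
   tree-like (anastomosis); the cycle is broken along the spanning tree and
   a warning is raised.
6. **Branch decomposition and pruning.** The spanning tree is decomposed
   into significant paths: the tree diameter path is accepted first, then
   iteratively the farthest remaining leaf's path to the accepted set,
   until no leaf lies farther than the pruning length (default: twice the
   median inscribed diameter along the skeleton — corallite-scale surface
   spurs are shorter, real branches are longer; the default is exposed as
   `prune_length`). This global decomposition deliberately replaces
   iterative leaf clipping, which can nibble a long branch to death through
   locally messy voxel neighbourhoods.
7. **Cleanup.** Junction–junction connectors shorter than the local branch
   diameter are contracted (two junction nodes inside one thick region);
   junctions left with two incident branches are spliced; two artifact
   filters remove terminal branches that are either much thinner than the
   colony's median branch (below 0.6×) or lie for most of their length
   (over 60%) inside another branch's tube — both signatures of the
   crease ridge where two branch surfaces intersect, whose own medial curve
   survives thinning. Finally, tip ends are trimmed back by one local
   radius: homotopic thinning runs the curve into the rounded end cap,
   whereas the medial axis of a tube ends one radius short of the surface.

Inscribed radii along the skeleton are read from the distance transform by
hill-climbing to the nearest local maximum of the distance field: a lattice
curve sits slightly off the true medial axis, and the pointwise value
under-reads the radius, most visibly for thick branches. For artifact
*filtering*, by contrast, the raw neighbourhood value is used — the
hill-climbed value of a crease spur leans into the neighbouring branch and
would mask exactly the artifacts the filters look for.

## Branch measures and colony traits

Per branch (oriented away from the basal node, the lowest tip on the
growth axis +y):

* `da` — inscribed diameter at the proximal end (the beginning of the
  branching point); `db` — one local diameter distal to the junction along
  the branch ("after branching" is not a point, so the offset is fixed at
  one diameter and documented); `dc` — at the tip (tip branches only).
* `b_angle` — angle between the axes of the two sibling branches at a
  junction, each axis estimated by a total-least-squares line fit to the
  branch centerline (first principal component, oriented
  proximal→distal; robust to lattice jaggedness; an endpoint-chord
  alternative is available via `direction = "chord"`).
* `g_angle` — angle between the branch axis and +y.
* `rb` — centerline arc length from branch origin to its next split or
  tip.
* `br_spacing` — distance from a branch tip to the nearest centerline
  point of a different branch. The centerline (not the surface) is the
  target convention because it makes ground truth exact in the simulator;
  users comparing against surface-target conventions should subtract the
  neighbour's local radius.

Colony traits: **thickness** = mean over branches of the representative
diameter (mean of interior inscribed diameters, excluding a half-diameter
margin at each end — the least junction-biased choice; `da`, `db` or `dc`
can be selected instead), **spacing** = mean `br_spacing` over tip
branches, **length-to-thickness ratio** = mean of `rb` over the branch's
own diameter. Aggregation uses the arithmetic mean by default (median
available). Traits are standardized with the sample (n−1) standard
deviation — the convention is recorded in the output metadata — and
colony-to-colony distances are Euclidean in the three-trait space.

# Genetics

The p-distance between aligned sequences is the proportion of differing
sites over comparable sites; sites with a gap or N in either sequence are
excluded (pairwise deletion — the standard convention; comparison is
case-insensitive, and IUPAC ambiguity codes other than N are demoted to N
with a warning). Samples carry one (homozygote) or two (heterozygote)
alleles; to standardize comparisons the homozygote's allele is duplicated
and the sample-level distance is the mean of the four inter-allele
comparisons. A heterozygote's four self-comparisons average to half its
inter-allele distance, but the matrix diagonal is defined as 0: clustering
and permutation machinery require a proper distance matrix.

# Trees and topological distances

The morphological dendrogram uses unweighted average linkage (UPGMA):
clusters merge at half the mean between-cluster distance, so cophenetic
distances equal the average distance at the merge and the tree is
ultrametric. Ties are broken by the lexicographic order of member labels,
and the two children of every merge are ordered the same way, so output is
identical across platforms and input orderings. WPGMA is available via
`method = "weighted"`.

Topological distances are cophenetic distances with all branch lengths set
to 1 — the number of edges between two leaves. Trees are treated as rooted
as parsed, and the root counts as an ordinary path vertex (its two
incident edges both count); users who prefer unrooted path lengths should
unroot explicitly before calling. Allele-level leaf distances collapse to
sample level by the same duplication-and-average rule as the sequence
distances.

# Congruence tests

Both tests permute *objects* — rows and columns simultaneously — and use
the add-one convention `p = (1 + #{null ≥ observed}) / (n_perm + 1)`, so
the smallest attainable p is `1/(n_perm + 1)`. The default is 1000
permutations, and seeds are mandatory arguments: every p-value in a report
is reproducible from the recorded seed.

* **Mantel.** `Z = Σ_{i<j} d1_ij d2_ij`; `r` is the Pearson correlation of
  the unrolled upper triangles (`r` is invariant under positive affine
  transforms of either matrix, `Z` is not); the reported `t` is the
  permutation-standardized deviate `(Z − mean Z_null)/sd Z_null`.
  Closed-form moment approximations are deliberately not used: the
  permutation deviate converges to the same quantity without extra
  assumptions. The default tail is one-sided (greater): congruence is a
  directional hypothesis.
* **CADM.** Distances are replaced by mid-ranks within each matrix;
  Kendall's W with tie correction, `W = 12S / (m²(N³−N) − mT)`, measures
  concordance of the m rank vectors. The global null permutes every matrix
  independently (a fixed-reference variant is a documented alternative);
  because W is invariant under a common relabeling, exact enumeration
  holds the first matrix fixed. A posteriori, matrix k receives the
  Pearson correlation between its ranks and the mean ranks of the others,
  with a p-value from permuting matrix k only. The tie correction is
  permutation-invariant and is precomputed once, which makes the
  999-permutation null loop cheap.
* **The two-matrix identity.** For m = 2, `W = (1 + ρ)/2` with ρ the
  Spearman correlation of the unrolled triangles. With mid-ranks and
  *unequal* tie structure the identity is only approximate (W normalizes
  by the arithmetic mean of the two rank variances, the correlation by
  their geometric mean); it is exact to machine precision on tie-free
  input, and the package's tests assert exactly that split.

`congruence_report()` assembles the table-style summary: one row per
genetic input and mode (`raw` distance matrices, or `topological`
tree-derived distances, collapsing allele leaves when a genotype map is
supplied), each row carrying the Mantel t/p, Kendall's W/p and the a
posteriori correlation/p. A failing row reports its error and leaves the
remaining rows intact.

# The synthetic study system

The generators exist to give every downstream stage a known truth; they are
measurement test fixtures, not biology.

* **Colonies.** Strictly bifurcating trees in 3D: a basal segment along
  +y; at each bifurcation the two children deflect symmetrically so the
  angle between them equals `branch_angle` (normal jitter optional), with
  the bifurcation plane's azimuth advancing by the golden angle. Segment
  lengths and radii take optional lognormal variation. Parameter sets
  whose non-adjacent segments overlap beyond a tolerated fraction (5%)
  are rejected as degenerate. Exact per-segment geometry — radii, lengths,
  angles, tip spacings, bifurcation count — is recorded, so recovery can
  be asserted, not eyeballed.
* **Sequences.** An equal-rates (Jukes–Cantor-style) substitution model on
  a star species tree: species ancestors sit at depth `divergence/2` from
  the root, alleles at `within_divergence/2` below their species ancestor
  (default `divergence/10`). The expected p-distance for a path of t
  substitutions/site is the closed form `3/4 (1 − e^{−4t/3})`, which
  calibrates the simulator: between-species allele pairs expect
  `f(divergence + within_divergence)`. Samples are heterozygous with a
  configured probability; homozygotes store a single allele. Hybrids carry
  one allele from each of two species — no recombination, mirroring the
  one-allele-per-parental-lineage pattern that motivates them. The richer
  Tamura-style models and ML tree inference used in empirical studies are
  out of scope; externally inferred trees are accepted as Newick.
* **Coupled datasets.** `generate_congruent_dataset()` draws trait vectors
  from species-specific unit-variance normals whose means separate by
  `effect_size` (in within-species s.d. units) and simulates a marker on
  the same species assignment. `effect_size = 0` makes morphology
  independent of genetics — the null configuration for calibration.

**Default study conditions** (in `demo_config()`): three species of four
colonies each, differing in radius (4 / 2 / 3 mm), branch length (22 / 18 /
34 mm) and branching angle (55° / 45° / 35°), rasterized at
0.33 × 0.33 × 1.50 mm/voxel; angle jitter 4°, length and radius
coefficients of variation 0.08 and 0.05 — enough within-species variation
that colonies are distinguishable individuals, small enough that species
separate. Markers: 300 aligned sites, divergence 0.08 and 0.05
substitutions/site, heterozygosity 0.3, one hybrid sample in the second
marker. No quantitative trait distributions are available for real
congeners, so these are the package's own choices, fixed once and exposed
in the configuration.

**What the generator does not emulate:** accretive growth, environmental
plasticity, corallite-scale surface texture, partial-volume gray levels
(volumes are already binary), scanning artifacts, recombination or
coalescent within-species structure. Passing recovery tests therefore
demonstrates that the measurement and testing machinery is correct on
clean branching geometry — not that segmentation of real scans, or real
marker evolution, is this well behaved.

# Numerical conventions and degenerate inputs

* Distance matrices are validated (square, symmetric to 1e-8, nonnegative,
  zero diagonal) and symmetrized exactly; label order mismatches are
  errors, never silently reordered.
* A sphere-like volume (no elongation beyond the pruning scale) yields
  zero branches and a degeneracy warning; an empty volume, a constant
  distance matrix, fewer than 4 objects in a permutation test, and
  unmapped allele labels are all hard errors.
* Branches with fewer than two centerline points are excluded from
  measurement with a warning; colonies with no tip branches have no
  defined spacing trait and raise an error.
* Zero-variance traits standardize to zero with a warning.
* Exact permutation enumeration guards its factorial growth (n ≤ 8 for
  Mantel, n ≤ 6 for CADM).

# Problem sizes in the shipped tests

The suites were sized to give each statistical assertion real power while
keeping a full run in the low minutes: 500 replicate null datasets
(15 objects, 999 permutations) for the size/uniformity checks of both
tests; 500 random trees (≤ 12 leaves) against a graph-search oracle; 200
random matrices (≤ 6 labels) against a naive agglomerative oracle plus
`stats::hclust`; cylinders of radius 2–8 mm and three-generation colonies
of radius 3 mm at CT spacing for morphometric recovery; 200 seeded
power-analysis runs (effect size 5, 15 samples, 199 permutations) plus a
twelve-colony end-to-end run for species recovery.

# Known limitations

* Branch lengths (`rb`) read short by roughly one radius per free end —
  the medial axis of a capped tube ends one radius inside the surface, and
  tip trimming enforces exactly that. Ratios are consistent across
  colonies, so classification is unaffected, but absolute `rb` values are
  conservative.
* Thickness recovers the inscribed diameter of the *discretized* colony;
  at 1.5 mm axial pitch this sits ~10–13% below the continuum diameter for
  3 mm-radius branches. Anything needing absolute accuracy beyond that
  should scan finer or calibrate against phantoms.
* Colonies with genuine anastomosis are flagged, not modeled: cycles are
  broken along the spanning tree and measures computed on the resulting
  tree.
* The two-matrix W identity is exact only up to tie-structure differences
  (see above).
* With very small colonies (a single bifurcation) the sibling-overlap
  region near the junction can dominate a branch's interior, biasing `da`
  upward; measures stabilize from two bifurcations on.
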