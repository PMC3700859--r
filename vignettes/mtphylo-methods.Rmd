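---
title: "Founder-lineage dating and phylogeography of mtDNA: methods and design choices"
author: "mtphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-lineage dating and phylogeography of mtDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtphylo)
```

## The problem

Human mitochondrial DNA is maternally inherited and non-recombining, so a
set of complete mitogenomes from a region can be read as a genealogy: each
haplotype is the record of the mutations accumulated on its maternal line.
Regional studies of this kind ask three questions that this package
operationalizes end to end:

1. **Which named lineage (haplogroup) does each sample belong to?**
2. **How old are the founder nodes of the region-specific clades?**
3. **How is a lineage distributed in space?**

The package works on rCRS-relative variant lists (the branch-label notation
of published mtDNA cladograms), reconstructs mutation-labelled genealogies
by exact maximum parsimony with median-joining verification, dates founder
nodes with the rho statistic under a purifying-selection-corrected clock,
and interpolates haplogroup frequency surfaces by ordinary kriging.

## Variant notation and hotspot masking

A variant token is an rCRS position, optionally suffixed with a derived
base (a suffix that is not the transition partner of the reference base
marks a transversion), prefixed with `@` for a back mutation, written
`pos.nB` for insertions and `pos del` for deletions. Parsing and
formatting round-trip bit-exactly on canonical labels; redundant transition
suffixes are canonicalized away.

Hypermutable sites carry essentially no genealogical signal and are removed
before any reconstruction. The default `hotspot_mask()` excludes positions
16182, 16183, 16519, the HVS-II poly-C tract and the AC repeat, and all
length-heteroplasmy tokens (poly-C insertion runs):

* the poly-C interval is taken as **303–315** and the AC repeat as
  **522–524**. Published legends typically say "variation around position
  310" and "523–524" without printing exact bounds; the intervals here
  follow standard forensic practice and are configurable, which is the
  honest encoding of a rule the literature states loosely.
* length heteroplasmies are represented as a *token class* and removed by
  the mask rather than modelled — they are alignment artifacts at
  homopolymer runs, not countable mutations.

Coordinates are 1-based rCRS positions throughout; circularity is ignored
because no analyzed feature spans the origin.

The bundled reference (`synthetic_rcrs()`) is a deterministic synthetic
16,569-bp sequence with the structural features the analyses rely on
(poly-C tract, AC repeat, pinned bases at classic positions such as T at
152 and A at 7765). It is labelled synthetic everywhere; no result in the
package depends on the true base at any other position, only on rCRS
coordinates.

## Haplogroup classification

Haplogroups are defined by a motif tree (Phylotree-style, one node per
line, defining variants relative to the parent). Classification scores
every node against the haplotype's variants *restricted to its declared
coverage*: `matched` defining variants present, `missed` expected but
absent, `extra_private` unexplained. The winner maximizes
`matched − missed`, ties resolved to the deeper node, then fewer
`extra_private`, then the lexicographically smaller name.

This scoring is a design choice: published studies classify by expert motif
reading, which is not reproducible by machine. The score is monotone in
motif evidence and the tie-breaks make the result deterministic and
order-invariant. Two consequences worth knowing:

* defining variants outside the haplotype's coverage are ignored, never
  counted as missed — a control-region haplotype is not penalized for
  untyped coding-region diagnostics;
* a back-mutated token (`@150`) counts as absence at nodes expecting the
  variant but does not block deeper assignments supported by the rest of
  the motif. This is exactly the V-lineage situation: np 150 is a known
  hotspot on the V stem, and haplotypes that reverted it still reach V
  (and V22, via the coding-region diagnostic at np 7765).

## Parsimony reconstruction and median-joining verification

Each distinct variant label is one binary character; the clade is rooted at
its haplogroup motif (not midpoint — the ancestral state is known from the
motif tree). The search is exact in the regime where dating happens:

* if the characters are pairwise compatible, the perfect phylogeny is
  built directly (it attains one change per character, the minimum);
* otherwise an exhaustive branch-and-bound search over topologies is run
  for up to 12 distinct haplotypes (the largest clade dated in practice),
  with a parsimony-ratchet heuristic above that. Ancestral states are then
  assigned by a deterministic Fitch pass anchored at the root motif.

Ties among equally parsimonious trees are broken by fewest recurrent
sites, then by the lexicographic order of sorted edge labels. Published
trees resolved such ties by hand; a documented deterministic convention is
the reproducible replacement. Every build ends with a conservation check:
replaying edge labels from the root must reproduce each observed haplotype
exactly, enforced at construction time.

Median-joining networks (minimum spanning network, iterated majority
medians of linked triplets, pruning of obsolete median vectors; tolerance
`epsilon`, default 0 as in the standard software) serve as the
verification route. On homoplasy-free data the network collapses to the
parsimony tree; `network_matches_tree()` performs that comparison up to
rooting, splicing out unsampled degree-2 Steiner points (such as an
unsampled root between two subclades, or a grafted stem ancestor) that a
median-joining construction never materializes.

## Rho dating and the corrected clock

For a clade with $n$ sampled haplotypes, $\rho$ is the mean mutation
distance to the reference node and its standard error is computed from the
genealogy's edge structure:

$$\sigma^2 \;=\; \sum_{e}\left(\frac{n_e}{n}\right)^{2} l_e$$

over edges below the reference node, with $n_e$ samples descending through
edge $e$ of $l_e$ mutations. Two reference nodes are dated: the clade MRCA
(*coalescence age*) and its parent in the motif tree (*splitting age*);
they differ by the stem branch of $s$ mutations, every sample passes
through the stem, so $\rho_{split} = \rho_{coal} + s$ and
$\sigma_{split}^2 = \sigma_{coal}^2 + s$ exactly.

Mutation counts convert to years with a complete-genome clock that corrects
for purifying selection: young lineages still carry mildly deleterious
variants that selection has not yet purged, so their apparent mutation rate
is faster than the long-term substitution rate. The package implements
this as a neutral long-term accumulation plus an exponentially decaying
transient excess,

$$t(\rho) \;=\; 3624\,\rho \;-\; B\left(1 - e^{-\rho/C}\right),$$

with the long-term rate fixed at one substitution per 3,624 years and
$B = 24376.79$ years, $C = 23.0702$ mutations calibrated once, by weighted
least squares, against the published (rho, age) calibration pairs for this
clock (six point estimates and twelve interval bounds). The fit reproduces
the calibration ages to within 0.2% and the implied years-per-mutation
rises from about 2,567 for very young clades to about 2,736 at
$\rho \approx 8$, the behaviour the published calibration shows over the
Holocene range. The original correction's exact parameterization is
published elsewhere and is not restated in the material this package works
from; the curve above is this package's own parameterization of the same
mechanism, and it is deliberately frozen — it is a calibration constant,
not a tuning knob. A linear mode (constant 2,590 years per mutation, the
least-squares constant over the same pairs) is available for sensitivity
checks.

Confidence intervals are normal-approximation intervals on the mutation
scale, $\rho \pm 1.96\sigma$, mapped through the clock. The lower bound is
clamped at zero *mutations* only; a tight young clade can legitimately
report a lower bound of a few years, and published tables show exactly
that. Ages are rounded to the nearest year for reporting; comparisons and
propagation use unrounded values.

## Frequency surfaces

Per-population frequencies are exact carrier counts over survey sizes;
area-wide ("total") rows pool counts, never average ratios. Interpolation
is ordinary kriging with a linear variogram $\gamma(h) = h$ and zero
nugget: an exact interpolator, scale-invariant in the variogram slope, and
the natural default when the study names kriging but no variogram. The
kriging system is a single dense linear solve — at survey scale (tens of
populations) nothing heavier is warranted. Inverse-distance weighting is
provided as an alternative; note its well-known bullseye flats between
data points (it is exact at the data but not monotone along a cline, which
kriging is). Coordinates are treated as planar degrees — adequate for a
region a few degrees across — and interpolated values are clipped to
$[0,1]$.

## The synthetic-data generator

`simulate_clade()` emulates the structure regional mtDNA studies date:
clades of a founder node with 7–12 sampled descendants, Poisson-distributed
mutations per branch, an optional 2–3-mutation stem to a sister lineage,
and recurrent hits at already-mutated sites with configurable probability
(finite sites, so masking and recurrence flagging are exercisable). Star
and coalescent topologies are provided, plus exact replay of a fixed
branch table. The seed fully determines the output, and the generator
restores the caller's RNG state.

`simulate_population_panel()` plants a spatial frequency peak (default
17% decaying to zero — the magnitude regional surveys report for a
confined founder lineage) and generates control-region panels whose
carrier counts equal the planted values exactly.

What the simulations do **not** emulate: rate heterogeneity across sites
beyond hotspot recurrence, heteroplasmy, sequencing error, sampling
non-independence (relatives), or population structure within a clade.
Passing the simulation suite therefore shows the *estimators* are
implemented correctly under the stated model, not that the model captures
every feature of real survey data.

The bundled clade table (`clades_synthetic_mitogenomes.tsv`) is a synthetic
stand-in for a study supplementary table that is not redistributable here.
It is constructed so that every statistic the study prints is reproduced
by computation: clade sizes 12/7/9, total mutation counts to the MRCA
(18/4/12, hence rho 1.50/0.57/1.33), edge-sharing structure giving sigma
0.41/0.29/0.42, and stems of 3/3/2 mutations. The bundled motif tree and
population table are likewise labelled synthetic.

## Numerical choices and degenerate inputs

* Classification, reconstruction and network construction are
  deterministic and input-order-invariant; all tie-breaks are documented
  above.
* A single haplotype yields a two-node tree and dates to zero if it equals
  the MRCA; empty variant sets, zero mutation rates and zero-carrier
  panels are all legal and tested.
* Kriging refuses collinear geometries and conflicting duplicate
  coordinates with clear errors; duplicate coordinates with equal values
  are deduplicated.
* Problem sizes: the validation suite runs 200 median-joining/parsimony
  equivalence replicates, 1,000 unbiasedness replicates and 500
  coverage replicates at the study's clade size (n = 12, 1.5 mutations
  per lineage) — sizes chosen to put Monte-Carlo error well below the
  tested margins while keeping the suite quick on a laptop.

## Known limitations

* The clock's correction parameters are calibrated to one published
  calibration (see above); applying the package to data dated under a
  different clock requires replacing those constants.
* Saillard-type intervals are Wald intervals on a Poisson-like scale:
  coverage at n = 12 sits in the low-to-mid 90s on star genealogies and
  degrades on deeply imbalanced coalescent genealogies, where a single
  mutation on a large shared branch moves rho in steps. This is a
  property of the estimator, not of the implementation.
* The exhaustive search guarantee stops at 12 distinct haplotypes;
  larger clades use a ratchet heuristic whose result is checked by replay
  but not guaranteed minimal.
* Haplotypes with coverage gaps at phylogenetically informative sites are
  rejected rather than imputed; restrict the analysis to shared coverage.
* No bootstrap or likelihood support values, no Bayesian dating, and no
  geodesic kriging — all outside the analysis this package reproduces.
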