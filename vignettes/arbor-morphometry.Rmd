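---
title: "Morphometry and classification of cutaneous afferent arbors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry and classification of cutaneous afferent arbors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborscape)
```

## The measurement model

A traced arbor is a rooted tree of 3-D nodes in skin coordinates:
micrometers throughout, +x the anterior-to-posterior axis (the direction
back-skin hair follicles tilt), z the depth below the epidermal surface
(surface = 0; full-thickness back skin is ~135 µm at the developmental
stage emulated here). On disk a trace is standard 7-column SWC; the radius
column is optional (0 when unknown) and is consumed only by the
thick-ending detector.

Solvent clearing compresses tissue in Z to roughly 92% of its original
thickness while leaving X and Y essentially unchanged, so depths measured
in cleared stacks are multiplied by the ratio original/cleared thickness
(`apply_z_correction`, e.g. 135/125) before any depth statistic is
reported. The correction is rejected below 1 — clearing only shrinks — and
provably leaves the XY hull area unchanged.

Per-arbor parameters:

* **Axon length** — the sum of 3-D parent–child segment lengths.
* **Branch points** — nodes with out-degree ≥ 2, counted once regardless of
  degree (a root with two children counts). This matches the convention of
  tracing software; defining a k-furcation as k−1 binary events would
  change totals by < 1% on realistic trees but is not what tracing programs
  report.
* **Arbor area** — the area of the 2-D convex hull of all node XY
  projections, the computational analogue of the convex polygon drawn
  around an isolated stained arbor. Degenerate inputs (< 3 distinct,
  collinear) give area 0 with a warning rather than an error, so a survey
  never aborts on a degenerate arbor.
* **Depth profile** — mean/SD/range of node z, over all nodes or restricted
  to terminals; ending depths are reported terminal-restricted.
* **Tier decomposition** — terminal depths are split at their largest gap;
  two tiers are declared when that gap is at least `min_gap` (default
  30 µm, about half the separation between an outer tier near 10 µm and an
  inner tier near 70 µm). Vertical connectors are maximal unbranched paths
  whose endpoints fall in different tiers and whose endpoint |Δz| exceeds
  `vertical_frac` (default 0.7) of the path length. Both knobs are
  arguments, not constants.
* **Percent difference** (tracing reproducibility) — |a−b|/max(a,b)×100 to
  two decimals. The larger-value denominator is the convention that
  reproduces both published checks (1888/86908 → 2.17%, 60/1071 → 5.60%).

## Ending detection and innervation statistics

Detection is purely geometric, operating on terminal branches (the maximal
unbranched path ending at each leaf) against a follicle map:

* **thick** — mean radius over the final `thick_window` (50 µm) of a branch
  at least `thick_ratio` (2.0) times the arbor median radius. Skipped when
  all radii are zero; forcing it then is an explicit error.
* **lanceolate** — at least `min_twigs` (3) short (≤ 30 µm), predominantly
  vertical (|Δz|/length ≥ 0.7) final segments whose leaves lie within
  `attach_radius` (40 µm ≈ one guard-follicle diameter) of a follicle
  center.
* **circumferential** — nodes in the radial band diameter/2 ± `ring_tol`
  (8 µm) of a follicle, spanning at least `min_ring_span` (60°) of its
  circumference, with at least `min_ring_nodes` (5) nodes. Only the
  contiguous run of in-band nodes starting at a branch's leaf counts, which
  rejects branches that merely pass through the band — a necessary guard,
  since dense free-ending arbors otherwise accumulate incidental "rings".
  The covered span over 360° is the ending's arc fraction.
* **merkel** — declared via trace metadata; Merkel contacts have no
  geometric signature at tracing resolution.
* **free** — every remaining terminal branch.

The ring and palisade tolerances are design values chosen to separate the
generator's endings from free endings by a wide margin; no published
thresholds exist for them, which is why they live in `ending_params()` and
are echoed into reports rather than hard-coded.

Assignment sends each follicle-associated ending to the nearest follicle
center within `attach_radius` of its centroid; ties resolve to the lower
follicle id, making assignment idempotent and order-independent.

Innervation statistics for an arbor with hull area A: the innervation
index is (distinct innervated follicles)/A, so index × A reproduces the
count exactly; the fraction innervated divides by the follicles whose
centers fall inside the hull, boundary inclusive. With no follicle center
in the hull the fraction is undefined and flagged, never silently 0.
Whether the "arbor territory" denominator should be the hull or a
hand-drawn polygon is not decidable from published material; the hull is
used because it is the package's territory definition everywhere else.

Coverage factors come in two estimators: area-based (mean arbor area of a
type × arbors of that type per unit area — the expected number of same-type
arbors over a random skin point; validated in the tests against a
Monte-Carlo point-coverage oracle) and follicle-based (g/f, fraction of
follicles contacted over mean arc fraction, under the assumption that each
follicle's circumference is fully and uniformly occupied).

## Orientation of C-shaped palisades

V_HF is the follicle tilt vector; V_NE is defined as the unit vector from
the follicle center to the XY centroid of the palisade's member nodes (the
body of the C), so "the opening of the C faces anterior" corresponds to an
angle near 0° against a posterior-pointing V_HF. The vector construction
itself is a design choice — published material states the qualitative
convention but not the formula. Per-ending angles are folded to [0°, 180°];
circular summaries use the resultant vector (mean = arg of the resultant,
SD = √(−2 ln R) in degrees). R numerically 0 flags the mean as undefined.
No printed mean/SD exists for the orientation distribution, so its
validation is property-based: posterior-biased generator surveys must give
a circular mean under 30°.

## Classification

The cascade formalizes a discrete-then-continuous decision structure:

1. any merkel ending → MCA;
2. free-ending dominance (free ≥ `free_dominance_ratio` × specialized,
   default 6): two-tier arbors → LA-FE, single-tier arbors at branch
   density ≥ `bushy_branch_density` (5 × 10⁻⁴ per µm²) → BE, otherwise
   unclassifiable;
3. mixtures of specialized kinds below `purity_min` (0.75) →
   unclassifiable (real arbors are uniform in their terminal structures);
4. dominant thick → TE;
5. circumferential: one follicle → I-FACE; hull area below
   `face_area_split` (5 × 10⁵ µm², between territories of a few hundred µm
   and of 1–2 mm diameter) → SA-FACE, else LA-FACE, with follicle-count
   consistency notes (< ~10 vs > ~100) in the rule trace;
6. lanceolate: one follicle → I-FALE; otherwise the side of the line
   log₁₀(index) = `fale_index_intercept` + `fale_index_slope` · log₁₀(A)
   decides HD-FALE (above) vs LD-FALE (below). The default line (slope 0,
   intercept −4.2) was fixed once against the default synthetic survey,
   where high-density arbors sit near 10⁻⁴ and low-density arbors near
   10⁻⁵ follicles/µm².

Every label carries the fired rule chain, sufficient to recompute it by
hand. The free-dominance step is an addition the decision order needs in
practice: a bushy arbor with ~10³ branch points will always produce a few
incidental ring detections, while genuinely follicle-associated arbors
carry at most occasional free endings.

## The synthetic generator

The generator exists so every stage has ground-truthed inputs; its defaults
are the study conditions and are not tuned per run.

* **Lattice** — a square grid at `lattice_density` = 1 × 10⁻⁴
  follicles/µm² with ±18 µm uniform jitter; a sparse `guard_fraction`
  (4%) of large-diameter (~50 µm) guard follicles; tilt vectors scattered
  about +x with 8° SD (under the ~10° reported for wild-type back skin).
  The density is derived, not published: it solves mean high-density
  follicle count ≈ occupancy × density × mean area (30 ≈ 0.9 × d ×
  3.4 × 10⁵).
* **Arbors** — a single afferent enters from below (z ≈ 120 µm), rises to
  the type's depth stratum, and elaborates its territory: follicle-
  targeting types build a nearest-neighbor backbone over an
  occupancy-determined target subset and place ring arcs or vertical
  palisade twigs; free-ending types grow by confined random branching with
  an exact scheduled branch-point count; thick-ending arbors enlarge radii
  over the final 50–100 µm of every branch; the largest free-ending type is
  built as two tiers (outer ≈ 10 µm, inner ≈ 70 µm) joined by 55–80
  straight vertical connectors. Multi-follicle arbors additionally send
  short branches to the territory rim, because traced arbors ramify across
  their whole territory — without them the hull systematically
  underestimates the territory by ~10–15%.
* **Distribution families** are modeling choices: log-normal areas
  (mean 3.4 × 10⁵, SD 3.2 × 10⁵ µm², clipped to the published
  1 × 10⁵–2.5 × 10⁶ range) and lengths; uniform territory diameters;
  per-follicle Bernoulli occupancy (0.9 for high-density, ~0.08 for
  low-density lanceolate types); small-count types draw 2 + Binomial(4,
  0.45) targets (mean 3.8, SD ~1.0).
* **Calibration** — two large-area circumferential constants (territory
  diameter 1.67–2.54 mm; occupancy 0.36–0.76) were set by one
  generate-and-measure calibration at a fixed seed so the pipeline-measured
  survey means sit at the published values (197 follicles, 57% innervated),
  then frozen. The implied territories are slightly larger than the quoted
  1–2 mm diameters; the published mean count and fraction, the quantities
  this package validates against, cannot all be reproduced at the derived
  lattice density with strictly 1–2 mm disks, and the means won.
* **Tracing noise** — `generate_trace_pair` jitters coordinates (SD = 2% of
  mean segment length) and drops terminal twigs (3%), bracketing the
  published 2.17%/5.60% reproducibility differences well inside 10%.

What the generator does **not** emulate: real branch tortuosity and
diameter taper, follicle rows and hair-cycle structure, competition between
neighboring arbors, partially overlapping arbors, imaging artifacts, or
tissue distortion beyond uniform Z shrinkage. Passing tests therefore
demonstrate that the measurement and classification chain is correct on
clean, well-separated geometry — not that it is robust to every tracing
pathology in real material.

Determinism: every generator function takes a seed and restores the
caller's RNG state; a survey derives per-arbor seeds from the master seed,
so identical (config, seed) reproduce exported SWC files byte-for-byte.

## Numerical choices and degenerate inputs

* Hulls use `grDevices::chull` plus the shoelace formula; point-in-hull is
  a convex half-plane test with boundary counted inside (tolerance 10⁻⁹).
* Angular span of a node set is 360° minus the largest angular gap.
* Written SWC and follicle CSV fix coordinate precision (10⁻⁴ µm and 10⁻⁶
  respectively) so round-trips are exact at the written precision.
* Single-node traces refuse length metrics; zero-hull arbors refuse the
  innervation summary; empty angle sets refuse circular statistics.
* Follicle-map tilt vectors are renormalized with a warning past 10⁻⁶
  deviation from unit length.

## Problem sizes

The test suite validates primitives against brute-force oracles (O(n³)
hull on ≤ 200-point clouds, per-edge summation on ≤ 500-node trees, direct
resultant sums on 10³ angles), runs classifier agreement on a 12-per-type
survey, and checks generator recovery of the published innervation
statistics on 300-arbor single-type surveys — the same size
`scripts/acceptance.R` uses. These sizes keep the full suite and the
acceptance script at a few minutes each on one CPU while leaving Monte
Carlo error well below the 3-SE acceptance bands.

## Known limitations

* Merkel-cell arbors are classified from a declared annotation only; there
  is no geometric Merkel signature at this scale.
* Circumferential bundles are not resolved into individual fibers; an arc
  ending is one ending regardless of fiber multiplicity.
* The high/low-density boundary and the other classifier thresholds were
  validated only against the synthetic survey; real material with
  intermediate densities would need the thresholds re-examined (they are
  all in `classifier_thresholds()`).
* Transverse lanceolate endings are not modeled or detected.
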