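---
title: "Methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what is modeled, which knobs exist, why the defaults are what they are, and
what the synthetic validation does and does not establish. Coordinates are
micrometers throughout; densities are reported per square millimeter.

## The two-branch design

A slide is a planar point pattern of CD8+ T-cell positions. Two branches
analyze it independently and are never allowed to feed each other:

* the **point-process branch** asks *what local interaction generates the
  pattern* — it models each sub-region parametrically;
* the **morphometric branch** asks *what the realized aggregates look
  like* — it is model-free and operates on the detected clusters
  themselves.

Keeping the branches independent means their agreement (e.g. fitted cells
per cluster vs. counted cluster sizes) is corroboration, not circularity.

## Moving-window point-process analysis

**Windows.** 500 µm square windows stepped by 250 µm (50% overlap). The
window must be small enough that local stationarity is defensible and large
enough to hold a useful number of cells; 500 µm spans a few cluster
diameters at typical lymphoid length scales. Only full-size windows are
generated, so all densities share the same denominator. Membership is
half-open, so non-overlapping tilings partition the points. Windows with
fewer than `n_min = 10` points report density only: the normal
approximation of the CSR test and K-based fitting are meaningless on a
handful of points.

**CSR test.** One-tailed Clark–Evans test against a clustered alternative
at α = 0.05. The index compares the observed mean nearest-neighbor distance
with its Poisson expectation. In bounded windows the raw expectation is
biased upward (edge cells have no neighbors beyond the boundary), which at
the 0.5 mm scale makes the uncorrected one-tailed test conservative enough
to matter. The default therefore applies Donnelly's rectangular correction
to the expectation *and* uses Donnelly's variance including its perimeter
term. The test suite verifies that the resulting type-I error over 1000
simulated Poisson windows of ~100 points is 0.05 within three binomial
standard errors; `correction = "none"` remains available for comparison.

**Thomas model.** Aggregated windows are fitted with the Thomas process:
Poisson parents of intensity κ, Poisson(μ) offspring per parent, isotropic
Gaussian displacements with standard deviation σ. Its K function is
`thomas_K_theoretical()`. Fitting is minimum contrast on K^q with q = 0.25,
the conventional variance-stabilizing exponent. Two numerical choices
deserve note:

* *Optimization.* Nelder–Mead on (log κ, log σ) from a deterministic 3 × 3
  grid of starting values (dispersion at 5/15/40% of the fitting range,
  offspring counts 3/10/40). Log-parameters keep the search unconstrained;
  the multistart guards against the contrast surface's occasional second
  basin. No randomness: refitting the same window reproduces the same fit.
* *Fitting range.* A pilot fit uses the conventional r_max of a quarter of
  the shorter window side. The Thomas correlation is exhausted beyond a few
  σ, and in small windows the empirical K at larger r contributes mostly
  noise, which drags κ upward and μ downward. The final fit therefore
  restricts r_max to 3σ̂ from the pilot, clamped to [40 µm, side/4]. The
  acceptance suite checks the resulting accuracy: over 200 windows at the
  study scale simulated from Thomas(κ = 40 mm⁻², μ = 15, σ = 25 µm), the
  median-aggregated estimates of all three parameters are within 15% of
  truth. (Per-window κ error cannot meet such a bound even in principle —
  a 0.25 mm² window holds ~10 parents, so a perfect parent-counting oracle
  would still carry ~30% Poisson error; accuracy lives in the aggregate.)

μ is recovered as λ̂/κ̂, which ties the fitted model to the observed
intensity exactly. Fits with dispersion pinned at implausible values
(σ above the window side, or collapsed to zero) are flagged
`converged = FALSE` and excluded from heterogeneity summaries.

**Derived quantities.** Offspring radii are Rayleigh(σ): mean distance
σ√(π/2), 95% radius σ√(2 ln 20), cluster area π r₉₅² (mm²). Note that
χ²₂(0.95) = 2 ln 20 exactly, so the 95% covariance ellipse of an isotropic
cluster has semi-axis equal to the Thomas r₉₅ — the two branches share one
95% convention.

**Envelopes.** CSR envelopes for L(r) − r use fixed-n uniform simulations
(n_sim = 99 default) with rank-based pointwise bands; with 39 simulations
at the 95% level the band is the simulation min/max. A global variant ranks
simulations by maximum absolute deviation and is the appropriate band for
model checking across the whole r range.

## Morphometric analysis

**Cluster detection.** HDBSCAN authored in the package: core distance =
distance to the K-th nearest neighbor (K = 4), mutual-reachability minimum
spanning tree (Prim's algorithm, O(n²) time and O(n) memory — adequate for
the slide sizes the package targets, tens of thousands of cells), condensed
tree at minimum cluster size minPts = 30, excess-of-mass extraction. The
root is never selectable, so one undifferentiated blob yields no clusters.
Two documented variants relative to reference implementations: points shed
from a sub-minPts branch are recorded as leaving at the λ of that split
(per-point levels inside the shed branch are not tracked), and cluster
extraction is plain excess-of-mass. On well-separated structures the
behavior matches reference implementations; label-identical output on
ambiguous data is not claimed. Membership strengths (leave level rescaled
between the cluster's birth and maximum level) are returned per member.

Density-based clustering *will* fragment dense uniform backgrounds into
spurious small clusters — this is inherent to the algorithm family, not an
artifact; on uniform noise the package's output profile matches
scikit-learn's implementation. Downstream analyses should rely on the
phenotype rules and size filters rather than raw cluster counts on
near-uniform slides.

**Membership trimming for shapes.** A detected cluster's standard
membership includes points that joined its branch barely above the birth
level — typically sparse background cells some distance outside the dense
body. Because the alpha-shape must contain *all* supplied points, a single
such straggler can force the shape to grow a long tendril and corrupt every
descriptor. Before morphometrics the pipeline therefore drops members with
membership strength below `prob_min = 0.05` and members whose core distance
exceeds `core_trim = 3` times the cluster's median core distance. The two
populations are far apart (genuine boundary members sit within about twice
the median; background stragglers at tens of times it), so the result is
insensitive to the exact thresholds. `detect_clusters()` itself always
reports the full standard membership.

**Alpha-shapes.** The Delaunay alpha-complex: triangles with circumradius
≤ α, boundary = edges on exactly one kept triangle. Starting at
α = 10 µm, α is multiplied by 1.2 until the complex is one single connected
region that contains every point and has no interior holes (Euler
characteristic V − E + F = 1), then refined by bisection between the last
failing and first passing value (relative tolerance 10⁻³). Termination is
guaranteed: at the maximum circumradius the complex is the full
triangulation of the convex hull. The no-holes requirement is part of the
package's definition of "one single connected region": merely-connected
complexes at small α are riddled with interior holes whose boundaries
inflate the perimeter and make circularity meaningless as a shape
descriptor. Degenerate clusters (< 3 points, collinear, duplicated points)
are excluded from morphometrics with a logged reason but retained in
counts.

**Descriptors.** Convexity A_α/A_conv, circularity 4πA_α/P_α² (clipped to
1 with a warning if numerical error pushes it above), covariance-ellipse
eccentricity √(1 − λ₂/λ₁) with semi-axes √(λᵢ χ²₂(0.95)). Collinear
clusters get e = 1 and zero ellipse area, flagged degenerate. All
descriptors are invariant to rigid motions; the dimensionless ones also to
scaling (property-tested).

**Phenotypes.** Circular: e < 0.8 AND f_conv > 0.8 AND f_circ > 0.5.
Elongated/irregular: e > 0.9 OR f_conv < 0.3 OR f_circ < 0.3. Thresholds
are configurable; the defaults make the classes disjoint and leave a
middle ground that satisfies neither.

## Heterogeneity

QCoD = (Q3 − Q1)/(Q3 + Q1) with type-7 (linear interpolation) quartiles.
The convention is switchable and logged because QCoD at small n is
sensitive to it; with type-7 quartiles the QCoD of two values {m, 3m} is
0.25, not 0.5 as conventions using the data extremes would give.
Intra-tumoral tables use only windows with converged fits (density is also
reported over all windows, as `density_all_mm2`) and only non-degenerate
clusters. Inter-tumoral dispersion applies QCoD to per-patient medians —
medians, not means, because window and cluster metrics are heavy-tailed.

## Tissue context and outcomes

The invasive front is the band within 250 µm of each side of the
tumor/normal shared boundary: tumor outline offset outward and inward by
the half-width (round joins), the annulus kept where it lies within the
half-width of normal tissue, clipped to annotated tissue. "250 micron width
on both sides" is read as half-width 250 µm per side (500 µm total);
configurable. Cell classes are mutually exclusive with band precedence:
peritumoral (in band), else intratumoral, else stromal. Cluster
association: any peritumoral member → invasive front; else any
intratumoral member → tumor; else normal. The ROI fallback is invasive
front → tumor → normal, so every annotated slide has exactly one ROI.
Per-region average density divides mutually exclusive cell counts by the
matching mutually exclusive region areas (band, tumor minus band, normal
minus band).

Responders: MSI patients with CR/PR; MSS patients additionally with SD
(stable disease in a mismatch-repair-proficient tumor is a favorable
outcome; in a deficient one it predicts relapse). Group comparison is a
two-sided Wilcoxon rank-sum (sidedness is a package choice; exact when
combined n ≤ 20 without ties, otherwise normal approximation with midranks
and continuity correction — a cohort of ~28 sits at the approximation
scale). The RECIST trend test is Jonckheere–Terpstra (PD < SD < PR < CR),
with the p-value by complete enumeration of label assignments when their
number is ≤ 20000 and by seeded permutation (default 10000) otherwise —
group sizes here are far too small for the normal approximation.

Detection evaluation matches detected to reference cells by
mutually-greedy nearest-neighbor pairing within 10 µm (about one lymphocyte
diameter; the matching rule and radius are package choices). Greedy
matching is deterministic and O(n log n); it equals the optimal assignment
whenever spacing exceeds twice the radius (property-tested against brute
force). Both evaluation-region samplers are provided — Latin hypercube
(default, 20 regions per slide) and a systematic grid — behind one switch.

## The synthetic-data generator

`slide_scenario()` defaults define the study conditions: a 4 × 4 mm slide
with a centered 2 × 2 mm tumor; Thomas(κ = 40 mm⁻², μ = 15, σ = 25 µm)
CD8+ cells in the tumor (≈600 cells/mm², mid-range for an infiltrated
tumor) over a 50 mm⁻² uniform normal background; no archetypes and no
detection noise unless requested. Parent simulation uses a 4σ edge guard.
Follicles are uniform disks (150 µm radius, 400 cells — a dense lymphoid
aggregate); elongated infiltrates are uniform rotated rectangles
(800 × 100 µm, 300 cells). Detection noise is independent thinning at the
miss rate plus uniform false detections at a per-area rate; at miss 0.25
and a false fraction of 0.12 it reproduces the recall/precision operating
point of a commercial cell detector on CD8 IHC.

What the generator does *not* emulate — and hence what passing tests do not
establish about clinical slides: density-dependent detection failure
(real false negatives concentrate in very dense regions), irregular tumor
geometry, tissue folds and staining artifacts, inhomogeneous background
intensity, and cluster shapes beyond disks/strips. Synthetic validation
shows the estimators recover truth under the stated model; it cannot show
the model is right for any particular slide.

## Problem sizes

The test suite and acceptance script run at deliberately moderate sizes:
200 windows for parameter recovery, 1000 windows for test calibration,
99-simulation envelopes, slides of roughly 2000–6500 cells, cohorts of 3–4
virtual patients. These sizes give the assertions comfortable statistical
margins while keeping a full run in minutes on one core; all of them scale
linearly in the obvious parameters if larger studies are needed.

## Known limitations

* Rectangular observation windows only for K and the CSR test; polygonal
  tissue masks enter through region assignment, not through edge
  correction.
* The Thomas fit assumes local homogeneity within a window; gradients
  across a window bias κ upward.
* HDBSCAN's O(n²) MST is the complexity bottleneck above ~10⁵ cells per
  slide.
* QCoD on fewer than ~8 values is convention-sensitive; inter-tumoral
  dispersion on small cohorts should be read qualitatively.
* No multiple-testing correction is applied to the outcome tests; raw
  p-values are reported.
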