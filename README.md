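# tilscape

Quantifying the spatial architecture of tumor-infiltrating CD8+ T cells
from whole-slide pathology data.

## The problem

Immunohistochemistry of a tumor section, after cell detection, reduces to a
*spatial point pattern*: thousands to hundreds of thousands of (x, y) cell
positions inside annotated tumor and normal tissue. The clinical questions —
does this patient's immune infiltrate form dense clusters? where do those
clusters sit relative to the invasive front? does any of this predict
response to PD-1 blockade? — are questions about the *statistics of that
point pattern*, not about individual cells. `tilscape` implements the full
workflow for users working with digital pathology exports (cell coordinate
tables plus region annotations): spatial statisticians, computational
pathologists, and systems-biology modelers who need interpretable
tissue-scale parameters for model calibration.

## What it computes

Two independent branches run on the same coordinates:

**Moving-window point-process branch.** The slide is scanned with 0.5 mm
windows in 0.25 mm steps. Each window is tested for complete spatial
randomness (one-tailed Clark–Evans test, Donnelly edge correction,
H_A: clustered). Aggregated windows are fitted with a Thomas cluster
process by minimum contrast against Ripley's K (isotropic edge correction):

    K(r) = πr² + (1/κ)(1 − exp(−r²/(4σ²)))

giving the local cluster density κ, cells per cluster μ = λ/κ, and cluster
dispersion σ. Because offspring distances from the cluster center are
Rayleigh(σ), the mean cell–center distance is σ√(π/2) and the radius
holding 95% of a cluster's cells is σ√(2 ln 20).

**Morphometric branch.** HDBSCAN (minPts = 30, K = 4) detects cell clusters
directly. Each cluster's outline is an alpha-shape, escalated from α = 10 µm
until it is one simply connected region containing all member cells; from it
come convexity f_conv = A_α/A_conv, circularity f_circ = 4πA_α/P_α², and
from the 95% covariance ellipse the eccentricity e = √(1 − λ₂/λ₁). Clusters
are phenotyped as *circular* (e < 0.8 and f_conv > 0.8 and f_circ > 0.5,
lymphoid-follicle-like) or *elongated/irregular* (e > 0.9 or f_conv < 0.3
or f_circ < 0.3, invasive-front-like).

**Heterogeneity and outcome.** Every metric's spread within a slide
(intra-tumoral) and across per-patient medians (inter-tumoral) is the
quartile coefficient of dispersion, QCoD = (Q3 − Q1)/(Q3 + Q1). Cells and
clusters are assigned to tumor, normal, or the ±250 µm invasive-front band
around the tumor/normal boundary; region-restricted cluster metrics are
compared between responders and non-responders (Wilcoxon rank-sum) and
across RECIST categories (Jonckheere–Terpstra trend test). A synthetic
virtual-slide generator (region-conditional Thomas/Poisson processes,
planted follicle and strip archetypes, configurable detection noise)
provides ground truth for every stage.

## Worked example

A virtual slide with the default scenario — a 2 × 2 mm tumor in a 4 × 4 mm
slide, CD8+ cells following a Thomas process (κ = 40 mm⁻², μ = 15,
σ = 25 µm) in the tumor over a sparse normal background:

```r
library(tilscape)

sim <- simulate_slide(slide_scenario(), seed = 42)
rs  <- run_slide(sim$true, sim$regions, patient_id = "virtual-01")

agg <- subset(rs$windows, verdict == "aggregated" & converged)
median(agg$mu)      # cells per cluster
median(agg$sigma)   # cluster dispersion (um)
rs$roi              # region of interest for outcome metrics
head(rs$summary)    # intra-tumoral heterogeneity table
```

Output from this exact run:

```
cells: 3214
windows: 196  aggregated+converged: 83
median cells/cluster (mu):   15.2
median sigma (um):           27.4
median mean_dist (um):       34.4
ROI: invasive_front
 branch          metric   n    median  qcod
 window     density_mm2  83  528.0     0.366
 window              mu  83   15.2     0.250
 window       mean_dist  83   34.4     0.097
 window    cluster_area  83    0.0142  0.193
 window density_all_mm2 196   64.0     0.814
```

The window branch recovers the generator's truth: μ̂ = 15.2 against the
planted 15 cells per cluster, σ̂ = 27.4 µm against 25, and the mean
cell-to-center distance 34.4 µm against the theoretical 25·√(π/2) = 31.3 µm.
The density QCoD over *all* windows (0.81) is much larger than over
tumor-core windows alone (0.37) — the slide is heterogeneous chiefly because
tumor and normal tissue differ, which is exactly what the intra-tumoral
dispersion indices are built to expose.

A thin command-line wrapper ships in `inst/cli/`:

```sh
Rscript inst/cli/tilscape simulate --seed 17 --out slide/ --follicles 3
Rscript inst/cli/tilscape run-all --cells slide/cells_true.csv \
        --regions slide/regions.geojson --out results/
```

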