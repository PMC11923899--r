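---
title: "Detecting and characterising excitatory/inhibitory neuron clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterising excitatory/inhibitory neuron clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical machinery: the
models and nulls, the tunable parameters and why their defaults are what
they are, what the synthetic-scene generator does and does not emulate,
the numerical choices, and the known limitations. The statements here are
backed by the package's test suite and `scripts/acceptance.R`; no result
is claimed that those do not themselves compute.

## 1. Data model

A **cell table** holds one row per neuron: coordinates in µm in a
per-section 2-D frame, section id, cortical layer (1–6), brain-region
label, class (`excitatory` / `inhibitory`) and a subclass label drawn
from a per-class vocabulary (defaults: excitatory L2, L2.3, L2.3.4, L3.4,
L3.4.5; inhibitory PV_CHC, RELN, OTHER_IN; unknown labels are accepted
and added). Sections are separate chips: no geometric quantity is ever
computed across sections. A **region annotation** maps regions to a lobe,
to functional systems (DMN, visual, somatosensory) and to an optional
cortical hierarchy level; unannotated regions resolve to "no system, no
level" and act as background in enrichment tests.

## 2. Window scan and permutation null

Within each stratum — `(section, layer)` by default, or `layer` with
pooled sections when requested — a square window of side $W$ slides on a
grid of step $s$. Membership is half-open, $[x_0, x_0+W) \times
[y_0, y_0+W)$, and the grid is anchored at step-multiples of the
stratum's bounding box and extended one window beyond the hull, so that
when $W$ is a multiple of $s$ every cell lies in exactly $(W/s)^2$
windows (a property the tests verify by brute force). Empty windows carry
no test; `min_window_n` (default 1) can raise the occupancy floor.

The null fixes all positions and permutes the class labels among the
stratum's cells — equivalent to shuffling each class's coordinates — and
one shuffle serves all windows jointly. With $n_{\mathrm{perm}}$ shuffles
the one-sided enrichment p-value for class $c$ uses the add-one estimator
$p = (1 + \#\{\text{count} \ge \text{observed}\}) / (1 + n_{\mathrm{perm}})$,
so $p \in (0, 1]$ always. For any fixed window the permuted count is
exactly hypergeometric; `exact_pvalue()` is that closed form and the test
suite checks $|p_{\mathrm{perm}} - p_{\mathrm{exact}}|$ against the
$3\sqrt{p(1-p)/n_{\mathrm{perm}}}$ Monte-Carlo band (plus the
$2/n_{\mathrm{perm}}$ granularity of the estimator) across random
configurations. A stratum containing a single class is degenerate and
reports $p = 1$ everywhere; at $\alpha < 0.5$ no window can be flagged
for both classes, since enrichment of one class is depletion of the
other under the fixed-total null.

Windows with $p < \alpha$ (strict inequality; default $\alpha = 0.05$)
for the same class are merged into **neuron clusters** when they share at
least one cell, taking connected components; a geometric-overlap
connectivity mode exists behind a flag for sensitivity analysis. Cluster
members are all cells of the component's windows, both classes included.
Cluster ids are deterministic (class prefix, stratum, smallest member
cell id), merging is idempotent and independent of window order, and a
fixed seed reproduces the output byte for byte (child seeds are derived
per sorted stratum key, so stratum iteration order is immaterial).

Parameters and defaults: window presets `macaque` (1000 µm / 100 µm),
`macaque_check` (400/100) and `mouse` (400/20); $n_{\mathrm{perm}} =
10\,000$; $\alpha = 0.05$ on raw p-values. No multiple-testing correction
is applied at the window stage and no minimum cluster size is imposed —
both deliberate fidelity choices to the method the package implements;
the FDR adjustment appears only in the composition-group enrichment
stage. The consequence — about 5 % of testable windows flagged per class
on pure noise — is quantified below.

## 3. Cluster metrics

* **E–I ratio** $n_{\mathrm{exc}}/n_{\mathrm{inh}}$. Pure-excitatory
  clusters have an undefined ratio, reported `NA` and excluded from all
  correlations (not $\infty$), since such clusters are analysed as their
  own category; pure-inhibitory clusters report 0.
* **Mean nearest-neighbour distance**: each member's distance to its
  nearest other member, averaged, computed within sections. The
  surrounding text of the method's description mentions both
  nearest-neighbour averaging and all-pairs averaging; nearest-neighbour
  is implemented as the default (an all-pairs mean is a one-line change
  on the same distance machinery) because it is the quantity the KD-tree
  search it describes computes. Distances use blocked brute force — exact,
  and fast enough at package scale; tests pin it to an $O(n^2)$ oracle.
* **Interregional flag**: at least two distinct member regions.
  Per-layer enrichment of interregional clusters is the odds ratio of the
  2×2 table "this layer vs all other layers × interregional or not",
  with the Woolf normal CI on $\log \mathrm{OR}$ and Haldane–Anscombe
  0.5 correction (flagged) for zero cells. The exact contrast is a
  documented package choice, as the figure it mirrors does not state one.
* **Coverage**: fraction of all neurons belonging to at least one
  cluster of either type, overall and per layer, with the SEM of
  per-section fractions.
* **Class balance**: 1-df goodness-of-fit comparing the observed split of
  cluster-member cells between excitatory and inhibitory clusters to the
  split expected from the overall class fractions.
* **Partnerships**: every excitatory–inhibitory cluster pair sharing a
  cell, with shared count, per-cluster overlap fractions, and the
  standard Jaccard coefficient $|A \cap B| / |A \cup B|$ (the method
  description's "total number of cells" is read as the union — the
  conventional Jaccard denominator; the alternative $|A|+|B|$ reading is
  noted and rejected as it would not be a Jaccard coefficient).
* **Nearest opposite cluster**: minimum over cross-cluster cell pairs of
  Euclidean distance within the stratum, 0 for overlapping clusters,
  ties to the smaller cluster id.
* **Coupling statistics**: Pearson correlations of partner-pair E–I
  ratios, adjacent-pair E–I ratios, and $\log_{10}$ size versus partner
  count and partnership propensity per type ($\log_{10}$ because cluster
  sizes span orders of magnitude). Correlations need at least 3 finite
  observations, otherwise `NA`.

The **region assigned** to a cluster is the plurality of member-cell
regions, ties broken lexicographically — needed by the composition stage
and chosen by this package, as the source method leaves it unspecified.

## 4. Subclass co-occurrence

Cluster memberships stay fixed while subclass labels shuffle among all
neurons of the stratum (both classes pooled). Per cluster and subclass
the one-sided enrichment p-value again uses the add-one estimator;
enrichment means $p < 0.05$, raw — the meta-permutation below is the
guard against inflated co-occurrence claims, so no per-cluster FDR is
applied. Clusters with two or more enriched subclasses are classified
`EE` / `II` / `EI` by the classes of those subclasses.

The **meta-permutation** asks whether the multi-enriched fraction
exceeds chance: each replicate shuffles the labels globally, reruns the
enrichment test with fresh inner shuffles, and records the null fraction;
the empirical p is add-one over replicates. Defaults follow the 500-
replicate protocol; the inner loop inside replicates may use
$n_{\mathrm{perm}} = 1000$ rather than $10\,000$ — the calibration
properties are identical and the cost drops tenfold.

Implementation note: a label permutation restricted to pairwise-disjoint
cluster memberships induces exactly a nested multivariate hypergeometric
distribution on the per-cluster subclass counts. The sampler uses that
decomposition (vectorised `rhyper`) for disjoint clusters and falls back
to explicit label permutation when memberships overlap (as E and I
clusters may); tests verify both paths against hypergeometric moments and
that per-cluster totals are conserved draw by draw.

## 5. Composition groups and functional enrichment

Per cluster, the proportion vector over the subclass vocabulary and its
binary presence vector. Adjacent-cluster similarity pairs each cluster
with its nearest same-type cluster and compares Pearson/Spearman
similarities of proportion vectors against an equal number of seeded
random non-nearest pairs (Wilcoxon rank-sum, one-sided). Per layer and
type, presence vectors are grouped by agglomerative clustering — Jaccard
distance with average linkage, both configurable: natural for
presence/absence data, where double absences should not count as
agreement — cut at $k$ groups ($k = 5$ by default, matching the granularity
of groups `h1..h5` the analysis is organised around; labels are assigned
by decreasing group size, deterministically). Group–system enrichment is
a one-sided Fisher test on "in group × assigned region in system",
Benjamini–Hochberg-adjusted across all (group, system) tests of the
call, enriched at adjusted $p < 0.05$; the reported OR is the sample OR
with Haldane correction where needed. Hierarchy correlations relate
region hierarchy levels to $\log_{10}$ cluster size and to E–I ratio per
cluster type, on per-cluster observations (a region-mean mode would be a
trivial variant), pooling layers.

## 6. The synthetic generator

`generate_background()` draws a homogeneous Poisson scene:
$N \sim \mathrm{Poisson}(\lambda \cdot \mathrm{area})$, uniform
positions, i.i.d. Bernoulli($p_I$) classes, i.i.d. subclasses from
per-class mixtures; optional horizontal layer bands (top band = layer 1)
and vertical region strips. Defaults: $p_I = 0.15$, matching the roughly
15 % inhibitory share of cortical neurons; $\lambda = 500$ cells/mm² —
a placeholder chosen to make window occupancies comfortably testable at
desk scale, since per-layer areal densities for the motivating datasets
are not published; uniform subclass mixtures within class.

`plant_clusters()` enriches discs by **resampling labels at fixed
positions** (Bernoulli at the disc's fraction), isolating composition
effects from density effects — the same separation the label-shuffle null
makes; a density multiplier adds Poisson extra points separately.
Overlapping discs of opposite enriched class are rejected to keep ground
truth unambiguous. `generate_partner_scene()` builds one E-enriched and
one I-enriched disc with a controlled intersection and returns the exact
member sets. One seeded RNG stream per call, with a documented draw
order and global RNG state restored, so fixtures are stable; child seeds
derive from the parent by a fixed affine map kept below $2^{31}$.

What the generator does **not** emulate: cortical curvature, laminar
thickness and density gradients, anisotropic or clustered backgrounds
beyond the planted discs, realistic subclass frequencies, section-to-
section variability, or any transcript-level noise. Passing tests on
these scenes therefore validate the *statistical machinery* —
calibration, recovery, estimator consistency, determinism — not the
biological conclusions one would draw from real cortex, whose densities
and effect sizes are orders of magnitude away from desk scale.

## 7. Numerical choices

Half-open window membership avoids double counting at shared edges;
grid coordinates are stabilised by rounding to 10⁻⁹ before floors, so µm
coordinates at exact step multiples bin deterministically. The add-one
p-value estimator keeps p strictly positive and significance strictly
`p < alpha`. Permutations are drawn as random class-position subsets and
counted through sparse incidence × indicator matrix products, chunked to
bound memory; the observed excitatory exceedance count reuses the
inhibitory one through the fixed window total. Degenerate inputs:
empty tables yield empty cluster sets; single-class strata are flagged;
clusters of size < 2 have undefined nearest-neighbour distance; expected
counts of zero abort the goodness-of-fit test; Jaccard distances between
all-absent presence vectors are set to 1.

## 8. Validation experiments and their problem sizes

The acceptance suite runs, at desk scale chosen by this package:
estimator–oracle agreement on 50 random strata ($N \le 200$,
$n_{\mathrm{perm}} = 10^4$); type-I calibration on ~20 000-cell CSR
scenes (5 seeds, flagged fraction ≤ 0.06 at $\alpha = 0.05$); recovery of
ten planted inhibitory discs (radius 500 µm, in-disc fraction 0.5,
$\lambda = 1000$/mm², 400/100 scan) with ≥ 9/10 discs hit and median
cell-level Jaccard ≥ 0.5; the nearest-neighbour closed form
$\mathbb{E}[d] = 1/(2\sqrt{\lambda})$ within 3 % at $n \approx 2\times10^4$;
co-occurrence calibration over 100 seeds (conservative, never
anti-conservative) and power on planted two-subclass clusters; byte-level
determinism; and sign recovery of planted qualitative contrasts.

Two experiment-design notes. The co-occurrence null p-value is *discrete*
at small cluster counts, hence conservative rather than uniform: the
calibration asserts validity (the fraction of seeds below a threshold
never exceeds it beyond Monte-Carlo error), not exact uniformity. And the
qualitative-contrast scene (many small inhibitory discs versus few large
excitatory ones) balances the planted inhibitory label surplus against
the excitatory discs' deficit so the pooled class fraction equals the
background's, and thresholds windows at $\alpha = 0.001$ for that
experiment only: its assertion is about cluster *counts*, and the raw
0.05 threshold tolerates ~5 % false-positive windows, which at several
thousand windows would add comparable numbers of small spurious clusters
to both classes and drown a dozen planted ones. The headline analyses
keep raw $p < 0.05$.

## 9. Known limitations

* At raw $\alpha = 0.05$ the scanner yields spurious small clusters on
  pure noise (~0.5 clusters/mm² per class at the tested densities); with
  genuinely structured data the signal dominates, but small-scene cluster
  counts should be interpreted with that floor in mind.
* Cluster extents are unions of significant windows and overshoot a
  planted disc by up to roughly one window at its rim; cell-level Jaccard
  against ground truth plateaus near 0.55–0.65 by geometry, not by
  detection failure.
* Permutation strata follow the section/layer annotation; the package
  never tests or corrects for within-stratum density gradients, which a
  homogeneous-label null attributes to enrichment.
* The nearest-neighbour mean is edge-biased upward slightly on bounded
  scenes (no correction is applied); at the validation scale the bias is
  within the tested 3 %.
* `hierarchical_groups()` requires a user-chosen $k$; the default 5 is a
  convention, and group labels are only comparable within one layer and
  type.
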