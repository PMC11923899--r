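# cortexclust

Spatial organisation of excitatory and inhibitory neurons in cortical
sections: sliding-window permutation enrichment, neuron-cluster detection,
and downstream characterisation.

## What it does, and for whom

Spatial single-cell assays of cortex yield, per coronal section, the 2-D
position of every neuron together with its cortical layer, brain-region
label, class (excitatory / inhibitory) and a finer subclass label. A
recurring question is whether these neurons are organised into local
*clusters* — patches where one class is over-represented relative to
chance — and what those clusters look like: how large they are, how their
excitation–inhibition balance varies, whether excitatory and inhibitory
clusters interlock, which cell subtypes co-occur inside them, and how all
of this maps onto annotated functional systems (default mode network,
visual, somatosensory) and the cortical hierarchy.

`cortexclust` implements that analysis as a tested R pipeline for anyone
working with layer-stratified neuron point patterns (macaque- or
mouse-style window presets included), plus a synthetic-scene generator so
every stage can be validated against planted ground truth.

## The method

Within each stratum (section × layer), a square window of side *W* slides
on a grid of step *s* (presets: macaque *W* = 1000 µm, *s* = 100 µm;
finer check 400/100; mouse 400/20). For each window the null distribution
of the in-window count of class *c* is obtained by permuting class labels
across the stratum's fixed cell positions (equivalently, shuffling each
class's coordinates); with *n* permutations the one-sided enrichment
p-value uses the add-one estimator

    p = (1 + #{ permuted count >= observed count }) / (1 + n).

For a single window this null is exactly hypergeometric —
`exact_pvalue()` exposes the closed form `P[X >= k]`, with
`X ~ Hypergeom(N, K, n_w)` — which the Monte-Carlo estimate is tested
against. Windows with `p < 0.05` that share at least one cell are merged
(connected components) into **neuron clusters**; a cluster's members are
all cells in its windows, of both classes.

Clusters are then characterised: E–I ratio `n_exc / n_inh` (undefined for
pure-excitatory clusters), mean nearest-neighbour distance, interregional
span, per-layer enrichment odds ratios, excitatory–inhibitory
**partnerships** (cluster pairs sharing cells, with Jaccard overlap),
subclass **co-occurrence** under a second label-permutation null with a
meta-permutation significance test, and **composition groups** from
hierarchical clustering of binary subclass-presence vectors (Jaccard
distance, average linkage) with one-sided Fisher + Benjamini–Hochberg
functional-system enrichment and hierarchy-level correlations.

## Worked example

Simulate a 3 × 3 mm section at 600 cells/mm² (15 % inhibitory), plant one
inhibitory-enriched disc and one excitatory-enriched disc, and scan it:

```r
library(cortexclust)

cfg <- scene_config(3000, 3000, lambda = 600, p_inh = 0.15, seed = 42)
bg <- generate_background(cfg)
scene <- plant_clusters(bg, list(
  planted_cluster(c(1000, 1000), 450, class = "inhibitory", fraction = 0.6),
  planted_cluster(c(2200, 2200), 450, class = "excitatory", fraction = 0.99)), cfg)

clusters <- detect_clusters(scene$cells, preset("macaque_check", n_perm = 1000, seed = 7))
clusters
#> <neuron_clusters> 5 clusters (4 excitatory, 1 inhibitory), 3715 member cells

cluster_summaries(clusters, scene$cells)[, c("cluster_id", "type", "size",
                                             "n_exc", "n_inh", "ei_ratio", "mean_nn_dist")]
#>         cluster_id       type size n_exc n_inh  ei_ratio mean_nn_dist
#> 1 E_S1_L1_c0000003 excitatory 2029  1850   179 10.335196     20.61870
#> 2 E_S1_L1_c0000006 excitatory  225   202    23  8.782609     19.49383
#> 3 E_S1_L1_c0000016 excitatory  119   107    12  8.916667     20.50040
#> 4 E_S1_L1_c0000042 excitatory   84    80     4 20.000000     21.82483
#> 5 I_S1_L1_c0000009 inhibitory 1301   919   382  2.405759     20.48100

find_partners(clusters)$pairs[, c("exc_cluster_id", "inh_cluster_id", "shared", "jaccard")]
#>     exc_cluster_id   inh_cluster_id shared     jaccard
#> 1 E_S1_L1_c0000003 I_S1_L1_c0000009     22 0.006650544
#> 2 E_S1_L1_c0000006 I_S1_L1_c0000009     21 0.013953488

coverage_stats(clusters, scene$cells)$overall
#> [1] 0.675
```

Reading this: the planted excitatory disc is detected (the 2029-cell
cluster around it), the planted inhibitory disc becomes the 1301-cell
inhibitory cluster with a much lower E–I ratio (2.4 vs ≥ 8.8), the two
cluster types share boundary cells (partnerships with small Jaccard
overlap), and 67.5 % of all neurons in the scene fall inside some
cluster. The smaller excitatory clusters are border/noise components that
a raw per-window `p < 0.05` threshold tolerates by construction.

A whole run — scan, properties, partnerships, co-occurrence, composition
groups, TSV/JSON exports and a reproducibility manifest — is one call:

```r
run_pipeline(list(out = "run1",
                  simulate = list(width = 3000, height = 3000, lambda = 600,
                                  planted = list(list(center = c(1000, 1000), radius = 450,
                                                      class = "inhibitory", fraction = 0.6))),
                  preset = "macaque_check", n_perm = 1000), seed = 42)
```

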