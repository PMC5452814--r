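---
title: "Host versus environment microbiome structure and the habitat-filtering workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host versus environment microbiome structure and the habitat-filtering workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habfilt)
```

# What this package computes

`habfilt` implements an analysis chain for amplicon surveys that sample
host-associated microbial communities (for example seagrass leaf and root
surfaces) together with their candidate environmental colonization sources
(seawater and sediment), replicated across seagrass beds nested in sites.
The chain asks four questions in order:

1. **Structure** — how do host communities differ from environmental ones,
   taxonomically and phylogenetically? (rarefaction, Shannon, Faith's PD,
   Canberra and normalized unweighted UniFrac distances, PCoA, ANOSIM with
   restricted permutations, dispersion tests, a bed-level centroid test)
2. **Origin** — what fraction of each host community came from each
   environment? (a Bayesian source-tracking classifier with an
   unknown-source component, fitted by collapsed Gibbs sampling)
3. **Selection** — which OTUs does the host enrich or deplete relative to
   its primary source? (TMM normalization, per-OTU negative-binomial GLMs
   with likelihood-ratio tests, BH correction)
4. **Mechanism** — do enriched taxa that are predicted to compete for the
   same exogenous resources cooccur? (metabolic-network seed sets, the
   competitive dissimilarity matrix C, Mantel and partial Mantel tests)

A positive cooccurrence–C association is the signature of **habitat
filtering**: taxa that need the same resources assemble where those
resources are supplied. The package ships a synthetic-data generator with
recorded ground truth, so the whole chain is testable without sequencing
data.

# Models and procedures

## Diversity and ordination

Counts are rarefied **without replacement** to a fixed depth (default
2,500); samples below the depth are dropped and listed, mirroring the usual
retention rule. Shannon diversity uses **base-2 logs** (bits); a `base`
argument switches to nats. Faith's PD sums branch lengths over the union of
root-to-tip paths of observed taxa and **includes the root path** by
default (`include_root = FALSE` restricts to the MRCA), matching the
convention of the classic QIIME-era tooling this pipeline interoperates
with.

Canberra distance skips double-zero coordinates entirely (they appear in
neither the sum nor any normalizing constant); two all-zero vectors are at
distance 0. Dialects differ here, so the choice is stated and tested.
Normalized unweighted UniFrac is presence/absence only: unique branch
length over the union branch length, 1 exactly when the two communities
share no branch.

PCoA is classical scaling: eigendecomposition of the double-centered
`-D²/2`. Coordinates are returned for positive-eigenvalue axes scaled by
`sqrt(λ)`; negative eigenvalues are **reported, not corrected** (no
Lingoes/Cailliez), because corrections would silently change the inputs of
the dispersion analysis. The axes belonging to negative eigenvalues are
kept separately for Anderson's real/imaginary centroid-distance correction.

## Permutation tests

ANOSIM uses Clarke's statistic `R = (r̄_between − r̄_within) / (M/2)` with
`M = n(n−1)/2` and average ranks on ties. Group labels are permuted **only
within strata** (sites), so spatial pseudoreplication cannot manufacture
significance; strata containing a single group are held fixed with a
warning, and a design where no stratum mixes groups is an error. With
`exact = TRUE` every within-stratum arrangement is enumerated and the
p-value is the exact tail fraction (identity included), which the test
suite checks against an independent enumeration oracle.

The dispersion test (`permdisp`) embeds samples by PCoA, computes each
sample's distance to its group **spatial centroid** with the squared
real-part minus squared imaginary-part correction (clamped at zero), and
permutes the distances' group labels under a one-way F statistic. This is
the centroid variant of the permdisp2 procedure; it agrees with
`vegan::betadisper(type = "centroid")` to numerical precision in the test
suite, which uses vegan only as an oracle.

The centroid proximity test asks whether host communities sit closer to
their **own bed's** environmental centroid than to other beds'. The
statistic is the mean over beds of the host–environment centroid distance
in PCoA space; the null re-pairs host beds with permuted environment beds.
The permutation scheme was genuinely open (host beds, environment beds, or
both could be shuffled); we permute the environment-bed assignment because
the bed centroid is the unit of comparison, and we **exclude the identity
pairing** from the null draws so that the null is genuinely mismatched — a
perfectly matched layout then attains the minimal p-value
`1/(n_perm + 1)` exactly. The test is one-sided ("closer than mismatched").

## Source tracking

Each host (sink) community is modelled as a mixture of the known
environmental sources plus an **unknown** source. Known sources enter as
fixed taxon-count profiles smoothed by a per-taxon pseudocount `alpha1`;
the unknown source has no training data — its profile accumulates from the
sink sequences currently assigned to it, smoothed by `alpha2`. A collapsed
Gibbs sampler reassigns each sink sequence `i` (taxon `x_i`) with

    P(z_i = k | ·) ∝ φ_k(x_i) · (n_k + β)

where `φ_k` is source `k`'s smoothed taxon distribution and `n_k` the
sink's current assignment totals excluding `i`. Reported proportions are
posterior means over retained draws and restarts; the sampler is written in
C++ on R's RNG, so a seed makes it bit-reproducible. Defaults
(`alpha1 = 0.001`, `alpha2 = 0.1`, `beta = 10`, 10 restarts, 100 burn-in
sweeps, 25 draws spaced 10 apart) follow the published defaults of the
classifier this stage reimplements; the smoothing is read as a plain
per-taxon pseudocount. Sinks are processed independently, and by default
the classifier is trained **per site** on that site's environmental
samples (global pooling is the fallback), since coastlines differ in
composition and the pipeline's unit of attribution is the local
environment.

The unknown component deserves emphasis: it absorbs any sink mass the
known profiles cannot explain — genuinely novel taxa, but also taxa whose
local abundance exceeds what finite training data support. Training
sources that are shallow or unrepresentative of the sink's locality
therefore inflate "unknown"; this is visible, by design, rather than
force-fitted onto the named sources.

## Differential abundance

The host compartment is compared only against its **primary source** (the
named source with the largest median attributed proportion; an exact tie is
an error demanding an explicit choice). On the combined unrarefied table,
OTUs detected fewer than `min_total = 5` times are removed — read as total
count across the compared samples (the incidence reading is available via
`filter_by = "incidence"`). TMM factors (trim 0.30 on M, 0.05 on A,
75th-percentile reference rule, geometric mean exactly 1) and the per-OTU
negative-binomial GLMs with likelihood-ratio tests are delegated to edgeR;
dispersions are estimated by adjusted profile likelihood and shrunk toward
a single common dispersion with `prior_df = 10` and **no abundance trend**
— the simplest scheme that stabilizes small-n estimates; this diverges
deliberately from edgeR's trended default and is stated here for that
reason. BH adjustment uses `m =` number of converged tests; non-converged
OTUs are reported but never called. Calls at `alpha = 0.01`: enriched iff
`p_adj < α` and log2FC > 0, depleted iff `p_adj < α` and log2FC < 0.

One property worth knowing: TMM is *near*-invariant, not exactly
invariant, to rescaling a single library, because the asymptotic precision
weights depend on library size; the test suite asserts invariance at 1e-2
relative tolerance.

## Reverse ecology

Reaction records expand into a directed compound graph (every substrate →
every product; reversible reactions contribute both directions; set
semantics). The **seed set** is the union of the source components
(in-degree-0 nodes) of the graph's strongly-connected-component
condensation: the minimal set of compounds the organism must acquire
exogenously to synthesize everything else. Every compound in a source
component of size `s` has confidence `1/s` — any one member suffices to
reach the rest — so confidences sum to the number of source components.
SCCs come from igraph's linear-time algorithm; correctness is checked
against a brute-force reachability definition on hundreds of random
digraphs.

The competitive dissimilarity matrix C holds pairwise **binary Jaccard**
distances between seed sets (low `c_ij` = high predicted resource overlap);
a confidence-weighted generalized Jaccard is available behind a flag but
excluded by default, since the plain Jaccard is what the index names.
Cooccurrence is binary Jaccard on presence/absence profiles across the host
compartment's rarefied samples (a quantitative Ružička variant is behind a
flag). No currency-metabolite exclusion list is applied by default.

Mantel tests correlate the upper triangles (Pearson by default) and permute
the second matrix's labels; tests are **one-sided for positive
association**, because that is the direction habitat filtering predicts.
The partial Mantel statistic is the first-order partial correlation
`r12·3`, recomputed per permutation of `d2`'s labels with `r13` fixed;
`|r13| = 1` or `|r23| = 1` is a degeneracy error, not a number.

# The synthetic study

`make_study()` generates the whole survey the pipeline assumes, with
ground truth recorded:

- two environment profiles (water, sediment) drawn Dirichlet(0.7) over the
  187-taxon "known" block — uneven, but not so heavy-tailed that training
  samples at depth ~2,500 miss a large share of the community;
- 4 sites × 2 beds × 3 samples of each community type at depth 3,000; each
  bed multiplies both source profiles by i.i.d. lognormal factors
  (`sd = 0.3`), shared by the bed's host and environmental samples — this
  gives the centroid test a true positive at realistic strength;
- hosts as mixtures: leaf = 0.85 water / 0.15 sediment, root = 0.3 / 0.7
  (renormalized to 0.9 total), plus a 0.1 unknown component supported on a
  reserved 15% taxon block, which keeps "unknown" identifiable;
- 10 enriched and 10 depleted taxa per compartment at |log2FC| = 3, pinned
  to base abundance 0.002 in both sources: host-responsive taxa are rare in
  the environment, so spiking them does not distort the host community's
  source signature;
- root-enriched taxa split between **two resource pools**; a root sample
  carries a pool's taxa only when it supplies that pool (occupancy 0.55) —
  the habitat-filtering coupling; leaf-enriched taxa occur independently
  (occupancy 0.7), the unstructured contrast;
- a random coalescent tree over all taxa, and per-OTU toy reaction networks
  whose seed sets are exactly the pool compounds (plus one private
  compound each) for root-enriched taxa and random compound subsets for
  leaf-enriched taxa.

Smaller single-purpose generators (`make_source_profiles`,
`make_mixed_sinks`, `spike_differential_taxa`, `make_random_tree`,
`make_toy_network`, `make_bedded_communities`, `make_assembly_scenario`)
expose each statistical structure separately for parameter-recovery tests.

**What the generator does not emulate** — and hence what passing tests do
and do not show about real data: the taxon universe is a few hundred OTUs,
not tens of thousands; there is no sequencing error, chimera formation, or
OTU-picking artifact; library sizes are constant rather than
heavy-tailed; metabolic networks are small constructions with known seed
sets rather than genome-scale reconstructions with gap-filling
uncertainty; and host communities, being mixtures of two sources plus an
unknown block, come out slightly *more* alpha-diverse than either single
environment, whereas real surveys often find sediment the most diverse
habitat. Tests passing here demonstrate algorithmic correctness and
calibration under the stated model, not robustness to those real-data
features.

# Numerical choices and degenerate inputs

- Permutation p-values are always `(1 + #{T* ≥ T}) / (1 + n_perm)` (or the
  exact enumeration fraction with the identity included), so `p ≥
  1/(n_perm+1)` and `p = 0` is impossible.
- Rank ties in ANOSIM get average ranks; statistic comparisons in
  permutation tails use a 1e-12 slack so ties count as exceedances.
- PCoA's positive/negative eigenvalue cutoff is `max|λ| · 1e-9`; distances
  to centroids clamp negative corrected squares at zero.
- An OTU with zero counts everywhere cannot be fitted: it is flagged
  non-converged, gets `NA` p-values, and is excluded from the BH `m`.
- Empty seed-set pairs are at Jaccard distance 0 (two organisms needing
  nothing compete for nothing); an OTU absent from every sample makes
  cooccurrence against another absent OTU the convention 0, with a warning.
- A zero-variance distance triangle makes Mantel's `r` undefined and is an
  error rather than an `NaN`.
- All generators and samplers take explicit seeds and restore the caller's
  RNG state; the pipeline manifest records every seed, so any stage can be
  reproduced in isolation.

# Test problem sizes

The suite exercises the oracle comparisons at sizes chosen to make
enumeration exact and simulations statistically informative: full
permutation enumeration at n = 4–6; 500 random digraphs of up to 40 nodes
against the brute-force seed-set definition; 500 null replicates for
Mantel calibration (99 permutations each); 50 replicates of the 500-OTU,
15+15 differential-abundance design for calibration and sensitivity; 20
sinks at depth 2,500 for source-proportion recovery; and 100 replicates
each of the structured ("root-like") and random ("leaf-like") assembly
scenarios at 30 OTUs × 40 samples. The end-to-end pipeline examples run on
a 4-site study (96 samples, 220 taxa).

# Known limitations

- The source tracker treats sinks independently and offers no
  leave-one-out validation of the sources themselves.
- Dispersion shrinkage is untrended; strongly abundance-dependent
  dispersion would favor edgeR's trended estimator.
- The seed-set formalism ignores reaction stoichiometry, gene expression
  and transport; confidences only encode SCC size.
- BIOM support covers the v1.0 JSON dialect only (dense and sparse); HDF5
  BIOM files must be converted upstream.
- Exact permutation modes enumerate up to roughly 2×10⁵ arrangements;
  larger designs fall back to sampled permutations.
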