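# habfilt

Host versus environment microbiome structure and habitat-filtering
assembly analysis.

## The problem

Amplicon surveys of host-associated microbiomes (the motivating system is
seagrass leaf and root surfaces sampled alongside adjacent seawater and
sediment, replicated across beds nested in sites) pose a chain of
questions: how different are host communities from their surroundings,
where do their members come from, which taxa does the host actively enrich
or deplete, and does *resource competition* explain which enriched taxa
occur together? `habfilt` implements that chain end to end for R users —
ecologists and bioinformaticians analyzing OTU tables with sample
metadata, a phylogeny, and (optionally) per-OTU metabolic networks.

## The methods at its core

- **Diversity and ordination.** Rarefaction without replacement to a fixed
  depth (default 2,500; shallower samples dropped); Shannon diversity
  `H = −Σ pᵢ log₂ pᵢ` (bits) and Faith's PD (total branch length spanned
  by a community, root path included); Canberra
  `d(x,y) = Σ |xₖ−yₖ|/(xₖ+yₖ)` (double zeros skipped) and normalized
  unweighted UniFrac (unique / union branch length); classical PCoA with
  negative eigenvalues reported, not corrected.
- **Permutation inference.** ANOSIM `R = (r̄_B − r̄_W)/(M/2)` with
  permutations restricted to within sites; the permdisp2 dispersion test on
  distances to group spatial centroids (Anderson's negative-eigenvalue
  correction); a Monte-Carlo test of whether hosts lie closer to their own
  bed's environmental centroid than to mismatched beds; exact enumeration
  modes for small designs.
- **Bayesian source tracking.** Each host community is decomposed into
  known environmental sources plus an unknown component by a collapsed
  Gibbs sampler, `P(zᵢ = k) ∝ φ_k(xᵢ)(n_k + β)`, trained per site on
  rarefied source counts (C++ core, seed-reproducible).
- **Source-guided differential abundance.** Host vs its primary source:
  <5-count filter, TMM normalization, per-OTU negative-binomial GLMs with
  likelihood-ratio tests (edgeR backend, dispersion shrunk toward a common
  value), Benjamini–Hochberg calls at adjusted P < 0.01.
- **Reverse ecology.** Directed compound graphs from reaction lists; each
  OTU's **seed set** = the source components of the graph's SCC
  condensation (confidence 1/|component|); the competitive dissimilarity
  matrix `C = [c_ij]` of Jaccard distances between seed sets; one-sided
  Mantel and partial Mantel tests (1,000 permutations, phylogeny
  controlled) of cooccurrence against C. A positive association is the
  habitat-filtering signature.

A synthetic-data generator (`make_study()` and smaller single-purpose
generators) produces study-shaped data with recorded ground truth, so the
entire pipeline is testable without sequencing data.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package functions and writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic study + ground truth
Rscript analysis/02_diversity.R             # rarefy, α/β diversity, PCoA, group tests
Rscript analysis/03_source_tracking.R       # Gibbs source attribution, centroid test
Rscript analysis/04_differential_abundance.R
Rscript analysis/05_reverse_ecology.R       # seed sets, C, Mantel tests
```

Output of a complete run (abridged):

```
anosim_leaf_water_canberra   anosim_r =  1.000  p = 0.000999
anosim_root_sediment_unifrac anosim_r =  0.979  p = 0.000999

Median attributed proportions per host compartment:
     water sediment
leaf 0.611    0.115
root 0.227    0.533
Primary sources: leaf -> water, root -> sediment
leaf vs own-bed water: mean centroid distance 81.354, p = 0.000999

leaf vs water: 61 enriched, 17 depleted of 215 tested OTUs
  spiked recovery: 10/10 enriched, 10/10 depleted
root vs sediment: 88 enriched, 41 depleted of 215 tested OTUs
  spiked recovery: 10/10 enriched, 10/10 depleted

leaf: Mantel: r = 0.230, p = 0.04595; partial (| phylogeny): r = 0.228, p = 0.05794
root: Mantel: r = 0.438, p = 0.01299; partial (| phylogeny): r = 0.435, p = 0.01299
```

Reading it: both host compartments differ from their environments
(ANOSIM), leaves are mostly water-sourced and roots mostly
sediment-sourced with a visible unknown fraction, every spiked taxon is
recovered by the differential-abundance stage, and the
cooccurrence–competition association is clearly positive for root-enriched
taxa — whose occurrence the generator couples to shared resource pools —
and weak/marginal for leaf-enriched taxa, whose occurrence is random (with
only 10 leaf OTUs a borderline p like the one above occurs at roughly the
nominal rate; the calibration tests in `tests/testthat/test-acceptance.R`
run this contrast over 100 replicates).

The same chain is available as one call, `run_pipeline(default_config(),
study = make_study())`, which writes per-stage outputs plus a manifest of
seeds and parameters; reruns with the same config are bit-identical.

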