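#!/usr/bin/env Rscript
# Stage 5: reverse-ecology test of habitat filtering.
#
# For each host compartment's enriched OTUs with metabolic networks: build
# compound graphs, compute seed sets (source components of the SCC
# condensation), form the competitive dissimilarity matrix C (Jaccard on
# seed sets) and the cooccurrence matrix (Jaccard on presence/absence over
# that compartment's rarefied samples), then test their association with
# one-sided Mantel tests (1,000 permutations) and a partial Mantel test
# controlling for patristic distances. A positive association for roots but
# not leaves is the habitat-filtering signature.

library(habfilt)

dir.create("results/reverse_ecology", showWarnings = FALSE, recursive = TRUE)
rar <- read_otu_table("results/diversity/rarefied_otu_table.tsv")
meta <- read_sample_metadata("results/data/synthetic_metadata.tsv")
tree <- read_newick("results/data/synthetic_tree.nwk")
reactions <- read_reaction_sets("results/data/synthetic_reactions.tsv")

for (ht in c("leaf", "root")) {
  da <- read.delim(sprintf(
    "results/differential_abundance/diffabund_%s.tsv", ht))
  enriched <- da$otu_id[da$call == "enriched"]
  with_net <- intersect(enriched, names(reactions))
  cat(sprintf("%s: %d enriched OTUs, %d with metabolic networks\n",
              ht, length(enriched), length(with_net)))
  if (length(with_net) < 4) next

  seeds <- lapply(with_net, function(o)
    build_compound_graph(reactions[[o]], otu_id = o) |> seed_set())
  C <- competition_matrix(seeds)
  write_dist_matrix(C, sprintf("results/reverse_ecology/competition_%s.tsv",
                               ht))
  seed_tab <- do.call(rbind, lapply(seeds, function(s)
    data.frame(otu_id = s$otu_id, compound = names(s$seeds),
               confidence = unname(s$seeds))))
  write_results(seed_tab, sprintf("results/reverse_ecology/seed_sets_%s.tsv",
                                  ht))

  ht_cols <- intersect(sample_ids(rar),
                       meta$sample_id[meta$community_type == ht])
  occ <- cooccurrence_matrix(
    otu_table(unclass(rar)[with_net, ht_cols, drop = FALSE]))
  mt <- mantel(occ, C, n_perm = 1000, seed = 105)
  phy <- phylo_distance_matrix(tree, with_net)
  pm <- partial_mantel(occ, C, phy, n_perm = 1000, seed = 105)
  cat(sprintf("  Mantel: r = %.3f, p = %.4g; partial (| phylogeny): r = %.3f, p = %.4g\n",
              mt$r, mt$p_value, pm$r, pm$p_value))
  write_results(list(
    mantel = mt[c("r", "p_value", "n_permutations", "method")],
    partial_mantel = pm[c("r", "p_value", "n_permutations", "method")]),
    sprintf("results/reverse_ecology/mantel_%s.json", ht))
}
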