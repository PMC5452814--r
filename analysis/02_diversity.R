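#!/usr/bin/env Rscript
# Stage 2: rarefaction, alpha/beta diversity, ordination, and the
# host-versus-environment permutation tests.
#
# Counts are rarefied to 2,500; Shannon (bits) and Faith's PD summarize
# alpha diversity; Canberra and normalized unweighted UniFrac distances feed
# a PCoA and the group tests. ANOSIM permutations are restricted to within
# sites to respect the blocked sampling design.

library(habfilt)

dir.create("results/diversity", showWarnings = FALSE, recursive = TRUE)
tab <- read_otu_table("results/data/synthetic_otu_table.tsv")
meta <- read_sample_metadata("results/data/synthetic_metadata.tsv")
tree <- read_newick("results/data/synthetic_tree.nwk")

rar <- rarefy(tab, 2500, seed = 101)
write_otu_table(rar, "results/diversity/rarefied_otu_table.tsv")

alpha <- alpha_diversity(rar, tree)
alpha$community_type <- meta$community_type[match(alpha$sample_id,
                                                  meta$sample_id)]
write_results(alpha, "results/diversity/alpha_diversity.tsv")
cat("Mean Shannon (bits) by community type:\n")
print(round(tapply(alpha$shannon, alpha$community_type, mean), 2))

d_can <- canberra_matrix(rar)
d_uni <- unifrac_matrix(rar, tree)
write_dist_matrix(d_can, "results/diversity/canberra.tsv")
write_dist_matrix(d_uni, "results/diversity/unifrac.tsv")

ord <- pcoa(d_can)
write_results(data.frame(sample_id = rownames(ord$coordinates),
                         ord$coordinates[, 1:4]),
              "results/diversity/pcoa_coordinates.tsv")
cat(sprintf("PCoA axis 1 and 2 explain %.1f%% and %.1f%% of the (positive) inertia\n",
            100 * ord$proportion_explained[1],
            100 * ord$proportion_explained[2]))

ids <- sample_ids(rar)
groups <- meta$community_type[match(ids, meta$sample_id)]
strata <- meta$site_id[match(ids, meta$sample_id)]

tests <- list()
for (nm in c("canberra", "unifrac")) {
  dm <- if (nm == "canberra") d_can else d_uni
  tests[[paste0("anosim_all_", nm)]] <-
    anosim(dm, groups, strata = strata, n_perm = 1000, seed = 102)
  for (pair in list(c("leaf", "water"), c("root", "sediment"))) {
    keep <- groups %in% pair
    sub <- dist_matrix(unclass(dm)[keep, keep])
    tests[[paste(c("anosim", pair, nm), collapse = "_")]] <-
      anosim(sub, groups[keep], strata = strata[keep], n_perm = 1000,
             seed = 102)
  }
  tests[[paste0("permdisp_", nm)]] <-
    permdisp(dm, groups, n_perm = 1000, seed = 102)
}
for (nm in names(tests)) {
  t <- tests[[nm]]
  cat(sprintf("%-28s %s = %6.3f  p = %.4g\n", nm, t$statistic_name,
              t$statistic, t$p_value))
}
write_results(lapply(tests, function(t)
  t[c("statistic", "statistic_name", "p_value", "n_permutations")]),
  "results/diversity/group_tests.json")
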