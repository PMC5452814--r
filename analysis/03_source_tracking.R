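#!/usr/bin/env Rscript
# Stage 3: Bayesian source tracking of host communities, primary-source
# selection, and the within- versus between-bed centroid proximity test.
#
# The classifier is trained per site on that site's water and sediment
# communities (rarefied counts) and applied to the site's leaf and root
# sinks; each sink is decomposed into water, sediment and unknown fractions.

library(habfilt)

dir.create("results/source_tracking", showWarnings = FALSE, recursive = TRUE)
meta <- read_sample_metadata("results/data/synthetic_metadata.tsv")
rar <- read_otu_table("results/diversity/rarefied_otu_table.tsv")

ids <- sample_ids(rar)
type <- meta$community_type[match(ids, meta$sample_id)]
site <- meta$site_id[match(ids, meta$sample_id)]
sink_ids <- ids[type %in% c("leaf", "root")]

props <- NULL
for (s in unique(site)) {
  sk <- intersect(sink_ids, ids[site == s])
  sc <- ids[site == s & type %in% c("water", "sediment")]
  fit <- fit_sources(otu_table(unclass(rar)[, sk, drop = FALSE]),
                     otu_table(unclass(rar)[, sc, drop = FALSE]),
                     type[match(sc, ids)], seed = 103)
  props <- rbind(props, fit$proportions)
}
props <- props[sink_ids, ]
attribution <- structure(list(proportions = props),
                         class = "source_attribution")
write_results(data.frame(sink_id = rownames(props), props,
                         check.names = FALSE),
              "results/source_tracking/source_proportions.tsv")

primary <- select_primary_source(attribution, meta)
meds <- attr(primary, "medians")
cat("Median attributed proportions per host compartment:\n")
print(round(meds, 3))
cat("Primary sources:", paste(names(primary), primary, sep = " -> ",
                              collapse = ", "), "\n")
write_results(c(as.list(primary),
                list(medians = as.data.frame(meds))),
              "results/source_tracking/primary_sources.json")

# are hosts closer to their own bed's environment than to other beds'?
ord <- pcoa(read_dist_matrix("results/diversity/canberra.tsv"))
for (ht in names(primary)) {
  env <- primary[[ht]]
  by_bed <- function(tp) {
    keep <- meta$community_type == tp & meta$sample_id %in% ids
    split(meta$sample_id[keep], meta$bed_id[keep])
  }
  ct <- centroid_proximity_test(ord, by_bed(ht), by_bed(env),
                                n_perm = 1000, seed = 104)
  cat(sprintf("%s vs own-bed %s: mean centroid distance %.3f, p = %.4g\n",
              ht, env, ct$statistic, ct$p_value))
  write_results(ct[c("statistic", "p_value", "n_permutations")],
                sprintf("results/source_tracking/centroid_%s.json", ht))
}
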