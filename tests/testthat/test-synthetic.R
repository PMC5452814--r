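test_that("source profiles sit on the simplex and respect the seed", {
  m <- make_source_profiles(3, 50, concentration = 0.5, seed = 4)
  expect_equal(rowSums(m), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(m, make_source_profiles(3, 50, 0.5, seed = 4))
  expect_false(identical(m, make_source_profiles(3, 50, 0.5, seed = 5)))

  flat <- make_source_profiles(2, 10, concentration = 1e6, seed = 1)
  expect_true(all(abs(flat - 0.1) < 0.01))

  expect_error(make_source_profiles(2, 10, concentration = 0), "positive")
})

test_that("mixed sinks are multinomials of the stated mixture", {
  src <- make_source_profiles(2, 80, 0.5, seed = 2)
  mix <- make_mixed_sinks(src, c(1, 0, 0), depth = 50000, n_sinks = 5,
                          seed = 3)
  expect_true(all(colSums(mix$table) == 50000))
  # degenerate mixture: empirical proportions converge to source 1
  props <- rowMeans(sweep(unclass(mix$table), 2, 50000, "/"))
  expect_lt(max(abs(props - src[1, ])), 0.01)
  expect_equal(unname(mix$truth$mixing_proportions[1, ]), c(1, 0, 0))

  expect_error(make_mixed_sinks(src, c(0.5, 0.5), n_sinks = 2),
               "components")
  expect_error(make_mixed_sinks(src, c(0.6, 0.6, 0.1), n_sinks = 1),
               "sum to 1")
})

test_that("spiked tables carry the requested fold changes", {
  base <- rep(1 / 40, 40)
  names(base) <- paste0("otu_", 1:40)
  sim <- spike_differential_taxa(base, c(otu_1 = 3, otu_2 = -3),
                                 n_host = 40, n_env = 40, depth = 4000,
                                 dispersion = 0.1, seed = 6)
  host <- rowMeans(unclass(sim$table)[, sim$groups == "host"])
  env <- rowMeans(unclass(sim$table)[, sim$groups == "env"])
  expect_gt(host["otu_1"] / env["otu_1"], 4)   # true ratio 8
  expect_lt(host["otu_2"] / env["otu_2"], 1 / 4)
  expect_equal(sim$truth$spiked_taxa, c(otu_1 = 3, otu_2 = -3))

  expect_error(spike_differential_taxa(base, c(nope = 2)), "not in base")
  expect_error(spike_differential_taxa(base, dispersion = -1), ">= 0")
})

test_that("null spiked data keep host and environment exchangeable", {
  base <- rep(1 / 30, 30); names(base) <- paste0("otu_", 1:30)
  sim <- spike_differential_taxa(base, numeric(), n_host = 20, n_env = 20,
                                 dispersion = 0.2, seed = 8)
  p <- apply(unclass(sim$table), 1, function(x)
    wilcox.test(x[sim$groups == "host"], x[sim$groups == "env"],
                exact = FALSE)$p.value)
  expect_gt(min(p), 1e-4)
  expect_gt(mean(p > 0.05), 0.8)
})

test_that("random trees are rooted, label-conserving and deterministic", {
  ids <- paste0("sp", 1:12)
  tr <- make_random_tree(ids, seed = 3)
  expect_true(ape::is.rooted(tr))
  expect_setequal(tr$tip.label, ids)
  expect_identical(write_newick(tr), write_newick(make_random_tree(ids, 3)))

  two <- make_random_tree(c("a", "b"), seed = 1)
  expect_equal(ape::Ntip(two), 2)
  expect_error(make_random_tree(c("a", "a")), "duplicate")
})

test_that("toy networks have exactly the recorded source components", {
  toy <- make_toy_network(1, n_downstream = 2, max_scc_size = 1, seed = 1)
  expect_length(toy$truth$seeds, 1)
  expect_equal(unname(toy$truth$seeds), 1)

  for (s in 1:5) {
    toy <- make_toy_network(3, n_downstream = 6, max_scc_size = 4, seed = s)
    got <- seed_set(build_compound_graph(toy$reactions, "x"))
    expect_equal(sort(got$seeds), sort(toy$truth$seeds))
    # every non-seed compound reachable from some seed
    g <- igraph::graph_from_data_frame(as.data.frame(
      build_compound_graph(toy$reactions, "x")$edges), directed = TRUE)
    reach <- is.finite(igraph::distances(
      g, v = intersect(names(toy$truth$seeds), names(igraph::V(g))),
      mode = "out"))
    non_seed <- setdiff(colnames(reach), names(toy$truth$seeds))
    expect_true(all(colSums(reach[, non_seed, drop = FALSE]) > 0))
  }
})

test_that("bedded communities encode a shared bed effect", {
  sim <- make_bedded_communities(n_beds = 4, bed_effect_sd = 0.8, seed = 2)
  expect_equal(ncol(sim$table), 4 * 6)
  expect_equal(nrow(sim$metadata), 24)
  expect_identical(sim$metadata,
                   make_bedded_communities(n_beds = 4, bed_effect_sd = 0.8,
                                           seed = 2)$metadata)
  # same-bed host/env profiles correlate more than cross-bed ones
  m <- sim$metadata
  rel <- sweep(unclass(sim$table), 2, colSums(sim$table), "/")
  bed_mean <- function(type, bed)
    rowMeans(rel[, m$sample_id[m$community_type == type & m$bed_id == bed],
                 drop = FALSE])
  own <- cor(bed_mean("leaf", "bed1"), bed_mean("water", "bed1"))
  cross <- cor(bed_mean("leaf", "bed1"), bed_mean("water", "bed3"))
  expect_gt(own, cross)
})
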