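make_training <- function(profiles, n_per_source = 6, depth = 2500,
                          seed = 1) {
  set.seed(seed)
  counts <- NULL
  groups <- character(0)
  for (k in seq_len(nrow(profiles))) {
    counts <- cbind(counts, rmultinom(n_per_source, depth, profiles[k, ]))
    groups <- c(groups, rep(rownames(profiles)[k], n_per_source))
  }
  rownames(counts) <- colnames(profiles)
  colnames(counts) <- paste0("src_", seq_len(ncol(counts)))
  list(table = otu_table(counts), groups = groups)
}

test_that("a sink matching one deep distinct source is attributed to it", {
  src <- make_source_profiles(2, 120, 0.2, seed = 31)
  expect_gt(js_divergence(src[1, ], src[2, ]), 0.3)
  train <- make_training(src, seed = 32)
  sinks <- make_mixed_sinks(src, c(1, 0, 0), depth = 2500, n_sinks = 3,
                            seed = 33)
  fit <- fit_sources(sinks$table, train$table, train$groups, seed = 34,
                     restarts = 4)
  expect_true(all(fit$proportions[, "source_1"] >= 0.9))
  expect_equal(rowSums(fit$proportions), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("two identical sources split the attribution symmetrically", {
  src <- make_source_profiles(1, 100, 0.5, seed = 35)
  twin <- rbind(src, src)
  rownames(twin) <- c("env_a", "env_b")
  train <- make_training(twin, seed = 36)
  sinks <- make_mixed_sinks(twin, c(0.5, 0.5, 0), depth = 2500,
                            n_sinks = 2, seed = 37)
  fit <- fit_sources(sinks$table, train$table, train$groups, seed = 38,
                     restarts = 4)
  gap <- abs(fit$proportions[, "env_a"] - fit$proportions[, "env_b"])
  expect_true(all(gap < 0.1))
  expect_true(all(rowSums(fit$proportions[, c("env_a", "env_b")]) > 0.85))
})

test_that("a sink with taxa absent from all sources goes to unknown", {
  src <- make_source_profiles(2, 100, 0.3, seed = 39)
  train <- make_training(src, seed = 40)
  sinks <- make_mixed_sinks(src, c(0, 0, 1), depth = 2500, n_sinks = 2,
                            seed = 41)
  fit <- fit_sources(sinks$table, train$table, train$groups, seed = 42,
                     restarts = 4)
  expect_true(all(fit$proportions[, "unknown"] >= 0.9))
})

test_that("the sampler is deterministic under a seed and validates inputs", {
  src <- make_source_profiles(2, 60, 0.4, seed = 43)
  train <- make_training(src, n_per_source = 3, depth = 800, seed = 44)
  sinks <- make_mixed_sinks(src, c(0.6, 0.3, 0.1), depth = 800,
                            n_sinks = 2, seed = 45)
  f1 <- fit_sources(sinks$table, train$table, train$groups, seed = 46,
                    restarts = 2)
  f2 <- fit_sources(sinks$table, train$table, train$groups, seed = 46,
                    restarts = 2)
  expect_identical(f1$proportions, f2$proportions)

  bad <- unclass(train$table)
  rownames(bad)[1] <- "other_taxon"
  expect_error(fit_sources(sinks$table, otu_table(bad), train$groups),
               "mismatch")
  # pooling every source sample into one environment is legitimate
  one <- fit_sources(sinks$table, train$table,
                     rep("water", length(train$groups)), seed = 1,
                     restarts = 1, n_draws = 2)
  expect_identical(colnames(one$proportions), c("water", "unknown"))
})

test_that("primary source selection takes the largest median and ties error", {
  props <- rbind(leaf1 = c(water = 0.8, sediment = 0.1, unknown = 0.1),
                 leaf2 = c(water = 0.7, sediment = 0.2, unknown = 0.1),
                 root1 = c(water = 0.3, sediment = 0.51, unknown = 0.19))
  attribution <- structure(list(proportions = props),
                           class = "source_attribution")
  meta <- data.frame(sample_id = c("leaf1", "leaf2", "root1"),
                     community_type = c("leaf", "leaf", "root"),
                     bed_id = "b1", site_id = "s1")
  sel <- select_primary_source(attribution, meta)
  expect_identical(sel[["leaf"]], "water")
  expect_identical(sel[["root"]], "sediment")
  expect_equal(attr(sel, "medians")["leaf", "water"], 0.75)

  tie <- structure(list(proportions = rbind(
    x = c(water = 0.5, sediment = 0.5, unknown = 0))),
    class = "source_attribution")
  meta2 <- data.frame(sample_id = "x", community_type = "leaf",
                      bed_id = "b", site_id = "s")
  expect_error(select_primary_source(tie, meta2), "tie")
  expect_error(select_primary_source(attribution, meta[-1, ]),
               "without metadata")
})
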