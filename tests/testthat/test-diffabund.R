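test_that("low-count filtering follows the total-count reading", {
  tab <- otu_table(matrix(c(2L, 3L, 40L, 2L, 2L, 60L), 3, 2,
                          dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  kept <- filter_low_count(tab, min_total = 5)
  expect_identical(taxon_ids(kept), c("b", "c"))   # totals 4, 5, 100
  expect_identical(attr(kept, "removed"), "a")

  expect_identical(taxon_ids(filter_low_count(tab, min_total = 0)),
                   taxon_ids(tab))
  expect_warning(empty <- filter_low_count(tab, min_total = 1000),
                 "all OTUs filtered")
  expect_equal(nrow(empty), 0)

  # incidence reading: "a" seen in 2 samples, passes min_total = 2
  expect_identical(taxon_ids(filter_low_count(tab, 2, by = "incidence")),
                   c("a", "b", "c"))
})

test_that("TMM factors are unity for equal or rescaled libraries", {
  x <- matrix(rep(c(10L, 20L, 30L, 40L), 3), 4, 3,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:3)))
  f <- tmm_factors(otu_table(x))
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-12)

  y <- x; y[, 2] <- x[, 2] * 2L
  f2 <- tmm_factors(otu_table(y))
  expect_equal(unname(f2$factors), rep(1, 3), tolerance = 1e-9)
  expect_equal(exp(mean(log(f2$factors))), 1, tolerance = 1e-12)
})

test_that("TMM compensates a spiked sample and matches an independent
           evaluation of the published formula", {
  set.seed(51)
  n <- 400
  base <- rpois(n, 60) + 1L
  a <- rpois(n, base); b <- rpois(n, base)
  spike_idx <- sample.int(n, n * 0.05)
  b[spike_idx] <- b[spike_idx] * 16L
  tab <- otu_table(matrix(as.integer(c(a, b)), n, 2,
                          dimnames = list(paste0("t", 1:n), c("ref", "spiked"))))
  f <- tmm_factors(tab)
  # independent evaluation: trimmed, precision-weighted mean of M-values
  lib <- colSums(tab)
  pa <- a / lib[1]; pb <- b / lib[2]
  keep <- a > 0 & b > 0
  M <- log2(pb / pa)[keep]
  A <- (log2(pb) + log2(pa))[keep] / 2
  w <- 1 / ((lib[2] - b) / (lib[2] * b) + (lib[1] - a) / (lib[1] * a))[keep]
  lo_m <- quantile(M, 0.30); hi_m <- quantile(M, 0.70)
  lo_a <- quantile(A, 0.05); hi_a <- quantile(A, 0.95)
  trim <- M >= lo_m & M <= hi_m & A >= lo_a & A <= hi_a
  f_spiked <- 2^(sum(M[trim] * w[trim]) / sum(w[trim]))
  expect_equal(f$factors[["spiked"]] / f$factors[["ref"]], f_spiked,
               tolerance = 0.05)
  # the spiked sample's factor drops below 1, shrinking its effective
  # library so the 95% unspiked taxa are no longer biased downward
  expect_lt(f$factors[["spiked"]] / f$factors[["ref"]], 1)
})

test_that("TMM is invariant to rescaling one library and flags disjoint
           samples", {
  tab <- random_table(100, 4, seed = 52)
  f1 <- tmm_factors(tab)
  scaled <- unclass(tab); scaled[, 3] <- scaled[, 3] * 7L
  f2 <- tmm_factors(otu_table(scaled))
  # near-invariant: only the asymptotic precision weights feel the scale
  expect_equal(f1$factors, f2$factors, tolerance = 1e-2)

  x <- matrix(c(5L, 0L, 3L, 0L, 9L, 0L), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_error(tmm_factors(otu_table(x)), "share no positive taxon")
})

test_that("label exchange negates fold changes and keeps p-values", {
  sim <- spike_differential_taxa(
    setNames(rep(1 / 50, 50), paste0("otu_", 1:50)),
    c(otu_1 = 2), n_host = 8, n_env = 8, depth = 2000, seed = 53)
  host <- otu_table(unclass(sim$table)[, sim$groups == "host"])
  env <- otu_table(unclass(sim$table)[, sim$groups == "env"])
  fwd <- nb_glm_lrt(host, env)
  rev <- nb_glm_lrt(env, host)
  expect_equal(fwd$log2_fold_change, -rev$log2_fold_change,
               tolerance = 1e-6)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-6)
})

test_that("degenerate all-zero OTUs are excluded from testing", {
  x <- rbind(matrix(rpois(20 * 16, 30), 20, 16), 0L)
  dimnames(x) <- list(c(paste0("t", 1:20), "zero"), paste0("s", 1:16))
  res <- nb_glm_lrt(otu_table(x[, 1:8]), otu_table(x[, 9:16]))
  expect_true(is.na(res$p_value[res$otu_id == "zero"]))
  expect_false(res$converged[res$otu_id == "zero"])
  padj <- bh_adjust(res$p_value)
  expect_true(is.na(padj[res$otu_id == "zero"]))
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(54)
  p <- runif(100)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # NA excluded from m: adjusting with an NA equals adjusting without it
  expect_equal(bh_adjust(c(p[1:10], NA))[1:10], bh_adjust(p[1:10]))
})

test_that("enrichment calls respect the sign/threshold invariant", {
  res <- data.frame(otu_id = c("a", "b", "c", "d"),
                    log2_fold_change = c(2, -2, 1, NA),
                    p_value = c(0.001, 0.001, 0.5, NA),
                    p_adjusted = c(0.005, 0.005, 0.02, NA))
  out <- call_enrichment(res, alpha = 0.01)
  expect_identical(out$call, c("enriched", "depleted", "unchanged",
                               "unchanged"))
  s <- attr(out, "summary")
  expect_equal(s$n_enriched, 1)
  expect_equal(s$n_depleted, 1)
  expect_equal(s$n_tested, 3)
})

test_that("null data give calibrated p-values and no calls", {
  base <- setNames(rep(1 / 200, 200), paste0("otu_", 1:200))
  sim <- spike_differential_taxa(base, numeric(), n_host = 15, n_env = 15,
                                 depth = 2500, dispersion = 0.2, seed = 55)
  res <- differential_abundance(
    otu_table(unclass(sim$table)[, sim$groups == "host"]),
    otu_table(unclass(sim$table)[, sim$groups == "env"]))
  p <- res$p_value[!is.na(res$p_value)]
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
  expect_lte(sum(res$call != "unchanged"), 2)
})
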