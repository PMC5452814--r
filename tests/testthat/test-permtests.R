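test_that("anosim attains R = 1 under complete separation", {
  # two tight clusters far apart
  m <- matrix(5, 6, 6); diag(m) <- 0
  m[1:3, 1:3] <- 0.1; m[4:6, 4:6] <- 0.1; diag(m) <- 0
  d <- dist_matrix(m, labels = paste0("s", 1:6))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  # only 20 distinct 3+3 partitions exist, so p is bounded well away from 0
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 0.5)
})

test_that("anosim matches vegan's R and the exact enumeration oracle", {
  skip_if_not_installed("vegan")
  d <- euclid_dist(12, seed = 21)
  g <- rep(c("a", "b"), 6)
  ours <- anosim(d, g, n_perm = 99, seed = 2)
  theirs <- vegan::anosim(stats::as.dist(unclass(d)), g, permutations = 49)
  expect_equal(ours$statistic, unname(theirs$statistic), tolerance = 1e-12)

  # exact p on a 6-sample, 2-strata fixture equals full enumeration
  d6 <- euclid_dist(6, seed = 22)
  g6 <- c("a", "a", "b", "a", "b", "b")
  s6 <- c("u", "u", "u", "v", "v", "v")
  exact <- anosim(d6, g6, strata = s6, exact = TRUE)
  oracle <- oracle_anosim_exact(unclass(d6), g6, s6)
  expect_equal(exact$statistic, oracle$r, tolerance = 1e-12)
  expect_equal(exact$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(exact$n_permutations, oracle$n)
})

test_that("anosim restricted permutations stay within strata", {
  d <- euclid_dist(8, seed = 23)
  g <- c("a", "a", "b", "b", "a", "a", "b", "b")
  s <- rep(c("u", "v"), each = 4)
  res <- anosim(d, g, strata = s, n_perm = 199, seed = 3)
  expect_true(res$p_value >= 1 / 200)
  # a stratum with one group only: warned and held fixed
  g2 <- c("a", "a", "a", "a", "a", "a", "b", "b")
  expect_warning(anosim(d, g2, strata = s, n_perm = 49, seed = 4),
                 "held fixed")
  expect_error(anosim(d, rep(c("a", "b"), each = 4),
                      strata = rep(c("u", "v"), each = 4), n_perm = 9),
               "no admissible")
})

test_that("anosim is null-centered and rank-invariant", {
  set.seed(5)
  rs <- replicate(40, {
    d <- euclid_dist(10, seed = sample.int(1e6, 1))
    anosim(d, rep(c("a", "b"), 5), n_perm = 19, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.1)
  # monotone transform of distances leaves R unchanged (rank-based)
  d <- euclid_dist(10, seed = 24)
  g <- rep(c("a", "b"), 5)
  r1 <- anosim(d, g, n_perm = 9, seed = 1)$statistic
  r2 <- anosim(dist_matrix(unclass(d)^2, labels = rownames(d)),
               g, n_perm = 9, seed = 1)$statistic
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("permdisp reproduces the spatial-centroid procedure", {
  skip_if_not_installed("vegan")
  tab <- random_table(25, 24, seed = 26)
  d <- canberra_matrix(tab)
  g <- rep(c("a", "b", "c"), each = 8)
  ours <- permdisp(d, g, n_perm = 99, seed = 6)
  bd <- vegan::betadisper(stats::as.dist(unclass(d)), g, type = "centroid")
  expect_equal(unname(ours$distances), unname(bd$distances),
               tolerance = 1e-10)
  expect_equal(ours$statistic,
               unname(vegan::permutest(bd, permutations = 19)$tab$F[1]),
               tolerance = 1e-10)
  expect_error(permdisp(d, c("a", rep("b", 23)), n_perm = 9), "size 1")
})

test_that("permdisp detects an inflated copy of a tight cluster", {
  set.seed(7)
  pts <- matrix(rnorm(20 * 3, sd = 0.2), 20)
  pts2 <- matrix(rnorm(20 * 3, sd = 1.0), 20) + 5
  d <- dist_matrix(as.matrix(dist(rbind(pts, pts2))),
                   labels = paste0("s", 1:40))
  res <- permdisp(d, rep(c("tight", "wide"), each = 20), n_perm = 999,
                  seed = 8)
  expect_lte(res$p_value, 0.01)
  expect_gt(res$group_means[["wide"]], res$group_means[["tight"]])
})

test_that("centroid proximity test separates matched from exchangeable beds", {
  # perfectly matched: host centroid == own env centroid, beds distinct
  beds <- paste0("bed", 1:6)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 5, -5, 5), 6, 2,
                    byrow = TRUE)
  coords <- NULL; host <- env <- list()
  for (b in seq_along(beds)) {
    h <- sprintf("h%d_%d", b, 1:2); e <- sprintf("e%d_%d", b, 1:2)
    off <- matrix(c(0.1, 0, -0.1, 0), 2, 2, byrow = TRUE)
    coords <- rbind(coords,
                    sweep(off, 2, centers[b, ], "+"),
                    sweep(off, 2, centers[b, ], "+"))
    host[[beds[b]]] <- h; env[[beds[b]]] <- e
    rownames(coords)[(4 * b - 3):(4 * b)] <- c(h, e)
  }
  ord <- list(coordinates = coords)
  res <- centroid_proximity_test(ord, host, env, n_perm = 999, seed = 9)
  expect_equal(res$p_value, 1 / 1000)
  expect_equal(res$statistic, 0, tolerance = 1e-12)

  expect_error(centroid_proximity_test(ord, host[1], env[1], n_perm = 9),
               ">= 2 beds")
})

test_that("centroid proximity test has power under a shared bed effect", {
  rej <- 0
  for (r in 1:10) {
    sim <- make_bedded_communities(n_beds = 6, bed_effect_sd = 1, seed = r)
    ord <- pcoa(canberra_matrix(sim$table))
    m <- sim$metadata
    hb <- split(m$sample_id[m$community_type == "leaf"],
                m$bed_id[m$community_type == "leaf"])
    eb <- split(m$sample_id[m$community_type == "water"],
                m$bed_id[m$community_type == "water"])
    res <- centroid_proximity_test(ord, hb, eb, n_perm = 199, seed = r)
    rej <- rej + (res$p_value <= 0.05)
  }
  expect_gte(rej, 9)
})
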