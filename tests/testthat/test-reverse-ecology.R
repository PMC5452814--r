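test_that("compound graphs expand reactions into substrate-product edges", {
  net <- build_compound_graph(list(reaction_record("R1", c("A", "B"), "C")))
  expect_setequal(paste(net$edges[, 1], net$edges[, 2]),
                  c("A C", "B C"))

  rev <- build_compound_graph(list(reaction_record("R1", "A", "B",
                                                   reversible = TRUE)))
  expect_setequal(paste(rev$edges[, 1], rev$edges[, 2]), c("A B", "B A"))

  dup <- build_compound_graph(list(reaction_record("R1", "A", "B"),
                                   reaction_record("R1b", "A", "B")))
  expect_equal(nrow(dup$edges), 1)
  expect_error(build_compound_graph(list()), "empty")
})

test_that("seed sets match the worked examples", {
  chain <- build_compound_graph(list(reaction_record("R1", "A", "B"),
                                     reaction_record("R2", "B", "C")))
  expect_equal(seed_set(chain)$seeds, c(A = 1))

  cyc <- build_compound_graph(list(reaction_record("R1", "A", "B"),
                                   reaction_record("R2", "B", "A"),
                                   reaction_record("R3", "B", "C")))
  s <- seed_set(cyc)
  expect_equal(sort(s$seeds), c(A = 0.5, B = 0.5))
  expect_false("C" %in% names(s$seeds))
  expect_length(s$components, 1)

  two <- build_compound_graph(list(reaction_record("R1", "A", "B"),
                                   reaction_record("R2", "C", "D")))
  expect_equal(sort(two$compounds), c("A", "B", "C", "D"))
  expect_equal(sort(seed_set(two)$seeds), c(A = 1, C = 1))
})

test_that("seed sets equal the brute-force reachability definition", {
  for (i in 1:50) {
    net <- random_digraph_net(sample(5:30, 1), runif(1, 0.02, 0.25),
                              seed = i)
    fast <- seed_set(net)
    slow <- brute_seed_set(net)
    expect_equal(sort(fast$seeds), sort(slow$seeds), tolerance = 1e-12)
    # confidence mass totals the number of source components
    expect_equal(sum(fast$seeds), length(fast$components))
  }
})

test_that("adding an upstream feeder moves seeds upstream, never downstream", {
  toy <- make_toy_network(2, n_downstream = 4, max_scc_size = 2, seed = 9)
  net <- build_compound_graph(toy$reactions)
  before <- seed_set(net)
  target <- names(before$seeds)[1]
  fed <- build_compound_graph(c(toy$reactions,
                                list(reaction_record("Rnew", "NEW", target))))
  after <- seed_set(fed)
  expect_true("NEW" %in% names(after$seeds))
  # the fed component loses seed status; all other seeds survive
  fed_comp <- before$components[[which(vapply(before$components,
                                              function(cp) target %in% cp,
                                              TRUE))]]
  expect_false(any(fed_comp %in% names(after$seeds)))
  expect_true(all(setdiff(names(before$seeds), fed_comp) %in%
                    names(after$seeds)))
})

test_that("seed jaccard distances follow the binary definition", {
  ss <- function(id, cpds) structure(
    list(otu_id = id, seeds = setNames(rep(1, length(cpds)), cpds),
         components = as.list(cpds)), class = "seed_set")
  expect_equal(seed_jaccard(ss("a", c("X", "Y")), ss("b", c("X", "Y"))), 0)
  expect_equal(seed_jaccard(ss("a", c("X")), ss("b", c("Y"))), 1)
  expect_equal(seed_jaccard(ss("a", c("A", "B")), ss("b", c("B", "C"))),
               2 / 3)
  expect_equal(seed_jaccard(ss("a", character(0)), ss("b", character(0))), 0)

  # weighted variant uses confidences
  a <- structure(list(otu_id = "a", seeds = c(X = 0.5, Y = 0.5),
                      components = list(c("X", "Y"))), class = "seed_set")
  b <- structure(list(otu_id = "b", seeds = c(X = 1),
                      components = list("X")), class = "seed_set")
  expect_equal(seed_jaccard(a, b, weighted = TRUE), 1 - 0.5 / 1.5)
})

test_that("competition matrices agree with the scalar operation", {
  toys <- lapply(1:4, function(i) {
    t <- make_toy_network(2, 3, 2, seed = i, prefix = paste0("N", i))
    seed_set(build_compound_graph(t$reactions, otu_id = paste0("otu", i)))
  })
  C <- competition_matrix(toys)
  expect_s3_class(C, "dist_matrix")
  expect_equal(unclass(C)[1, 3], seed_jaccard(toys[[1]], toys[[3]]))
  expect_true(all(unclass(C) >= 0 & unclass(C) <= 1))

  toys[[2]]$otu_id <- "otu1"
  expect_error(competition_matrix(toys), "duplicate")
})

test_that("cooccurrence distances are presence/absence jaccard", {
  x <- matrix(0L, 3, 3, dimnames = list(c("o1", "o2", "o3"),
                                        paste0("s", 1:3)))
  x["o1", c(1, 2)] <- 1L
  x["o2", c(2, 3)] <- 1L
  x["o3", c(3, 1)] <- 5L
  d <- cooccurrence_matrix(otu_table(x))
  expect_equal(unclass(d)["o1", "o2"], 2 / 3)

  ident <- rbind(a = c(1L, 1L, 0L), b = c(9L, 3L, 0L))
  colnames(ident) <- paste0("s", 1:3)
  expect_equal(unclass(cooccurrence_matrix(otu_table(ident)))["a", "b"], 0)

  comp <- rbind(a = c(1L, 0L), b = c(0L, 1L))
  colnames(comp) <- c("s1", "s2")
  expect_equal(unclass(cooccurrence_matrix(otu_table(comp)))["a", "b"], 1)

  absent <- rbind(a = c(0L, 0L), b = c(0L, 0L), c = c(1L, 0L))
  colnames(absent) <- c("s1", "s2")
  expect_warning(d0 <- cooccurrence_matrix(otu_table(absent)),
                 "absent from every sample")
  expect_equal(unclass(d0)["a", "b"], 0)
  expect_equal(unclass(d0)["a", "c"], 1)
})

test_that("patristic distances sum branch lengths along paths", {
  cherry <- parse_newick("(A:1,B:1);")
  expect_equal(unclass(phylo_distance_matrix(cherry))["A", "B"], 2)
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  d <- phylo_distance_matrix(tr)
  expect_equal(unclass(d)["A", "C"], 4)
  expect_equal(diag(unclass(d)), setNames(rep(0, 3), c("A", "B", "C")))
  expect_error(phylo_distance_matrix(tr, c("A", "Z")), "missing")
})

test_that("mantel matches vegan and its exact enumeration oracle", {
  skip_if_not_installed("vegan")
  d1 <- euclid_dist(12, seed = 61)
  d2 <- euclid_dist(12, seed = 62)
  ours <- mantel(d1, d2, n_perm = 99, seed = 1)
  theirs <- vegan::mantel(stats::as.dist(unclass(d1)),
                          stats::as.dist(unclass(d2)), permutations = 49)
  expect_equal(ours$r, unname(theirs$statistic), tolerance = 1e-12)

  # identity: r = 1, minimal p
  self <- mantel(d1, d1, n_perm = 199, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 200)

  # exact p equals full 4! and 5! enumeration
  for (n in 4:5) {
    a <- euclid_dist(n, seed = 70 + n)
    b <- euclid_dist(n, seed = 80 + n)
    exact <- mantel(a, b, exact = TRUE)
    oracle <- oracle_mantel_exact(unclass(a), unclass(b))
    expect_equal(exact$r, oracle$r, tolerance = 1e-12)
    expect_equal(exact$p_value, oracle$p, tolerance = 1e-12)
  }

  expect_error(mantel(d1, dist_matrix(matrix(0, 12, 12),
                                      labels = rownames(d1))),
               "zero-variance")
})

test_that("mantel is invariant to a consistent relabeling", {
  d1 <- euclid_dist(10, seed = 63)
  d2 <- euclid_dist(10, seed = 64)
  r0 <- mantel(d1, d2, n_perm = 9, seed = 1)$r
  perm <- sample(rownames(d1))
  r1 <- mantel(dist_matrix(unclass(d1)[perm, perm]),
               dist_matrix(unclass(d2)[perm, perm]), n_perm = 9,
               seed = 1)$r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("partial mantel removes a shared driver and flags degeneracy", {
  set.seed(65)
  n <- 25
  z <- matrix(rnorm(n * 2), n)
  d3 <- dist_matrix(as.matrix(dist(z)), labels = paste0("p", 1:n))
  mk <- function(noise_sd) {
    pts <- z + matrix(rnorm(n * 2, sd = noise_sd), n)
    dist_matrix(as.matrix(dist(pts)), labels = paste0("p", 1:n))
  }
  d1 <- mk(0.4); d2 <- mk(0.4)
  raw <- mantel(d1, d2, n_perm = 99, seed = 3)
  part <- partial_mantel(d1, d2, d3, n_perm = 99, seed = 3)
  expect_gt(raw$r, 0.5)
  expect_lt(abs(part$r), 0.25)

  # d2 == d3 makes r23 = 1: degenerate
  expect_error(partial_mantel(d1, d3, d3, n_perm = 9), "degenerate")

  # a control uncorrelated with both leaves r essentially unchanged
  d3b <- euclid_dist(n, seed = 66)
  rownames_match <- dist_matrix(unclass(d3b), labels = paste0("p", 1:n))
  part2 <- partial_mantel(d1, d2, rownames_match, n_perm = 99, seed = 4)
  expect_equal(part2$r, raw$r, tolerance = 0.1)
})
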