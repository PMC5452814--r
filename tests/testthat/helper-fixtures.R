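# Shared fixtures and independent oracles, all built in code.

# four-tip balanced tree used by the hand-computed diversity checks
balanced_tree <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

tiny_table <- function() {
  otu_table(matrix(c(1L, 3L, 2L, 4L), 2, 2,
                   dimnames = list(c("t1", "t2"), c("s1", "s2"))))
}

random_table <- function(n_taxa, n_samples, lambda = 20, seed = 1) {
  set.seed(seed)
  otu_table(matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                   dimnames = list(paste0("t", seq_len(n_taxa)),
                                   paste0("s", seq_len(n_samples)))))
}

# distance matrix from random points in Euclidean space
euclid_dist <- function(n, dim = 3, seed = 1) {
  set.seed(seed)
  pts <- matrix(rnorm(n * dim), n)
  dist_matrix(as.matrix(dist(pts)), labels = paste0("p", seq_len(n)))
}

# ---- independent seed-set oracle -------------------------------------------
# Brute-force definition via full reachability: a compound c belongs to the
# seed set iff every compound that reaches c is also reached by c (i.e. no
# compound outside c's SCC feeds it); its SCC and confidence are likewise
# derived from mutual reachability only.
brute_seed_set <- function(net) {
  g <- igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = net$compounds)
  reach <- is.finite(igraph::distances(g, mode = "out"))
  cpds <- rownames(reach)
  seeds <- numeric(0)
  comps <- list()
  handled <- character(0)
  for (c in cpds) {
    if (c %in% handled) next
    into_c <- cpds[reach[, c]]
    scc <- cpds[reach[, c] & reach[c, ]]
    if (all(reach[c, into_c])) {       # nothing outside the SCC reaches c
      comps[[length(comps) + 1]] <- scc
      seeds[scc] <- 1 / length(scc)
      handled <- c(handled, scc)
    }
  }
  list(seeds = seeds, components = comps)
}

random_digraph_net <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  cpds <- paste0("c", seq_len(n_nodes))
  pairs <- expand.grid(from = cpds, to = cpds, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p_edge, ]
  if (!nrow(pairs)) pairs <- data.frame(from = cpds[1], to = cpds[min(2, n_nodes)])
  structure(list(otu_id = "rand",
                 compounds = cpds,
                 edges = cbind(from = pairs$from, to = pairs$to),
                 provenance = rep("r", nrow(pairs))),
            class = "metabolic_network")
}

# ---- brute-force permutation-test oracles ----------------------------------
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  out <- NULL
  for (p in seq_len(n)) {
    out <- rbind(out, t(apply(sub, 1, function(row) append(row, n, p - 1))))
  }
  out
}

# exact one-sided mantel p by enumerating every relabeling of d2
oracle_mantel_exact <- function(d1, d2, method = "pearson") {
  n <- nrow(d1)
  v1 <- d1[upper.tri(d1)]
  robs <- cor(v1, d2[upper.tri(d2)], method = method)
  perms <- perms_of(n)
  rs <- apply(perms, 1, function(idx) {
    m <- unclass(d2)[idx, idx]
    cor(v1, m[upper.tri(m)], method = method)
  })
  list(r = robs, p = mean(rs >= robs - 1e-12))
}

# exact anosim p by enumerating within-strata label arrangements
oracle_anosim_exact <- function(d, groups, strata) {
  rv <- rank(d[upper.tri(d)])
  M <- length(rv)
  pi_ <- row(d)[upper.tri(d)]; pj <- col(d)[upper.tri(d)]
  stat <- function(g) {
    w <- g[pi_] == g[pj]
    (mean(rv[!w]) - mean(rv[w])) / (M / 2)
  }
  idx_by_s <- split(seq_along(groups), strata)
  arrangements <- list(groups)
  for (idx in idx_by_s) {
    pp <- perms_of(length(idx))
    arrangements <- unlist(lapply(arrangements, function(g)
      lapply(seq_len(nrow(pp)), function(r) {
        g2 <- g; g2[idx] <- g[idx][pp[r, ]]; g2
      })), recursive = FALSE)
  }
  stats <- vapply(arrangements, stat, 0)
  list(r = stat(groups), p = mean(stats >= stat(groups) - 1e-12),
       n = length(stats))
}
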