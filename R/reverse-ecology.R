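#' Build a compound graph from reaction records
#'
#' Nodes are chemical compounds; each reaction contributes a directed edge
#' from every substrate to every product (and the reverse edges when the
#' reaction is reversible). Duplicate reactions collapse under set semantics.
#'
#' @param reactions list of [reaction_record()]s (non-empty).
#' @param otu_id organism identifier carried on the network.
#' @return a `metabolic_network`: list with `otu_id`, `compounds`, `edges`
#'   (2-column character matrix), and `provenance` (reaction id per edge).
#' @export
build_compound_graph <- function(reactions, otu_id = "organism") {
  if (!length(reactions)) stop("empty reaction list", call. = FALSE)
  from <- character(0); to <- character(0); via <- character(0)
  for (r in reactions) {
    e <- expand.grid(s = r$substrates, p = r$products,
                     stringsAsFactors = FALSE)
    from <- c(from, e$s); to <- c(to, e$p)
    via <- c(via, rep(r$reaction_id, nrow(e)))
    if (r$reversible) {
      from <- c(from, e$p); to <- c(to, e$s)
      via <- c(via, rep(r$reaction_id, nrow(e)))
    }
  }
  key <- paste(from, to, sep = "\r")
  keep <- !duplicated(key)
  structure(list(otu_id = otu_id,
                 compounds = sort(unique(c(from, to))),
                 edges = cbind(from = from[keep], to = to[keep]),
                 provenance = via[keep]),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("metabolic_network '%s': %d compounds, %d directed edges\n",
              x$otu_id, length(x$compounds), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    as.data.frame(net$edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = net$compounds)
}

#' Seed set of a metabolic network
#'
#' The seed set is the minimal set of compounds an organism must acquire
#' exogenously to synthesize every other compound in its network: the union
#' of the source components (in-degree-0 nodes) of the strongly connected
#' component condensation of the compound graph. Every compound in a source
#' component of size `s` carries confidence `1/s`, reflecting that any one
#' member of the component suffices to reach the rest.
#'
#' @param net a `metabolic_network` from [build_compound_graph()].
#' @return a `seed_set`: list with `otu_id`, `seeds` (named confidence
#'   vector), and `components` (list of source-component compound vectors).
#' @export
seed_set <- function(net) {
  if (!length(net$compounds))
    return(structure(list(otu_id = net$otu_id, seeds = numeric(0),
                          components = list()), class = "seed_set"))
  g <- as_igraph(net)
  memb <- igraph::components(g, mode = "strong")$membership
  from_c <- memb[net$edges[, "from"]]
  to_c <- memb[net$edges[, "to"]]
  has_inflow <- unique(to_c[from_c != to_c])
  src <- setdiff(unique(memb), has_inflow)
  comps <- lapply(src, function(k) names(memb)[memb == k])
  seeds <- unlist(lapply(comps, function(cp)
    stats::setNames(rep(1 / length(cp), length(cp)), cp)))
  if (is.null(seeds)) seeds <- numeric(0)
  structure(list(otu_id = net$otu_id, seeds = seeds, components = comps),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed_set '%s': %d seed compounds in %d source components\n",
              x$otu_id, length(x$seeds), length(x$components)))
  invisible(x)
}

#' Jaccard distance between two seed sets
#'
#' Binary by default (`1 - |A intersect B| / |A union B|` on compound
#' identity); with `weighted = TRUE` a generalized Jaccard on the confidence
#' vectors (`1 - sum min / sum max`). Two empty seed sets are at distance 0.
#'
#' @param a,b `seed_set` objects.
#' @param weighted use confidences.
#' @export
seed_jaccard <- function(a, b, weighted = FALSE) {
  sa <- names(a$seeds); sb <- names(b$seeds)
  if (!length(sa) && !length(sb)) return(0)
  if (!weighted) {
    1 - length(intersect(sa, sb)) / length(union(sa, sb))
  } else {
    all <- union(sa, sb)
    va <- stats::setNames(numeric(length(all)), all); va[sa] <- a$seeds
    vb <- stats::setNames(numeric(length(all)), all); vb[sb] <- b$seeds
    1 - sum(pmin(va, vb)) / sum(pmax(va, vb))
  }
}

#' Competitive dissimilarity matrix C
#'
#' Pairwise Jaccard distances between OTU seed sets. Low `c_ij` means high
#' predicted overlap in exogenously required resources, i.e. stronger
#' potential competition.
#'
#' @param seed_sets list of `seed_set` objects with distinct `otu_id`s.
#' @param weighted passed to [seed_jaccard()].
#' @return a [dist_matrix] over OTUs.
#' @export
competition_matrix <- function(seed_sets, weighted = FALSE) {
  ids <- vapply(seed_sets, `[[`, "", "otu_id")
  if (anyDuplicated(ids))
    stop("duplicate otu_id among seed sets", call. = FALSE)
  if (length(seed_sets) < 2) stop("need >= 2 OTUs", call. = FALSE)
  n <- length(seed_sets)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      m[i, j] <- m[j, i] <- seed_jaccard(seed_sets[[i]], seed_sets[[j]],
                                         weighted = weighted)
  dist_matrix(m, labels = ids)
}

#' OTU cooccurrence distance matrix
#'
#' Jaccard distances between OTU occurrence profiles across samples:
#' `1 - (#samples where both present) / (#samples where either present)` on
#' presence/absence (the default), or the quantitative Ruzicka variant
#' (`method = "ruzicka"`). A pair of OTUs absent everywhere gets distance 0
#' with a warning.
#'
#' @param table an [otu_table] restricted to the OTUs of interest (rarefied
#'   upstream when comparability across samples matters).
#' @param method `"binary"` or `"ruzicka"`.
#' @return a [dist_matrix] over OTUs (rows of `table`).
#' @export
cooccurrence_matrix <- function(table, method = c("binary", "ruzicka")) {
  method <- match.arg(method)
  table <- as_otu_table(table)
  n <- nrow(table)
  if (method == "binary") {
    P <- (unclass(table) > 0) * 1
    both <- P %*% t(P)
    occ <- rowSums(P)
    either <- outer(occ, occ, "+") - both
    if (any(occ == 0))
      warning("OTU(s) absent from every sample: ",
              paste(rownames(table)[occ == 0], collapse = ", "),
              "; pairwise distances involving two such OTUs set to 0",
              call. = FALSE)
    d <- ifelse(either > 0, 1 - both / either, 0)
  } else {
    X <- unclass(table)
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1))
      for (j in (i + 1):n) {
        mx <- sum(pmax(X[i, ], X[j, ]))
        d[i, j] <- d[j, i] <- if (mx > 0)
          1 - sum(pmin(X[i, ], X[j, ])) / mx else 0
      }
  }
  diag(d) <- 0
  dist_matrix(d, labels = rownames(table))
}

#' Patristic distance matrix between taxa
#'
#' Sum of branch lengths along the tree path between each pair of tips.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @param otu_ids tips to include (default all).
#' @return a [dist_matrix].
#' @export
phylo_distance_matrix <- function(tree, otu_ids = tree$tip.label) {
  miss <- setdiff(otu_ids, tree$tip.label)
  if (length(miss))
    stop("tips missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- ape::cophenetic.phylo(tree)[otu_ids, otu_ids]
  dist_matrix(d, tol = 1e-6)
}

#' Mantel test results
#' @keywords internal
mantel_result <- function(r, p, n_perm, method, controlled = NULL) {
  structure(list(r = r, p_value = p, n_permutations = as.integer(n_perm),
                 method = method, controlled = controlled),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("mantel%s: r = %.4f, p = %.4g (%d permutations, %s)\n",
              if (is.null(x$controlled)) "" else " (partial)",
              x$r, x$p_value, x$n_permutations, x$method))
  invisible(x)
}

align_to <- function(d, labels) dist_matrix(unclass(d)[labels, labels])

#' Mantel test of association between two distance matrices
#'
#' Correlates the upper-triangle vectors of two aligned distance matrices and
#' assesses significance by simultaneously permuting rows and columns of the
#' second matrix. One-sided by default (positive association), matching the
#' habitat-filtering expectation that OTUs with overlapping predicted
#' resources cooccur. With `exact = TRUE` all `n!` relabelings are enumerated
#' and the p-value is the exact fraction with `r* >= r` (identity included).
#'
#' @param d1,d2 [dist_matrix] objects over the same labels.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param alternative `"greater"` (one-sided, default) or `"two.sided"`.
#' @param exact enumerate all relabelings (small n only).
#' @return a `mantel_result`: `r`, `p_value`, `n_permutations`, `method`.
#' @export
mantel <- function(d1, d2, method = c("pearson", "spearman"), n_perm = 1000,
                   seed = 1, alternative = c("greater", "two.sided"),
                   exact = FALSE) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- as_dist_matrix(d1); d2 <- as_dist_matrix(d2)
  if (!setequal(rownames(d1), rownames(d2)))
    stop("matrices have different labels", call. = FALSE)
  d2 <- align_to(d2, rownames(d1))
  n <- nrow(d1)
  if (n < 4) stop("mantel needs n >= 4", call. = FALSE)
  v1 <- upper_vec(d1)
  if (stats::sd(v1) == 0 || stats::sd(upper_vec(d2)) == 0)
    stop("zero-variance distance triangle: r undefined", call. = FALSE)
  r_of <- function(idx) stats::cor(v1, upper_vec(unclass(d2)[idx, idx]),
                                   method = method)
  observed <- r_of(seq_len(n))
  side <- function(rs) if (alternative == "greater")
    rs >= observed - 1e-12 else abs(rs) >= abs(observed) - 1e-12
  if (exact) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, r_of)
    p <- sum(side(rs)) / length(rs)
    n_rep <- length(rs)
  } else {
    set.seed(seed)
    rs <- replicate(n_perm, r_of(sample.int(n)))
    p <- (1 + sum(side(rs))) / (1 + n_perm)
    n_rep <- n_perm
  }
  mantel_result(observed, p, n_rep, method)
}

partial_r <- function(r12, r13, r23) {
  if (1 - r13^2 < 1e-12 || 1 - r23^2 < 1e-12)
    stop("degenerate partial correlation: |r13| or |r23| = 1", call. = FALSE)
  (r12 - r13 * r23) / sqrt((1 - r13^2) * (1 - r23^2))
}

#' Partial Mantel test
#'
#' First-order partial correlation `r12.3` between the triangles of `d1` and
#' `d2` controlling for `d3` (e.g., phylogenetic distances), with the null
#' distribution obtained by permuting `d2`'s labels and recomputing `r12.3`
#' each draw.
#'
#' @inheritParams mantel
#' @param d3 the controlled [dist_matrix].
#' @export
partial_mantel <- function(d1, d2, d3, method = c("pearson", "spearman"),
                           n_perm = 1000, seed = 1,
                           alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  d1 <- as_dist_matrix(d1); d2 <- as_dist_matrix(d2); d3 <- as_dist_matrix(d3)
  if (!setequal(rownames(d1), rownames(d2)) ||
      !setequal(rownames(d1), rownames(d3)))
    stop("matrices have different labels", call. = FALSE)
  d2 <- align_to(d2, rownames(d1)); d3 <- align_to(d3, rownames(d1))
  n <- nrow(d1)
  if (n < 4) stop("partial mantel needs n >= 4", call. = FALSE)
  v1 <- upper_vec(d1); v3 <- upper_vec(d3)
  cc <- function(a, b) stats::cor(a, b, method = method)
  r13 <- cc(v1, v3)
  stat <- function(idx) {
    v2 <- upper_vec(unclass(d2)[idx, idx])
    partial_r(cc(v1, v2), r13, cc(v2, v3))
  }
  observed <- stat(seq_len(n))
  set.seed(seed)
  rs <- replicate(n_perm, stat(sample.int(n)))
  side <- if (alternative == "greater") rs >= observed - 1e-12
          else abs(rs) >= abs(observed) - 1e-12
  p <- (1 + sum(side)) / (1 + n_perm)
  mantel_result(observed, p, n_perm, method, controlled = "d3")
}
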