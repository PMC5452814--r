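#' Rarefy an OTU table
#'
#' Subsamples every sample (column) to exactly `depth` counts without
#' replacement. Samples whose total falls below `depth` are dropped and
#' reported in the `"dropped"` attribute; this mirrors the usual retention
#' rule for a fixed sequencing depth.
#'
#' @param table an [otu_table].
#' @param depth target depth (>= 1).
#' @param seed integer seed; the operation is deterministic given the seed.
#' @return a rarefied [otu_table]; `attr(, "dropped")` lists removed samples.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  table <- as_otu_table(table)
  if (length(depth) != 1 || depth < 1)
    stop("depth must be a positive integer", call. = FALSE)
  depth <- as.integer(depth)
  totals <- colSums(table)
  keep <- totals >= depth
  dropped <- colnames(table)[!keep]
  if (length(dropped))
    message("rarefy: dropping ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  out <- matrix(0L, nrow(table), sum(keep),
                dimnames = list(rownames(table), colnames(table)[keep]))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  cols <- which(keep)
  for (j in seq_along(cols)) {
    x <- table[, cols[j]]
    pool <- rep.int(seq_along(x), x)
    take <- pool[sample.int(length(pool), depth)]
    out[, j] <- tabulate(take, nbins = length(x))
  }
  res <- otu_table(out)
  attr(res, "dropped") <- dropped
  res
}

#' Shannon diversity (bits by default)
#'
#' `H = -sum p_i log_base p_i` over taxa with positive counts. Base 2 gives
#' entropy in bits, the convention used throughout this pipeline; pass
#' `base = exp(1)` for nats.
#'
#' @param counts nonnegative count (or abundance) vector with positive sum.
#' @param base logarithm base.
#' @export
shannon <- function(counts, base = 2) {
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  s <- sum(counts)
  if (s <= 0) stop("shannon undefined for a zero-sum vector", call. = FALSE)
  p <- counts[counts > 0] / s
  -sum(p * log(p, base = base))
}

# Per-edge presence of a set of observed tips, tree in postorder.
# Returns logical over edges: does the subtree below the edge contain an
# observed tip?
edge_presence <- function(tree, observed_tips) {
  miss <- setdiff(observed_tips, tree$tip.label)
  if (length(miss))
    stop("taxa missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n_node <- ape::Ntip(tree) + tree$Nnode
  pres <- logical(n_node)
  pres[match(observed_tips, tree$tip.label)] <- TRUE
  e <- tree$edge
  for (i in seq_len(nrow(e))) {          # postorder: children before parents
    if (pres[e[i, 2]]) pres[e[i, 1]] <- TRUE
  }
  pres[e[, 2]]
}

#' Faith's phylogenetic diversity
#'
#' Total branch length on the union of root-to-tip paths of the observed
#' taxa. The path to the root is included by default (`include_root = TRUE`);
#' with `include_root = FALSE` only branches below the observed taxa's most
#' recent common ancestor count.
#'
#' @param counts named nonnegative vector (names = taxa) or character vector
#'   of observed taxa.
#' @param tree a rooted [ape::phylo] with branch lengths.
#' @param include_root include the root path (default).
#' @export
faith_pd <- function(counts, tree, include_root = TRUE) {
  observed <- if (is.character(counts)) counts else {
    if (is.null(names(counts)))
      stop("counts must be named by taxon", call. = FALSE)
    names(counts)[counts > 0]
  }
  if (!length(observed)) return(0)
  tree <- stats::reorder(tree, "postorder")
  on_path <- edge_presence(tree, observed)
  pd <- sum(tree$edge.length[on_path])
  if (!include_root && length(observed) >= 1) {
    # subtract the chain of single-lineage edges above the MRCA
    mrca <- if (length(observed) == 1) match(observed, tree$tip.label)
            else ape::getMRCA(tree, observed)
    root <- ape::Ntip(tree) + 1L
    node <- mrca
    while (node != root) {
      i <- which(tree$edge[, 2] == node)
      pd <- pd - tree$edge.length[i]
      node <- tree$edge[i, 1]
    }
  }
  pd
}

#' Canberra distance between two count vectors
#'
#' `sum_k |x_k - y_k| / (x_k + y_k)` over indices where `x_k + y_k > 0`;
#' double-zero indices are skipped (the ecological convention), so two all-zero
#' vectors are at distance 0.
#'
#' @param x,y equal-length nonnegative vectors.
#' @export
canberra <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (any(x < 0) || any(y < 0)) stop("negative entries", call. = FALSE)
  s <- x + y
  keep <- s > 0
  if (!any(keep)) return(0)
  sum(abs(x[keep] - y[keep]) / s[keep])
}

#' Canberra distance matrix across samples
#' @param table an [otu_table] (taxa x samples).
#' @return a [dist_matrix] over samples.
#' @export
canberra_matrix <- function(table) {
  table <- as_otu_table(table)
  n <- ncol(table)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- canberra(table[, i], table[, j])
    }
  }
  dist_matrix(m, labels = colnames(table))
}

#' Normalized unweighted UniFrac distance
#'
#' Presence/absence measure on a shared rooted phylogeny: the fraction of the
#' branch length on the union of the two communities' root-to-tip paths that
#' is unique to one community. 0 for identical presence sets, 1 when no branch
#' is shared.
#'
#' @param x,y named count vectors (names = taxa) or character vectors of
#'   observed taxa.
#' @param tree rooted [ape::phylo] with branch lengths.
#' @export
unweighted_unifrac <- function(x, y, tree) {
  obs <- function(v) if (is.character(v)) v else names(v)[v > 0]
  a <- obs(x); b <- obs(y)
  tree <- stats::reorder(tree, "postorder")
  pa <- edge_presence(tree, a)
  pb <- edge_presence(tree, b)
  union_len <- sum(tree$edge.length[pa | pb])
  if (union_len == 0) return(0)
  shared_len <- sum(tree$edge.length[pa & pb])
  1 - shared_len / union_len
}

#' Unweighted UniFrac distance matrix across samples
#' @param table an [otu_table].
#' @param tree rooted [ape::phylo]; every taxon with a positive count must be
#'   a tip.
#' @return a [dist_matrix] over samples.
#' @export
unifrac_matrix <- function(table, tree) {
  table <- as_otu_table(table)
  tree <- stats::reorder(tree, "postorder")
  present_taxa <- rownames(table)[rowSums(table) > 0]
  miss <- setdiff(present_taxa, tree$tip.label)
  if (length(miss))
    stop("taxa missing from tree: ", paste(miss, collapse = ", "),
         call. = FALSE)
  n <- ncol(table)
  P <- vapply(seq_len(n), function(j)
    edge_presence(tree, rownames(table)[table[, j] > 0]),
    logical(nrow(tree$edge)))
  len <- tree$edge.length
  shared <- crossprod(P * len, P)            # branch length on both
  occ <- colSums(P * len)                    # branch length per sample
  union_len <- outer(occ, occ, "+") - shared
  d <- ifelse(union_len > 0, 1 - shared / union_len, 0)
  diag(d) <- 0
  dist_matrix(d, labels = colnames(table))
}

#' Principal-coordinate analysis (classical metric MDS)
#'
#' Double-centers `-D^2/2`, eigendecomposes, and returns coordinates on the
#' positive-eigenvalue axes scaled by `sqrt(eigenvalue)`. Negative eigenvalues
#' (non-Euclidean input) are retained in the eigenvalue vector and their
#' (unit-scaled) axes kept separately for Anderson's imaginary-part
#' correction; no Lingoes/Cailliez correction is applied.
#'
#' @param d a [dist_matrix].
#' @return a `pcoa_result`: `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, descending), `proportion_explained`, and
#'   `neg_coordinates` (axes for negative eigenvalues, scaled by
#'   `sqrt(-eigenvalue)`).
#' @export
pcoa <- function(d) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  B <- -0.5 * unclass(d)^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  B <- ctr %*% B %*% ctr
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- eig$values > tol
  neg <- eig$values < -tol
  coords <- eig$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(eig$values[pos]), sum(pos))
  negco <- eig$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-eig$values[neg]), sum(neg))
  rownames(coords) <- rownames(negco) <- rownames(d)
  colnames(coords) <- if (sum(pos)) paste0("PCo", seq_len(sum(pos)))
  pe <- pmax(eig$values, 0) / sum(pmax(eig$values, 0))
  structure(list(coordinates = coords, eigenvalues = eig$values,
                 proportion_explained = pe, neg_coordinates = negco),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d positive axes (axis 1: %.1f%%)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$proportion_explained[1]))
  invisible(x)
}

#' Alpha diversity per sample
#'
#' Convenience wrapper computing Shannon diversity (and Faith's PD when a
#' tree is supplied) for every sample of a table.
#'
#' @param table an [otu_table].
#' @param tree optional rooted [ape::phylo].
#' @return data.frame with columns `sample_id`, `shannon`, and optionally
#'   `faith_pd`.
#' @export
alpha_diversity <- function(table, tree = NULL) {
  table <- as_otu_table(table)
  out <- data.frame(
    sample_id = colnames(table),
    shannon = apply(table, 2, shannon),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(tree)) {
    tree <- stats::reorder(tree, "postorder")
    out$faith_pd <- apply(table, 2, faith_pd, tree = tree)
  }
  out
}
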