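#' Group permutation test results
#'
#' Common container for the ANOSIM, dispersion, and centroid-proximity tests:
#' a statistic, its permutation p-value, and the permutation count.
#'
#' @param statistic observed statistic.
#' @param p_value permutation p-value.
#' @param n_permutations number of permutations (or enumerated arrangements).
#' @param statistic_name one of `"anosim_r"`, `"permdisp_f"`,
#'   `"centroid_delta"`.
#' @param ... extra fields stored alongside.
#' @export
group_test_result <- function(statistic, p_value, n_permutations,
                              statistic_name, ...) {
  stopifnot(p_value >= 1 / (n_permutations + 1), p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value,
                 n_permutations = as.integer(n_permutations),
                 statistic_name = match.arg(statistic_name,
                   c("anosim_r", "permdisp_f", "centroid_delta")), ...),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (%d permutations)\n",
              x$statistic_name, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}

# All n! permutations of 1..n as a matrix (rows). Only used for small n.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    if (pos == 1) cbind(n, sub, deparse.level = 0)
    else if (pos == n) cbind(sub, n, deparse.level = 0)
    else cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
               sub[, pos:(n - 1), drop = FALSE], deparse.level = 0)
  }))
}

# Shuffle labels independently within each stratum; strata with no label
# diversity are left fixed.
permute_within_strata <- function(labels, strata) {
  out <- labels
  for (s in unique(strata)) {
    idx <- which(strata == s)
    if (length(unique(labels[idx])) > 1)
      out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}

# Enumerate every within-strata arrangement of labels (cartesian product of
# per-stratum permutations). Returns a matrix with one arrangement per row.
enumerate_within_strata <- function(labels, strata, limit = 2e5) {
  strata <- as.character(strata)
  groups <- split(seq_along(labels), strata)
  total <- prod(vapply(groups, function(i) factorial(length(i)), 0))
  if (total > limit)
    stop("exact enumeration infeasible: ", total, " arrangements",
         call. = FALSE)
  arrangements <- matrix(labels, 1, length(labels))
  for (idx in groups) {
    perms <- all_permutations(length(idx))
    grown <- matrix(NA_character_, nrow(arrangements) * nrow(perms),
                    length(labels))
    r <- 0L
    for (a in seq_len(nrow(arrangements))) {
      base <- arrangements[a, ]
      for (p in seq_len(nrow(perms))) {
        row <- base
        row[idx] <- base[idx][perms[p, ]]
        r <- r + 1L
        grown[r, ] <- row
      }
    }
    arrangements <- grown
  }
  arrangements
}

anosim_stat <- function(rank_vec, within) {
  n_pairs <- length(rank_vec)
  rb <- mean(rank_vec[!within])
  rw <- mean(rank_vec[within])
  (rb - rw) / (n_pairs / 2)
}

#' Analysis of similarities (ANOSIM) with restricted permutations
#'
#' Clarke's rank-based R statistic: `R = (mean between-group rank - mean
#' within-group rank) / (M/2)` with `M = n(n-1)/2` and average ranks on ties.
#' Group labels are permuted only within strata (e.g., sampling locations) to
#' respect a blocked design; strata with a single group provide no admissible
#' relabelings and are left fixed (with a warning). With `exact = TRUE` every
#' within-strata arrangement is enumerated and the p-value is the exact
#' fraction of arrangements with `R* >= R` (the identity included).
#'
#' @param d a [dist_matrix] over samples.
#' @param groups group label per sample.
#' @param strata optional stratum label per sample; `NULL` = free permutation.
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed RNG seed.
#' @param exact enumerate all arrangements instead of sampling.
#' @return a [group_test_result] with `statistic_name = "anosim_r"`.
#' @export
anosim <- function(d, groups, strata = NULL, n_perm = 999, seed = 1,
                   exact = FALSE) {
  d <- as_dist_matrix(d)
  n <- nrow(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  if (length(unique(groups)) < 2)
    stop("anosim needs >= 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs >= 2 samples", call. = FALSE)
  if (is.null(strata)) strata <- rep("all", n)
  strata <- as.character(strata)
  diverse <- vapply(split(groups, strata),
                    function(g) length(unique(g)) > 1, TRUE)
  if (!any(diverse))
    stop("no stratum contains more than one group: no admissible permutation",
         call. = FALSE)
  if (!all(diverse))
    warning("strata with a single group are held fixed: ",
            paste(names(diverse)[!diverse], collapse = ", "), call. = FALSE)

  rank_vec <- rank(upper_vec(d))          # average ranks on ties
  pair_i <- row(d)[upper.tri(d)]
  pair_j <- col(d)[upper.tri(d)]
  observed <- anosim_stat(rank_vec, groups[pair_i] == groups[pair_j])

  if (exact) {
    arr <- enumerate_within_strata(groups, strata)
    stats <- apply(arr, 1, function(g)
      anosim_stat(rank_vec, g[pair_i] == g[pair_j]))
    p <- sum(stats >= observed - 1e-12) / length(stats)
    n_rep <- length(stats)
  } else {
    set.seed(seed)
    stats <- replicate(n_perm, {
      g <- permute_within_strata(groups, strata)
      anosim_stat(rank_vec, g[pair_i] == g[pair_j])
    })
    p <- (1 + sum(stats >= observed - 1e-12)) / (1 + n_perm)
    n_rep <- n_perm
  }
  group_test_result(observed, p, n_rep, "anosim_r",
                    null_distribution = stats)
}

# Distance of each sample to its group centroid in PCoA space, with
# Anderson's real/imaginary correction for negative eigenvalues:
# z^2 = d_real^2 - d_imag^2, clamped at zero.
centroid_distances <- function(ord, groups) {
  sq_to_centroid <- function(M) {
    if (!ncol(M)) return(numeric(nrow(M)))
    out <- numeric(nrow(M))
    for (g in unique(groups)) {
      idx <- which(groups == g)
      ctr <- colMeans(M[idx, , drop = FALSE])
      out[idx] <- rowSums(sweep(M[idx, , drop = FALSE], 2, ctr)^2)
    }
    out
  }
  z2 <- sq_to_centroid(ord$coordinates) - sq_to_centroid(ord$neg_coordinates)
  sqrt(pmax(z2, 0))
}

oneway_f <- function(z, groups) {
  k <- length(unique(groups))
  n <- length(z)
  gm <- mean(z)
  means <- tapply(z, groups, mean)
  sizes <- tapply(z, groups, length)
  ssb <- sum(sizes * (means - gm)^2)
  ssw <- sum((z - means[groups])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Homogeneity of multivariate dispersions (permdisp)
#'
#' Embeds the samples by [pcoa()], computes each sample's distance to its
#' group spatial centroid with the real/imaginary split for negative
#' eigenvalues, and tests equality of mean distances with a one-way F
#' statistic whose null distribution comes from permuting the distances'
#' group labels.
#'
#' @inheritParams anosim
#' @return a [group_test_result] with `statistic_name = "permdisp_f"` and a
#'   `group_means` field (mean distance to centroid per group).
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  if (any(table(groups) < 2))
    stop("dispersion undefined for a group of size 1", call. = FALSE)
  ord <- pcoa(d)
  z <- centroid_distances(ord, groups)
  observed <- oneway_f(z, groups)
  set.seed(seed)
  stats <- replicate(n_perm, oneway_f(z, sample(groups)))
  p <- (1 + sum(stats >= observed - 1e-12)) / (1 + n_perm)
  group_test_result(observed, p, n_perm, "permdisp_f",
                    group_means = tapply(z, groups, mean),
                    distances = stats::setNames(z, rownames(d)))
}

#' Within- versus between-bed centroid proximity test
#'
#' Tests whether host communities sit closer (in ordination space) to the
#' environmental communities of their own seagrass bed than to those of other
#' beds. The statistic is the mean over beds of the Euclidean distance between
#' the host-sample centroid and the environmental-sample centroid of the same
#' bed. The null distribution re-pairs host beds with permuted environmental
#' beds (the identity pairing is excluded, so the null is genuinely
#' mismatched); small p means own-bed environments are closer than mismatched
#' ones (one-sided).
#'
#' @param ord a `pcoa_result` embedding all involved samples.
#' @param host_samples named list: bed id -> host sample ids.
#' @param env_samples named list: bed id -> environmental sample ids (same
#'   bed ids as `host_samples`).
#' @param n_perm number of bed permutations.
#' @param seed RNG seed.
#' @param axes which coordinate axes to use (default all positive axes).
#' @return a [group_test_result] with `statistic_name = "centroid_delta"`.
#' @export
centroid_proximity_test <- function(ord, host_samples, env_samples,
                                    n_perm = 999, seed = 1, axes = NULL) {
  beds <- names(host_samples)
  if (length(beds) < 2) stop("need >= 2 beds", call. = FALSE)
  if (!setequal(beds, names(env_samples)))
    stop("host and environmental bed ids differ", call. = FALSE)
  env_samples <- env_samples[beds]
  co <- ord$coordinates
  if (!is.null(axes)) co <- co[, axes, drop = FALSE]
  centroid <- function(ids) {
    miss <- setdiff(ids, rownames(co))
    if (length(miss))
      stop("samples not in ordination: ", paste(miss, collapse = ", "),
           call. = FALSE)
    colMeans(co[ids, , drop = FALSE])
  }
  hc <- t(vapply(host_samples, centroid, numeric(ncol(co))))
  ec <- t(vapply(env_samples, centroid, numeric(ncol(co))))
  pair_dist <- function(perm) mean(sqrt(rowSums((hc - ec[perm, ,
                                                drop = FALSE])^2)))
  observed <- pair_dist(seq_along(beds))
  set.seed(seed)
  k <- length(beds)
  rand_mismatch <- function() {          # non-identity bed pairing
    repeat {
      perm <- sample.int(k)
      if (!all(perm == seq_len(k))) return(perm)
    }
  }
  stats <- replicate(n_perm, pair_dist(rand_mismatch()))
  p <- (1 + sum(stats <= observed + 1e-12)) / (1 + n_perm)
  group_test_result(observed, p, n_perm, "centroid_delta",
                    null_distribution = stats)
}
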