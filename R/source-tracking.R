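#' Bayesian microbial source tracking
#'
#' Attributes each sink (host) community to a set of known environmental
#' sources plus an "unknown" component, with a collapsed Gibbs sampler over
#' per-sequence latent source assignments. Known sources are summarized by
#' their (collapsed, smoothed) taxon profiles; the unknown source's profile
#' accumulates from the current assignments, which lets taxa unexplained by
#' any known environment be absorbed rather than force-fitted. Reported
#' proportions are posterior means over retained draws and restarts.
#'
#' @param sinks an [otu_table] of sink communities (taxa x sinks), rarefied
#'   to a common depth upstream.
#' @param sources an [otu_table] of source samples over the same taxon list.
#' @param source_groups environment label per source column (e.g. `"water"`,
#'   `"sediment"`); columns sharing a label are pooled.
#' @param alpha1 per-taxon pseudocount of the known-source profiles.
#' @param alpha2 per-taxon pseudocount of the unknown source.
#' @param beta Dirichlet prior on the sink's mixing proportions.
#' @param n_burnin burn-in sweeps per restart.
#' @param n_draws retained draws per restart.
#' @param spacing sweeps between retained draws.
#' @param restarts independent chain restarts.
#' @param seed RNG seed (the sampler is deterministic given the seed).
#' @return a `source_attribution`: list with `proportions` and
#'   `posterior_sd` (sinks x sources+unknown matrices) and `n_draws_total`.
#' @export
fit_sources <- function(sinks, sources, source_groups,
                        alpha1 = 0.001, alpha2 = 0.1, beta = 10,
                        n_burnin = 100, n_draws = 25, spacing = 10,
                        restarts = 10, seed = 1) {
  sinks <- as_otu_table(sinks); sources <- as_otu_table(sources)
  if (!identical(rownames(sinks), rownames(sources))) {
    off <- union(setdiff(rownames(sinks), rownames(sources)),
                 setdiff(rownames(sources), rownames(sinks)))
    if (length(off))
      stop("taxon universe mismatch between sinks and sources: ",
           paste(utils::head(off, 10), collapse = ", "), call. = FALSE)
    sources <- otu_table(unclass(sources)[rownames(sinks), , drop = FALSE])
  }
  source_groups <- as.character(source_groups)
  stopifnot(length(source_groups) == ncol(sources))
  envs <- unique(source_groups)
  m <- vapply(envs, function(e)
    rowSums(unclass(sources)[, source_groups == e, drop = FALSE]),
    numeric(nrow(sources)))
  if (any(colSums(m) == 0))
    stop("empty source group: ",
         paste(envs[colSums(m) == 0], collapse = ", "), call. = FALSE)
  storage.mode(m) <- "integer"

  labels <- c(envs, "unknown")
  props <- sds <- matrix(NA_real_, ncol(sinks), length(labels),
                         dimnames = list(colnames(sinks), labels))
  with_seed(seed, {
    for (j in seq_len(ncol(sinks))) {
      x <- unclass(sinks)[, j]
      if (sum(x) == 0) stop("empty sink: ", colnames(sinks)[j],
                            call. = FALSE)
      tokens <- rep.int(seq_along(x) - 1L, x)
      draws <- st_gibbs_sink(as.integer(tokens), m, alpha1, alpha2, beta,
                             as.integer(n_burnin), as.integer(n_draws),
                             as.integer(spacing), as.integer(restarts))
      props[j, ] <- colMeans(draws)
      sds[j, ] <- apply(draws, 2, stats::sd)
    }
  })
  structure(list(proportions = props, posterior_sd = sds,
                 n_draws_total = restarts * n_draws,
                 hyperparameters = list(alpha1 = alpha1, alpha2 = alpha2,
                                        beta = beta)),
            class = "source_attribution")
}

#' @export
print.source_attribution <- function(x, ...) {
  cat(sprintf("source_attribution: %d sinks x %d sources (%d draws each)\n",
              nrow(x$proportions), ncol(x$proportions), x$n_draws_total))
  print(round(utils::head(x$proportions), 3))
  invisible(x)
}

#' Select each host compartment's primary colonization source
#'
#' For every host community type among the sinks, the named (non-unknown)
#' source with the largest median attributed proportion. An exact tie is an
#' error demanding an explicit override, since the downstream differential
#' abundance comparison hinges on this choice.
#'
#' @param attribution a `source_attribution` from [fit_sources()].
#' @param metadata sample metadata (see [read_sample_metadata()]) covering
#'   every sink.
#' @return named character vector: community type -> source id, with the
#'   per-type median proportions in `attr(, "medians")`.
#' @export
select_primary_source <- function(attribution, metadata) {
  props <- attribution$proportions
  miss <- setdiff(rownames(props), metadata$sample_id)
  if (length(miss))
    stop("sinks without metadata: ", paste(miss, collapse = ", "),
         call. = FALSE)
  type <- metadata$community_type[match(rownames(props),
                                        metadata$sample_id)]
  named <- setdiff(colnames(props), "unknown")
  meds <- t(vapply(unique(type), function(ct)
    apply(props[type == ct, named, drop = FALSE], 2, stats::median),
    numeric(length(named))))
  rownames(meds) <- unique(type)
  out <- character(nrow(meds))
  for (i in seq_len(nrow(meds))) {
    top <- which(meds[i, ] == max(meds[i, ]))
    if (length(top) > 1)
      stop("tie between sources ", paste(named[top], collapse = " and "),
           " for community type '", rownames(meds)[i],
           "'; pass an explicit choice", call. = FALSE)
    out[i] <- named[top]
  }
  names(out) <- rownames(meds)
  attr(out, "medians") <- meds
  out
}
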