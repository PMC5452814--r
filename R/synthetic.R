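#' Synthetic source community profiles
#'
#' Draws `n_sources` relative-abundance vectors from a symmetric
#' Dirichlet(`concentration`) over `n_taxa` taxa. Small concentrations give
#' sparse, well-separated profiles (distinct environments); large ones give
#' near-uniform profiles.
#'
#' @param n_sources number of source environments (>= 1).
#' @param n_taxa number of taxa (>= 2).
#' @param concentration Dirichlet concentration (> 0).
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return matrix (sources x taxa), rows summing to 1, with taxon colnames
#'   `otu_1..` and source rownames `source_1..`.
#' @export
make_source_profiles <- function(n_sources, n_taxa, concentration = 0.5,
                                 seed = 1) {
  stopifnot(n_sources >= 1, n_taxa >= 2)
  if (concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  with_seed(seed, {
    m <- rdirichlet(n_sources, concentration, k = n_taxa)
    dimnames(m) <- list(paste0("source_", seq_len(n_sources)),
                        paste0("otu_", seq_len(n_taxa)))
    m
  })
}

#' Synthetic sink communities as mixtures of sources
#'
#' Each sink community is a multinomial draw of size `depth` from the mixed
#' profile `sum_k mixing_k * profile_k`, where the final mixing component
#' weights an "unknown" profile not represented among the known sources. The
#' true mixing proportions are recorded for parameter-recovery tests.
#'
#' @param sources matrix from [make_source_profiles()] (sources x taxa).
#' @param mixing numeric vector of length `nrow(sources) + 1` (last entry =
#'   unknown), or a matrix with one such row per sink; rows must sum to 1.
#' @param unknown_profile probability vector over the same taxa (by default a
#'   Dirichlet draw supported on a reserved final block of taxa, which keeps
#'   the unknown component identifiable).
#' @param depth sequencing depth per sink.
#' @param n_sinks number of sink samples.
#' @param seed RNG seed.
#' @return list with `table` (an [otu_table], sinks as columns) and `truth`
#'   (list with `mixing_proportions` matrix and `unknown_profile`).
#' @export
make_mixed_sinks <- function(sources, mixing, unknown_profile = NULL,
                             depth = 2500, n_sinks = 10, seed = 1) {
  stopifnot(depth >= 1, n_sinks >= 1)
  n_src <- nrow(sources)
  n_taxa <- ncol(sources)
  if (is.null(dim(mixing)))
    mixing <- matrix(mixing, n_sinks, length(mixing), byrow = TRUE)
  if (ncol(mixing) != n_src + 1)
    stop("mixing must have nrow(sources) + 1 components (last = unknown)",
         call. = FALSE)
  if (nrow(mixing) != n_sinks)
    stop("mixing rows must match n_sinks", call. = FALSE)
  if (any(abs(rowSums(mixing) - 1) > 1e-8))
    stop("mixing rows must sum to 1", call. = FALSE)
  with_seed(seed, {
    if (is.null(unknown_profile)) {
      # reserved block: last ~20% of taxa
      block <- seq.int(max(1L, floor(0.8 * n_taxa) + 1L), n_taxa)
      unknown_profile <- numeric(n_taxa)
      unknown_profile[block] <- rdirichlet(1, 0.5, k = length(block))
    }
    stopifnot(length(unknown_profile) == n_taxa)
    profiles <- rbind(sources, unknown = unknown_profile / sum(unknown_profile))
    counts <- matrix(0L, n_taxa, n_sinks,
                     dimnames = list(colnames(sources),
                                     paste0("sink_", seq_len(n_sinks))))
    for (j in seq_len(n_sinks)) {
      p <- as.numeric(mixing[j, ] %*% profiles)
      counts[, j] <- stats::rmultinom(1, depth, p)
    }
    rownames(mixing) <- colnames(counts)
    colnames(mixing) <- c(rownames(sources), "unknown")
    list(table = otu_table(counts),
         truth = list(mixing_proportions = mixing,
                      unknown_profile = unknown_profile))
  })
}

#' Spike taxa with known fold changes into host vs environment tables
#'
#' Environmental samples have expected count `depth * base_profile`; host
#' samples have the same except spiked taxa, whose expectation is multiplied
#' by `2^log2FC`. Counts are negative binomial with variance
#' `mu + dispersion * mu^2` (`dispersion = 0` gives Poisson), the same
#' parameterization the differential-abundance stage fits.
#'
#' @param base_profile probability vector over taxa (names optional; default
#'   names `otu_1..`).
#' @param spiked named numeric vector: taxon -> true log2 fold change
#'   (host over environment). May be empty.
#' @param n_host,n_env group sample sizes.
#' @param depth expected library size.
#' @param dispersion NB overdispersion (>= 0).
#' @param seed RNG seed.
#' @return list with `table` (an [otu_table], host columns first), `groups`
#'   (factor `"host"`/`"env"` per column), and `truth` (`spiked_taxa`).
#' @export
spike_differential_taxa <- function(base_profile, spiked = numeric(),
                                    n_host = 15, n_env = 15, depth = 2500,
                                    dispersion = 0.2, seed = 1) {
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  n_taxa <- length(base_profile)
  taxa <- names(base_profile)
  if (is.null(taxa)) taxa <- paste0("otu_", seq_len(n_taxa))
  if (length(spiked)) {
    bad <- setdiff(names(spiked), taxa)
    if (length(bad))
      stop("spiked taxa not in base profile: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  base_profile <- base_profile / sum(base_profile)
  mu_env <- depth * base_profile
  mu_host <- mu_env
  mu_host[match(names(spiked), taxa)] <-
    mu_host[match(names(spiked), taxa)] * 2^spiked
  draw <- function(mu, n) {
    m <- if (dispersion == 0)
      matrix(stats::rpois(n_taxa * n, mu), n_taxa, n)
    else
      matrix(stats::rnbinom(n_taxa * n, mu = mu, size = 1 / dispersion),
             n_taxa, n)
    m
  }
  with_seed(seed, {
    counts <- cbind(draw(mu_host, n_host), draw(mu_env, n_env))
    dimnames(counts) <- list(taxa, c(paste0("host_", seq_len(n_host)),
                                     paste0("env_", seq_len(n_env))))
    list(table = otu_table(counts),
         groups = factor(rep(c("host", "env"), c(n_host, n_env)),
                         levels = c("env", "host")),
         truth = list(spiked_taxa = spiked))
  })
}

#' Random rooted tree over given taxa
#'
#' Coalescent-style random joins with exponential waiting times
#' ([ape::rcoal()]), deterministic under the seed.
#'
#' @param taxon_ids unique taxon labels (>= 2).
#' @param seed RNG seed.
#' @return a rooted binary [ape::phylo] whose tips are `taxon_ids`.
#' @export
make_random_tree <- function(taxon_ids, seed = 1) {
  if (anyDuplicated(taxon_ids))
    stop("duplicate taxon ids", call. = FALSE)
  if (length(taxon_ids) < 2) stop("need >= 2 taxa", call. = FALSE)
  with_seed(seed, ape::rcoal(length(taxon_ids), tip.label = taxon_ids))
}

#' Toy metabolic network with known seed sets
#'
#' Constructs a compound graph whose strongly-connected-component
#' condensation is a DAG with exactly `n_seed_components` source components
#' (each a single compound or an explicit directed cycle of size up to
#' `max_scc_size`) and `n_downstream` additional compounds, each reachable
#' from at least one source component. The exact seed set is returned as
#' ground truth.
#'
#' @param n_seed_components number of source SCCs (>= 1).
#' @param n_downstream number of reachable non-source compounds (>= 1).
#' @param max_scc_size maximal source-component size (>= 1).
#' @param seed RNG seed.
#' @param prefix compound-id prefix (lets several networks share or avoid a
#'   compound namespace).
#' @return list with `reactions` (list of [reaction_record()]s) and `truth`
#'   (list with `seed_components`: list of compound-id vectors, and `seeds`:
#'   named confidence vector `1/|component|`).
#' @export
make_toy_network <- function(n_seed_components, n_downstream = 3,
                             max_scc_size = 1, seed = 1, prefix = "C") {
  stopifnot(n_seed_components >= 1, n_downstream >= 1, max_scc_size >= 1)
  with_seed(seed, {
    reactions <- list()
    rx <- 0L
    add <- function(s, p) {
      rx <<- rx + 1L
      reactions[[rx]] <<- reaction_record(sprintf("%s_R%d", prefix, rx), s, p)
    }
    components <- vector("list", n_seed_components)
    for (k in seq_len(n_seed_components)) {
      size <- sample.int(max_scc_size, 1)
      comp <- sprintf("%s_s%d_%d", prefix, k, seq_len(size))
      if (size > 1) {
        for (i in seq_len(size)) add(comp[i], comp[if (i == size) 1 else i + 1])
      }
      components[[k]] <- comp
    }
    seed_pool <- unlist(components)
    downstream <- sprintf("%s_d%d", prefix, seq_len(n_downstream))
    for (i in seq_len(n_downstream)) {
      parents <- c(seed_pool, downstream[seq_len(i - 1)])
      add(parents[sample.int(length(parents), 1)], downstream[i])
    }
    # singleton source components never appear as products; make sure they
    # exist in the network by feeding a downstream node from each
    singles <- seed_pool[!seed_pool %in% unlist(lapply(reactions,
                                                       `[[`, "products"))]
    for (s in setdiff(singles, unlist(lapply(reactions, `[[`, "substrates"))))
      add(s, downstream[sample.int(n_downstream, 1)])
    conf <- unlist(lapply(components, function(c)
      stats::setNames(rep(1 / length(c), length(c)), c)))
    list(reactions = reactions,
         truth = list(seed_components = components, seeds = conf))
  })
}

#' Bed-structured host and environment communities
#'
#' Emulates a blocked field design: every bed perturbs a shared base profile
#' by i.i.d. lognormal factors (`sdlog = bed_effect_sd`), and host and
#' environmental samples of the same bed share that perturbed profile. With
#' `bed_effect_sd > 0` the within- versus between-bed centroid test has a
#' true positive; with 0 beds are exchangeable.
#'
#' @param n_beds number of beds (>= 2); beds are nested two-per-site.
#' @param n_host,n_env samples per bed and type.
#' @param n_taxa taxa in the base profile.
#' @param bed_effect_sd lognormal sd of per-bed perturbations (>= 0).
#' @param depth sequencing depth.
#' @param concentration Dirichlet concentration of the base profile.
#' @param seed RNG seed.
#' @return list with `table` (an [otu_table]), `metadata` (sample_id,
#'   community_type (`"leaf"` hosts / `"water"` environment), bed_id,
#'   site_id), and `truth` (`bed_effect_sd`).
#' @export
make_bedded_communities <- function(n_beds = 6, n_host = 3, n_env = 3,
                                    n_taxa = 150, bed_effect_sd = 1,
                                    depth = 2500, concentration = 0.5,
                                    seed = 1) {
  stopifnot(n_beds >= 2, bed_effect_sd >= 0)
  with_seed(seed, {
    base <- as.numeric(rdirichlet(1, concentration, k = n_taxa))
    taxa <- paste0("otu_", seq_len(n_taxa))
    counts <- NULL
    meta <- NULL
    for (b in seq_len(n_beds)) {
      pert <- base * stats::rlnorm(n_taxa, 0, bed_effect_sd)
      pert <- pert / sum(pert)
      n_b <- n_host + n_env
      cb <- stats::rmultinom(n_b, depth, pert)
      ids <- sprintf("bed%d_%s%d", b,
                     rep(c("host", "env"), c(n_host, n_env)),
                     c(seq_len(n_host), seq_len(n_env)))
      colnames(cb) <- ids
      counts <- cbind(counts, cb)
      meta <- rbind(meta, data.frame(
        sample_id = ids,
        community_type = rep(c("leaf", "water"), c(n_host, n_env)),
        bed_id = sprintf("bed%d", b),
        site_id = sprintf("site%d", ceiling(b / 2)),
        stringsAsFactors = FALSE))
    }
    rownames(counts) <- taxa
    list(table = otu_table(counts), metadata = validate_sample_metadata(meta),
         truth = list(bed_effect_sd = bed_effect_sd))
  })
}

#' Synthetic habitat-filtering scenario for the cooccurrence-vs-competition
#' contrast
#'
#' `type = "structured"` emulates a root-like community: enriched OTUs draw
#' their seed compounds from a small number of shared resource pools and
#' occur in exactly the samples that supply their pool (up to occupancy
#' noise), so predicted resource overlap and cooccurrence are coupled.
#' `type = "random"` emulates a leaf-like community: seed sets are random
#' compound subsets and occupancy is i.i.d., so no association exists.
#'
#' @param type `"structured"` or `"random"`.
#' @param n_otus number of enriched OTUs.
#' @param n_samples number of host samples.
#' @param n_pools number of resource pools (structured case).
#' @param pool_size compounds per pool.
#' @param occupancy baseline probability a pool (or OTU) is present in a
#'   sample.
#' @param noise probability an OTU's presence state is flipped.
#' @param seed RNG seed.
#' @return list with `reactions` (named list otu -> reaction records),
#'   `table` (presence counts, OTUs x samples), and `truth` (`pools`: otu ->
#'   pool assignment or NA).
#' @export
make_assembly_scenario <- function(type = c("structured", "random"),
                                   n_otus = 30, n_samples = 40, n_pools = 4,
                                   pool_size = 6, occupancy = 0.5,
                                   noise = 0.05, seed = 1) {
  type <- match.arg(type)
  with_seed(seed, {
    otus <- paste0("otu_", seq_len(n_otus))
    compounds <- paste0("cpd_", seq_len(n_pools * pool_size))
    pool_of <- rep(NA_integer_, n_otus)
    seeds <- vector("list", n_otus)
    if (type == "structured") {
      pool_of <- rep(seq_len(n_pools), length.out = n_otus)
      pool_cpds <- split(compounds, rep(seq_len(n_pools), each = pool_size))
      for (i in seq_len(n_otus)) {
        own <- pool_cpds[[pool_of[i]]]
        seeds[[i]] <- c(own, sprintf("cpd_priv_%d", i))
      }
      avail <- matrix(stats::runif(n_pools * n_samples) < occupancy,
                      n_pools, n_samples)
      pres <- avail[pool_of, , drop = FALSE]
    } else {
      for (i in seq_len(n_otus))
        seeds[[i]] <- c(sample(compounds, pool_size), sprintf("cpd_priv_%d", i))
      pres <- matrix(stats::runif(n_otus * n_samples) < occupancy,
                     n_otus, n_samples)
    }
    flip <- matrix(stats::runif(n_otus * n_samples) < noise,
                   n_otus, n_samples)
    pres <- xor(pres, flip)
    counts <- matrix(0L, n_otus, n_samples,
                     dimnames = list(otus, paste0("samp_", seq_len(n_samples))))
    counts[pres] <- 1L + stats::rpois(sum(pres), 20)
    # a network per OTU whose seed set is exactly the chosen compounds:
    # every seed compound feeds a private downstream chain
    reactions <- stats::setNames(vector("list", n_otus), otus)
    for (i in seq_len(n_otus)) {
      down <- sprintf("down_%d_%d", i, 1:2)
      recs <- list()
      for (k in seq_along(seeds[[i]]))
        recs[[k]] <- reaction_record(sprintf("%s_R%d", otus[i], k),
                                     seeds[[i]][k],
                                     down[1 + (k %% 2)])
      recs[[length(recs) + 1]] <- reaction_record(
        sprintf("%s_Rlink", otus[i]), down[1], down[2])
      reactions[[i]] <- recs
    }
    list(reactions = reactions, table = otu_table(counts),
         truth = list(pools = stats::setNames(pool_of, otus),
                      seed_sets = stats::setNames(seeds, otus)))
  })
}
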