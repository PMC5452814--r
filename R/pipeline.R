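#' Default pipeline configuration
#'
#' Returns the frozen default profile of the analysis: rarefaction depth
#' 2,500; 1,000 permutations for every permutation test; BH significance
#' level 0.01; low-count filter at 5 total reads; source-tracking
#' hyperparameters `alpha1 = 0.001`, `alpha2 = 0.1`, `beta = 10` with 10
#' restarts, 100 burn-in sweeps and 25 retained draws spaced 10 apart; and
#' an explicit seed for every stage that consumes randomness.
#'
#' @param ... named overrides, e.g. `depth = 1000` or
#'   `seeds = list(rarefy = 7)` (lists are merged field-wise).
#' @return a `pipeline_config` list.
#' @export
default_config <- function(...) {
  cfg <- list(
    inputs = list(otu_table = NULL, metadata = NULL, tree = NULL,
                  reactions = NULL),
    output_dir = "results/pipeline",
    depth = 2500,
    n_perm = 1000,
    alpha = 0.01,
    min_total = 5,
    filter_by = "total",
    mantel_method = "pearson",
    sourcetracker = list(alpha1 = 0.001, alpha2 = 0.1, beta = 10,
                         n_burnin = 100, n_draws = 25, spacing = 10,
                         restarts = 10, site_resolved = TRUE),
    seeds = list(rarefy = 101, grouptests = 102, sourcetracking = 103,
                 mantel = 104),
    stages = list(diversity = TRUE, grouptests = TRUE,
                  sourcetracking = TRUE, diffabund = TRUE,
                  reverse_ecology = TRUE))
  modifyList(structure(cfg, class = "pipeline_config"), list(...))
}

#' Read a pipeline configuration from YAML
#'
#' Values found in the file override the frozen defaults of
#' [default_config()].
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' Returns findings rather than raising: missing input files, label
#' inconsistencies between table, metadata and tree, and parameter values
#' diverging from the default analysis profile (flagged `"divergent"`, not
#' wrong).
#'
#' @param config a `pipeline_config`.
#' @return character vector of findings (empty when clean).
#' @export
validate_config <- function(config) {
  findings <- character(0)
  note <- function(...) findings <<- c(findings, sprintf(...))
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (!is.null(p) && !file.exists(p)) note("missing input file [%s]: %s",
                                             nm, p)
  }
  ref <- default_config()
  for (par in c("depth", "n_perm", "alpha", "min_total")) {
    if (!identical(as.numeric(config[[par]]), as.numeric(ref[[par]])))
      note("divergent parameter %s = %s (default profile uses %s)",
           par, config[[par]], ref[[par]])
  }
  tab <- meta <- tree <- NULL
  try_read <- function(expr) tryCatch(expr, error = function(e) {
    note("%s", conditionMessage(e)); NULL })
  if (!is.null(config$inputs$otu_table) &&
      file.exists(config$inputs$otu_table))
    tab <- try_read(read_otu_table(config$inputs$otu_table))
  if (!is.null(config$inputs$metadata) && file.exists(config$inputs$metadata))
    meta <- try_read(read_sample_metadata(config$inputs$metadata))
  if (!is.null(config$inputs$tree) && file.exists(config$inputs$tree))
    tree <- try_read(read_newick(config$inputs$tree))
  if (!is.null(tab) && !is.null(meta)) {
    orphan <- setdiff(sample_ids(tab), meta$sample_id)
    if (length(orphan))
      note("samples without metadata: %s", paste(orphan, collapse = ", "))
  }
  if (!is.null(tab) && !is.null(tree)) {
    missing_tips <- setdiff(taxon_ids(tab), tree$tip.label)
    if (length(missing_tips))
      note("%d taxa absent from the tree (phylogenetic stages will fail for them)",
           length(missing_tips))
  }
  findings
}

#' Simulate a full host/environment study
#'
#' Generates a coherent synthetic data set with the structure every pipeline
#' stage assumes: two environmental source communities (water, sediment) with
#' distinct Dirichlet profiles; per-bed lognormal perturbations shared by the
#' bed's host and environmental samples; leaf sinks dominated by water and
#' root sinks by sediment (Dirichlet-multinomial mixtures with an unknown
#' component on a reserved taxon block); host-enriched/depleted taxa spiked
#' with known log2 fold changes; a random coalescent tree; and per-OTU toy
#' reaction networks in which the spiked-enriched root taxa draw seed
#' compounds from shared resource pools (the habitat-filtering signal) while
#' leaf taxa get random seed sets.
#'
#' @param n_sites number of sites (two beds each).
#' @param n_per_type samples per bed per community type.
#' @param n_taxa taxon universe size.
#' @param depth sequencing depth of every sample.
#' @param bed_effect_sd lognormal sd of the per-bed perturbation.
#' @param n_spiked number of enriched and of depleted taxa per compartment.
#' @param log2fc spiked absolute log2 fold change.
#' @param unknown_fraction mixing weight of the unknown component in hosts.
#' @param seed RNG seed.
#' @return list with `table` ([otu_table]), `metadata`, `tree`, `reactions`
#'   (named list otu -> records), and `truth` (mixing, spiked taxa, pools).
#' @export
make_study <- function(n_sites = 4, n_per_type = 3, n_taxa = 220,
                       depth = 3000, bed_effect_sd = 0.3, n_spiked = 10,
                       log2fc = 3, unknown_fraction = 0.1, seed = 1) {
  with_seed(seed, {
    taxa <- paste0("otu_", seq_len(n_taxa))
    known_block <- seq_len(floor(0.85 * n_taxa))
    unk_block <- setdiff(seq_len(n_taxa), known_block)
    water <- sediment <- numeric(n_taxa)
    # concentration 0.7: uneven but not so heavy-tailed that finite source
    # training at depth ~2,500 misses a large share of the community
    water[known_block] <- rdirichlet(1, 0.7, k = length(known_block))
    sediment[known_block] <- rdirichlet(1, 0.7, k = length(known_block))
    unknown <- numeric(n_taxa)
    unknown[unk_block] <- rdirichlet(1, 0.5, k = length(unk_block))
    # known-source mixing weights (renormalized; the unknown component gets
    # unknown_fraction of each host community)
    mix <- list(leaf = c(water = 0.85, sediment = 0.15),
                root = c(water = 0.3, sediment = 0.7))
    mix <- lapply(mix, function(m) m / sum(m))
    # spiked taxa: distinct sets per compartment, drawn from the known
    # block and pinned to a low base abundance (host-responsive taxa are
    # rare in the environment, so enrichment does not distort the host
    # community's source signature)
    pick <- sample(known_block, 4 * n_spiked)
    water[pick] <- sediment[pick] <- 0.002
    water <- water / sum(water)
    sediment <- sediment / sum(sediment)
    spiked <- list(
      leaf = stats::setNames(rep(c(log2fc, -log2fc), each = n_spiked),
                             taxa[pick[seq_len(2 * n_spiked)]]),
      root = stats::setNames(rep(c(log2fc, -log2fc), each = n_spiked),
                             taxa[pick[2 * n_spiked + seq_len(2 * n_spiked)]]))
    # root-enriched taxa are split between two shared resource pools; a
    # root sample carries a pool's taxa only when it supplies that pool
    root_enr <- names(spiked$root)[spiked$root > 0]
    pool_of_enr <- 1 + (seq_along(root_enr) %% 2)
    pool_occupancy <- 0.55
    # leaf colonization is patchy but unstructured: enriched taxa arrive
    # independently, with no resource-pool coupling
    leaf_enr <- names(spiked$leaf)[spiked$leaf > 0]
    leaf_occupancy <- 0.7
    counts <- NULL; meta <- NULL
    mixing_truth <- list()
    for (s in seq_len(n_sites)) {
      for (bi in 1:2) {
        bed <- sprintf("site%d_bed%d", s, bi)
        pert <- stats::rlnorm(n_taxa, 0, bed_effect_sd)
        w_b <- water * pert / sum(water * pert)
        sd_b <- sediment * pert / sum(sediment * pert)
        profiles <- list(water = w_b, sediment = sd_b)
        for (type in c("water", "sediment", "leaf", "root")) {
          if (type %in% c("water", "sediment")) {
            p <- profiles[[type]]
            cb <- stats::rmultinom(n_per_type, depth, p)
          } else {
            known <- mix[[type]]["water"] * w_b +
              mix[[type]]["sediment"] * sd_b
            p <- (1 - unknown_fraction) * known + unknown_fraction * unknown
            lfc <- spiked[[type]]
            idx <- match(names(lfc), taxa)
            p[idx] <- p[idx] * 2^lfc
            mixing_truth[[paste(bed, type, sep = "_")]] <-
              c(mix[[type]] * (1 - unknown_fraction),
                unknown = unknown_fraction)
            cb <- matrix(0L, n_taxa, n_per_type)
            for (j in seq_len(n_per_type)) {
              pj <- p
              if (type == "root") {
                # habitat filtering: each root sample supplies a random
                # subset of resource pools; enriched taxa persist only where
                # their pool's resources are available
                avail <- stats::runif(2) < pool_occupancy
                off <- root_enr[!avail[pool_of_enr]]
              } else {
                off <- leaf_enr[stats::runif(length(leaf_enr)) >
                                  leaf_occupancy]
              }
              pj[match(off, taxa)] <- pj[match(off, taxa)] * 0.02
              cb[, j] <- stats::rmultinom(1, depth, pj / sum(pj))
            }
          }
          ids <- sprintf("%s_%s_%d", bed, type, seq_len(n_per_type))
          colnames(cb) <- ids
          counts <- cbind(counts, cb)
          meta <- rbind(meta, data.frame(
            sample_id = ids, community_type = type, bed_id = bed,
            site_id = sprintf("site%d", s), stringsAsFactors = FALSE))
        }
      }
    }
    rownames(counts) <- taxa
    tree <- ape::rcoal(n_taxa, tip.label = taxa)
    # reverse-ecology truth: root-enriched taxa share the two resource
    # pools that drove their occurrence above; leaf-enriched taxa get
    # random seed sets
    leaf_enriched <- names(spiked$leaf)[spiked$leaf > 0]
    compounds <- paste0("cpd_", 1:24)
    pools <- split(compounds, rep(1:2, each = 12))
    reactions <- list()
    mk_net <- function(otu, seeds) {
      recs <- list()
      for (k in seq_along(seeds))
        recs[[k]] <- reaction_record(sprintf("%s_R%d", otu, k), seeds[k],
                                     sprintf("down_%s", otu))
      recs
    }
    pool_truth <- c()
    for (i in seq_along(root_enr)) {
      pool_truth[root_enr[i]] <- pool_of_enr[i]
      reactions[[root_enr[i]]] <-
        mk_net(root_enr[i],
               c(pools[[pool_of_enr[i]]], sprintf("cpd_priv_%s",
                                                  root_enr[i])))
    }
    for (otu in leaf_enriched)
      reactions[[otu]] <- mk_net(otu, c(sample(compounds, 6),
                                        sprintf("cpd_priv_%s", otu)))
    list(table = otu_table(counts),
         metadata = validate_sample_metadata(meta),
         tree = tree, reactions = reactions,
         truth = list(mixing_proportions = mixing_truth,
                      spiked_taxa = spiked, pools = pool_truth,
                      bed_effect_sd = bed_effect_sd))
  })
}

#' Write a synthetic study bundle to disk
#'
#' Emits the full set of pipeline inputs produced by [make_study()]: OTU
#' table (tsv), sample metadata (tsv), newick tree, combined reaction file,
#' and the ground truth as JSON (clearly labelled synthetic).
#'
#' @param dir output directory (created).
#' @param study optional existing [make_study()] result.
#' @param ... passed to [make_study()].
#' @return invisible named vector of written paths.
#' @export
write_synthetic_bundle <- function(dir, study = NULL, ...) {
  if (is.null(study)) study <- make_study(...)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu_table = file.path(dir, "synthetic_otu_table.tsv"),
             metadata = file.path(dir, "synthetic_metadata.tsv"),
             tree = file.path(dir, "synthetic_tree.nwk"),
             reactions = file.path(dir, "synthetic_reactions.tsv"),
             truth = file.path(dir, "synthetic_truth.json"))
  write_otu_table(study$table, paths["otu_table"])
  utils::write.table(study$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_newick(study$tree, paths["tree"])
  write_reactions(study$reactions, paths["reactions"])
  truth <- study$truth
  truth$spiked_taxa <- lapply(truth$spiked_taxa, as.list)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: rarefaction; alpha diversity; Canberra (and UniFrac,
#' when a tree is supplied) distances with PCoA; ANOSIM (restricted to
#' within-site permutations) and dispersion tests of host versus environment
#' community types; Bayesian source tracking of host sinks on the
#' environmental sources; primary-source selection; the within- versus
#' between-bed centroid proximity test of each host compartment against its
#' primary source; source-guided differential abundance (low-count filter,
#' TMM, NB GLM + LRT, BH, calls); and, when reaction networks are supplied,
#' seed sets, the competitive dissimilarity matrix, cooccurrence of enriched
#' OTUs, and (partial) Mantel tests. Per-stage outputs are written under
#' `config$output_dir` together with a JSON manifest of parameters, seeds
#' and input checksums; a rerun with the same config is bit-identical.
#'
#' @param config a `pipeline_config` (see [default_config()]); inputs may be
#'   file paths (`config$inputs`) or in-memory objects passed via `study`.
#' @param study optional [make_study()]-shaped list (`table`, `metadata`,
#'   `tree`, `reactions`) overriding file inputs.
#' @return invisible list of stage results (also written to disk).
#' @export
run_pipeline <- function(config = default_config(), study = NULL) {
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  inputs <- stage("read_inputs", {
    if (!is.null(study)) study
    else list(
      table = read_otu_table(config$inputs$otu_table),
      metadata = read_sample_metadata(config$inputs$metadata),
      tree = if (!is.null(config$inputs$tree))
        read_newick(config$inputs$tree),
      reactions = if (!is.null(config$inputs$reactions))
        read_reaction_sets(config$inputs$reactions))
  })
  meta <- inputs$metadata
  type_of <- function(ids) meta$community_type[match(ids, meta$sample_id)]

  rar <- stage("rarefy",
               rarefy(inputs$table, config$depth, seed = config$seeds$rarefy))
  write_otu_table(rar, file.path(out_dir, "rarefied_otu_table.tsv"))
  results$rarefied <- rar

  if (isTRUE(config$stages$diversity)) {
    alpha <- stage("alpha_diversity", alpha_diversity(rar, inputs$tree))
    write_results(alpha, file.path(out_dir, "alpha_diversity.tsv"))
    dist_can <- stage("canberra", canberra_matrix(rar))
    write_dist_matrix(dist_can, file.path(out_dir, "canberra.tsv"))
    results$alpha <- alpha
    results$canberra <- dist_can
    if (!is.null(inputs$tree)) {
      results$unifrac <- stage("unifrac", unifrac_matrix(rar, inputs$tree))
      write_dist_matrix(results$unifrac, file.path(out_dir, "unifrac.tsv"))
    }
    ord <- stage("pcoa", pcoa(dist_can))
    utils::write.table(
      data.frame(sample_id = rownames(ord$coordinates),
                 signif(ord$coordinates[, seq_len(min(5,
                   ncol(ord$coordinates))), drop = FALSE], 6)),
      file.path(out_dir, "pcoa_coordinates.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$ordination <- ord
  }

  if (isTRUE(config$stages$grouptests)) {
    if (!isTRUE(config$stages$diversity))
      stop("pipeline stage 'grouptests' needs the diversity stage enabled",
           call. = FALSE)
    ids <- sample_ids(rar)
    groups <- type_of(ids)
    strata <- meta$site_id[match(ids, meta$sample_id)]
    results$anosim <- stage("anosim",
      anosim(results$canberra, groups, strata = strata,
             n_perm = config$n_perm, seed = config$seeds$grouptests))
    results$permdisp <- stage("permdisp",
      permdisp(results$canberra, groups, n_perm = config$n_perm,
               seed = config$seeds$grouptests))
    # pairwise host-vs-environment contrasts (effect sizes of interest)
    results$anosim_pairwise <- list()
    for (pair in list(c("leaf", "water"), c("root", "sediment"))) {
      keep <- groups %in% pair
      if (length(unique(groups[keep])) == 2 &&
          all(table(groups[keep]) >= 2)) {
        sub <- dist_matrix(unclass(results$canberra)[keep, keep])
        results$anosim_pairwise[[paste(pair, collapse = "_vs_")]] <-
          stage("anosim_pairwise",
                anosim(sub, groups[keep], strata = strata[keep],
                       n_perm = config$n_perm,
                       seed = config$seeds$grouptests))
      }
    }
    write_results(c(list(
      anosim = results$anosim[c("statistic", "p_value", "n_permutations")],
      permdisp = results$permdisp[c("statistic", "p_value",
                                    "n_permutations")]),
      lapply(results$anosim_pairwise, function(x)
        x[c("statistic", "p_value", "n_permutations")])),
      file.path(out_dir, "group_tests.json"))
  }

  host_types <- intersect(c("leaf", "root"), unique(meta$community_type))
  env_types <- intersect(c("water", "sediment"), unique(meta$community_type))
  if (isTRUE(config$stages$sourcetracking) && length(host_types) &&
      length(env_types)) {
    ids <- sample_ids(rar)
    sink_ids <- ids[type_of(ids) %in% host_types]
    src_ids <- ids[type_of(ids) %in% env_types]
    st <- config$sourcetracker
    fit_one <- function(sinks, sources, groups, seed)
      fit_sources(sinks, sources, groups,
                  alpha1 = st$alpha1, alpha2 = st$alpha2, beta = st$beta,
                  n_burnin = st$n_burnin, n_draws = st$n_draws,
                  spacing = st$spacing, restarts = st$restarts, seed = seed)
    attribution <- stage("sourcetracking", {
      if (isTRUE(st$site_resolved)) {
        sites <- meta$site_id[match(sink_ids, meta$sample_id)]
        parts <- lapply(unique(sites), function(s) {
          sk <- sink_ids[sites == s]
          sc <- src_ids[meta$site_id[match(src_ids, meta$sample_id)] == s]
          fit_one(otu_table(unclass(rar)[, sk, drop = FALSE]),
                  otu_table(unclass(rar)[, sc, drop = FALSE]),
                  type_of(sc), seed = config$seeds$sourcetracking)
        })
        merged <- parts[[1]]
        merged$proportions <- do.call(rbind,
                                      lapply(parts, `[[`, "proportions"))
        merged$posterior_sd <- do.call(rbind,
                                       lapply(parts, `[[`, "posterior_sd"))
        merged$proportions <- merged$proportions[sink_ids, , drop = FALSE]
        merged$posterior_sd <- merged$posterior_sd[sink_ids, , drop = FALSE]
        merged
      } else {
        fit_one(otu_table(unclass(rar)[, sink_ids, drop = FALSE]),
                otu_table(unclass(rar)[, src_ids, drop = FALSE]),
                type_of(src_ids), seed = config$seeds$sourcetracking)
      }
    })
    results$source_attribution <- attribution
    write_results(data.frame(sink_id = rownames(attribution$proportions),
                             signif(attribution$proportions, 6),
                             check.names = FALSE),
                  file.path(out_dir, "source_proportions.tsv"))
    results$primary_source <- stage("primary_source",
                                    select_primary_source(attribution, meta))
    write_results(as.list(results$primary_source),
                  file.path(out_dir, "primary_sources.json"))

    if (isTRUE(config$stages$grouptests)) {
      results$centroid_tests <- list()
      for (ht in host_types) {
        env <- results$primary_source[[ht]]
        beds <- meta$bed_id
        by_bed <- function(tp) {
          keep <- meta$community_type == tp &
            meta$sample_id %in% rownames(results$ordination$coordinates)
          split(meta$sample_id[keep], beds[keep])
        }
        hb <- by_bed(ht); eb <- by_bed(env)
        shared_beds <- intersect(names(hb)[lengths(hb) > 0],
                                 names(eb)[lengths(eb) > 0])
        if (length(shared_beds) >= 2) {
          results$centroid_tests[[ht]] <- stage(
            paste0("centroid_", ht),
            centroid_proximity_test(results$ordination, hb[shared_beds],
                                    eb[shared_beds],
                                    n_perm = config$n_perm,
                                    seed = config$seeds$grouptests))
        }
      }
      if (length(results$centroid_tests))
        write_results(lapply(results$centroid_tests, function(x)
          x[c("statistic", "p_value", "n_permutations")]),
          file.path(out_dir, "centroid_tests.json"))
    }
  }

  if (isTRUE(config$stages$diffabund)) {
    if (is.null(results$primary_source))
      stop("pipeline stage 'diffabund' needs the sourcetracking stage",
           call. = FALSE)
    results$diffabund <- list()
    for (ht in host_types) {
      env <- results$primary_source[[ht]]
      hcols <- meta$sample_id[meta$community_type == ht]
      ecols <- meta$sample_id[meta$community_type == env]
      da <- stage(paste0("diffabund_", ht), differential_abundance(
        otu_table(unclass(inputs$table)[, hcols, drop = FALSE]),
        otu_table(unclass(inputs$table)[, ecols, drop = FALSE]),
        alpha = config$alpha, min_total = config$min_total,
        filter_by = config$filter_by))
      results$diffabund[[ht]] <- da
      write_results(da[, c("otu_id", "log2_fold_change", "p_value",
                           "p_adjusted", "call")],
                    file.path(out_dir, paste0("diffabund_", ht, ".tsv")))
    }
  }

  if (isTRUE(config$stages$reverse_ecology) &&
      !is.null(inputs$reactions) && length(results$diffabund)) {
    results$reverse_ecology <- list()
    for (ht in host_types) {
      da <- results$diffabund[[ht]]
      enriched <- da$otu_id[da$call == "enriched"]
      with_net <- intersect(enriched, names(inputs$reactions))
      if (length(with_net) < 4) next
      re <- stage(paste0("reverse_ecology_", ht), {
        nets <- lapply(with_net, function(o)
          build_compound_graph(inputs$reactions[[o]], otu_id = o))
        seeds <- lapply(nets, seed_set)
        C <- competition_matrix(seeds)
        # occurrence profiles across the host compartment's own samples
        ht_cols <- intersect(sample_ids(rar),
                             meta$sample_id[meta$community_type == ht])
        occ <- cooccurrence_matrix(
          otu_table(unclass(rar)[with_net, ht_cols, drop = FALSE]))
        mt <- mantel(occ, C, method = config$mantel_method,
                     n_perm = config$n_perm, seed = config$seeds$mantel)
        pm <- if (!is.null(inputs$tree)) {
          phy <- phylo_distance_matrix(inputs$tree, with_net)
          partial_mantel(occ, C, phy, method = config$mantel_method,
                         n_perm = config$n_perm,
                         seed = config$seeds$mantel)
        }
        list(seed_sets = seeds, competition = C, cooccurrence = occ,
             mantel = mt, partial_mantel = pm)
      })
      results$reverse_ecology[[ht]] <- re
      write_dist_matrix(re$competition,
                        file.path(out_dir,
                                  paste0("competition_", ht, ".tsv")))
      rep_out <- list(mantel = re$mantel[c("r", "p_value",
                                           "n_permutations", "method")])
      if (!is.null(re$partial_mantel))
        rep_out$partial_mantel <- re$partial_mantel[c("r", "p_value",
                                                      "n_permutations",
                                                      "method")]
      write_results(rep_out, file.path(out_dir,
                                       paste0("mantel_", ht, ".json")))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("habfilt")),
    parameters = config[c("depth", "n_perm", "alpha", "min_total",
                          "filter_by", "mantel_method")],
    sourcetracker = config$sourcetracker,
    seeds = config$seeds,
    input_checksums = if (!is.null(config$inputs$otu_table))
      as.list(tools::md5sum(unlist(Filter(Negate(is.null),
                                          config$inputs)))),
    outputs = list.files(out_dir))
  write_results(manifest, file.path(out_dir, "manifest.json"))
  invisible(results)
}
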