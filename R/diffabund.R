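#' Remove underpowered OTUs
#'
#' Drops OTUs detected fewer than `min_total` times across the compared
#' samples. The default reading counts total reads (`by = "total"`, the
#' edgeR-style filter); `by = "incidence"` instead counts the number of
#' samples in which the OTU appears.
#'
#' @param table an [otu_table].
#' @param min_total detection threshold (rows with value `< min_total` are
#'   removed; 0 disables filtering).
#' @param by `"total"` or `"incidence"`.
#' @return filtered [otu_table]; `attr(, "removed")` lists dropped OTUs.
#' @export
filter_low_count <- function(table, min_total = 5,
                             by = c("total", "incidence")) {
  by <- match.arg(by)
  table <- as_otu_table(table)
  score <- if (by == "total") rowSums(table) else rowSums(table > 0)
  keep <- score >= min_total
  removed <- rownames(table)[!keep]
  if (!any(keep)) {
    warning("all OTUs filtered out", call. = FALSE)
    out <- otu_table(table[keep, , drop = FALSE])
  } else {
    out <- otu_table(table[keep, , drop = FALSE])
  }
  attr(out, "removed") <- removed
  out
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors (Robinson-Oshlack), computed by
#' edgeR: the reference is the sample whose 75th-percentile relative
#' abundance is closest to the mean of those percentiles; per sample, the
#' factor is `2^` the precision-weighted mean of log-ratios (M-values)
#' after symmetric trimming of `trim_m` on M and `trim_a` on A; factors are
#' rescaled to geometric mean 1.
#'
#' @param table an [otu_table] (>= 2 samples, positive column sums).
#' @param trim_m trim fraction on M-values.
#' @param trim_a trim fraction on A-values.
#' @return a `norm_factors` object: list with `factors` (named, geometric
#'   mean 1) and `reference_sample`.
#' @export
tmm_factors <- function(table, trim_m = 0.30, trim_a = 0.05) {
  table <- as_otu_table(table)
  if (ncol(table) < 2) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(table)
  if (any(lib == 0)) stop("sample with zero total count", call. = FALSE)
  f75 <- apply(sweep(unclass(table), 2, lib, "/"), 2,
               stats::quantile, probs = 0.75)
  ref <- colnames(table)[which.min(abs(f75 - mean(f75)))]
  shares_ref <- colSums(unclass(table) > 0 & unclass(table)[, ref] > 0) > 0
  if (!all(shares_ref))
    stop("sample(s) share no positive taxon with reference '", ref, "': ",
         paste(colnames(table)[!shares_ref], collapse = ", "), call. = FALSE)
  f <- edgeR::calcNormFactors(unclass(table), method = "TMM",
                              refColumn = match(ref, colnames(table)),
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- f / exp(mean(log(f)))               # geometric mean exactly 1
  structure(list(factors = stats::setNames(f, colnames(table)),
                 reference_sample = ref),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors: %d samples, reference '%s', range [%.3f, %.3f]\n",
              length(x$factors), x$reference_sample, min(x$factors),
              max(x$factors)))
  invisible(x)
}

#' Negative-binomial GLM likelihood-ratio tests per OTU
#'
#' Fits, for every OTU, a log-link negative-binomial GLM of counts on a
#' host-versus-source indicator with offset `log(library size x TMM factor)`,
#' and compares it to the intercept-only model with a likelihood-ratio test
#' (chi-square, 1 df). Per-OTU dispersions are estimated by adjusted profile
#' likelihood and shrunk toward the common dispersion with `prior_df`
#' weight (no abundance trend). Fitting and testing are delegated to edgeR.
#'
#' @param host,source [otu_table]s with identical taxon lists (post-filter);
#'   columns are the two groups' samples.
#' @param factors a `norm_factors` object covering all samples (default:
#'   recomputed on the combined table).
#' @param prior_df shrinkage weight toward the common dispersion.
#' @param site optional factor over all samples (host then source columns)
#'   entered as an additive covariate.
#' @return data.frame with columns `otu_id`, `log2_fold_change` (host over
#'   source), `p_value`, `mean_normalized_abundance` (average log2 CPM), and
#'   `converged`; non-converged OTUs carry `NA` p-values.
#' @export
nb_glm_lrt <- function(host, source, factors = NULL, prior_df = 10,
                       site = NULL) {
  host <- as_otu_table(host); source <- as_otu_table(source)
  if (!identical(rownames(host), rownames(source)))
    stop("host and source tables must share the taxon list", call. = FALSE)
  counts <- cbind(unclass(host), unclass(source))
  group <- factor(rep(c("host", "source"), c(ncol(host), ncol(source))),
                  levels = c("source", "host"))
  if (is.null(factors)) factors <- tmm_factors(otu_table(counts))
  miss <- setdiff(colnames(counts), names(factors$factors))
  if (length(miss))
    stop("normalization factors missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  # OTUs with no counts anywhere cannot be fitted: flagged, excluded
  fit_ok <- rowSums(counts) > 0
  y <- edgeR::DGEList(counts = counts[fit_ok, , drop = FALSE], group = group)
  y$samples$norm.factors <- factors$factors[colnames(counts)]
  design <- if (is.null(site)) stats::model.matrix(~group)
            else stats::model.matrix(~factor(site) + group)
  y <- edgeR::estimateDisp(y, design, prior.df = prior_df,
                           trend.method = "none")
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = ncol(design))
  tab <- lrt$table
  out <- data.frame(otu_id = rownames(counts),
                    log2_fold_change = NA_real_, p_value = NA_real_,
                    mean_normalized_abundance = NA_real_,
                    converged = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  converged <- is.finite(tab$PValue) & is.finite(tab$logFC)
  out$log2_fold_change[fit_ok] <- tab$logFC
  out$p_value[fit_ok] <- ifelse(converged, tab$PValue, NA_real_)
  out$mean_normalized_abundance[fit_ok] <- tab$logCPM
  out$converged[fit_ok] <- converged
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; `NA` entries (non-converged
#' tests) are excluded from the test count `m` and stay `NA`.
#'
#' @param p_values numeric vector in `[0, 1]`, `NA` allowed.
#' @return adjusted p-values, order preserved.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Call enriched and depleted OTUs
#'
#' Adds `p_adjusted` (when absent) and a `call` column: `enriched` when
#' `p_adjusted < alpha` and the fold change is positive, `depleted` when
#' negative, `unchanged` otherwise (including non-converged OTUs).
#'
#' @param results data.frame from [nb_glm_lrt()] (optionally already carrying
#'   `p_adjusted`).
#' @param alpha BH significance level.
#' @return `results` with `p_adjusted` and `call` columns; the summary counts
#'   are in `attr(, "summary")`.
#' @export
call_enrichment <- function(results, alpha = 0.01) {
  if (is.null(results$p_adjusted))
    results$p_adjusted <- bh_adjust(results$p_value)
  sig <- !is.na(results$p_adjusted) & results$p_adjusted < alpha
  results$call <- "unchanged"
  results$call[sig & results$log2_fold_change > 0] <- "enriched"
  results$call[sig & results$log2_fold_change < 0] <- "depleted"
  attr(results, "summary") <- list(
    n_enriched = sum(results$call == "enriched"),
    n_depleted = sum(results$call == "depleted"),
    n_tested = sum(!is.na(results$p_value)),
    alpha = alpha)
  results
}

#' Source-guided differential abundance, end to end
#'
#' Combines a host compartment with its primary source environment, removes
#' underpowered OTUs, computes TMM factors, fits per-OTU NB GLMs with a
#' likelihood-ratio test, BH-adjusts, and calls enrichment at `alpha`.
#'
#' @param host,source [otu_table]s over a shared taxon universe (unrarefied
#'   counts).
#' @param alpha BH level for calls.
#' @param min_total low-count filter threshold (applied to the combined
#'   table).
#' @param filter_by `"total"` or `"incidence"` (see [filter_low_count()]).
#' @param prior_df,site passed to [nb_glm_lrt()].
#' @return the called results table (see [call_enrichment()]).
#' @export
differential_abundance <- function(host, source, alpha = 0.01, min_total = 5,
                                   filter_by = "total", prior_df = 10,
                                   site = NULL) {
  host <- as_otu_table(host); source <- as_otu_table(source)
  shared <- intersect(rownames(host), rownames(source))
  combined <- otu_table(cbind(unclass(host)[shared, , drop = FALSE],
                              unclass(source)[shared, , drop = FALSE]))
  kept <- filter_low_count(combined, min_total = min_total, by = filter_by)
  taxa <- rownames(kept)
  res <- nb_glm_lrt(otu_table(unclass(host)[taxa, , drop = FALSE]),
                    otu_table(unclass(source)[taxa, , drop = FALSE]),
                    prior_df = prior_df, site = site)
  call_enrichment(res, alpha = alpha)
}
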