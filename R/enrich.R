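#' Count factor-bound genes targeted by one miRNA family
#'
#' Gene-level count: the number of genes in `gene_set` with at least one
#' predicted site of `family_id` (multiple sites in one gene count once).
#'
#' @param sites site data frame.
#' @param family_id family to count.
#' @param gene_set character vector of gene ids.
#' @return integer count.
#' @export
count_family_targets <- function(sites, family_id, gene_set) {
  if (!family_id %in% sites$family_id) {
    stop(sprintf("unknown miRNA family '%s'", family_id), call. = FALSE)
  }
  fam_genes <- unique(sites$gene_id[sites$family_id == family_id])
  sum(unique(gene_set) %in% fam_genes)
}

# Per-gene prediction totals used by the correction factor r.
# level = "site": total predicted sites (all families) per gene;
# level = "pair": number of distinct families predicted per gene.
gene_prediction_totals <- function(sites, genes, level = c("site", "pair")) {
  level <- match.arg(level)
  if (level == "pair") {
    sites <- sites[!duplicated(pair_key(sites$family_id, sites$gene_id)), ,
      drop = FALSE
    ]
  }
  tab <- table(factor(sites$gene_id, levels = genes))
  as.numeric(tab)
}

#' Corrected Monte-Carlo over-representation test for one miRNA family
#'
#' Tests whether the targets of `family_id` are over-represented among
#' `factor_genes` within the universe of genes carrying predictions. Given
#' n = |factor genes in universe| and m = factor genes targeted by the
#' family, each iteration draws n genes uniformly without replacement from
#' the universe and counts the drawn genes targeted by the family (z).
#' Because factor-bound genes tend to carry more predictions overall (longer
#' UTRs), z is corrected by r = (total predictions in the factor genes) /
#' (total predictions in the draw), giving z* = z * r. The default p-value is
#' the upper tail p = (1 + #\{z* >= m\}) / (n_iter + 1).
#'
#' @param sites site data frame (the full filtered prediction set).
#' @param family_id family to test.
#' @param factor_genes character vector of factor-bound gene ids
#'   (intersected with the universe).
#' @param universe_genes character vector: all genes with predictions.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param rng_seed integer seed (required).
#' @param tail `"upper"` (default: count z* >= m as extreme) or
#'   `"literal_lower"` (count z* < m), kept for audit.
#' @param r_level `"site"` (default: r uses site-level totals) or `"pair"`
#'   (distinct (family, gene) totals).
#' @return a one-row data frame of class `enrichment_result`: family_id, n,
#'   m, n_iter, null_mean, null_sd, p_raw, rng_seed.
#' @export
enrichment_test <- function(sites, family_id, factor_genes, universe_genes,
                            n_iter = 10000L, rng_seed,
                            tail = c("upper", "literal_lower"),
                            r_level = c("site", "pair")) {
  tail <- match.arg(tail)
  r_level <- match.arg(r_level)
  if (missing(rng_seed)) {
    stop("rng_seed is required for enrichment_test", call. = FALSE)
  }
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  res <- enrich_mc(
    sites, family_id, factor_genes, universe_genes,
    n_iter, rng_seed, tail, r_level
  )
  structure(res, class = c("enrichment_result", "data.frame"))
}

enrich_mc <- function(sites, family_ids, factor_genes, universe_genes,
                      n_iter, rng_seed, tail, r_level) {
  universe <- sort(unique(universe_genes))
  N <- length(universe)
  factor_in <- sort(intersect(unique(factor_genes), universe))
  n <- length(factor_in)
  if (n == 0L) stop("no factor-bound genes in the universe", call. = FALSE)
  if (N < n) stop("universe smaller than the factor gene set", call. = FALSE)

  totals <- gene_prediction_totals(sites, universe, r_level)
  total_factor <- sum(totals[match(factor_in, universe)])

  # gene x family target indicator
  ind <- vapply(family_ids, function(f) {
    if (!f %in% sites$family_id) {
      stop(sprintf("unknown miRNA family '%s'", f), call. = FALSE)
    }
    universe %in% unique(sites$gene_id[sites$family_id == f])
  }, logical(N))
  ind <- matrix(ind, nrow = N)
  m <- colSums(ind[match(factor_in, universe), , drop = FALSE])

  set.seed(rng_seed)
  zs <- matrix(NA_real_, nrow = n_iter, ncol = length(family_ids))
  n_resampled <- 0L
  for (it in seq_len(n_iter)) {
    repeat {
      idx <- sample.int(N, n)
      draw_total <- sum(totals[idx])
      if (draw_total > 0) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 1000L * n_iter) {
        stop("correction factor undefined: draws keep having zero predictions",
          call. = FALSE
        )
      }
    }
    r <- total_factor / draw_total
    zs[it, ] <- colSums(ind[idx, , drop = FALSE]) * r
  }
  if (n_resampled > 0L) {
    message(sprintf(
      "enrichment test: %d draws with zero predictions were resampled",
      n_resampled
    ))
  }
  p_raw <- vapply(seq_along(family_ids), function(j) {
    k <- if (tail == "upper") sum(zs[, j] >= m[j]) else sum(zs[, j] < m[j])
    (1 + k) / (n_iter + 1)
  }, numeric(1))
  data.frame(
    family_id = family_ids, n = n, m = as.integer(m), n_iter = n_iter,
    null_mean = colMeans(zs), null_sd = apply(zs, 2, stats::sd),
    p_raw = p_raw, rng_seed = rng_seed, stringsAsFactors = FALSE
  )
}

#' Enrichment test for every family in a dataset, with BH adjustment
#'
#' Runs the corrected Monte-Carlo test of [enrichment_test()] for all
#' families (or a supplied subset) against one factor-bound gene list,
#' sharing one set of random draws across families, and appends
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param sites site data frame.
#' @param factor_genes character vector of factor-bound gene ids.
#' @param universe_genes universe of genes with predictions; defaults to all
#'   genes present in `sites`.
#' @param family_ids families to test; defaults to all families in `sites`.
#' @param dataset_id label carried into the result (one factor dataset /
#'   cell type per call).
#' @param n_iter,rng_seed,tail,r_level as in [enrichment_test()].
#' @return data frame: dataset_id, family_id, n, m, n_iter, null_mean,
#'   null_sd, p_raw, p_adj.
#' @export
enrich_dataset <- function(sites, factor_genes, universe_genes = NULL,
                           family_ids = NULL, dataset_id = "dataset1",
                           n_iter = 10000L, rng_seed,
                           tail = c("upper", "literal_lower"),
                           r_level = c("site", "pair")) {
  tail <- match.arg(tail)
  r_level <- match.arg(r_level)
  if (missing(rng_seed)) {
    stop("rng_seed is required for enrich_dataset", call. = FALSE)
  }
  if (is.null(universe_genes)) universe_genes <- unique(sites$gene_id)
  if (is.null(family_ids)) family_ids <- sort(unique(sites$family_id))
  res <- enrich_mc(
    sites, family_ids, factor_genes, universe_genes,
    check_count(n_iter, "n_iter", min = 1L), rng_seed, tail, r_level
  )
  res$p_adj <- bh_adjust(res$p_raw)
  cbind(dataset_id = dataset_id, res, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment, returned in input order
#' and capped at 1. Inputs must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return numeric vector of adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
    any(p_values <= 0 | p_values > 1)) {
    stop("p-values must be in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select enriched families across factor datasets
#'
#' Under the default `any_dataset` rule a family is selected iff its
#' BH-adjusted p-value is below `alpha` in at least one dataset; under
#' `all_datasets` it must pass in every dataset in which it was tested.
#'
#' @param results data frame(s) from [enrich_dataset()] (rows may span
#'   several `dataset_id`s).
#' @param alpha significance level for adjusted p-values (default 0.05).
#' @param rule `"any_dataset"` (default) or `"all_datasets"`.
#' @return list of class `family_selection`: `selected` (character vector),
#'   `alpha`, `rule`, and `evidence` (the per-dataset result table).
#' @export
select_families <- function(results, alpha = 0.05,
                            rule = c("any_dataset", "all_datasets")) {
  rule <- match.arg(rule)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  if (!is.data.frame(results) || !nrow(results)) {
    stop("no enrichment results to select from", call. = FALSE)
  }
  hits <- tapply(results$p_adj < alpha, results$family_id, if (rule ==
    "any_dataset") {
    any
  } else {
    all
  })
  selected <- sort(names(hits)[unlist(hits)])
  structure(
    list(selected = selected, alpha = alpha, rule = rule, evidence = results),
    class = "family_selection"
  )
}
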