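#' Ratio-of-means resampling test
#'
#' Compares two groups of values through the ratio of their means,
#' z = mean(values_A) / mean(values_B). The null is built by drawing, in each
#' of `n_iter` iterations, |values_A| values from `pool_A` and |values_B|
#' values from `pool_B` (each without replacement, the two draws independent)
#' and forming z* = x*/y*. For z > 1 the p-value is
#' (1 + #\{z* > z\}) / (n_iter + 1); for z < 1 it is
#' (1 + #\{z* < z\}) / (n_iter + 1); for z = 1 exactly, p = 1. The pools are
#' the complete datasets the two observed samples were taken from (e.g. all
#' site-level values in factor-bound UTRs versus all site-level values).
#'
#' @param values_A,values_B observed values for the two groups.
#' @param pool_A,pool_B complete datasets to resample from; each must be at
#'   least as large as the corresponding sample.
#' @param n_iter resampling iterations (default 10000).
#' @param rng_seed integer seed (required).
#' @return list of class `ratio_test`: n_A, n_B, x, y, z, n_iter, p,
#'   rng_seed, n_resampled.
#' @export
ratio_permutation_test <- function(values_A, values_B, pool_A, pool_B,
                                   n_iter = 10000L, rng_seed) {
  if (missing(rng_seed)) {
    stop("rng_seed is required for ratio_permutation_test", call. = FALSE)
  }
  n_iter <- check_count(n_iter, "n_iter", min = 1L)
  for (nm in c("values_A", "values_B", "pool_A", "pool_B")) {
    v <- get(nm)
    if (!is.numeric(v) || !length(v) || !all(is.finite(v))) {
      stop(sprintf("%s must be a nonempty finite numeric vector", nm),
        call. = FALSE
      )
    }
  }
  n_A <- length(values_A)
  n_B <- length(values_B)
  if (length(pool_A) < n_A || length(pool_B) < n_B) {
    stop("pools must be at least as large as the observed samples",
      call. = FALSE
    )
  }
  x <- mean(values_A)
  y <- mean(values_B)
  if (y == 0) stop("mean of values_B is zero; ratio undefined", call. = FALSE)
  z <- x / y

  # canonical pool order: same seed + same multiset of values => same p
  pool_A <- sort(pool_A)
  pool_B <- sort(pool_B)

  set.seed(rng_seed)
  zs <- numeric(n_iter)
  n_resampled <- 0L
  NA_pool <- length(pool_A)
  NB_pool <- length(pool_B)
  for (it in seq_len(n_iter)) {
    repeat {
      xs <- mean(pool_A[sample.int(NA_pool, n_A)])
      ys <- mean(pool_B[sample.int(NB_pool, n_B)])
      if (ys != 0) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > 1000L * n_iter) {
        stop("resampled denominator keeps being zero", call. = FALSE)
      }
    }
    zs[it] <- xs / ys
  }
  if (n_resampled) {
    message(sprintf(
      "ratio test: %d iterations with zero denominator resampled", n_resampled
    ))
  }
  p <- if (z > 1) {
    (1 + sum(zs > z)) / (n_iter + 1)
  } else if (z < 1) {
    (1 + sum(zs < z)) / (n_iter + 1)
  } else {
    1
  }
  structure(
    list(
      n_A = n_A, n_B = n_B, x = x, y = y, z = z, n_iter = n_iter,
      p = p, rng_seed = rng_seed, n_resampled = n_resampled
    ),
    class = "ratio_test"
  )
}

#' Fisher's exact test on single- versus multi-site pair proportions
#'
#' Two-sided exact test on the 2x2 table with rows (selected, background) and
#' columns (multi-site pairs, single-site pairs).
#'
#' @param counts_selected length-2 vector (multi, single) for the selected
#'   set.
#' @param counts_background length-2 vector (multi, single) for the
#'   background set.
#' @param alternative passed to [stats::fisher.test()]; default two-sided.
#' @return list of class `fisher_result`: table, p, odds_ratio.
#' @export
fisher_multiplicity <- function(counts_selected, counts_background,
                                alternative = "two.sided") {
  cnt <- c(counts_selected, counts_background)
  if (length(cnt) != 4L || !is.numeric(cnt) || anyNA(cnt) || any(cnt < 0) ||
    any(cnt != round(cnt))) {
    stop("counts must be nonnegative integers (multi, single) per set",
      call. = FALSE
    )
  }
  tab <- matrix(as.integer(cnt),
    nrow = 2, byrow = TRUE,
    dimnames = list(
      set = c("selected", "background"),
      sites = c("multi", "single")
    )
  )
  if (any(rowSums(tab) == 0)) {
    stop("each set must contain at least one pair", call. = FALSE)
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  structure(
    list(
      table = tab, p = ft$p.value,
      odds_ratio = unname(ft$estimate)
    ),
    class = "fisher_result"
  )
}

#' Per-family Fisher tests of multi-site proportions
#'
#' For each family present in the selected set, tests the family's selected
#' pairs (multi vs single) against the background pairs (by default pooled
#' over all families; `family_matched = TRUE` restricts the background to the
#' same family). Families with zero selected pairs are skipped with a
#' message. The attribute `n_significant` counts families with p below
#' `alpha`.
#'
#' @param groups_selected,groups_background groups data frames from
#'   [group_pairs()] / [split_sets()].
#' @param family_ids families to test; defaults to all families in the
#'   selected set.
#' @param alpha significance level used for the `n_significant` summary.
#' @param family_matched use the same family's background pairs instead of
#'   the pooled background.
#' @param alternative passed to [stats::fisher.test()].
#' @return data frame: family_id, sel_multi, sel_single, bg_multi,
#'   bg_single, odds_ratio, p, significant.
#' @export
per_family_fisher <- function(groups_selected, groups_background,
                              family_ids = NULL, alpha = 0.05,
                              family_matched = FALSE,
                              alternative = "two.sided") {
  if (is.null(family_ids)) {
    family_ids <- sort(unique(groups_selected$family_id))
  }
  skipped <- setdiff(family_ids, groups_selected$family_id)
  if (length(skipped)) {
    message(sprintf(
      "per_family_fisher: %d families with zero selected pairs skipped",
      length(skipped)
    ))
    family_ids <- setdiff(family_ids, skipped)
  }
  bg_multi_all <- sum(groups_background$multiplicity >= 2L)
  bg_single_all <- sum(groups_background$multiplicity == 1L)
  rows <- lapply(family_ids, function(f) {
    sel <- groups_selected[groups_selected$family_id == f, , drop = FALSE]
    if (family_matched) {
      bg <- groups_background[groups_background$family_id == f, , drop = FALSE]
      bgm <- sum(bg$multiplicity >= 2L)
      bgs <- sum(bg$multiplicity == 1L)
    } else {
      bgm <- bg_multi_all
      bgs <- bg_single_all
    }
    fr <- fisher_multiplicity(
      c(sum(sel$multiplicity >= 2L), sum(sel$multiplicity == 1L)),
      c(bgm, bgs),
      alternative = alternative
    )
    data.frame(
      family_id = f,
      sel_multi = fr$table[1, 1], sel_single = fr$table[1, 2],
      bg_multi = fr$table[2, 1], bg_single = fr$table[2, 2],
      odds_ratio = fr$odds_ratio, p = fr$p,
      significant = fr$p < alpha, stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      family_id = character(), sel_multi = integer(),
      sel_single = integer(), bg_multi = integer(), bg_single = integer(),
      odds_ratio = numeric(), p = numeric(), significant = logical(),
      stringsAsFactors = FALSE
    )
  }
  attr(out, "n_significant") <- sum(out$significant)
  attr(out, "n_skipped") <- length(skipped)
  out
}

#' One summary-table row comparing a feature between two sets
#'
#' Emits the per-set N / mean / sd and the [ratio_permutation_test()] p-value
#' for one named feature contrast, in the layout of the pipeline's summary
#' table.
#'
#' @param values_selected,values_background observed feature values in the
#'   two sets.
#' @param pool_selected,pool_background complete datasets to resample from.
#' @param label analysis name for the row.
#' @param n_iter,rng_seed as in [ratio_permutation_test()].
#' @return one-row data frame: analysis, n_selected, mean_selected,
#'   sd_selected, n_background, mean_background, sd_background, ratio, p.
#' @export
compare_feature <- function(values_selected, values_background,
                            pool_selected, pool_background, label,
                            n_iter = 10000L, rng_seed) {
  if (!length(values_selected) || !length(values_background)) {
    return(data.frame(
      analysis = label, n_selected = length(values_selected),
      mean_selected = NA_real_, sd_selected = NA_real_,
      n_background = length(values_background),
      mean_background = NA_real_, sd_background = NA_real_,
      ratio = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    ))
  }
  rt <- ratio_permutation_test(
    values_selected, values_background,
    pool_selected, pool_background,
    n_iter = n_iter, rng_seed = rng_seed
  )
  data.frame(
    analysis = label, n_selected = rt$n_A,
    mean_selected = rt$x, sd_selected = stats::sd(values_selected),
    n_background = rt$n_B, mean_background = rt$y,
    sd_background = stats::sd(values_background),
    ratio = rt$z, p = rt$p, stringsAsFactors = FALSE
  )
}
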