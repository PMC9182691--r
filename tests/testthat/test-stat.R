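test_that("degenerate and symmetric cases of the ratio test behave exactly", {
  const <- rep(5, 6)
  r <- ratio_permutation_test(const[1:3], const[1:3], const, const,
    n_iter = 50, rng_seed = 1
  )
  expect_equal(r$z, 1)
  expect_equal(r$p, 1)

  a <- c(1, 4, 9)
  b <- c(2, 2, 5)
  pa <- c(a, 7, 8)
  pb <- c(b, 1, 3)
  fwd <- ratio_permutation_test(a, b, pa, pb, n_iter = 100, rng_seed = 2)
  rev_ <- ratio_permutation_test(b, a, pb, pa, n_iter = 100, rng_seed = 2)
  expect_equal(rev_$z, 1 / fwd$z)
})

test_that("ratio test inputs are validated", {
  expect_error(
    ratio_permutation_test(1:3, 1:3, 1:2, 1:5, n_iter = 10, rng_seed = 1),
    "at least as large"
  )
  expect_error(
    ratio_permutation_test(1:3, c(0, 0), 1:5, c(0, 0, 1), n_iter = 10, rng_seed = 1),
    "zero"
  )
  expect_error(
    ratio_permutation_test(c(1, NA), 1:2, 1:5, 1:5, n_iter = 10, rng_seed = 1),
    "finite"
  )
  expect_error(ratio_permutation_test(1:3, 1:3, 1:5, 1:5, n_iter = 10), "rng_seed")
})

test_that("Monte-Carlo ratio p matches exhaustive enumeration over all draw pairs", {
  set.seed(40)
  pool_A <- round(stats::rlnorm(8, 3, 0.6), 1)
  pool_B <- round(stats::rlnorm(8, 3, 0.6), 1)
  values_A <- pool_A[c(1, 4, 6)]
  values_B <- pool_B[c(2, 3, 8)]
  oracle <- ratio_exact_oracle(values_A, values_B, pool_A, pool_B)
  n_iter <- 20000
  mc <- ratio_permutation_test(values_A, values_B, pool_A, pool_B,
    n_iter = n_iter, rng_seed = 13
  )
  expect_equal(mc$z, oracle$z)
  se <- sqrt(oracle$exact_p * (1 - oracle$exact_p) / n_iter)
  expect_lt(abs(mc$p - oracle$exact_p), 3 * se + 2 / n_iter)
})

test_that("ratio test is bit-reproducible under a seed and invariant to pool ordering", {
  set.seed(50)
  pa <- stats::runif(30, 1, 9)
  pb <- stats::runif(25, 1, 9)
  va <- pa[1:10]
  vb <- pb[1:8]
  r1 <- ratio_permutation_test(va, vb, pa, pb, n_iter = 500, rng_seed = 77)
  r2 <- ratio_permutation_test(va, vb, pa, pb, n_iter = 500, rng_seed = 77)
  expect_identical(r1, r2)
  r3 <- ratio_permutation_test(va, vb, sample(pa), sample(pb),
    n_iter = 500, rng_seed = 77
  )
  expect_identical(r1$p, r3$p)
})

test_that("resampling draws from each group's own pool keep a stable type-I error level", {
  # The procedure is not a classical permutation test: the tail is chosen by
  # the observed direction of z, so under the null the rejection rate at a
  # nominal alpha is about 2 * alpha (both directional 5% tails reject).
  # The level is characterized as that constant and checked within 3
  # binomial SE.
  set.seed(60)
  n_rep <- 300
  level <- 0.10
  rejections <- vapply(seq_len(n_rep), function(i) {
    pool <- stats::rlnorm(60, 2, 0.5)
    pa <- pool[1:30]
    pb <- pool[31:60]
    va <- pa[sample.int(30, 12)]
    vb <- pb[sample.int(30, 12)]
    r <- ratio_permutation_test(va, vb, pa, pb, n_iter = 400, rng_seed = 1000 + i)
    r$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - level), 3 * sqrt(level * (1 - level) / n_rep))
})

test_that("Fisher test on the multiplicity table matches the hypergeometric oracle", {
  flat <- fisher_multiplicity(c(1, 1), c(1, 1))
  expect_equal(flat$p, 1.0)
  big <- fisher_multiplicity(c(1855, 13154), c(7871, 86369))
  expect_lt(big$p, 0.001)
  expect_gt(big$odds_ratio, 1)
  set.seed(3)
  for (i in 1:50) {
    tab <- c(sample(0:10, 2, TRUE) + c(1, 0), sample(0:10, 2, TRUE) + c(0, 1))
    got <- fisher_multiplicity(tab[1:2], tab[3:4])$p
    expect_equal(got, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
      tolerance = 1e-12
    )
  }
  expect_error(fisher_multiplicity(c(-1, 2), c(1, 1)), "nonnegative")
  expect_error(fisher_multiplicity(c(0, 0), c(1, 1)), "at least one pair")
})

test_that("per-family Fisher tests delegate to the 2x2 test and flag planted multi-site excess", {
  mk_groups <- function(fam, n_multi, n_single) {
    data.frame(
      family_id = fam,
      gene_id = sprintf("%s_g%04d", fam, seq_len(n_multi + n_single)),
      multiplicity = c(rep(2L, n_multi), rep(1L, n_single)),
      stringsAsFactors = FALSE
    )
  }
  sel <- mk_groups("famA", 10, 10)
  bg <- mk_groups("famZ", 100, 900)
  res <- per_family_fisher(sel, bg)
  expect_identical(nrow(res), 1L)
  expect_equal(res$p, fisher_multiplicity(c(10, 10), c(100, 900))$p)

  # equal proportions, large counts -> p near 1
  sel2 <- mk_groups("famB", 50, 450)
  res2 <- per_family_fisher(sel2, bg)
  expect_gt(res2$p, 0.5)

  # family with zero selected pairs is skipped with a message
  expect_message(
    res3 <- per_family_fisher(sel, bg, family_ids = c("famA", "famQ")),
    "skipped"
  )
  expect_identical(attr(res3, "n_skipped"), 1L)
})

test_that("multi-site boost planted only in factor genes is recovered per family", {
  ds <- generate_dataset(synth_config(
    n_genes = 400L, n_families = 4L, enriched_families = 1L,
    enrichment_factor = 1, utr_len_log_mean = log(1200),
    utr_len_log_sd = 0.4, site_rate = 0.5, multi_site_boost = 1,
    factor_fraction = 0.3, rng_seed = 90
  ))
  # plant extra duplicate sites for fam01 inside factor genes only
  extra <- ds$sites[
    ds$sites$family_id == "fam01" & ds$sites$gene_id %in% ds$factor_genes,
  ]
  extra$start <- extra$start + 1000L
  extra$end <- extra$end + 1000L
  len <- ds$utrs$length[match(extra$gene_id, ds$utrs$gene_id)]
  extra <- extra[extra$end <= len, ]
  sites <- rbind(ds$sites, extra)
  groups <- group_pairs(sites)
  suppressMessages({
    ps <- split_sets(
      groups, c("fam01", "fam02"),
      ds$factor_genes
    )
  })
  res <- per_family_fisher(ps$selected, ps$background)
  expect_true(res$significant[res$family_id == "fam01"])
  expect_false(res$significant[res$family_id == "fam02"])
})

test_that("feature comparison rows carry per-set stats and handle empty input", {
  v <- c(1, 2, 3, 4)
  row <- compare_feature(v, v, v, v, "identical", n_iter = 50, rng_seed = 1)
  expect_equal(row$ratio, 1)
  expect_equal(row$p, 1)
  expect_identical(row$analysis, "identical")
  empty <- compare_feature(numeric(0), v, v, v, "empty", n_iter = 50, rng_seed = 1)
  expect_true(is.na(empty$p))
  expect_identical(empty$n_selected, 0L)
})
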