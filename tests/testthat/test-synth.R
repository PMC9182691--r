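test_that("invalid configuration fields are rejected by name", {
  expect_error(synth_config(base_gc = 1.2, rng_seed = 1), "base_gc")
  expect_error(synth_config(factor_fraction = -0.1, rng_seed = 1), "factor_fraction")
  expect_error(synth_config(enrichment_factor = 0.5, rng_seed = 1), "enrichment_factor")
  expect_error(synth_config(enriched_families = 99, rng_seed = 1), "enriched_families")
  expect_error(synth_config(site_rate = -1, rng_seed = 1), "site_rate")
  expect_error(synth_config(), "rng_seed")
})

test_that("site_rate = 0 yields a dataset with zero sites", {
  ds <- generate_dataset(quick_config(rng_seed = 11, site_rate = 0, n_genes = 30L))
  expect_identical(nrow(ds$sites), 0L)
  expect_identical(nrow(ds$utrs), 30L)
})

test_that("every planted seed complement occurs verbatim at its coordinates", {
  ds <- generate_dataset(quick_config(rng_seed = 5))
  seq_of <- ds$utrs$sequence[match(ds$sites$gene_id, ds$utrs$gene_id)]
  planted <- substr(seq_of, ds$sites$start + 1L, ds$sites$end)
  expected <- ds$families$seed[match(ds$sites$family_id, ds$families$family_id)]
  expect_identical(planted, expected)
  # coordinates inside the UTR
  len <- ds$utrs$length[match(ds$sites$gene_id, ds$utrs$gene_id)]
  expect_true(all(ds$sites$start >= 0 & ds$sites$end <= len))
})

test_that("same seed gives bit-identical datasets; earlier genes are stable when n_genes grows", {
  a <- generate_dataset(quick_config(rng_seed = 3))
  b <- generate_dataset(quick_config(rng_seed = 3))
  expect_identical(a, b)
  bigger <- generate_dataset(quick_config(rng_seed = 3, n_genes = 140L))
  expect_identical(bigger$utrs$sequence[1:120], a$utrs$sequence)
})

test_that("enrichment_factor = 1 leaves per-family density flat across the factor split", {
  ds <- generate_dataset(quick_config(
    rng_seed = 21, n_genes = 400L, site_rate = 0.4,
    enrichment_factor = 1, enriched_families = 1L, multi_site_boost = 1
  ))
  dr <- density_ratio(ds, "fam01")
  # identical generating rates: compare counts to a binomial split of the
  # pooled total by exposure (kb) share
  total <- dr$n_in + dr$n_out
  share <- dr$kb_in / (dr$kb_in + dr$kb_out)
  se <- sqrt(total * share * (1 - share))
  expect_lt(abs(dr$n_in - total * share), 3 * se + 1)
})

test_that("planted enrichment is recovered by direct counting at the configured factor", {
  ds <- generate_dataset(synth_config(
    n_genes = 500L, n_families = 2L, enriched_families = 1L,
    enrichment_factor = 4, utr_len_log_mean = log(800),
    utr_len_log_sd = 0.5, site_rate = 0.4, multi_site_boost = 1,
    rng_seed = 33
  ))
  dr1 <- density_ratio(ds, "fam01")
  ratio1 <- dr1$rate_in / dr1$rate_out
  # 3 SE of a ratio of two Poisson rates (delta method on log scale)
  se_log <- sqrt(1 / dr1$n_in + 1 / dr1$n_out)
  expect_lt(abs(log(ratio1) - log(4)), 3 * se_log)
  dr2 <- density_ratio(ds, "fam02")
  se_log2 <- sqrt(1 / dr2$n_in + 1 / dr2$n_out)
  expect_lt(abs(log(dr2$rate_in / dr2$rate_out)), 3 * se_log2)
})

test_that("mean UTR length matches the configured log-normal at n = 5000", {
  cfg <- synth_config(
    n_genes = 5000L, utr_len_log_mean = log(400),
    utr_len_log_sd = 0.5, site_rate = 0.05, rng_seed = 8
  )
  ds <- generate_dataset(cfg)
  mu <- 400 * exp(0.5^2 / 2)
  sd_ln <- mu * sqrt(exp(0.5^2) - 1)
  expect_lt(abs(mean(ds$utrs$length) - mu), 3 * sd_ln / sqrt(5000))
})

test_that("write/read round trip is lossless and empty datasets give header-only files", {
  ds <- generate_dataset(quick_config(rng_seed = 9, n_genes = 40L))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$utrs, ds$utrs)
  expect_identical(back$sites, ds$sites)
  expect_identical(back$families, ds$families)
  expect_identical(back$factor_genes, ds$factor_genes)
  expect_identical(
    length(Biostrings::readDNAStringSet(file.path(dir, "utrs.fasta"))), 40L
  )

  empty <- generate_dataset(quick_config(rng_seed = 9, n_genes = 0L))
  dir2 <- withr::local_tempdir()
  write_dataset(empty, dir2)
  expect_identical(nrow(read_tsv_file(file.path(dir2, "sites.tsv"))), 0L)
  expect_identical(nrow(read_tsv_file(file.path(dir2, "utrs.tsv"))), 0L)
})

test_that("unwritable output path raises an I/O error", {
  ds <- generate_dataset(quick_config(rng_seed = 2, n_genes = 5L))
  target <- file.path(withr::local_tempdir(), "f")
  file.create(target) # a file, not a directory
  expect_error(write_dataset(ds, target), "cannot create|not writable")
})

test_that("GC near planted sites is lower than in random windows by about the dip depth", {
  cfg <- synth_config(
    n_genes = 250L, utr_len_log_mean = log(2000), utr_len_log_sd = 0.3,
    base_gc = 0.44, gc_gradient_per_kb = 0, n_families = 2L,
    site_rate = 0.05, multi_site_boost = 1, factor_fraction = 0,
    enriched_families = 1L, enrichment_factor = 1,
    gc_dip_depth = 0.10, dip_halfwidth = 100L, rng_seed = 61
  )
  ds <- generate_dataset(cfg)
  win <- 80L
  near <- mapply(function(g, s, e) {
    seqs <- ds$utrs$sequence[match(g, ds$utrs$gene_id)]
    L <- nchar(seqs)
    gc_content(paste0(
      substr(seqs, max(1, s - win + 1), s),
      substr(seqs, e + 1, min(L, e + win))
    ))
  }, ds$sites$gene_id, ds$sites$start, ds$sites$end)
  set.seed(99)
  rand <- replicate(400, {
    i <- sample(nrow(ds$utrs), 1)
    L <- ds$utrs$length[i]
    a <- sample(L - 2 * win, 1)
    gc_content(substr(ds$utrs$sequence[i], a, a + 2 * win - 1))
  })
  diff <- mean(rand) - mean(near, na.rm = TRUE)
  se <- sqrt(stats::var(rand) / length(rand) + stats::var(near) / length(near))
  # random windows sometimes overlap a dip, so the gap is slightly below 0.10
  expect_lt(abs(diff - 0.10), 3 * se + 0.01)
})
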