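mk_utr <- function(gene, seq) {
  data.frame(
    gene_id = gene, transcript_id = paste0("t", gene), symbol = gene,
    species = "9606", sequence = seq, length = nchar(seq),
    stringsAsFactors = FALSE
  )
}

mk_sites <- function(gene, starts, ends, family = "famA") {
  data.frame(
    family_id = family, gene_id = gene, transcript_id = paste0("t", gene),
    species = "9606", start = as.integer(starts), end = as.integer(ends),
    site_type = "7mer-m8", stringsAsFactors = FALSE
  )
}

test_that("gc_content handles pure, mixed, N-containing and empty slices", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ANGC"), 2 / 3) # N excluded from both sides
  expect_true(is.na(gc_content("")))
  expect_true(is.na(gc_content("NNN")))
  expect_error(gc_content(42), "character")
})

test_that("UTR length statistics cover the requested genes and log missing ones", {
  utrs <- rbind(mk_utr("g1", strrep("A", 100)), mk_utr("g2", strrep("A", 300)))
  s1 <- utr_length_stats(utrs, "g1")
  expect_equal(s1$mean, 100)
  expect_true(is.na(s1$sd))
  s2 <- utr_length_stats(utrs, c("g1", "g2", "g2"))
  expect_equal(s2$mean, 200)
  expect_identical(s2$n, 2L)
  expect_message(
    s3 <- utr_length_stats(utrs, c("g1", "gX")),
    "1 genes without"
  )
  expect_identical(s3$n_missing, 1L)
})

test_that("site positional features satisfy the exact length identity", {
  utrs <- mk_utr("g1", strrep("A", 100))
  sf <- site_features(mk_sites("g1", c(10, 0, 93), c(17, 7, 100)), utrs)
  expect_equal(sf$dist_start, c(10, 0, 93))
  expect_equal(sf$dist_end, c(83, 93, 0))
  expect_equal(sf$rel_pos, c(0.10, 0, 0.93))
  expect_equal(sf$dist_start + sf$dist_end + (sf$end - sf$start), sf$utr_length)
  expect_error(
    site_features(mk_sites("g1", 95, 102), utrs),
    "out of UTR bounds"
  )
})

test_that("positional identity holds for every site of a generated dataset, and so does the mean identity", {
  ds <- generate_dataset(quick_config(rng_seed = 17))
  sf <- site_features(ds$sites, ds$utrs)
  expect_identical(
    sf$dist_start + sf$dist_end + (sf$end - sf$start),
    sf$utr_length
  )
  expect_equal(
    mean(sf$dist_start) + mean(sf$dist_end) + mean(sf$end - sf$start),
    mean(sf$utr_length)
  )
})

test_that("GC profile bins around sites match hand-computed fractions", {
  # per-50-nt blocks of known composition around one 7-nt site at [100, 107)
  seqs <- paste0(
    strrep("A", 50), strrep("G", 50), strrep("T", 7),
    strrep("G", 25), strrep("T", 25), strrep("C", 20), strrep("A", 30)
  )
  utrs <- mk_utr("g1", seqs)
  sites <- mk_sites("g1", 100, 107)
  prof <- gc_profile_around_sites(sites, utrs, half_window = 100, bin = 50)
  expect_identical(nrow(prof), 4L)
  # up2 = [0,50) all A; up1 = [50,100) all G; down1 = [107,157) 25 G + 25 T;
  # down2 = [157,207) 20 C + 30 A
  expect_equal(prof$mean_gc, c(0, 1, 0.5, 0.4))
  expect_identical(prof$n_obs, rep(1L, 4))
  # all-G sequence: every bin is 1
  utrs2 <- mk_utr("g2", strrep("G", 300))
  prof2 <- gc_profile_around_sites(
    mk_sites("g2", 150, 157), utrs2,
    half_window = 100, bin = 50
  )
  expect_equal(prof2$mean_gc, rep(1, 4))
})

test_that("bins truncated by the UTR boundary contribute covered nucleotides only", {
  utrs <- mk_utr("g1", paste0(strrep("G", 10), strrep("A", 107)))
  # site at the UTR start: no upstream contribution at all
  p0 <- gc_profile_around_sites(
    mk_sites("g1", 0, 7), utrs,
    half_window = 100, bin = 50
  )
  expect_identical(p0$n_obs[1:2], c(0L, 0L))
  expect_true(all(is.na(p0$mean_gc[1:2])))
  # site at 20: first upstream bin covers only positions 0..19 (10 G, 10 A)
  p1 <- gc_profile_around_sites(
    mk_sites("g1", 20, 27), utrs,
    half_window = 100, bin = 50
  )
  expect_identical(p1$n_obs[2], 1L)
  expect_equal(p1$mean_gc[2], 0.5)
  expect_identical(p1$n_obs[1], 0L) # bin -100..-50 fully outside
})

test_that("background GC windows reproduce composition, gradient sign and determinism", {
  utrs <- rbind(mk_utr("g1", strrep("C", 1200)), mk_utr("g2", strrep("C", 1500)))
  prof <- background_gc_profile(utrs, n_regions = 50, rng_seed = 5)
  expect_equal(prof$mean_gc, rep(1, 20))
  expect_identical(prof$n_obs, rep(50L, 20))

  ds <- generate_dataset(synth_config(
    n_genes = 150L, utr_len_log_mean = log(2500), utr_len_log_sd = 0.2,
    gc_gradient_per_kb = -0.08, site_rate = 0, gc_dip_depth = 0,
    rng_seed = 30
  ))
  bp <- background_gc_profile(ds$utrs, n_regions = 2000, rng_seed = 6)
  slope <- stats::coef(stats::lm(bp$mean_gc ~ seq_len(20)))[2]
  expect_lt(slope, 0)
  bp2 <- background_gc_profile(ds$utrs, n_regions = 2000, rng_seed = 6)
  expect_identical(bp, bp2)
  expect_error(
    background_gc_profile(mk_utr("g", "ACGT"), n_regions = 5, rng_seed = 1),
    "no UTR of length"
  )
})

test_that("multiplicity table counts multi-site pairs overall and per family", {
  g <- group_pairs(rbind(
    mk_sites("g1", c(0, 10, 20), c(7, 17, 27)),
    mk_sites("g2", 0, 7),
    mk_sites("g3", 0, 7)
  ))
  mt <- multiplicity_table(g)
  expect_identical(mt$pairs_total, 3L)
  expect_identical(mt$pairs_multi, 1L)
  empty <- multiplicity_table(group_pairs(six_gene_fixture()[0, ]))
  expect_identical(empty$pairs_total, 0L)
  expect_identical(empty$pairs_multi, 0L)

  fix <- group_pairs(six_gene_fixture())
  mf <- multiplicity_table(fix)
  # manual tally: famA has pairs g1(2), g2(1), g5(2); famB g1(1), g3(2), g4(1), g6(1)
  expect_identical(mf$pairs_total, 7L)
  expect_identical(mf$pairs_multi, 3L)
  pf <- mf$per_family
  expect_identical(pf$pairs_multi[pf$family_id == "famA"], 2L)
  expect_identical(pf$pairs_multi[pf$family_id == "famB"], 1L)
})

test_that("inter-site gaps pair consecutive sites and keep strictly positive gaps", {
  seqs <- paste0(
    strrep("A", 17), strrep("G", 20), strrep("T", 13), strrep("C", 50)
  )
  utrs <- mk_utr("g1", seqs)
  g <- group_pairs(mk_sites("g1", c(10, 50), c(17, 57)))
  feats <- intersite_features(g, utrs)
  expect_identical(nrow(feats), 1L)
  expect_identical(feats$gap, 33L)
  expect_equal(feats$gap_gc, gc_content(substr(seqs, 18, 50)))
  expect_equal(feats$gap_gc, 20 / 33)

  g3 <- group_pairs(mk_sites("g1", c(10, 50, 80), c(17, 57, 87)))
  expect_identical(nrow(intersite_features(g3, utrs)), 2L)

  # adjacent sites: gap 0 is excluded and logged
  gadj <- group_pairs(mk_sites("g1", c(10, 17), c(17, 24)))
  expect_message(fadj <- intersite_features(gadj, utrs), "excluded")
  expect_identical(nrow(fadj), 0L)
  expect_identical(attr(fadj, "n_excluded"), 1L)

  # single-site groups yield nothing
  expect_identical(
    nrow(intersite_features(group_pairs(mk_sites("g1", 10, 17)), utrs)), 0L
  )
})

test_that("entries per group equal multiplicity - 1 - excluded non-positive gaps", {
  ds <- generate_dataset(quick_config(rng_seed = 41, multi_site_boost = 4))
  g <- group_pairs(ds$sites)
  feats <- suppressMessages(intersite_features(g, ds$utrs))
  n_expected <- sum(pmax(g$multiplicity - 1L, 0L)) - attr(feats, "n_excluded")
  expect_identical(nrow(feats), n_expected)
})
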