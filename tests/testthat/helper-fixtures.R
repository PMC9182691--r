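# Fixtures are built in code; nothing is read from disk except files the
# helpers themselves write to tempdirs.

# A fast generator configuration: short UTRs, few families. Used wherever the
# test checks structure or determinism rather than a planted effect size.
quick_config <- function(rng_seed, ...) {
  args <- list(
    n_genes = 120L, utr_len_log_mean = log(600), utr_len_log_sd = 0.5,
    n_families = 4L, site_rate = 0.3, rng_seed = rng_seed
  )
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synth_config, args)
}

# Hand-built six-gene fixture used by the enrichment tests. Gene g1..g6,
# two families. Site-level totals per gene are part of the fixture contract:
#   famA targets: g1, g2, g5   famB targets: g1, g3, g4, g6
#   sites per gene: g1: 3 (2 A + 1 B), g2: 1, g3: 2, g4: 1, g5: 2, g6: 1
six_gene_fixture <- function() {
  data.frame(
    family_id = c("famA", "famA", "famB", "famA", "famB", "famB", "famA", "famA", "famB", "famB"),
    gene_id = c("g1", "g1", "g1", "g2", "g3", "g3", "g5", "g5", "g4", "g6"),
    transcript_id = "t", species = "9606",
    start = c(0L, 10L, 20L, 0L, 0L, 10L, 0L, 10L, 0L, 0L),
    end = c(7L, 17L, 27L, 7L, 7L, 17L, 7L, 17L, 7L, 7L),
    site_type = "7mer-m8", stringsAsFactors = FALSE
  )
}

# Exhaustive-enumeration oracle for the corrected Monte-Carlo enrichment
# test: iterates every subset of size n of the universe and applies the same
# z, r, z* arithmetic. Returns the exact upper-tail probability P(z* >= m).
enrich_exact_oracle <- function(sites, family_id, factor_genes, universe) {
  universe <- sort(unique(universe))
  fam_genes <- unique(sites$gene_id[sites$family_id == family_id])
  totals <- sapply(universe, function(g) sum(sites$gene_id == g))
  factor_in <- sort(intersect(factor_genes, universe))
  n <- length(factor_in)
  m <- sum(factor_in %in% fam_genes)
  total_factor <- sum(totals[factor_in])
  combos <- utils::combn(length(universe), n)
  zstar <- apply(combos, 2, function(idx) {
    draw <- universe[idx]
    z <- sum(draw %in% fam_genes)
    z * total_factor / sum(totals[draw])
  })
  list(m = m, exact_p = mean(zstar >= m), zstar = zstar)
}

# Exhaustive oracle for the ratio-of-means resampling test over all
# C(|pool_A|, n_A) x C(|pool_B|, n_B) draw pairs.
ratio_exact_oracle <- function(values_A, values_B, pool_A, pool_B) {
  z <- mean(values_A) / mean(values_B)
  xs <- apply(utils::combn(length(pool_A), length(values_A)), 2,
    function(i) mean(pool_A[i])
  )
  ys <- apply(utils::combn(length(pool_B), length(values_B)), 2,
    function(i) mean(pool_B[i])
  )
  zs <- as.vector(outer(xs, ys, "/"))
  p <- if (z > 1) mean(zs > z) else if (z < 1) mean(zs < z) else 1
  list(z = z, exact_p = p)
}

# Direct hypergeometric-sum oracle for the two-sided Fisher exact test on a
# 2x2 table (a b / c d): sum the probabilities of all tables with the same
# margins whose probability does not exceed that of the observed table.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  dens <- stats::dhyper(lo:hi, m, n2, k)
  min(1, sum(dens[dens <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)]))
}

# Step-up BH oracle applied literally: q_i = min_{j >= i} p_(j) * M / j.
bh_oracle <- function(p) {
  M <- length(p)
  o <- order(p)
  q <- p[o] * M / seq_len(M)
  q <- rev(cummin(rev(q)))
  out <- numeric(M)
  out[o] <- pmin(1, q)
  out
}

# Writes a synthetic dataset out as TargetScan-dialect flat files (gapped UTR
# table, 1-based inclusive predicted-targets table, family-info table with
# numeric conservation codes), optionally with a mouse copy of every site so
# the human-mouse conservation filter keeps everything. Returns the paths.
write_targetscan_dialect <- function(ds, dir, gap_every = 0L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- ds$utrs$sequence
  if (gap_every > 0) {
    seqs <- vapply(seqs, function(s) {
      chunks <- substring(
        s, seq(1, nchar(s), gap_every),
        pmin(seq(gap_every, nchar(s) + gap_every - 1, gap_every), nchar(s))
      )
      paste(chunks, collapse = "-")
    }, character(1), USE.NAMES = FALSE)
  }
  utr_path <- file.path(dir, "UTR_Sequences.txt")
  write.table(
    data.frame(
      `Refseq ID` = ds$utrs$transcript_id, `Gene ID` = ds$utrs$gene_id,
      `Gene Symbol` = ds$utrs$symbol, `Species ID` = ds$utrs$species,
      `UTR sequence` = seqs, check.names = FALSE
    ),
    utr_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  site_path <- file.path(dir, "Predicted_Targets_Info.txt")
  mk_rows <- function(sites, species) {
    data.frame(
      `miR Family` = sites$family_id, `Gene ID` = sites$gene_id,
      `Gene Symbol` = sites$gene_id, `Transcript ID` = sites$transcript_id,
      `Species ID` = species, `UTR start` = sites$start + 1L,
      `UTR end` = sites$end, `Site type` = sites$site_type,
      check.names = FALSE
    )
  }
  write.table(rbind(mk_rows(ds$sites, "9606"), mk_rows(ds$sites, "10090")),
    site_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  fam_path <- file.path(dir, "miR_Family_Info.txt")
  code <- c(broadly_conserved = 2L, conserved = 1L, poorly_conserved = 0L)
  write.table(
    data.frame(
      `miR family` = ds$families$family_id,
      `Seed+m8` = ds$families$seed,
      `Family Conservation?` = code[ds$families$conservation_class],
      check.names = FALSE
    ),
    fam_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  fg_path <- file.path(dir, "factor_genes.txt")
  writeLines(ds$factor_genes, fg_path)
  list(
    utr_file = utr_path, site_file = site_path, family_file = fam_path,
    factor_genes_file = fg_path
  )
}

# Site-level table from a groups data frame (independent of the package's
# internal flattening helper).
flatten_groups_for_test <- function(groups) {
  data.frame(
    family_id = rep(groups$family_id, groups$multiplicity),
    gene_id = rep(groups$gene_id, groups$multiplicity),
    start = unlist(groups$starts, use.names = FALSE),
    end = unlist(groups$ends, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE)
}

# Per-family site density (sites per kb) inside and outside the factor set.
density_ratio <- function(ds, family_id) {
  fac <- ds$utrs$gene_id %in% ds$factor_genes
  kb_in <- sum(ds$utrs$length[fac]) / 1000
  kb_out <- sum(ds$utrs$length[!fac]) / 1000
  s <- ds$sites[ds$sites$family_id == family_id, ]
  n_in <- sum(s$gene_id %in% ds$factor_genes)
  n_out <- nrow(s) - n_in
  list(
    rate_in = n_in / kb_in, rate_out = n_out / kb_out,
    n_in = n_in, n_out = n_out, kb_in = kb_in, kb_out = kb_out
  )
}
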