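#' GC content of sequence slices
#'
#' Fraction (#G + #C) / (slice length excluding N). N bases are excluded from
#' both numerator and denominator; an empty or all-N slice yields `NA`
#' (undefined), never 0.
#'
#' @param x character vector of nucleotide slices.
#' @return numeric vector of fractions in \[0, 1\] (or NA).
#' @export
gc_content <- function(x) {
  if (!is.character(x)) stop("gc_content expects character input", call. = FALSE)
  gc <- nchar(gsub("[^GCgc]", "", x))
  valid <- nchar(gsub("[Nn]", "", x))
  ifelse(valid > 0, gc / valid, NA_real_)
}

#' Summary statistics of 3'-UTR lengths over a gene set
#'
#' @param utrs UTR data frame.
#' @param gene_set character vector of gene ids (deduplicated); genes with no
#'   UTR record are excluded with a logged count.
#' @return list: n, mean, sd, values, n_missing.
#' @export
utr_length_stats <- function(utrs, gene_set) {
  genes <- unique(gene_set)
  if (!length(genes)) stop("gene_set must be nonempty", call. = FALSE)
  hit <- match(genes, utrs$gene_id)
  n_missing <- sum(is.na(hit))
  if (n_missing) {
    message(sprintf(
      "utr_length_stats: %d genes without a UTR record excluded", n_missing
    ))
  }
  values <- utrs$length[hit[!is.na(hit)]]
  list(
    n = length(values), mean = mean(values),
    sd = stats::sd(values), values = values, n_missing = n_missing
  )
}

#' Positional features of binding sites within their UTRs
#'
#' For each site: `dist_start` = nucleotides from the 5' end of the UTR to
#' the site start, `dist_end` = nucleotides from the site end to the 3' end
#' of the UTR, `rel_pos` = dist_start / UTR length. The identity
#' dist_start + dist_end + site length = UTR length holds exactly.
#'
#' @param sites site data frame (needs family_id, gene_id, start, end).
#' @param utrs UTR data frame.
#' @return data frame: family_id, gene_id, start, end, utr_length,
#'   dist_start, dist_end, rel_pos.
#' @export
site_features <- function(sites, utrs) {
  len <- utrs$length[match(sites$gene_id, utrs$gene_id)]
  if (anyNA(len)) {
    stop("site references a gene without a UTR record", call. = FALSE)
  }
  if (any(sites$start < 0L | sites$end <= sites$start | sites$end > len)) {
    stop("site coordinates out of UTR bounds", call. = FALSE)
  }
  data.frame(
    family_id = sites$family_id, gene_id = sites$gene_id,
    start = sites$start, end = sites$end, utr_length = len,
    dist_start = sites$start, dist_end = len - sites$end,
    rel_pos = sites$start / len, stringsAsFactors = FALSE
  )
}

ci99_half <- function(sd, n) ifelse(n >= 2, 2.576 * sd / sqrt(n), NA_real_)

profile_from_values <- function(values_by_bin, bin_labels, offsets) {
  n_obs <- vapply(values_by_bin, length, integer(1))
  mean_gc <- vapply(values_by_bin, function(v) {
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  sd_gc <- vapply(values_by_bin, function(v) {
    if (length(v) >= 2) stats::sd(v) else NA_real_
  }, numeric(1))
  half <- ci99_half(sd_gc, n_obs)
  data.frame(
    bin = bin_labels, offset_start = offsets$start, offset_end = offsets$end,
    n_obs = n_obs, mean_gc = mean_gc, sd_gc = sd_gc,
    ci_low = mean_gc - half, ci_high = mean_gc + half,
    stringsAsFactors = FALSE
  )
}

#' Windowed GC-content profile around binding sites
#'
#' GC content in fixed-width bins flanking each site: upstream bins are
#' measured back from the site start, downstream bins forward from the site
#' end; the site body is excluded. Bins truncated by the UTR boundary
#' contribute only their covered nucleotides, and a site contributes to a bin
#' only when at least one nucleotide of that bin lies inside the UTR. Per-bin
#' mean GC with a 99% normal-approximation confidence interval of the mean
#' (mean +/- 2.576 sd / sqrt(n), undefined when n < 2).
#'
#' @param sites site data frame.
#' @param utrs UTR data frame (with sequences).
#' @param half_window flank width on each side, nt (default 500).
#' @param bin bin width, nt (default 50).
#' @return data frame with one row per bin (2 * half_window / bin rows):
#'   bin label, signed site-relative offsets, n_obs, mean_gc, sd_gc, ci_low,
#'   ci_high. Offsets are relative to the site start (upstream) or site end
#'   (downstream).
#' @export
gc_profile_around_sites <- function(sites, utrs, half_window = 500L,
                                    bin = 50L) {
  k <- as.integer(half_window / bin)
  stopifnot(k >= 1L, half_window == k * bin)
  n_bins <- 2L * k
  vals <- matrix(NA_real_, nrow = nrow(sites), ncol = n_bins)

  irow <- 0L
  for (g in unique(sites$gene_id)) {
    row <- match(g, utrs$gene_id)
    if (is.na(row)) stop(sprintf("no UTR record for gene '%s'", g), call. = FALSE)
    cum <- seq_cumcounts(utrs$sequence[row])
    L <- cum$len
    gsites <- sites[sites$gene_id == g, , drop = FALSE]
    for (j in seq_len(nrow(gsites))) {
      irow <- irow + 1L
      s <- gsites$start[j]
      e <- gsites$end[j]
      for (b in seq_len(k)) {
        # upstream bin b: [s - b*bin, s - (b-1)*bin)
        a0 <- max(0L, s - b * bin)
        a1 <- min(L, s - (b - 1L) * bin)
        if (a1 > a0) {
          w <- window_gc(cum, a0, a1)
          if (w["n"] > 0) vals[irow, k - b + 1L] <- w["gc"]
        }
        # downstream bin b: [e + (b-1)*bin, e + b*bin)
        d0 <- max(0L, e + (b - 1L) * bin)
        d1 <- min(L, e + b * bin)
        if (d1 > d0) {
          w <- window_gc(cum, d0, d1)
          if (w["n"] > 0) vals[irow, k + b] <- w["gc"]
        }
      }
    }
  }
  values <- lapply(seq_len(n_bins), function(b) {
    v <- vals[, b]
    v[!is.na(v)]
  })
  offs <- list(
    start = c(-rev(seq_len(k)) * bin, (seq_len(k) - 1L) * bin),
    end = c(-(rev(seq_len(k)) - 1L) * bin, seq_len(k) * bin)
  )
  labels <- c(
    sprintf("up%02d", rev(seq_len(k))),
    sprintf("down%02d", seq_len(k))
  )
  profile_from_values(values, labels, offs)
}

#' Background GC profile from random UTR windows
#'
#' Samples `n_regions` windows of `region_len` nt from UTRs at least that
#' long (a UTR is chosen uniformly among eligible UTRs, then a start
#' uniformly within it), splits each window into `region_len / bin` bins and
#' summarises per-bin GC with a 99% CI, exactly as in
#' [gc_profile_around_sites()].
#'
#' @param utrs UTR data frame.
#' @param region_len window length, nt (default 1000).
#' @param n_regions number of windows (default 10000).
#' @param rng_seed integer seed (required).
#' @param bin bin width, nt (default 50).
#' @return data frame with one row per bin: bin label, 5'-to-3' offsets
#'   within the window, n_obs, mean_gc, sd_gc, ci_low, ci_high.
#' @export
background_gc_profile <- function(utrs, region_len = 1000L,
                                  n_regions = 10000L, rng_seed, bin = 50L) {
  if (missing(rng_seed)) {
    stop("rng_seed is required for background_gc_profile", call. = FALSE)
  }
  n_regions <- check_count(n_regions, "n_regions", min = 1L)
  k <- as.integer(region_len / bin)
  stopifnot(k >= 1L, region_len == k * bin)
  eligible <- which(utrs$length >= region_len)
  if (!length(eligible)) {
    stop(sprintf("no UTR of length >= %d nt available", region_len),
      call. = FALSE
    )
  }
  set.seed(rng_seed)
  pick <- eligible[sample.int(length(eligible), n_regions, replace = TRUE)]
  maxstart <- utrs$length[pick] - region_len
  starts <- as.integer(floor(stats::runif(n_regions, 0, maxstart + 1)))
  starts <- pmin(starts, maxstart)

  cums <- lapply(
    unique(pick),
    function(rw) seq_cumcounts(utrs$sequence[rw])
  )
  names(cums) <- as.character(unique(pick))
  vals <- matrix(NA_real_, nrow = n_regions, ncol = k)
  for (i in seq_len(n_regions)) {
    cum <- cums[[as.character(pick[i])]]
    for (b in seq_len(k)) {
      w <- window_gc(
        cum, starts[i] + (b - 1L) * bin,
        starts[i] + b * bin
      )
      if (w["n"] > 0) vals[i, b] <- w["gc"]
    }
  }
  values <- lapply(seq_len(k), function(b) {
    v <- vals[, b]
    v[!is.na(v)]
  })
  offs <- list(start = (seq_len(k) - 1L) * bin, end = seq_len(k) * bin)
  profile_from_values(values, sprintf("bin%02d", seq_len(k)), offs)
}

#' Multi-site multiplicity summary
#'
#' Counts pairs with one versus multiple sites of the same family, overall
#' and per family.
#'
#' @param groups data frame from [group_pairs()].
#' @return list: pairs_total, pairs_multi, per_family (data frame family_id,
#'   pairs_total, pairs_multi).
#' @export
multiplicity_table <- function(groups) {
  if (!nrow(groups)) {
    return(list(
      pairs_total = 0L, pairs_multi = 0L,
      per_family = data.frame(
        family_id = character(), pairs_total = integer(),
        pairs_multi = integer(), stringsAsFactors = FALSE
      )
    ))
  }
  multi <- groups$multiplicity >= 2L
  per_total <- table(groups$family_id)
  per_multi <- table(factor(groups$family_id[multi],
    levels = names(per_total)
  ))
  list(
    pairs_total = nrow(groups), pairs_multi = sum(multi),
    per_family = data.frame(
      family_id = names(per_total),
      pairs_total = as.integer(per_total),
      pairs_multi = as.integer(per_multi),
      stringsAsFactors = FALSE
    )
  )
}

#' Distances and GC content between consecutive same-family sites
#'
#' For each (family, gene) group with multiplicity >= 2, consecutive sites
#' (sorted by start) yield gap = next start - current end and the GC content
#' of the intervening sequence. Only strictly positive gaps are emitted;
#' adjacent or overlapping consecutive sites are excluded with a count kept
#' in attribute `n_excluded`.
#'
#' @param groups data frame from [group_pairs()].
#' @param utrs UTR data frame (with sequences).
#' @return data frame: family_id, gene_id, gap, gap_gc; attribute
#'   `n_excluded` counts non-positive gaps dropped.
#' @export
intersite_features <- function(groups, utrs) {
  rows <- list()
  n_excluded <- 0L
  multi <- groups[groups$multiplicity >= 2L, , drop = FALSE]
  for (j in seq_len(nrow(multi))) {
    s <- multi$starts[[j]]
    e <- multi$ends[[j]]
    gaps <- s[-1L] - e[-length(e)]
    pos <- gaps > 0L
    n_excluded <- n_excluded + sum(!pos)
    if (!any(pos)) next
    row <- match(multi$gene_id[j], utrs$gene_id)
    if (is.na(row)) {
      stop(sprintf("no UTR record for gene '%s'", multi$gene_id[j]),
        call. = FALSE
      )
    }
    seqs <- substring(
      utrs$sequence[row],
      e[-length(e)][pos] + 1L, s[-1L][pos]
    )
    rows[[length(rows) + 1L]] <- data.frame(
      family_id = multi$family_id[j], gene_id = multi$gene_id[j],
      gap = gaps[pos], gap_gc = gc_content(seqs),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      family_id = character(), gene_id = character(),
      gap = integer(), gap_gc = numeric(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  if (n_excluded) {
    message(sprintf(
      "intersite_features: %d non-positive gaps excluded", n_excluded
    ))
  }
  attr(out, "n_excluded") <- n_excluded
  out
}
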