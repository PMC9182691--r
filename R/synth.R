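#' Configuration for the synthetic 3'-UTR / binding-site generator
#'
#' Builds and validates the parameter set used by [generate_dataset()]. The
#' defaults emulate the regime of genome-wide seed-match predictions on
#' representative human 3'-UTRs: heavy-tailed (log-normal) UTR lengths with
#' the mean/sd of real representative UTRs, a genome-like base GC fraction
#' with a shallow 5'-to-3' decreasing gradient, Poisson site counts
#' proportional to UTR length, a factor-bound gene subset in which chosen
#' miRNA families are enriched, an elevated rate of second and further sites
#' in already-hit (family, gene) pairs, and a local GC depression around
#' planted sites.
#'
#' @param n_genes number of genes (UTRs) to generate.
#' @param utr_len_log_mean,utr_len_log_sd log-scale mean and sd of the
#'   log-normal UTR length distribution (nucleotides).
#' @param base_gc baseline probability that a background position is G or C.
#' @param gc_gradient_per_kb signed change in GC probability per 1000 nt
#'   moving 5' to 3' along the UTR.
#' @param n_families number of miRNA families; each gets a random distinct
#'   seed-complement of length `seed_length`.
#' @param seed_length length (nt) of the planted seed-match, default 7.
#' @param site_rate expected number of sites per kilobase per family in
#'   unenriched genes.
#' @param multi_site_boost multiplier (>= 1) applied to the rate of second
#'   and further sites once a (family, gene) pair has at least one site.
#' @param factor_fraction fraction of genes marked as bound by the
#'   transcription factor.
#' @param enriched_families integer indices (1-based) of the families whose
#'   site rate is multiplied by `enrichment_factor` inside factor-bound genes.
#' @param enrichment_factor relative rate multiplier (>= 1) for enriched
#'   families inside factor-bound genes.
#' @param gc_dip_depth fraction subtracted from the local GC probability
#'   within `dip_halfwidth` nt of a planted site (site body excluded; planted
#'   seed-matches are written verbatim and never resampled).
#' @param dip_halfwidth half-width (nt) of the GC dip around each site.
#' @param rng_seed integer seed; the same seed gives bit-identical datasets.
#'   Sequences are generated from per-gene sub-streams derived from this
#'   seed, so increasing `n_genes` does not perturb earlier genes.
#'
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 500L,
                         utr_len_log_mean = 7.55,
                         utr_len_log_sd = 0.73,
                         base_gc = 0.44,
                         gc_gradient_per_kb = -0.02,
                         n_families = 40L,
                         seed_length = 7L,
                         site_rate = 0.05,
                         multi_site_boost = 2,
                         factor_fraction = 0.25,
                         enriched_families = 1:4,
                         enrichment_factor = 4,
                         gc_dip_depth = 0.10,
                         dip_halfwidth = 100L,
                         rng_seed) {
  n_genes <- check_count(n_genes, "n_genes")
  n_families <- check_count(n_families, "n_families")
  seed_length <- check_count(seed_length, "seed_length", min = 4L)
  dip_halfwidth <- check_count(dip_halfwidth, "dip_halfwidth")
  if (!is.numeric(utr_len_log_mean) || length(utr_len_log_mean) != 1L ||
    is.na(utr_len_log_mean)) {
    stop_config("utr_len_log_mean", "must be a single number")
  }
  if (!is.numeric(utr_len_log_sd) || length(utr_len_log_sd) != 1L ||
    is.na(utr_len_log_sd) || utr_len_log_sd < 0) {
    stop_config("utr_len_log_sd", "must be a single non-negative number")
  }
  check_fraction(base_gc, "base_gc")
  check_fraction(factor_fraction, "factor_fraction")
  check_fraction(gc_dip_depth, "gc_dip_depth")
  if (!is.numeric(gc_gradient_per_kb) || length(gc_gradient_per_kb) != 1L ||
    is.na(gc_gradient_per_kb)) {
    stop_config("gc_gradient_per_kb", "must be a single number")
  }
  if (!is.numeric(site_rate) || length(site_rate) != 1L || is.na(site_rate) ||
    site_rate < 0) {
    stop_config("site_rate", "must be a single non-negative number")
  }
  if (!is.numeric(multi_site_boost) || length(multi_site_boost) != 1L ||
    is.na(multi_site_boost) || multi_site_boost < 1) {
    stop_config("multi_site_boost", "must be a single number >= 1")
  }
  if (!is.numeric(enrichment_factor) || length(enrichment_factor) != 1L ||
    is.na(enrichment_factor) || enrichment_factor < 1) {
    stop_config("enrichment_factor", "must be a single number >= 1")
  }
  enriched_families <- as.integer(enriched_families)
  if (anyNA(enriched_families) ||
    any(enriched_families < 1L | enriched_families > n_families)) {
    stop_config("enriched_families", "indices must lie in 1..n_families")
  }
  if (missing(rng_seed)) stop_config("rng_seed", "is required (no default)")
  rng_seed <- check_count(rng_seed, "rng_seed")

  structure(
    list(
      n_genes = n_genes, utr_len_log_mean = utr_len_log_mean,
      utr_len_log_sd = utr_len_log_sd, base_gc = base_gc,
      gc_gradient_per_kb = gc_gradient_per_kb, n_families = n_families,
      seed_length = seed_length, site_rate = site_rate,
      multi_site_boost = multi_site_boost, factor_fraction = factor_fraction,
      enriched_families = unique(sort(enriched_families)),
      enrichment_factor = enrichment_factor, gc_dip_depth = gc_dip_depth,
      dip_halfwidth = dip_halfwidth, rng_seed = rng_seed
    ),
    class = "synth_config"
  )
}

site_type_for_length <- function(len) {
  if (len == 7L) "7mer-m8" else if (len == 8L) "8mer" else "unknown"
}

empty_sites_df <- function() {
  data.frame(
    family_id = character(), gene_id = character(),
    transcript_id = character(), species = character(),
    start = integer(), end = integer(), site_type = character(),
    stringsAsFactors = FALSE
  )
}

empty_utrs_df <- function() {
  data.frame(
    gene_id = character(), transcript_id = character(), symbol = character(),
    species = character(), sequence = character(), length = integer(),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic dataset of UTRs, planted binding sites and a
#' factor-bound gene set
#'
#' Draws per-gene UTR lengths from the configured log-normal, plants each
#' family's 7-nt seed complement at Poisson counts proportional to UTR
#' length, boosts the planting rate for enriched families inside factor-bound
#' genes, resamples local nucleotide composition with a reduced G+C
#' probability around each planted site (the seed-match itself is written
#' verbatim and exempt from resampling), and records the generating truth.
#' Planted sites never overlap within a gene so that every recorded
#' seed-match occurs verbatim at its coordinates.
#'
#' @param config a [synth_config()].
#' @return an object of class `synthetic_dataset`: a list with elements
#'   `utrs` (data frame: gene_id, transcript_id, symbol, species, sequence,
#'   length), `sites` (data frame: family_id, gene_id, transcript_id,
#'   species, start, end, site_type; 0-based half-open coordinates),
#'   `families` (family_id, seed, conservation_class), `factor_genes`
#'   (character vector) and `truth` (list: enriched_families, the planted
#'   `sites` table).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) {
    config <- do.call(synth_config, as.list(config))
  }
  cfg <- config
  sl <- cfg$seed_length
  min_len <- max(sl, 30L)

  # family seeds from the root stream: distinct random k-mers
  set.seed(cfg$rng_seed)
  fam_ids <- sprintf("fam%02d", seq_len(cfg$n_families))
  fam_seeds <- character(0)
  while (length(unique(fam_seeds)) < cfg$n_families) {
    fam_seeds <- vapply(seq_len(cfg$n_families), function(i) {
      paste(sample(c("A", "C", "G", "T"), sl, replace = TRUE), collapse = "")
    }, character(1))
  }
  families <- data.frame(
    family_id = fam_ids, seed = fam_seeds,
    conservation_class = rep("broadly_conserved", cfg$n_families),
    stringsAsFactors = FALSE
  )

  enriched <- rep(FALSE, cfg$n_families)
  enriched[cfg$enriched_families] <- TRUE

  utr_rows <- vector("list", cfg$n_genes)
  site_rows <- vector("list", cfg$n_genes)
  factor_flags <- logical(cfg$n_genes)

  for (i in seq_len(cfg$n_genes)) {
    set.seed(derive_seed(cfg$rng_seed, i))
    L <- max(min_len, as.integer(round(stats::rlnorm(
      1, cfg$utr_len_log_mean, cfg$utr_len_log_sd
    ))))
    is_factor <- stats::runif(1) < cfg$factor_fraction
    factor_flags[i] <- is_factor

    # per-family site counts: Poisson primary count, plus boosted extras
    # once the (family, gene) pair is hit
    rate <- cfg$site_rate * L / 1000
    fam_rate <- rate *
      ifelse(is_factor & enriched, cfg$enrichment_factor, 1)
    k <- stats::rpois(cfg$n_families, fam_rate)
    if (cfg$multi_site_boost > 1 && any(k > 0)) {
      hit <- k > 0
      k[hit] <- k[hit] +
        stats::rpois(sum(hit), fam_rate[hit] * (cfg$multi_site_boost - 1))
    }

    # left-to-right placement with rejection of any overlap in this gene
    starts <- integer(0)
    fams <- integer(0)
    if (sum(k) > 0 && L >= sl) {
      for (f in seq_len(cfg$n_families)) {
        placed <- 0L
        attempts <- 0L
        while (placed < k[f] && attempts < 60L * k[f]) {
          attempts <- attempts + 1L
          cand <- as.integer(floor(stats::runif(1, 0, L - sl + 1)))
          if (cand > L - sl) cand <- L - sl
          if (!any(cand < starts + sl & cand + sl > starts)) {
            starts <- c(starts, cand)
            fams <- c(fams, f)
            placed <- placed + 1L
          }
        }
      }
    }

    # per-position GC probability: base + gradient, dipped near sites
    p_gc <- cfg$base_gc + cfg$gc_gradient_per_kb * ((seq_len(L) - 1) / 1000)
    if (cfg$gc_dip_depth > 0 && length(starts)) {
      dip <- logical(L)
      seedpos <- logical(L)
      for (jj in seq_along(starts)) {
        a <- max(1L, starts[jj] + 1L - cfg$dip_halfwidth)
        b <- min(L, starts[jj] + sl + cfg$dip_halfwidth)
        dip[a:b] <- TRUE
        seedpos[(starts[jj] + 1L):(starts[jj] + sl)] <- TRUE
      }
      p_gc[dip & !seedpos] <- p_gc[dip & !seedpos] - cfg$gc_dip_depth
    }
    p_gc <- clamp(p_gc, 0.02, 0.98)

    gc_draw <- stats::runif(L) < p_gc
    half <- stats::runif(L) < 0.5
    chars <- ifelse(gc_draw, ifelse(half, "G", "C"), ifelse(half, "A", "T"))
    # plant seed complements verbatim
    for (jj in seq_along(starts)) {
      chars[(starts[jj] + 1L):(starts[jj] + sl)] <-
        strsplit(fam_seeds[fams[jj]], "")[[1]]
    }
    gene_id <- sprintf("G%05d", i)
    utr_rows[[i]] <- data.frame(
      gene_id = gene_id, transcript_id = sprintf("T%05d", i),
      symbol = gene_id, species = "9606",
      sequence = paste(chars, collapse = ""), length = L,
      stringsAsFactors = FALSE
    )
    if (length(starts)) {
      ord <- order(starts)
      site_rows[[i]] <- data.frame(
        family_id = fam_ids[fams[ord]], gene_id = gene_id,
        transcript_id = sprintf("T%05d", i), species = "9606",
        start = starts[ord], end = starts[ord] + sl,
        site_type = site_type_for_length(sl),
        stringsAsFactors = FALSE
      )
    }
  }

  utrs <- if (cfg$n_genes) do.call(rbind, utr_rows) else empty_utrs_df()
  keep <- !vapply(site_rows, is.null, logical(1))
  sites <- if (any(keep)) do.call(rbind, site_rows[keep]) else empty_sites_df()
  rownames(utrs) <- NULL
  rownames(sites) <- NULL

  structure(
    list(
      utrs = utrs, sites = sites, families = families,
      factor_genes = utrs$gene_id[factor_flags],
      truth = list(
        enriched_families = fam_ids[enriched],
        sites = sites
      ),
      config = cfg
    ),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits `utrs.tsv`, `sites.tsv`, `families.tsv`, `factor_genes.txt` and
#' `utrs.fasta` (record id = gene id). The tables round-trip losslessly
#' through [read_dataset()].
#'
#' @param ds a `synthetic_dataset` (or any list with the same elements).
#' @param out_dir output directory, created if absent.
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(ds, out_dir) {
  if (!dir.exists(out_dir) &&
    !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
      call. = FALSE
    )
  }
  if (file.access(out_dir, mode = 2L) != 0L) {
    stop(sprintf("output directory '%s' is not writable", out_dir),
      call. = FALSE
    )
  }
  paths <- file.path(out_dir, c(
    "utrs.tsv", "sites.tsv", "families.tsv",
    "factor_genes.txt", "utrs.fasta"
  ))
  utr_cols <- c("gene_id", "transcript_id", "symbol", "species", "length")
  write_tsv(ds$utrs[, utr_cols, drop = FALSE], paths[1])
  write_tsv(ds$sites, paths[2])
  write_tsv(ds$families, paths[3])
  writeLines(ds$factor_genes, paths[4])
  seqs <- Biostrings::DNAStringSet(ds$utrs$sequence)
  names(seqs) <- ds$utrs$gene_id
  Biostrings::writeXStringSet(seqs, paths[5])
  invisible(paths)
}

#' Read a dataset previously written by [write_dataset()]
#'
#' @param dir directory containing `utrs.tsv`, `sites.tsv`, `families.tsv`,
#'   `factor_genes.txt` and `utrs.fasta`.
#' @return a list with elements `utrs`, `sites`, `families`, `factor_genes`,
#'   shaped exactly as in a `synthetic_dataset`.
#' @export
read_dataset <- function(dir) {
  utrs <- read_tsv(file.path(dir, "utrs.tsv"), colClasses = "character")
  utrs$length <- as.integer(utrs$length)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "utrs.fasta"))
  seq_map <- as.character(fa)
  utrs$sequence <- unname(seq_map[utrs$gene_id])
  utrs <- utrs[, c(
    "gene_id", "transcript_id", "symbol", "species",
    "sequence", "length"
  )]
  sites <- read_tsv(file.path(dir, "sites.tsv"), colClasses = "character")
  if (nrow(sites)) {
    sites$start <- as.integer(sites$start)
    sites$end <- as.integer(sites$end)
  } else {
    sites <- empty_sites_df()
  }
  families <- read_tsv(file.path(dir, "families.tsv"),
    colClasses = "character"
  )
  fg_path <- file.path(dir, "factor_genes.txt")
  factor_genes <- if (file.size(fg_path) > 0) readLines(fg_path) else character()
  list(
    utrs = utrs, sites = sites, families = families,
    factor_genes = factor_genes
  )
}
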