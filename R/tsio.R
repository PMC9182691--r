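#' Read a TargetScan-style 3'-UTR sequence table
#'
#' Parses the tab-delimited UTR-sequences dialect (one row per transcript x
#' species, columns: transcript id, gene id, gene symbol, species taxon id,
#' gapped alignment sequence), restricts to one species, strips alignment
#' gaps, normalises U to T and uppercase, recomputes lengths from the
#' degapped sequence, and keeps one record per (gene_id, species) --
#' representative-UTR selection is taken as given by the file order.
#'
#' @param path path to the tab-delimited file (header row expected).
#' @param species taxon id to retain (e.g. `9606` for human).
#' @return a data frame of UTR records: gene_id, transcript_id, symbol,
#'   species, sequence, length.
#' @export
read_utr_table <- function(path, species) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != 5L)
  if (length(bad)) {
    stop(sprintf(
      "parse error in '%s': expected 5 tab-separated columns, got %d at line %d",
      path, nf[bad[1]], bad[1]
    ), call. = FALSE)
  }
  df <- read_tsv(path, colClasses = "character")
  names(df) <- c("transcript_id", "gene_id", "symbol", "species", "sequence")
  df <- df[df$species == as.character(species), , drop = FALSE]
  if (!nrow(df)) {
    warning(sprintf("no UTR records for species %s in '%s'", species, path),
      call. = FALSE
    )
    out <- empty_utrs_df()
    return(out)
  }
  df$sequence <- normalize_nt(gsub("-", "", df$sequence, fixed = TRUE))
  df$length <- nchar(df$sequence)
  df <- df[!duplicated(paste(df$gene_id, df$species)), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("gene_id", "transcript_id", "symbol", "species", "sequence", "length")]
}

ts_col <- function(nms, pattern, what, path) {
  hit <- grep(pattern, nms, ignore.case = TRUE)
  if (!length(hit)) {
    stop(sprintf("parse error in '%s': no column matching %s", path, what),
      call. = FALSE
    )
  }
  hit[1]
}

KNOWN_SITE_TYPES <- c("7mer-a1", "7mer-m8", "8mer", "8mer-1a")

#' Read a TargetScan-style predicted-targets site table
#'
#' Parses the tab-delimited predicted-targets dialect (columns include miRNA
#' family, gene id, transcript id, species taxon id, 1-based inclusive UTR
#' start / UTR end, site type), restricts to one species and converts
#' coordinates to the internal 0-based half-open convention
#' (`start - 1`, `end`) on the ungapped representative UTR. If `utrs` is
#' supplied, sites referencing unknown genes are collected into a rejects
#' report (attribute `rejects`), and sites whose coordinates exceed the
#' degapped UTR length are dropped with a logged count (attribute
#' `n_rejected_coords`).
#'
#' @param path path to the tab-delimited file (header row expected).
#' @param species taxon id to retain.
#' @param utrs optional UTR data frame from [read_utr_table()] used to
#'   validate gene ids and coordinates.
#' @return a data frame of binding sites: family_id, gene_id, transcript_id,
#'   species, start, end, site_type.
#' @export
read_site_table <- function(path, species, utrs = NULL) {
  df <- read_tsv(path, colClasses = "character")
  nms <- names(df)
  i_fam <- ts_col(nms, "fam", "the miRNA family", path)
  i_gene <- ts_col(nms, "gene.?id", "'Gene ID'", path)
  i_tx <- ts_col(nms, "transcript", "'Transcript ID'", path)
  i_sp <- ts_col(nms, "species", "'Species ID'", path)
  i_start <- ts_col(nms, "utr.?.?start", "'UTR start'", path)
  i_end <- ts_col(nms, "utr.?.?end", "'UTR end'", path)
  i_type <- grep("site.?type", nms, ignore.case = TRUE)

  out <- data.frame(
    family_id = df[[i_fam]], gene_id = df[[i_gene]],
    transcript_id = df[[i_tx]], species = df[[i_sp]],
    start = suppressWarnings(as.integer(df[[i_start]])) - 1L,
    end = suppressWarnings(as.integer(df[[i_end]])),
    site_type = if (length(i_type)) tolower(df[[i_type[1]]]) else "unknown",
    stringsAsFactors = FALSE
  )
  out$site_type[!(out$site_type %in% KNOWN_SITE_TYPES)] <- "unknown"
  out <- out[out$species == as.character(species), , drop = FALSE]
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    stop(sprintf(
      "parse error in '%s': non-numeric UTR coordinates (row %d of species subset)",
      path, bad
    ), call. = FALSE)
  }

  rejects <- out[0, , drop = FALSE]
  n_bad_coord <- 0L
  if (!is.null(utrs)) {
    known <- out$gene_id %in% utrs$gene_id
    rejects <- out[!known, , drop = FALSE]
    out <- out[known, , drop = FALSE]
    len <- utrs$length[match(out$gene_id, utrs$gene_id)]
    ok <- out$start >= 0L & out$end > out$start & out$end <= len
    n_bad_coord <- sum(!ok)
    out <- out[ok, , drop = FALSE]
    if (nrow(rejects) || n_bad_coord) {
      message(sprintf(
        "read_site_table: dropped %d sites on unknown genes, %d with out-of-range coordinates",
        nrow(rejects), n_bad_coord
      ))
    }
  }
  rownames(out) <- NULL
  attr(out, "rejects") <- rejects
  attr(out, "n_rejected_coords") <- n_bad_coord
  out
}

#' Read a miRNA family info table
#'
#' Accepts either the internal dialect (columns `family_id`, `seed`,
#' `conservation_class`) or the TargetScan family-info dialect (columns
#' 'miR family', 'Seed+m8', 'Family Conservation?', where conservation code
#' 2 means broadly conserved, 1 conserved, and lower codes poorly conserved).
#'
#' @param path path to the tab-delimited file.
#' @return data frame: family_id, seed, conservation_class (one row per
#'   family).
#' @export
read_family_table <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  nms <- names(df)
  if (all(c("family_id", "seed", "conservation_class") %in% nms)) {
    out <- df[, c("family_id", "seed", "conservation_class")]
  } else {
    i_fam <- ts_col(nms, "fam", "the miRNA family", path)
    i_seed <- ts_col(nms, "seed", "the seed", path)
    i_cons <- ts_col(nms, "conserv", "the conservation class", path)
    code <- suppressWarnings(as.integer(df[[i_cons]]))
    cls <- ifelse(code >= 2, "broadly_conserved",
      ifelse(code == 1, "conserved", "poorly_conserved")
    )
    cls[is.na(code)] <- "poorly_conserved"
    out <- data.frame(
      family_id = df[[i_fam]],
      seed = normalize_nt(df[[i_seed]]),
      conservation_class = cls, stringsAsFactors = FALSE
    )
  }
  out <- out[!duplicated(out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the prediction filters: broad conservation and optional human-mouse
#' target conservation
#'
#' Keeps only sites of broadly conserved families. When
#' `require_mouse_conservation` is set, a human site is kept only if the same
#' (family, gene) pair also has at least one predicted site in the supplied
#' mouse site collection. Reports (as attributes `n_families`, `n_pairs`,
#' `n_sites` and a message) the counts surviving. Idempotent.
#'
#' @param sites site data frame (internal convention).
#' @param families family table from [read_family_table()].
#' @param mouse_sites site data frame for mouse; required when
#'   `require_mouse_conservation` is TRUE.
#' @param require_mouse_conservation keep a (family, gene) pair only when it
#'   is predicted in both species.
#' @return the filtered site data frame.
#' @export
filter_predictions <- function(sites, families, mouse_sites = NULL,
                               require_mouse_conservation = FALSE) {
  broad <- families$family_id[
    families$conservation_class == "broadly_conserved"
  ]
  out <- sites[sites$family_id %in% broad, , drop = FALSE]
  if (require_mouse_conservation) {
    if (is.null(mouse_sites)) {
      stop(paste(
        "invalid configuration: require_mouse_conservation is set",
        "but no mouse site collection was supplied"
      ), call. = FALSE)
    }
    mouse_pairs <- unique(pair_key(mouse_sites$family_id, mouse_sites$gene_id))
    out <- out[pair_key(out$family_id, out$gene_id) %in% mouse_pairs, ,
      drop = FALSE
    ]
  }
  rownames(out) <- NULL
  n_fam <- length(unique(out$family_id))
  n_pairs <- length(unique(pair_key(out$family_id, out$gene_id)))
  message(sprintf(
    "filter_predictions: %d families, %d unique (family, gene) pairs, %d sites retained",
    n_fam, n_pairs, nrow(out)
  ))
  attr(out, "n_families") <- n_fam
  attr(out, "n_pairs") <- n_pairs
  attr(out, "n_sites") <- nrow(out)
  out
}
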