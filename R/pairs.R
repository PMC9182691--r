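#' Group predicted sites into (family, gene) pairs
#'
#' One group per distinct (family_id, gene_id); sites are sorted by start and
#' the multiplicity (number of sites of that family in that UTR) recorded.
#'
#' @param sites site data frame.
#' @return data frame with columns family_id, gene_id, multiplicity, and
#'   list-columns `starts` and `ends` (0-based half-open site coordinates,
#'   ascending by start).
#' @export
group_pairs <- function(sites) {
  if (!nrow(sites)) {
    out <- data.frame(
      family_id = character(), gene_id = character(),
      multiplicity = integer(), stringsAsFactors = FALSE
    )
    out$starts <- list()
    out$ends <- list()
    return(out)
  }
  ord <- order(sites$family_id, sites$gene_id, sites$start, sites$end)
  s <- sites[ord, , drop = FALSE]
  key <- pair_key(s$family_id, s$gene_id)
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(s)), factor(key, levels = key[first]))
  out <- data.frame(
    family_id = s$family_id[first], gene_id = s$gene_id[first],
    multiplicity = lengths(idx), stringsAsFactors = FALSE
  )
  out$starts <- lapply(idx, function(i) s$start[i])
  out$ends <- lapply(idx, function(i) s$end[i])
  rownames(out) <- NULL
  out
}

#' Split pair groups into selected and background sets
#'
#' The selected set holds groups whose family is in `selected_families` AND
#' whose gene is factor-bound; every other group is background. The control
#' subset `background_in_factor_utrs` holds background groups whose gene is
#' factor-bound (the background-in-factor-UTRs contrast).
#'
#' @param groups data frame from [group_pairs()].
#' @param selected_families character vector of enriched family ids.
#' @param factor_genes character vector of factor-bound gene ids.
#' @return list of class `pair_sets` with elements `selected`, `background`,
#'   `background_in_factor_utrs` (each a groups data frame) and `counts`.
#' @export
split_sets <- function(groups, selected_families, factor_genes) {
  if (!length(factor_genes)) {
    stop("factor_genes must be nonempty", call. = FALSE)
  }
  if (!length(selected_families)) selected_families <- character(0)
  ord <- order(groups$family_id, groups$gene_id)
  groups <- groups[ord, , drop = FALSE]
  rownames(groups) <- NULL
  sel <- groups$family_id %in% selected_families &
    groups$gene_id %in% factor_genes
  selected <- groups[sel, , drop = FALSE]
  background <- groups[!sel, , drop = FALSE]
  bif <- background[background$gene_id %in% factor_genes, , drop = FALSE]
  if (!nrow(selected)) {
    warning("selected pair set is empty", call. = FALSE)
  }
  counts <- c(
    selected = nrow(selected), background = nrow(background),
    background_in_factor_utrs = nrow(bif),
    selected_sites = sum(selected$multiplicity),
    background_sites = sum(background$multiplicity)
  )
  message(sprintf(
    "split_sets: %d selected pairs (%d sites), %d background pairs (%d sites), %d background pairs in factor UTRs",
    counts["selected"], counts["selected_sites"], counts["background"],
    counts["background_sites"], counts["background_in_factor_utrs"]
  ))
  structure(
    list(
      selected = selected, background = background,
      background_in_factor_utrs = bif, counts = counts
    ),
    class = "pair_sets"
  )
}

# Flatten a groups data frame back to a site-level table.
flatten_groups <- function(groups) {
  if (!nrow(groups)) {
    return(empty_sites_df()[, c("family_id", "gene_id", "start", "end")])
  }
  n <- groups$multiplicity
  data.frame(
    family_id = rep(groups$family_id, n),
    gene_id = rep(groups$gene_id, n),
    start = unlist(groups$starts, use.names = FALSE),
    end = unlist(groups$ends, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# Serialise groups for the pairs_*.tsv outputs.
groups_to_table <- function(groups) {
  spans <- mapply(function(s, e) paste(sprintf("%d-%d", s, e), collapse = ";"),
    groups$starts, groups$ends,
    SIMPLIFY = TRUE, USE.NAMES = FALSE
  )
  data.frame(
    family_id = groups$family_id, gene_id = groups$gene_id,
    multiplicity = groups$multiplicity,
    sites = if (length(spans)) spans else character(0),
    stringsAsFactors = FALSE
  )
}
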