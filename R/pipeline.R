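#' Build a validated pipeline run configuration
#'
#' @param mode `"synthetic"` (generate data with [generate_dataset()]) or
#'   `"targetscan"` (read flat files).
#' @param output_dir directory for all outputs.
#' @param rng_seed root integer seed; per-stage seeds are derived from it
#'   deterministically so a rerun of one stage reproduces its output.
#' @param synth a [synth_config()] or argument list for it (synthetic mode;
#'   if it carries no `rng_seed`, the stage seed derived from `rng_seed` is
#'   used).
#' @param utr_file,site_file,family_file,mouse_site_file,factor_genes_file
#'   input paths (targetscan mode). `factor_genes_file` may name several
#'   files (one factor dataset each).
#' @param species taxon id of the analysis species (default 9606, human).
#' @param require_mouse_conservation keep only (family, gene) pairs predicted
#'   in both human and mouse (needs `mouse_site_file`).
#' @param n_iter_enrich,n_iter_ratio Monte-Carlo iteration counts.
#' @param alpha significance level for adjusted enrichment p-values and the
#'   per-family Fisher summary.
#' @param selection_rule `"any_dataset"` or `"all_datasets"` (see
#'   [select_families()]).
#' @param enrich_tail,enrich_r_level audit flags of [enrichment_test()].
#' @param fisher_alternative sidedness of the Fisher tests.
#' @param family_matched_fisher per-family Fisher against family-matched
#'   background instead of the pooled background.
#' @param n_background_regions random 1000-nt windows per background GC
#'   profile.
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "targetscan"),
                       output_dir, rng_seed,
                       synth = list(),
                       utr_file = NULL, site_file = NULL, family_file = NULL,
                       mouse_site_file = NULL, factor_genes_file = NULL,
                       species = "9606",
                       require_mouse_conservation = FALSE,
                       n_iter_enrich = 10000L, n_iter_ratio = 10000L,
                       alpha = 0.05,
                       selection_rule = "any_dataset",
                       enrich_tail = "upper", enrich_r_level = "site",
                       fisher_alternative = "two.sided",
                       family_matched_fisher = FALSE,
                       n_background_regions = 10000L) {
  mode <- match.arg(mode)
  if (missing(output_dir)) stop_config("output_dir", "is required")
  if (missing(rng_seed)) stop_config("rng_seed", "is required")
  rng_seed <- check_count(rng_seed, "rng_seed")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_config("alpha", "must lie in (0, 1)")
  }
  if (mode == "targetscan") {
    for (nm in c("utr_file", "site_file", "family_file", "factor_genes_file")) {
      v <- get(nm)
      if (is.null(v)) stop_config(nm, "is required in targetscan mode")
      if (!all(file.exists(v))) {
        stop_config(nm, sprintf("does not exist: %s", paste(v, collapse = ", ")))
      }
    }
    if (require_mouse_conservation &&
      (is.null(mouse_site_file) || !file.exists(mouse_site_file))) {
      stop_config("mouse_site_file", "is required when require_mouse_conservation is set")
    }
  }
  structure(
    list(
      mode = mode, output_dir = output_dir, rng_seed = rng_seed,
      synth = synth, utr_file = utr_file, site_file = site_file,
      family_file = family_file, mouse_site_file = mouse_site_file,
      factor_genes_file = factor_genes_file, species = as.character(species),
      require_mouse_conservation = require_mouse_conservation,
      n_iter_enrich = check_count(n_iter_enrich, "n_iter_enrich", 1L),
      n_iter_ratio = check_count(n_iter_ratio, "n_iter_ratio", 1L),
      alpha = alpha, selection_rule = selection_rule,
      enrich_tail = enrich_tail, enrich_r_level = enrich_r_level,
      fisher_alternative = fisher_alternative,
      family_matched_fisher = family_matched_fisher,
      n_background_regions = check_count(
        n_background_regions,
        "n_background_regions", 1L
      )
    ),
    class = "run_config"
  )
}

#' Read a plain-text key = value run configuration file
#'
#' Lines of the form `key = value` (comments start with `#`). Numeric-looking
#' values are coerced; `synth.<field>` keys populate the synthetic generator
#' configuration; `factor_genes_file` may be a comma-separated list.
#'
#' @param path configuration file path.
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  args <- list()
  synth <- list()
  for (m in kv) {
    if (length(m) != 3L) next
    key <- trimws(m[2])
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num) && grepl("^[-0-9.eE+]+$", val)) val <- num
    if (identical(val, "TRUE") || identical(val, "true")) val <- TRUE
    if (identical(val, "FALSE") || identical(val, "false")) val <- FALSE
    if (startsWith(key, "synth.")) {
      synth[[sub("^synth\\.", "", key)]] <- val
    } else if (key == "factor_genes_file" && is.character(val)) {
      args[[key]] <- trimws(strsplit(val, ",")[[1]])
    } else if (key == "enriched_families" && is.character(val)) {
      synth[["enriched_families"]] <- as.integer(trimws(strsplit(val, ",")[[1]]))
    } else {
      args[[key]] <- val
    }
  }
  args$synth <- synth
  do.call(run_config, args)
}

stage_seed <- function(cfg, stage) {
  derive_seed(cfg$rng_seed, switch(stage,
    synth = 1L, enrich = 2L, background_gc = 3L, ratio = 4L
  ), salt = 7L)
}

load_inputs <- function(cfg) {
  if (cfg$mode == "synthetic") {
    sc <- cfg$synth
    if (!inherits(sc, "synth_config")) {
      if (is.null(sc$rng_seed)) sc$rng_seed <- stage_seed(cfg, "synth")
      sc <- do.call(synth_config, sc)
    }
    ds <- generate_dataset(sc)
    list(
      utrs = ds$utrs, sites = ds$sites, families = ds$families,
      factor_sets = list(dataset1 = ds$factor_genes), dataset = ds
    )
  } else {
    utrs <- read_utr_table(cfg$utr_file, cfg$species)
    sites <- read_site_table(cfg$site_file, cfg$species, utrs = utrs)
    families <- read_family_table(cfg$family_file)
    mouse <- NULL
    if (cfg$require_mouse_conservation) {
      mouse <- read_site_table(cfg$mouse_site_file, "10090")
    }
    sites <- filter_predictions(sites, families,
      mouse_sites = mouse,
      require_mouse_conservation = cfg$require_mouse_conservation
    )
    files <- cfg$factor_genes_file
    factor_sets <- lapply(files, readLines)
    names(factor_sets) <- if (!is.null(names(files)) && all(nzchar(names(files)))) {
      names(files)
    } else {
      tools::file_path_sans_ext(basename(files))
    }
    list(
      utrs = utrs, sites = sites, families = families,
      factor_sets = factor_sets, dataset = NULL
    )
  }
}

#' Run the full analysis pipeline
#'
#' Sequences the stages: data (synthetic generation or flat-file reading and
#' filtering), per-dataset family enrichment with BH adjustment, family
#' selection, pair-set construction, feature extraction (UTR lengths, site
#' positions, GC profiles, multiplicity, inter-site features) and statistics
#' (ratio resampling tests, Fisher tests). All tables are written under
#' `config$output_dir` together with a `run_manifest.json` and a plain-text
#' `report.txt`. Identical config and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, the result bundle (list of all tables) with class
#'   `pipeline_bundle`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, as.list(cfg))
  out <- cfg$output_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE)) {
    stop(sprintf("pipeline stage 'setup' failed: cannot create '%s'", out),
      call. = FALSE
    )
  }

  run_stage <- function(name, expr) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  inputs <- run_stage("data", load_inputs(cfg))
  utrs <- inputs$utrs
  sites <- inputs$sites
  if (cfg$mode == "synthetic") {
    run_stage("data", write_dataset(inputs$dataset, file.path(out, "data")))
  }
  universe <- sort(unique(sites$gene_id))

  enr_seed <- stage_seed(cfg, "enrich")
  enrichment <- run_stage("enrich", {
    res <- lapply(seq_along(inputs$factor_sets), function(i) {
      enrich_dataset(sites, inputs$factor_sets[[i]],
        universe_genes = universe,
        dataset_id = names(inputs$factor_sets)[i],
        n_iter = cfg$n_iter_enrich,
        rng_seed = derive_seed(enr_seed, i),
        tail = cfg$enrich_tail, r_level = cfg$enrich_r_level
      )
    })
    do.call(rbind, res)
  })
  selection <- run_stage("enrich", {
    select_families(enrichment, alpha = cfg$alpha, rule = cfg$selection_rule)
  })
  write_tsv(enrichment, file.path(out, "enrichment.tsv"))
  writeLines(selection$selected, file.path(out, "selected_families.txt"))

  factor_genes <- sort(unique(unlist(inputs$factor_sets)))
  psets <- run_stage("pairs", {
    groups <- group_pairs(sites)
    split_sets(groups, selection$selected, factor_genes)
  })
  write_tsv(groups_to_table(psets$selected), file.path(out, "pairs_selected.tsv"))
  write_tsv(groups_to_table(psets$background), file.path(out, "pairs_background.tsv"))
  write_tsv(
    groups_to_table(psets$background_in_factor_utrs),
    file.path(out, "pairs_background_in_factor.tsv")
  )

  feat <- run_stage("features", pipeline_features(cfg, utrs, psets, factor_genes))
  for (nm in names(feat$files)) write_tsv(feat$files[[nm]], file.path(out, nm))

  stats_out <- run_stage(
    "stats",
    pipeline_stats(cfg, utrs, psets, feat, universe, factor_genes)
  )
  write_tsv(stats_out$table1, file.path(out, "table1.tsv"))
  write_tsv(stats_out$fisher_overall, file.path(out, "fisher_overall.tsv"))
  write_tsv(stats_out$fisher_per_family, file.path(out, "fisher_per_family.tsv"))

  bundle <- structure(
    list(
      config = cfg, enrichment = enrichment, selection = selection,
      pair_sets = psets, features = feat, stats = stats_out,
      dataset = inputs$dataset, utrs = utrs, sites = sites,
      factor_genes = factor_genes, output_dir = out
    ),
    class = "pipeline_bundle"
  )

  manifest <- list(
    package = as.character(utils::packageVersion("mirtarnet")),
    r_version = as.character(getRversion()),
    mode = cfg$mode, rng_seed = cfg$rng_seed,
    config = cfg[setdiff(names(cfg), "synth")],
    synth = if (cfg$mode == "synthetic") unclass(inputs$dataset$config) else NULL,
    input_checksums = if (cfg$mode == "targetscan") {
      as.list(tools::md5sum(unlist(cfg[c(
        "utr_file", "site_file",
        "family_file", "factor_genes_file"
      )], use.names = FALSE)))
    } else {
      NULL
    },
    outputs = list.files(out, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  writeLines(make_report(bundle), file.path(out, "report.txt"))
  invisible(bundle)
}

pipeline_features <- function(cfg, utrs, psets, factor_genes) {
  bg_seed <- stage_seed(cfg, "background_gc")
  sel_sites <- flatten_groups(psets$selected)
  bg_sites <- flatten_groups(psets$background)
  bif_sites <- flatten_groups(psets$background_in_factor_utrs)

  sf <- list(
    selected = if (nrow(sel_sites)) site_features(sel_sites, utrs) else NULL,
    background = if (nrow(bg_sites)) site_features(bg_sites, utrs) else NULL,
    background_in_factor = if (nrow(bif_sites)) {
      site_features(bif_sites, utrs)
    } else {
      NULL
    }
  )
  profiles <- list(
    selected = gc_profile_around_sites(sel_sites, utrs),
    background = gc_profile_around_sites(bg_sites, utrs),
    background_in_factor = gc_profile_around_sites(bif_sites, utrs)
  )
  factor_utrs <- utrs[utrs$gene_id %in% factor_genes, , drop = FALSE]
  bg_prof <- list(
    factor_utrs = background_gc_profile(factor_utrs,
      n_regions = cfg$n_background_regions, rng_seed = derive_seed(bg_seed, 1)
    ),
    all_utrs = background_gc_profile(utrs,
      n_regions = cfg$n_background_regions, rng_seed = derive_seed(bg_seed, 2)
    )
  )
  mult <- list(
    selected = multiplicity_table(psets$selected),
    background = multiplicity_table(psets$background)
  )
  inter <- list(
    selected = intersite_features(psets$selected, utrs),
    background = intersite_features(psets$background, utrs),
    background_in_factor = intersite_features(
      psets$background_in_factor_utrs, utrs
    )
  )
  gene_gc <- function(gene_set) {
    u <- utrs[utrs$gene_id %in% gene_set, , drop = FALSE]
    stats::setNames(gc_content(u$sequence), u$gene_id)
  }

  files <- list(
    "gc_profile_selected.tsv" = profiles$selected,
    "gc_profile_background.tsv" = profiles$background,
    "gc_profile_background_in_factor.tsv" = profiles$background_in_factor,
    "gc_background_factor_utrs.tsv" = bg_prof$factor_utrs,
    "gc_background_all_utrs.tsv" = bg_prof$all_utrs,
    "multiplicity_selected.tsv" = mult$selected$per_family,
    "multiplicity_background.tsv" = mult$background$per_family,
    "intersite_selected.tsv" = inter$selected,
    "intersite_background.tsv" = inter$background,
    "intersite_background_in_factor.tsv" = inter$background_in_factor
  )
  list(
    site_features = sf, profiles = profiles, background_profiles = bg_prof,
    multiplicity = mult, intersite = inter, gene_gc = gene_gc, files = files
  )
}

pipeline_stats <- function(cfg, utrs, psets, feat, universe, factor_genes) {
  rt_seed <- stage_seed(cfg, "ratio")
  sel_genes <- unique(psets$selected$gene_id)
  factor_in_universe <- intersect(factor_genes, universe)

  len_sel <- if (length(sel_genes)) {
    utr_length_stats(utrs, sel_genes)
  } else {
    list(values = numeric(0))
  }
  len_all <- utr_length_stats(utrs, universe)
  len_pool_sel <- utr_length_stats(utrs, factor_in_universe)

  sf <- feat$site_features
  pool_pos <- if (!is.null(sf$background_in_factor) || !is.null(sf$selected)) {
    rbind(sf$selected, sf$background_in_factor)
  } else {
    NULL
  }
  all_pos <- rbind(sf$selected, sf$background)

  gc_sel <- feat$gene_gc(sel_genes)
  gc_all <- feat$gene_gc(universe)
  gc_pool_sel <- feat$gene_gc(factor_in_universe)

  k <- 0L
  next_seed <- function() {
    k <<- k + 1L
    derive_seed(rt_seed, k)
  }
  row <- function(va, vb, pa, pb, label) {
    compare_feature(va, vb, pa, pb, label,
      n_iter = cfg$n_iter_ratio,
      rng_seed = next_seed()
    )
  }
  inter <- feat$intersite
  inter_pool_sel <- rbind(inter$selected, inter$background_in_factor)
  rows <- list(
    row(
      len_sel$values, len_all$values, len_pool_sel$values, len_all$values,
      "utr_length"
    ),
    row(
      sf$selected$dist_start, sf$background$dist_start,
      pool_pos$dist_start, all_pos$dist_start, "dist_utr_start_to_site"
    ),
    row(
      sf$selected$dist_end, sf$background$dist_end,
      pool_pos$dist_end, all_pos$dist_end, "dist_site_to_utr_end"
    ),
    row(
      sf$selected$rel_pos, sf$background$rel_pos,
      pool_pos$rel_pos, all_pos$rel_pos, "relative_site_position"
    ),
    row(gc_sel, gc_all, gc_pool_sel, gc_all, "utr_gc_content"),
    row(
      inter$selected$gap, inter$background$gap,
      inter_pool_sel$gap, c(inter$selected$gap, inter$background$gap),
      "intersite_distance"
    ),
    row(
      inter$background_in_factor$gap, inter$background$gap,
      inter_pool_sel$gap, c(inter$selected$gap, inter$background$gap),
      "intersite_distance_background_in_factor"
    ),
    row(
      inter$selected$gap_gc, inter$background$gap_gc,
      inter_pool_sel$gap_gc, c(inter$selected$gap_gc, inter$background$gap_gc),
      "intersite_gc"
    ),
    row(
      inter$background_in_factor$gap_gc, inter$background$gap_gc,
      inter_pool_sel$gap_gc, c(inter$selected$gap_gc, inter$background$gap_gc),
      "intersite_gc_background_in_factor"
    )
  )
  table1 <- do.call(rbind, rows)

  mult <- feat$multiplicity
  fisher_overall <- if (mult$selected$pairs_total > 0 &&
    mult$background$pairs_total > 0) {
    fo <- fisher_multiplicity(
      c(
        mult$selected$pairs_multi,
        mult$selected$pairs_total - mult$selected$pairs_multi
      ),
      c(
        mult$background$pairs_multi,
        mult$background$pairs_total - mult$background$pairs_multi
      ),
      alternative = cfg$fisher_alternative
    )
    data.frame(
      selected_multi = fo$table[1, 1], selected_single = fo$table[1, 2],
      background_multi = fo$table[2, 1], background_single = fo$table[2, 2],
      odds_ratio = fo$odds_ratio, p = fo$p, stringsAsFactors = FALSE
    )
  } else {
    data.frame(
      selected_multi = mult$selected$pairs_multi,
      selected_single = mult$selected$pairs_total - mult$selected$pairs_multi,
      background_multi = mult$background$pairs_multi,
      background_single = mult$background$pairs_total -
        mult$background$pairs_multi,
      odds_ratio = NA_real_, p = NA_real_, stringsAsFactors = FALSE
    )
  }
  fisher_per_family <- per_family_fisher(
    psets$selected, psets$background,
    alpha = cfg$alpha, family_matched = cfg$family_matched_fisher,
    alternative = cfg$fisher_alternative
  )
  list(
    table1 = table1, fisher_overall = fisher_overall,
    fisher_per_family = fisher_per_family,
    n_significant_families = attr(fisher_per_family, "n_significant")
  )
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Render a plain-text report from a pipeline bundle
#'
#' Four sections: the summary statistics table with resampling p-values, the
#' GC profile tables around sites and for random background windows, the
#' multiplicity summary with the Fisher tests, and the inter-site summary.
#' Missing sections are marked explicitly rather than crashing.
#'
#' @param bundle the list returned by [run_pipeline()].
#' @return character vector of report lines.
#' @export
make_report <- function(bundle) {
  section <- function(title, body) {
    c(paste0("== ", title, " =="), body, "")
  }
  lines <- c(
    "mirtarnet pipeline report",
    sprintf(
      "mode: %s | seed: %d | alpha: %g",
      bundle$config$mode, bundle$config$rng_seed, bundle$config$alpha
    ),
    sprintf(
      "selected families (%d): %s",
      length(bundle$selection$selected),
      if (length(bundle$selection$selected)) {
        paste(bundle$selection$selected, collapse = ", ")
      } else {
        "(none)"
      }
    ),
    ""
  )

  t1 <- bundle$stats$table1
  lines <- c(lines, section("Summary statistics (selected vs background)", if (is.null(t1)) {
    "[missing: summary table]"
  } else {
    c(
      sprintf(
        "%-40s %8s %10s %10s %8s %10s %10s %8s %10s",
        "analysis", "N_sel", "mean_sel", "sd_sel", "N_bg",
        "mean_bg", "sd_bg", "ratio", "p"
      ),
      sprintf(
        "%-40s %8d %10s %10s %8d %10s %10s %8s %10s",
        t1$analysis, t1$n_selected, fmt_num(t1$mean_selected),
        fmt_num(t1$sd_selected), t1$n_background,
        fmt_num(t1$mean_background), fmt_num(t1$sd_background),
        fmt_num(t1$ratio), fmt_num(t1$p)
      )
    )
  }))

  prof <- bundle$features$profiles
  bgp <- bundle$features$background_profiles
  gc_body <- if (is.null(prof)) {
    "[missing: GC profiles]"
  } else {
    unlist(lapply(names(prof), function(nm) {
      p <- prof[[nm]]
      c(
        sprintf("-- GC around sites: %s --", nm),
        sprintf(
          "%-8s %6s %8s %8s %8s", "bin", "n", "mean_gc", "ci_low", "ci_high"
        ),
        sprintf(
          "%-8s %6d %8s %8s %8s", p$bin, p$n_obs, fmt_num(p$mean_gc),
          fmt_num(p$ci_low), fmt_num(p$ci_high)
        )
      )
    }))
  }
  bg_body <- if (is.null(bgp)) {
    "[missing: background GC profiles]"
  } else {
    unlist(lapply(names(bgp), function(nm) {
      p <- bgp[[nm]]
      c(
        sprintf("-- background windows: %s --", nm),
        sprintf("%-8s %6d mean_gc %s", p$bin, p$n_obs, fmt_num(p$mean_gc))
      )
    }))
  }
  lines <- c(lines, section("GC-content profiles", c(gc_body, bg_body)))

  mult <- bundle$features$multiplicity
  fo <- bundle$stats$fisher_overall
  mult_body <- if (is.null(mult)) {
    "[missing: multiplicity]"
  } else {
    c(
      sprintf(
        "selected: %d of %d pairs with multiple sites",
        mult$selected$pairs_multi, mult$selected$pairs_total
      ),
      sprintf(
        "background: %d of %d pairs with multiple sites",
        mult$background$pairs_multi, mult$background$pairs_total
      ),
      if (is.null(fo)) {
        "[missing: overall Fisher test]"
      } else {
        sprintf(
          "Fisher exact test: odds ratio %s, p = %s",
          fmt_num(fo$odds_ratio), fmt_num(fo$p)
        )
      },
      sprintf(
        "families with p < alpha (per-family test): %d of %d",
        bundle$stats$n_significant_families,
        nrow(bundle$stats$fisher_per_family)
      )
    )
  }
  lines <- c(lines, section("Multi-site multiplicity", mult_body))

  inter <- bundle$features$intersite
  inter_body <- if (is.null(inter)) {
    "[missing: inter-site features]"
  } else {
    unlist(lapply(names(inter), function(nm) {
      x <- inter[[nm]]
      if (!nrow(x)) {
        return(sprintf("%s: no multi-site pairs (empty contrast)", nm))
      }
      sprintf(
        "%s: n = %d, mean gap = %s nt, mean gap GC = %s",
        nm, nrow(x), fmt_num(mean(x$gap)), fmt_num(mean(x$gap_gc, na.rm = TRUE))
      )
    }))
  }
  c(lines, section("Inter-site distance and GC", inter_body))
}
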