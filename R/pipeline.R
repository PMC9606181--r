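#' Default pipeline configuration
#'
#' All analysis constants in one place: confidence thresholds
#' (low 0.79, primary 0.83, high 0.87; negative cutoff 0.83), hub
#' percentile 80, community sign policy, tree-cut fraction grid including
#' the primary 0.70 cut, ANOVA alpha 0.05, and the master seed. Values can
#' be overridden individually or loaded from a YAML file with
#' [read_config()].
#'
#' @param seed master seed for synthetic runs
#' @return a named list of class `run_config`
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    thresholds = default_thresholds("methods"),
    hub_percentile = 80,
    require_all_levels = TRUE,
    sign_policy = "positive_only",
    cut_fractions = seq(0.50, 0.95, by = 0.05),
    primary_cut = 0.70,
    alpha = 0.05,
    display_threshold = 0.6,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_config()].
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (k == "thresholds") {
      for (t in names(user$thresholds)) cfg$thresholds[[t]] <- user$thresholds[[t]]
    } else {
      cfg[[k]] <- user[[k]]
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' Checks threshold ordering (low < primary < high), percentile range and
#' fraction bounds before any computation happens.
#'
#' @param config a `run_config`
#' @return invisibly, the config
#' @export
validate_config <- function(config) {
  th <- config$thresholds
  if (!(th$low < th$primary && th$primary < th$high)) {
    stop("thresholds must be strictly increasing: low < primary < high",
         call. = FALSE)
  }
  if (th$negative <= 0) stop("negative cutoff must be positive", call. = FALSE)
  if (config$hub_percentile <= 0 || config$hub_percentile >= 100) {
    stop("hub_percentile must lie in (0, 100)", call. = FALSE)
  }
  if (any(config$cut_fractions <= 0) || any(config$cut_fractions > 1)) {
    stop("cut_fractions must lie in (0, 1]", call. = FALSE)
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  invisible(config)
}

#' Read activity tables from CSV/TSV
#'
#' Accepts either the wide dialect (one file per group: an `animal` column
#' followed by one numeric column per region; the group label is given or
#' taken from the file name) or the long dialect (columns `animal`,
#' `group`, `region`, `density`), auto-detected from the header. "NA" and
#' empty tokens become missing values; negative densities and duplicate
#' (animal, region) pairs are errors.
#'
#' @param path input file
#' @param group_label group label for a wide file (default: file name
#'   without the extension)
#' @return named list of `region_activity_table`
#' @export
read_region_table <- function(path, group_label = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  header <- names(df)
  if (anyDuplicated(header)) {
    stop("duplicated column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  if (all(c("animal", "group", "region", "density") %in% header)) {
    return(long_to_tables(df))
  }
  if (!"animal" %in% header) {
    stop("wide files need an 'animal' column; long files need ",
         "animal/group/region/density", call. = FALSE)
  }
  group_label <- group_label %||% sub("\\.[^.]*$", "", basename(path))
  vals <- as.matrix(df[, setdiff(header, "animal"), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df$animal)
  check_densities(vals)
  tab <- structure(list(group_label = group_label, values = vals,
                        animal_ids = rownames(vals)),
                   class = "region_activity_table")
  stats::setNames(list(tab), group_label)
}

long_to_tables <- function(df) {
  key <- paste(df$group, df$animal, df$region, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (animal, region) entry: ", d$animal, " / ", d$region,
         " in group ", d$group, call. = FALSE)
  }
  tables <- lapply(split(df, df$group), function(g) {
    wide <- stats::reshape(g[, c("animal", "region", "density")],
                           idvar = "animal", timevar = "region",
                           direction = "wide")
    vals <- as.matrix(wide[, -1L, drop = FALSE])
    colnames(vals) <- sub("^density\\.", "", colnames(vals))
    rownames(vals) <- as.character(wide$animal)
    # keep first-appearance region order
    vals <- vals[, unique(g$region), drop = FALSE]
    check_densities(vals)
    structure(list(group_label = g$group[1L], values = vals,
                   animal_ids = rownames(vals)),
              class = "region_activity_table")
  })
  tables[unique(df$group)]
}

check_densities <- function(vals) {
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative density values are not allowed", call. = FALSE)
  }
  invisible(vals)
}

#' Run the full coactivation-network pipeline
#'
#' For every group: the inter-regional Pearson correlation matrix, the six
#' thresholded networks (three confidence levels for the positive sign and
#' the negative network reported at each level's label for bookkeeping
#' symmetry), per-node degree and betweenness metrics, the composite hub
#' report, spectral community detection on the weighted network, and
#' complete-linkage hierarchical clustering with the tree-cut module
#' profile. Optionally a region-wise factorial ANOVA stage. All outputs are
#' written under `out_dir` together with a manifest (config, seed, counts,
#' package version) that makes the run auditable and re-runnable.
#'
#' @param config a `run_config`
#' @param tables named list of `region_activity_table`; if `NULL`, a
#'   synthetic cohort is generated from `design`/`planted`
#' @param design,planted synthetic design used when `tables` is `NULL`
#'   (defaults: [default_study_design()] with the config seed and
#'   [default_planted_structure()])
#' @param out_dir output directory; `NULL` computes everything in memory
#'   and writes nothing
#' @param run_anova logical; run the per-region factorial ANOVA stage
#'   (default TRUE when group labels parse into factors)
#' @return a named list: `groups` (per-group results), `manifest`,
#'   `anova` (optional)
#' @export
run_pipeline <- function(config = default_config(), tables = NULL,
                         design = NULL, planted = NULL, out_dir = NULL,
                         run_anova = NULL) {
  validate_config(config)
  if (is.null(tables)) {
    design <- design %||% default_study_design(seed = config$seed)
    planted <- planted %||% default_planted_structure()
    tables <- generate_cohort(design, planted)
  }
  usable <- vapply(tables, function(t) nrow(t$values) >= 2, logical(1))
  skipped <- names(tables)[!usable]
  for (g in skipped) {
    message("skipping group '", g, "': fewer than 2 animals")
  }
  tables <- tables[usable]
  if (!length(tables)) stop("no usable groups", call. = FALSE)

  groups <- lapply(tables, function(tab) analyse_group(tab, config))
  names(groups) <- vapply(tables, function(t) t$group_label, character(1))

  anova_out <- NULL
  parseable <- all(lengths(strsplit(names(groups), "_", fixed = TRUE)) %in%
                     c(2L, 3L))
  run_anova <- run_anova %||% (parseable && length(groups) >= 4)
  if (isTRUE(run_anova)) {
    nf <- length(strsplit(names(groups)[1], "_", fixed = TRUE)[[1]])
    factors <- c("genotype", "treatment", "stress")[seq_len(nf)]
    anova_out <- region_anova_report(cohort_long(tables), factors = factors,
                                     alpha = config$alpha)
  }

  manifest <- build_manifest(config, groups)
  result <- list(groups = groups, manifest = manifest, anova = anova_out)
  if (!is.null(out_dir)) write_run(result, tables, out_dir, config)
  result
}

analyse_group <- function(tab, config) {
  corr <- suppressWarnings(correlation_matrix(tab))
  nets_pos <- lapply(stats::setNames(nm = c("low", "primary", "high")),
                     function(lv) threshold_network(corr, lv, "positive",
                                                    config$thresholds))
  net_neg <- threshold_network(corr, "primary", "negative",
                               config$thresholds)
  metrics <- data.frame(
    region = corr$region_names,
    degree_low = node_degree(nets_pos$low),
    degree_primary = node_degree(nets_pos$primary),
    degree_high = node_degree(nets_pos$high),
    degree_negative = node_degree(net_neg),
    betweenness = betweenness_centrality(nets_pos$primary),
    stringsAsFactors = FALSE, row.names = NULL)
  hubs <- suppressWarnings(
    identify_hubs(nets_pos, percentile = config$hub_percentile,
                  require_all_levels = config$require_all_levels))
  wnet <- weighted_network(corr, sign_policy = config$sign_policy)
  modules <- suppressWarnings(spectral_communities(wnet))
  dend_input <- euclidean_distance_matrix(corr)
  dend <- complete_linkage(dend_input)
  profile <- cut_profile(dend, config$cut_fractions)
  primary_labels <- tree_cut(dend, config$primary_cut)
  list(group_label = tab$group_label,
       n_animals = nrow(tab$values),
       correlation = corr,
       networks = c(nets_pos, list(negative = net_neg)),
       metrics = metrics,
       hubs = hubs,
       modules = modules,
       dendrogram = dend,
       excluded_regions = attr(dend_input, "excluded"),
       cut_profile = profile,
       tree_modules = primary_labels)
}

build_manifest <- function(config, groups) {
  list(
    package = "fosnet",
    version = as.character(utils::packageVersion("fosnet")),
    seed = config$seed,
    config = config[setdiff(names(config), "seed")],
    config_hash = config_hash(config),
    groups = lapply(groups, function(g) list(
      n_animals = g$n_animals,
      edges_low = sum(g$networks$low$adjacency) / 2,
      edges_primary = sum(g$networks$primary$adjacency) / 2,
      edges_high = sum(g$networks$high$adjacency) / 2,
      edges_negative = sum(g$networks$negative$adjacency) / 2,
      n_hubs = length(g$hubs$hubs),
      hubs = g$hubs$hubs,
      n_modules_spectral = g$modules$n_modules,
      Q = g$modules$Q,
      n_modules_tree_cut = length(unique(g$tree_modules)),
      excluded_regions = g$excluded_regions))
  )
}

config_hash <- function(config) {
  flat <- paste(deparse(config[order(names(config))]), collapse = "")
  sprintf("%08x", string_hash(flat))
}

write_run <- function(result, tables, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (g in result$groups) {
    gd <- file.path(out_dir, g$group_label)
    dir.create(gd, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(region = g$correlation$region_names,
                                g$correlation$r, check.names = FALSE),
                     file.path(gd, "correlation.csv"), row.names = FALSE)
    edges <- do.call(rbind, lapply(g$networks, function(net)
      network_edges(net, g$correlation)))
    utils::write.table(edges, file.path(gd, "edges.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(merge(g$metrics,
                             g$hubs$trace[, c("region", "is_hub")],
                             by = "region", sort = FALSE),
                       file.path(gd, "node_metrics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(hubs = g$hubs$hubs, cutoffs = as.list(g$hubs$cutoffs),
           percentile = g$hubs$percentile),
      file.path(gd, "hubs.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(
      data.frame(region = names(g$modules$labels),
                 module_id = unname(g$modules$labels)),
      file.path(gd, "modules.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
    jsonlite::write_json(
      list(Q = g$modules$Q, n_modules = g$modules$n_modules),
      file.path(gd, "modularity.json"), auto_unbox = TRUE, digits = NA)
    merges <- data.frame(step = seq_len(nrow(g$dendrogram$merge)),
                         a = g$dendrogram$merge[, 1L],
                         b = g$dendrogram$merge[, 2L],
                         height = g$dendrogram$height)
    utils::write.table(merges, file.path(gd, "dendrogram_merges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.csv(g$cut_profile, file.path(gd, "cut_profile.csv"),
                     row.names = FALSE)
    utils::write.table(
      data.frame(region = names(g$tree_modules),
                 module_id = unname(g$tree_modules)),
      file.path(gd, "tree_modules.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  utils::write.table(cohort_long(tables),
                     file.path(out_dir, "cohort_long.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(result$anova)) {
    anova_df <- do.call(rbind, lapply(names(result$anova), function(rg) {
      a <- result$anova[[rg]]
      data.frame(region = rg, as.data.frame(a), stringsAsFactors = FALSE)
    }))
    utils::write.csv(anova_df, file.path(out_dir, "anova_report.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
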