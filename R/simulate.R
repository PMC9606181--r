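#' Build the target latent correlation matrix from planted structure
#'
#' Assembles a region-by-region correlation target: `within_module_r` inside
#' planted modules, `between_module_r` across modules, and hub rows/columns
#' raised by `hub_extra_r` (capped at `r_max`). The raw target need not be a
#' valid correlation matrix, so it is repaired by clipping negative
#' eigenvalues at zero and re-normalising the diagonal to one
#' (`cov2cor`-style); the repair is deterministic.
#'
#' @param planted a [planted_structure()]
#' @param regions optional region subset/order; defaults to the regions of
#'   `planted`
#' @return symmetric positive semidefinite matrix with unit diagonal,
#'   dimnames = regions
#' @examples
#' p <- planted_structure(setNames(rep(1:2, each = 3), paste0("R", 1:6)),
#'                        within_module_r = 0.8, between_module_r = 0)
#' round(build_target_correlation(p), 2)
#' @export
build_target_correlation <- function(planted, regions = NULL) {
  stopifnot(inherits(planted, "planted_structure"))
  all_regions <- names(planted$module_assignment)
  regions <- regions %||% all_regions
  if (!all(regions %in% all_regions)) {
    stop("regions must be drawn from the planted structure", call. = FALSE)
  }
  mod <- planted$module_assignment[regions]
  R <- length(regions)
  same <- outer(mod, mod, "==")
  target <- ifelse(same, planted$within_module_r, planted$between_module_r)
  if (length(planted$hub_regions) && planted$hub_extra_r != 0) {
    is_hub <- regions %in% planted$hub_regions
    boost <- outer(is_hub, is_hub, "|")
    target <- target + boost * planted$hub_extra_r
  }
  target <- pmin(target, planted$r_max)
  diag(target) <- 1
  dimnames(target) <- list(regions, regions)
  repair_psd(target)
}

# Eigenvalue clipping at zero + diagonal re-normalisation. Symmetrises
# first to wash out floating-point asymmetry.
repair_psd <- function(m) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-12) {
    diag(m) <- 1
    return(m)
  }
  lam <- pmax(e$values, 0)
  fixed <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(fixed))
  if (any(d <= 0)) stop("target correlation is not repairable", call. = FALSE)
  fixed <- fixed / outer(d, d)
  fixed <- (fixed + t(fixed)) / 2
  diag(fixed) <- 1
  dimnames(fixed) <- dimnames(m)
  fixed
}

#' Generate a synthetic factorial cohort of regional activity densities
#'
#' Draws each group's animals from a correlated log-normal model: a latent
#' Gaussian vector with the planted target correlation is transformed to
#' strictly positive densities with per-region mean
#' `base_mean * group_effect` and coefficient of variation `noise_cv`.
#' Correlation is planted on the latent (log) scale; the realised Pearson
#' correlation of the densities themselves is slightly attenuated, which is
#' the usual behaviour of log-normal marginals.
#'
#' Each group uses a child seed derived by hashing its label together with
#' the design's master seed, so cohorts are reproducible and adding a group
#' never changes the draws of existing groups.
#'
#' @param design a [study_design()]
#' @param planted a [planted_structure()] over the same regions
#' @return named list of `region_activity_table` objects (one per group),
#'   each with fields `group_label`, `values` (animals x regions matrix),
#'   `animal_ids`, and attributes carrying the design seed
#' @export
generate_cohort <- function(design, planted) {
  stopifnot(inherits(design, "study_design"),
            inherits(planted, "planted_structure"))
  if (!setequal(design$region_names, names(planted$module_assignment))) {
    stop("design and planted structure disagree on region names",
         call. = FALSE)
  }
  regions <- design$region_names
  target <- build_target_correlation(planted, regions)
  e <- eigen(target, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(regions))
  s2 <- log(1 + planted$noise_cv^2)
  s <- sqrt(s2)
  tables <- lapply(design$groups, function(g) {
    n <- design$n_per_cell[[g]]
    eff <- group_effect_vector(planted$group_effects, g, regions)
    mu <- log(planted$base_mean[regions] * eff) - s2 / 2
    set.seed(child_seed(design$seed, g))
    z <- matrix(stats::rnorm(n * length(regions)), nrow = n)
    latent <- z %*% t(A)
    dens <- exp(sweep(latent * s, 2L, mu, "+"))
    dimnames(dens) <- list(sprintf("%s_a%02d", g, seq_len(n)), regions)
    structure(list(group_label = g,
                   values = dens,
                   animal_ids = rownames(dens)),
              class = "region_activity_table")
  })
  stats::setNames(tables, design$groups)
}

group_effect_vector <- function(group_effects, group, regions) {
  eff <- stats::setNames(rep(1, length(regions)), regions)
  ge <- group_effects[[group]]
  if (!is.null(ge)) {
    ge <- unlist(ge)
    bad <- setdiff(names(ge), regions)
    if (length(bad)) {
      stop("group_effects name unknown regions: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    eff[names(ge)] <- ge
  }
  eff
}

#' Per-group mean and SEM summary of activity tables
#'
#' Region-major summary in the style of a densities table: one row per
#' region, and for every group a mean and a standard error of the mean
#' (sd / sqrt(n)).
#'
#' @param tables list of `region_activity_table` objects
#' @return data.frame with columns `region`, then `<group>_mean` and
#'   `<group>_sem` per group
#' @export
summarize_cohort <- function(tables) {
  if (!length(tables)) stop("no groups supplied", call. = FALSE)
  for (tab in tables) {
    if (!inherits(tab, "region_activity_table")) {
      stop("tables must be region_activity_table objects", call. = FALSE)
    }
    if (nrow(tab$values) < 2) {
      stop("group '", tab$group_label,
           "' has fewer than 2 animals; SEM undefined", call. = FALSE)
    }
  }
  regions <- colnames(tables[[1L]]$values)
  out <- data.frame(region = regions, stringsAsFactors = FALSE)
  for (tab in tables) {
    v <- tab$values[, regions, drop = FALSE]
    n <- nrow(v)
    out[[paste0(tab$group_label, "_mean")]] <- colMeans(v)
    out[[paste0(tab$group_label, "_sem")]] <- apply(v, 2L, stats::sd) / sqrt(n)
  }
  rownames(out) <- NULL
  out
}

#' Convert activity tables to one long-format data frame
#'
#' @param tables list of `region_activity_table`
#' @return data.frame with columns animal, group, region, density
#' @export
cohort_long <- function(tables) {
  do.call(rbind, lapply(tables, function(tab) {
    v <- tab$values
    data.frame(animal = rep(rownames(v), times = ncol(v)),
               group = tab$group_label,
               region = rep(colnames(v), each = nrow(v)),
               density = as.vector(v),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write a cohort to disk
#'
#' One wide CSV per group (animals x regions), a combined long-format TSV
#' (`cohort_long.tsv`), and a JSON sidecar recording the design and planted
#' structure.
#'
#' @param tables list of `region_activity_table`
#' @param dir output directory (created if needed)
#' @param design,planted optional objects recorded in the sidecar
#' @return invisibly, the paths written
#' @export
write_cohort <- function(tables, dir, design = NULL, planted = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (tab in tables) {
    p <- file.path(dir, paste0("activity_", tab$group_label, ".csv"))
    df <- data.frame(animal = rownames(tab$values), tab$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  long_path <- file.path(dir, "cohort_long.tsv")
  utils::write.table(cohort_long(tables), long_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  paths <- c(paths, long_path)
  side <- list(
    groups = vapply(tables, function(t) t$group_label, character(1)),
    n_per_group = vapply(tables, function(t) nrow(t$values), integer(1)))
  if (!is.null(design)) {
    side$design <- design[c("genotypes", "treatments", "stress_conditions",
                            "region_names", "seed")]
    side$design$n_per_cell <- as.list(design$n_per_cell)
  }
  if (!is.null(planted)) {
    side$planted <- list(
      module_assignment = as.list(planted$module_assignment),
      within_module_r = planted$within_module_r,
      between_module_r = planted$between_module_r,
      hub_regions = planted$hub_regions,
      hub_extra_r = planted$hub_extra_r,
      noise_cv = planted$noise_cv,
      base_mean = as.list(planted$base_mean))
  }
  side_path <- file.path(dir, "cohort_meta.json")
  jsonlite::write_json(side, side_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, side_path))
}
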