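#' Inter-regional Pearson correlation matrix for one group
#'
#' Correlates every pair of regions across the animals of a group using
#' pairwise-complete observations. Regions with zero variance (or all
#' missing) get `NA` rows/columns and a named warning; pairs with fewer
#' than 3 complete observations are flagged as low-support in the
#' `low_support` attribute (a logical matrix).
#'
#' @param table a `region_activity_table` or a plain animals x regions
#'   numeric matrix with column names
#' @param group_label optional label when a bare matrix is supplied
#' @return object of class `correlation_matrix`: list with `r` (symmetric,
#'   unit diagonal), `n_animals`, `region_names`, `group_label`,
#'   `zero_variance` (character vector), `low_support`
#' @examples
#' m <- cbind(A = c(1, 2, 3, 4, 5), B = c(2, 1, 4, 3, 5))
#' correlation_matrix(m)$r
#' @export
correlation_matrix <- function(table, group_label = NULL) {
  if (inherits(table, "region_activity_table")) {
    group_label <- group_label %||% table$group_label
    v <- table$values
  } else {
    v <- as.matrix(table)
  }
  if (is.null(colnames(v))) stop("regions must be named", call. = FALSE)
  if (nrow(v) < 2) stop("at least 2 animals are required", call. = FALSE)
  regions <- colnames(v)
  sds <- apply(v, 2L, stats::sd, na.rm = TRUE)
  zero_var <- regions[is.na(sds) | sds == 0]
  r <- suppressWarnings(
    stats::cor(v, use = "pairwise.complete.obs", method = "pearson"))
  if (length(zero_var)) {
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
    warning("zero-variance region(s) dropped from correlation: ",
            paste(zero_var, collapse = ", "), call. = FALSE)
  }
  ok <- !(regions %in% zero_var)
  diag(r)[ok] <- 1
  obs <- !is.na(v)
  pair_n <- crossprod(obs)  # complete observations per pair
  low_support <- pair_n < 3
  structure(list(r = r, n_animals = nrow(v), region_names = regions,
                 group_label = group_label, zero_variance = zero_var,
                 low_support = low_support),
            class = "correlation_matrix")
}

#' Default confidence-level thresholds
#'
#' Fixed Pearson r cutoffs for the low / primary / high confidence
#' networks and the negative-network cutoff. `preset` selects between the
#' main convention (low 0.79, negative 0.83) and an alternative that some
#' published figure legends use (low 0.78, negative 0.87).
#'
#' @param preset `"methods"` (default) or `"figures"`
#' @return named list with `low`, `primary`, `high`, `negative`
#' @export
default_thresholds <- function(preset = c("methods", "figures")) {
  preset <- match.arg(preset)
  switch(preset,
         methods = list(low = 0.79, primary = 0.83, high = 0.87,
                        negative = 0.83),
         figures = list(low = 0.78, primary = 0.83, high = 0.87,
                        negative = 0.87))
}

#' Threshold a correlation matrix into a binary confidence network
#'
#' The positive network at level L contains the edge (i, j) iff
#' `r_ij >= r_cut(L)`; the negative network contains (i, j) iff
#' `r_ij <= -negative_cut`. Missing correlations never create edges;
#' isolated nodes are retained so that all networks share the node set.
#'
#' @param corr a [correlation_matrix()]
#' @param level `"low"`, `"primary"` or `"high"` (ignored for the negative
#'   sign, which has a single cutoff)
#' @param sign `"positive"` or `"negative"`
#' @param thresholds named list as from [default_thresholds()]
#' @return object of class `thresholded_network`: list with `adjacency`
#'   (logical symmetric matrix, FALSE diagonal), `level`, `sign`, `r_cut`,
#'   `region_names`, `group_label`
#' @export
threshold_network <- function(corr, level = "primary",
                              sign = c("positive", "negative"),
                              thresholds = default_thresholds()) {
  stopifnot(inherits(corr, "correlation_matrix"))
  sign <- match.arg(sign)
  if (sign == "positive") {
    if (!level %in% c("low", "primary", "high")) {
      stop("unknown confidence level: ", level, call. = FALSE)
    }
    r_cut <- thresholds[[level]]
  } else {
    r_cut <- thresholds$negative
  }
  if (is.null(r_cut)) stop("threshold not configured for level ", level,
                           call. = FALSE)
  r <- corr$r
  adj <- if (sign == "positive") r >= r_cut else r <= -r_cut
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  adj <- adj | t(adj)  # enforce symmetry even under asymmetric NA patterns
  structure(list(adjacency = adj, level = level, sign = sign, r_cut = r_cut,
                 region_names = corr$region_names,
                 group_label = corr$group_label),
            class = "thresholded_network")
}

#' Edge list of a thresholded network
#'
#' @param net a `thresholded_network`
#' @param corr optional matching `correlation_matrix` to annotate each edge
#'   with its r value
#' @return data.frame with region_a, region_b (and r, level, sign)
#' @export
network_edges <- function(net, corr = NULL) {
  stopifnot(inherits(net, "thresholded_network"))
  idx <- which(net$adjacency & upper.tri(net$adjacency), arr.ind = TRUE)
  out <- data.frame(region_a = net$region_names[idx[, 1L]],
                    region_b = net$region_names[idx[, 2L]],
                    stringsAsFactors = FALSE)
  if (!is.null(corr)) {
    out$r <- corr$r[idx]
  }
  out$level <- if (nrow(out)) net$level else character(0)
  out$sign <- if (nrow(out)) net$sign else character(0)
  out
}

#' Write a thresholded network as GraphML
#'
#' Minimal GraphML export (nodes keyed by region name, optional `r` edge
#' attribute) readable by igraph, Gephi and Cytoscape.
#'
#' @param net a `thresholded_network`
#' @param path output file
#' @param corr optional `correlation_matrix` supplying edge weights
#' @return invisibly, `path`
#' @export
write_graphml <- function(net, path, corr = NULL) {
  edges <- network_edges(net, corr)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="r" for="edge" attr.name="r" attr.type="double"/>')
  w('  <graph id="%s" edgedefault="undirected">',
    paste0(net$group_label %||% "net", "_", net$level, "_", net$sign))
  for (rn in net$region_names) w('    <node id="%s"/>', rn)
  for (i in seq_len(nrow(edges))) {
    if (!is.null(edges$r)) {
      w('    <edge source="%s" target="%s"><data key="r">%.10g</data></edge>',
        edges$region_a[i], edges$region_b[i], edges$r[i])
    } else {
      w('    <edge source="%s" target="%s"/>', edges$region_a[i],
        edges$region_b[i])
    }
  }
  w("  </graph>")
  w("</graphml>")
  invisible(path)
}
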