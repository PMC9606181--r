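#' Node degree of a thresholded network
#'
#' Number of supra-threshold correlations incident to each region; isolated
#' regions score 0.
#'
#' @param net a `thresholded_network` or a logical/0-1 adjacency matrix
#' @return named integer vector over regions
#' @export
node_degree <- function(net) {
  adj <- as_adjacency(net)
  stats::setNames(as.integer(rowSums(adj)), rownames(adj))
}

as_adjacency <- function(net) {
  if (inherits(net, "thresholded_network")) {
    adj <- net$adjacency
  } else {
    adj <- as.matrix(net) != 0
    if (is.null(rownames(adj))) {
      dimnames(adj) <- list(paste0("n", seq_len(nrow(adj))),
                            paste0("n", seq_len(nrow(adj))))
    }
  }
  if (!isTRUE(all.equal(adj, t(adj)))) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  diag(adj) <- FALSE
  adj
}

#' Normalized betweenness centrality
#'
#' For each node v, the fraction of shortest paths between all ordered
#' pairs (s, t), s != t != v, that pass through v:
#' sum over pairs of sigma_st(v) / sigma_st, divided by (R-1)(R-2).
#' Disconnected pairs contribute nothing. Computed with Brandes'
#' dependency-accumulation algorithm on the unweighted, undirected graph;
#' pair contributions are counted once per unordered pair and the
#' undirected normalisation (R-1)(R-2)/2 is applied, which is equivalent.
#'
#' @param net a `thresholded_network` or adjacency matrix
#' @return named numeric vector in [0, 1]
#' @examples
#' path3 <- rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0))
#' betweenness_centrality(path3)  # middle node: 1
#' @export
betweenness_centrality <- function(net) {
  adj <- as_adjacency(net)
  R <- nrow(adj)
  cb <- numeric(R)
  if (R > 2) {
    nbrs <- apply(adj, 1L, which, simplify = FALSE)
    for (s in seq_len(R)) {
      # Brandes (2001): BFS from s with path counting, then back-propagation
      # of pair dependencies in reverse order of discovery.
      sigma <- numeric(R); sigma[s] <- 1
      dist <- rep(-1L, R); dist[s] <- 0L
      preds <- vector("list", R)
      order_stack <- integer(0)
      queue <- c(s)
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        order_stack <- c(order_stack, v)
        for (w in nbrs[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            queue <- c(queue, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(R)
      for (w in rev(order_stack)) {
        for (v in preds[[w]]) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
        if (w != s) cb[w] <- cb[w] + delta[w]
      }
    }
    cb <- cb / 2            # each unordered pair accumulated from both ends
    cb <- cb / ((R - 1) * (R - 2) / 2)
  }
  stats::setNames(cb, rownames(adj))
}

#' Composite hub identification across confidence networks
#'
#' A region is a hub iff its degree reaches the `percentile`-th percentile
#' in each of the low, primary and high positive confidence networks, and
#' its betweenness centrality on the primary network reaches the same
#' percentile. Percentile cutoffs use the nearest-rank method over all R
#' regions; ties at a cutoff qualify. With `require_all_levels = FALSE`
#' only the primary-network degree percentile is enforced.
#'
#' @param nets named list with elements `low`, `primary`, `high`, each a
#'   positive `thresholded_network` over the same regions
#' @param percentile hub percentile (default 80)
#' @param require_all_levels logical; default TRUE
#' @return object of class `hub_report`: list with `hubs` (character),
#'   `cutoffs`, and `trace` (per-region data.frame of metrics and the four
#'   sub-criteria)
#' @export
identify_hubs <- function(nets, percentile = 80, require_all_levels = TRUE) {
  stopifnot(all(c("low", "primary", "high") %in% names(nets)))
  regions <- nets$primary$region_names
  for (lv in c("low", "primary", "high")) {
    if (!identical(nets[[lv]]$region_names, regions)) {
      stop("networks must share an identical node set", call. = FALSE)
    }
  }
  deg <- sapply(c("low", "primary", "high"),
                function(lv) node_degree(nets[[lv]]))
  btw <- betweenness_centrality(nets$primary)
  cutoffs <- c(degree_low = nearest_rank_cutoff(deg[, "low"], percentile),
               degree_primary = nearest_rank_cutoff(deg[, "primary"],
                                                    percentile),
               degree_high = nearest_rank_cutoff(deg[, "high"], percentile),
               betweenness = nearest_rank_cutoff(btw, percentile))
  pass_low <- deg[, "low"] >= cutoffs[["degree_low"]]
  pass_primary <- deg[, "primary"] >= cutoffs[["degree_primary"]]
  pass_high <- deg[, "high"] >= cutoffs[["degree_high"]]
  pass_btw <- btw >= cutoffs[["betweenness"]]
  hub <- if (require_all_levels) {
    pass_low & pass_primary & pass_high & pass_btw
  } else {
    pass_primary & pass_btw
  }
  if (all(deg == 0)) {
    warning("all degrees are zero; no hubs identified", call. = FALSE)
    hub[] <- FALSE
  }
  trace <- data.frame(region = regions,
                      degree_low = deg[, "low"],
                      degree_primary = deg[, "primary"],
                      degree_high = deg[, "high"],
                      betweenness = btw,
                      pass_degree_low = pass_low,
                      pass_degree_primary = pass_primary,
                      pass_degree_high = pass_high,
                      pass_betweenness = pass_btw,
                      is_hub = hub,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(hubs = regions[hub], cutoffs = cutoffs,
                 percentile = percentile,
                 require_all_levels = require_all_levels, trace = trace),
            class = "hub_report")
}
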