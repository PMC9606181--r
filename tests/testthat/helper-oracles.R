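# Independent oracles and graph utilities used across the test files.
# These deliberately avoid the package's own algorithms: betweenness is
# recomputed from walk-count matrices, modularity from a literal double
# sum, complete linkage from a naive O(n^3) loop, and best partitions by
# exhaustive enumeration.

# --- graphs ----------------------------------------------------------------

adj_from_edges <- function(n, edges) {
  a <- matrix(FALSE, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- TRUE
  }
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

# decode a bitmask over the upper triangle into an adjacency matrix
adj_from_mask <- function(n, mask) {
  a <- matrix(FALSE, n, n)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bitwAnd(mask, bitwShiftL(1L, k)) != 0L) a[i, j] <- a[j, i] <- TRUE
      k <- k + 1L
    }
  }
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

is_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[1L] <- TRUE
  queue <- 1L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

random_graph <- function(n, p = 0.3) {
  a <- matrix(FALSE, n, n)
  a[upper.tri(a)] <- stats::runif(n * (n - 1) / 2) < p
  a <- a | t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

# --- betweenness oracle ----------------------------------------------------

# Geodesic counts from walk-count matrices: a walk whose length equals the
# graph distance is necessarily a shortest path, so sigma_st is the
# (s, t) entry of A^d(s,t). Pair dependencies are then summed explicitly.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  A <- adj * 1
  walks <- vector("list", n)
  walks[[1L]] <- A
  for (k in 2:max(2L, n)) walks[[k]] <- walks[[k - 1L]] %*% A
  dmat <- matrix(Inf, n, n)
  diag(dmat) <- 0
  for (k in seq_len(n)) {
    newly <- walks[[k]] > 0 & !is.finite(dmat)
    dmat[newly] <- k
  }
  sigma <- function(s, t) {
    if (s == t) return(1)
    d <- dmat[s, t]
    if (!is.finite(d)) return(0)
    walks[[d]][s, t]
  }
  cb <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        d <- dmat[s, t]
        if (!is.finite(d)) next
        if (dmat[s, v] + dmat[v, t] == d) {
          cb[v] <- cb[v] + sigma(s, v) * sigma(v, t) / sigma(s, t)
        }
      }
    }
  }
  names(cb) <- rownames(adj)
  if (n > 2) cb / ((n - 1) * (n - 2) / 2) else cb
}

# --- modularity oracles ----------------------------------------------------

# literal double sum over all node pairs
naive_modularity <- function(W, labels) {
  diag(W) <- 0
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (labels[i] == labels[j]) {
        q <- q + W[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# all set partitions of n items as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxid + 1L)) {
      rec(c(prefix, v), max(maxid, v))
    }
  }
  rec(integer(0), 0L)
  out
}

best_partition_Q <- function(W) {
  parts <- all_partitions(nrow(W))
  best <- -Inf
  for (p in parts) {
    q <- fosnet::modularity_score(fosnet::weighted_network(W), p)
    if (q > best) best <- q
  }
  best
}

# --- clustering oracle -----------------------------------------------------

# textbook complete-linkage agglomeration: merge the closest cluster pair,
# inter-cluster distance = max pairwise distance; returns sorted heights
naive_complete_linkage_heights <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- max(dmat[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# --- ANOVA oracle ----------------------------------------------------------

# independent matrix-algebra Type-III F computation: for each term, the
# SS is the RSS increase from deleting that term's columns from the full
# sum-to-zero design matrix
lstsq_type3_F <- function(data, response, factors) {
  for (f in factors) data[[f]] <- factor(data[[f]])
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  contr <- setNames(rep(list("contr.sum"), length(factors)), factors)
  mm <- model.matrix(fml, data, contrasts.arg = contr)
  asg <- attr(mm, "assign")
  y <- data[[response]]
  rss <- function(X) {
    fit <- qr(X)
    sum((y - X %*% qr.coef(fit, y))^2)
  }
  rss_full <- rss(mm)
  df_den <- nrow(mm) - ncol(mm)
  terms <- attr(terms(fml), "term.labels")
  out <- sapply(seq_along(terms), function(ti) {
    drop <- asg == ti
    ss <- rss(mm[, !drop, drop = FALSE]) - rss_full
    df_num <- sum(drop)
    (ss / df_num) / (rss_full / df_den)
  })
  setNames(out, terms)
}

# --- misc ------------------------------------------------------------------

jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

one_group_design <- function(regions, n, seed) {
  fosnet::study_design(genotypes = "WT", treatments = "vehicle",
                       stress_conditions = "naive", n_per_cell = as.integer(n),
                       region_names = regions, seed = seed)
}

three_block_structure <- function(regions, within = 0.8, between = 0.1) {
  fosnet::planted_structure(
    stats::setNames(rep(1:3, each = length(regions) / 3), regions),
    within_module_r = within, between_module_r = between,
    base_mean = stats::setNames(
      exp(seq(log(30), log(900), length.out = length(regions))), regions),
    noise_cv = 0.5)
}
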