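#' Build a weighted network from a correlation matrix
#'
#' The weighted coactivation network used for community detection. Under
#' the default `positive_only` policy negative correlations are set to 0;
#' under `signed` the full signed matrix is kept and modularity uses the
#' asymmetric positive/negative decomposition. The diagonal is zeroed and
#' missing correlations become 0 (no evidence of coactivation).
#'
#' @param corr a [correlation_matrix()] or a symmetric numeric matrix
#' @param sign_policy `"positive_only"` (default) or `"signed"`
#' @return object of class `weighted_network`: list with `W`, `sign_policy`,
#'   `region_names`, `group_label`
#' @export
weighted_network <- function(corr, sign_policy = c("positive_only",
                                                   "signed")) {
  sign_policy <- match.arg(sign_policy)
  if (inherits(corr, "correlation_matrix")) {
    W <- corr$r
    regions <- corr$region_names
    group <- corr$group_label
  } else {
    W <- as.matrix(corr)
    regions <- rownames(W) %||% paste0("n", seq_len(nrow(W)))
    group <- NULL
  }
  W[is.na(W)] <- 0
  diag(W) <- 0
  W <- (W + t(W)) / 2
  if (sign_policy == "positive_only") W <- pmax(W, 0)
  dimnames(W) <- list(regions, regions)
  structure(list(W = W, sign_policy = sign_policy, region_names = regions,
                 group_label = group),
            class = "weighted_network")
}

#' Modularity Q of a partition on a weighted network
#'
#' Positive-only: `Q = (1/2m) * sum_ij (W_ij - k_i k_j / 2m) * [c_i == c_j]`
#' with weighted degrees k and total weight m. Signed: the asymmetric
#' decomposition `Q = Q+ - (m- / (m+ + m-)) * Q-`, where Q+ and Q- are the
#' positive-only modularity of the positive and negative parts of W.
#'
#' @param net a `weighted_network` (or matrix, coerced with the default
#'   policy)
#' @param labels membership vector over nodes (any label type)
#' @return numeric Q in [-1, 1]; an all-zero network returns 0 with a
#'   warning
#' @export
modularity_score <- function(net, labels) {
  if (!inherits(net, "weighted_network")) net <- weighted_network(net)
  W <- net$W
  if (length(labels) != nrow(W)) {
    stop("labels must cover all nodes", call. = FALSE)
  }
  if (net$sign_policy == "signed") {
    Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
    mp <- sum(Wp) / 2; mn <- sum(Wn) / 2
    if (mp + mn == 0) {
      warning("network has no weight; Q defined as 0", call. = FALSE)
      return(0)
    }
    qp <- if (mp > 0) modularity_positive(Wp, labels) else 0
    qn <- if (mn > 0) modularity_positive(Wn, labels) else 0
    return(qp - mn / (mp + mn) * qn)
  }
  if (sum(W) == 0) {
    warning("network has no weight; Q defined as 0", call. = FALSE)
    return(0)
  }
  modularity_positive(W, labels)
}

modularity_positive <- function(W, labels) {
  m2 <- sum(W)  # 2m
  k <- rowSums(W)
  S <- outer(labels, labels, "==")
  sum((W - outer(k, k) / m2) * S) / m2
}

#' Spectral community detection on the weighted correlation network
#'
#' Maximises modularity by recursive bisection with the leading eigenvector
#' of the modularity matrix `B = W - k k' / 2m` (generalised to subgraphs),
#' followed by Kernighan-Lin-style single-node fine-tuning after every
#' split. Splitting stops when no bisection increases Q. Connected
#' components are handled independently and singleton components become
#' singleton modules. Deterministic: the leading eigenvector is oriented so
#' its first nonzero entry is positive, and zero entries join the positive
#' side.
#'
#' Under the `signed` policy the same procedure runs on the modularity
#' matrix of the asymmetric signed decomposition
#' `B = (B+ / (2m+ + 2m-)) - (B- / (2m+ + 2m-))` scaled consistently with
#' [modularity_score()].
#'
#' @param net a `weighted_network` (or matrix/`correlation_matrix`, coerced
#'   with the default positive-only policy)
#' @param min_gain smallest Q improvement accepted for a split (default
#'   1e-10; guards floating-point noise)
#' @return object of class `module_assignment`: list with `labels` (named
#'   integer vector, consecutive ids in node order), `Q`, `n_modules`, and
#'   `trace` (per-split Q gains)
#' @export
spectral_communities <- function(net, min_gain = 1e-10) {
  if (!inherits(net, "weighted_network")) net <- weighted_network(net)
  W <- abs_weight_matrix(net)
  R <- nrow(W)
  regions <- net$region_names
  comp <- graph_components(W != 0)
  labels <- integer(R)
  trace <- list()
  next_id <- 1L
  for (ci in sort(unique(comp))) {
    idx <- which(comp == ci)
    if (length(idx) == 1L) {
      labels[idx] <- next_id
      next_id <- next_id + 1L
      next
    }
    groups <- split_recursively(net, idx, min_gain, trace)
    trace <- groups$trace
    for (g in groups$groups) {
      labels[g] <- next_id
      next_id <- next_id + 1L
    }
  }
  labels <- refine_partition(net, labels)
  labels <- match(labels, unique(labels))  # consecutive ids in node order
  names(labels) <- regions
  structure(list(labels = labels, Q = modularity_score(net, labels),
                 n_modules = length(unique(labels)), trace = trace),
            class = "module_assignment")
}

# Global Kernighan-Lin refinement over the whole partition: in each pass
# every node is tentatively moved once (to whichever existing or new module
# gives the largest Q change, even when negative), the best configuration
# seen during the pass is kept, and passes repeat until Q stops improving.
# This recovers optima that recursive bisection cannot reach, such as
# odd-way partitions of symmetric graphs. Deterministic: ties resolve to
# the lowest node index and lowest module id.
refine_partition <- function(net, labels) {
  B <- modularity_matrix(net)
  R <- length(labels)
  q_of <- function(l) sum(B * outer(l, l, "=="))
  best_q <- q_of(labels)
  repeat {
    cur <- labels
    moved <- rep(FALSE, R)
    pass_best_q <- best_q
    pass_best <- labels
    for (step in seq_len(R)) {
      ids <- sort(unique(cur))
      S <- outer(cur, ids, "==") * 1          # node x module indicator
      M <- B %*% S                            # B row sums per module
      own <- M[cbind(seq_len(R), match(cur, ids))]
      stay <- 2 * (own - diag(B))
      # gain of moving node i to module d (columns), or to a new
      # singleton module (gain = -stay)
      gains <- 2 * M - stay
      gains[cbind(seq_len(R), match(cur, ids))] <- -Inf  # no-op move
      gains <- cbind(gains, -stay)            # last column: new module
      gains[moved, ] <- -Inf
      if (all(!is.finite(gains))) break
      # deterministic tie-break: among maximal gains prefer the last
      # candidate in column-major order, i.e. new-singleton moves first,
      # so tied exploration steps change the module count rather than
      # rotate an existing split (the keep-best rule discards any
      # exploration that fails to improve Q)
      max_gain <- max(gains)
      cand <- which(gains > max_gain - 1e-14)
      flat <- cand[length(cand)]
      best_i <- (flat - 1L) %% R + 1L
      col <- (flat - 1L) %/% R + 1L
      cur[best_i] <- if (col > length(ids)) max(cur) + 1L else ids[col]
      moved[best_i] <- TRUE
      cur_q <- q_of(cur)
      if (cur_q > pass_best_q + 1e-12) {
        pass_best_q <- cur_q
        pass_best <- cur
      }
    }
    if (pass_best_q > best_q + 1e-12) {
      best_q <- pass_best_q
      labels <- pass_best
    } else {
      break
    }
  }
  labels
}

# For component finding and spectral work we need a single matrix view of
# the network; signed networks use the modularity matrix of the
# decomposition, positive-only networks use W itself.
abs_weight_matrix <- function(net) {
  if (net$sign_policy == "signed") abs(net$W) else net$W
}

graph_components <- function(adj) {
  R <- nrow(adj)
  comp <- integer(R)
  cur <- 0L
  for (s in seq_len(R)) {
    if (comp[s] == 0L) {
      cur <- cur + 1L
      queue <- s
      comp[s] <- cur
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# Global modularity matrix consistent with modularity_score().
modularity_matrix <- function(net) {
  W <- net$W
  if (net$sign_policy == "signed") {
    Wp <- pmax(W, 0); Wn <- pmax(-W, 0)
    mp2 <- sum(Wp); mn2 <- sum(Wn)
    Bp <- if (mp2 > 0) (Wp - outer(rowSums(Wp), rowSums(Wp)) / mp2) / mp2
          else matrix(0, nrow(W), ncol(W))
    Bn <- if (mn2 > 0) (Wn - outer(rowSums(Wn), rowSums(Wn)) / mn2) / mn2
          else matrix(0, nrow(W), ncol(W))
    # scaled so that sum(B * S) equals Q+ - mn/(mp+mn) Q-
    Bp - (mn2 / (mp2 + mn2)) * Bn
  } else {
    m2 <- sum(W)
    if (m2 == 0) return(matrix(0, nrow(W), ncol(W)))
    (W - outer(rowSums(W), rowSums(W)) / m2) / m2
  }
}

split_recursively <- function(net, idx, min_gain, trace) {
  B <- modularity_matrix(net)
  recurse <- function(idx, trace) {
    split <- bisect_group(B, idx, min_gain)
    if (is.null(split)) {
      return(list(groups = list(idx), trace = trace))
    }
    trace[[length(trace) + 1L]] <- list(
      size = length(idx), gain = split$gain,
      sizes = c(length(split$left), length(split$right)))
    left <- recurse(split$left, trace)
    right <- recurse(split$right, left$trace)
    list(groups = c(left$groups, right$groups), trace = right$trace)
  }
  recurse(idx, trace)
}

# One candidate bisection of the node set `idx` using the subgraph
# modularity matrix B^(g) = B[g,g] - diag(rowSums(B[g,g])), leading
# eigenvector sign split, then KL-style fine-tuning. Returns NULL when the
# best found split does not increase Q by at least min_gain.
bisect_group <- function(B, idx, min_gain) {
  ng <- length(idx)
  if (ng < 2L) return(NULL)
  Bg <- B[idx, idx, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg)
  e <- eigen(Bg, symmetric = TRUE)
  u <- e$vectors[, 1L]
  if (e$values[1L] <= min_gain) {
    s <- rep(1, ng)  # indivisible by the spectral criterion; still try KL
  } else {
    s <- ifelse(u >= 0, 1, -1)
    first_nz <- which(abs(u) > 1e-12)[1L]
    if (!is.na(first_nz) && u[first_nz] < 0) s <- -s
  }
  s <- fine_tune(Bg, s)
  # B here is pre-scaled by 1/2m, so the split gain is s' Bg s / 2
  gain <- as.numeric(t(s) %*% Bg %*% s) / 2
  if (gain <= min_gain || length(unique(s)) == 1L) return(NULL)
  list(left = idx[s > 0], right = idx[s < 0], gain = gain)
}

# Kernighan-Lin style refinement: repeatedly move the single node whose
# flip most increases s' Bg s / 4, each node at most once per pass, keeping
# the best intermediate state; passes repeat until no improvement.
fine_tune <- function(Bg, s) {
  ng <- length(s)
  q_of <- function(s) as.numeric(t(s) %*% Bg %*% s) / 2
  best_q <- q_of(s)
  repeat {
    moved <- rep(FALSE, ng)
    cur <- s
    cur_q <- best_q
    pass_best_q <- best_q
    pass_best_s <- s
    for (step in seq_len(ng)) {
      # delta of flipping node i: Q' - Q = -s_i * (Bg s)_i + Bg_ii
      bs <- as.vector(Bg %*% cur)
      deltas <- (-cur * bs + diag(Bg))
      deltas[moved] <- -Inf
      i <- which.max(deltas)
      cur[i] <- -cur[i]
      moved[i] <- TRUE
      cur_q <- q_of(cur)
      if (cur_q > pass_best_q + 1e-14) {
        pass_best_q <- cur_q
        pass_best_s <- cur
      }
    }
    if (pass_best_q > best_q + 1e-14) {
      best_q <- pass_best_q
      s <- pass_best_s
    } else {
      break
    }
  }
  s
}
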