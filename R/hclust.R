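#' Euclidean distance matrix between correlation profiles
#'
#' Pairwise Euclidean distances between the rows of the inter-regional
#' correlation matrix, so two regions are close when they co-vary with the
#' rest of the brain in the same way. Regions with missing correlations
#' (e.g. zero variance in the group) are excluded first and recorded in the
#' `excluded` attribute. The unit self-correlation entries are part of each
#' profile by default; `drop_diagonal = TRUE` removes the two coordinates
#' involving the pair itself from each comparison.
#'
#' @param corr a [correlation_matrix()] or symmetric numeric matrix
#' @param drop_diagonal logical, default FALSE
#' @return a `dist` object with an `excluded` attribute
#' @export
euclidean_distance_matrix <- function(corr, drop_diagonal = FALSE) {
  r <- if (inherits(corr, "correlation_matrix")) corr$r else as.matrix(corr)
  usable <- apply(r, 1L, function(x) !all(is.na(x)))
  excluded <- rownames(r)[!usable]
  r <- r[usable, usable, drop = FALSE]
  if (nrow(r) < 3) {
    stop("fewer than 3 usable regions for distance computation",
         call. = FALSE)
  }
  if (anyNA(r)) {
    stop("correlation matrix still contains missing entries after region ",
         "exclusion", call. = FALSE)
  }
  if (!drop_diagonal) {
    d <- stats::dist(r, method = "euclidean")
  } else {
    R <- nrow(r)
    m <- matrix(0, R, R, dimnames = dimnames(r))
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        keep <- setdiff(seq_len(R), c(i, j))
        m[i, j] <- m[j, i] <- sqrt(sum((r[i, keep] - r[j, keep])^2))
      }
    }
    d <- stats::as.dist(m)
  }
  attr(d, "excluded") <- excluded
  d
}

#' Complete-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise distance (the "complete" method), whose merge heights
#' are guaranteed monotone. A thin wrapper over [stats::hclust()] that
#' validates the input and returns the standard `hclust` object (merge
#' table, heights, leaf order).
#'
#' @param dist a `dist` object or symmetric distance matrix
#' @return an `hclust` object
#' @export
complete_linkage <- function(dist) {
  if (!inherits(dist, "dist")) dist <- stats::as.dist(as.matrix(dist))
  if (any(!is.finite(dist))) {
    stop("distances must be finite", call. = FALSE)
  }
  stats::hclust(dist, method = "complete")
}

#' Cut a dendrogram at a fraction of its maximum merge height
#'
#' The cut height is `fraction * max(merge height)`; merges at exactly the
#' cut height are kept, so `fraction = 1` always yields a single module.
#'
#' @param dend an `hclust` object
#' @param fraction cut fraction in (0, 1]
#' @return named integer vector of module labels over the leaves
#' @export
tree_cut <- function(dend, fraction = 0.70) {
  stopifnot(inherits(dend, "hclust"))
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  h <- fraction * max(dend$height)
  stats::cutree(dend, h = h)
}

#' Module counts across a grid of tree-cut fractions
#'
#' Profiles modular structure by counting modules at each cut fraction;
#' counts are non-increasing in the fraction. The default grid runs from
#' 0.50 to 0.95 in steps of 0.05 and includes the conventional primary cut
#' at 0.70.
#'
#' @param dend an `hclust` object
#' @param fractions ascending cut fractions in (0, 1]
#' @return data.frame with columns `fraction`, `n_modules`
#' @export
cut_profile <- function(dend, fractions = seq(0.50, 0.95, by = 0.05)) {
  if (is.unsorted(fractions)) {
    stop("fractions must be sorted ascending", call. = FALSE)
  }
  counts <- vapply(fractions,
                   function(f) length(unique(tree_cut(dend, f))), integer(1))
  data.frame(fraction = fractions, n_modules = counts)
}
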