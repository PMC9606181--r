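#' Factorial ANOVA on per-animal densities of one region
#'
#' Fits a fully crossed fixed-effects linear model of density on the given
#' factors and reports every main effect and interaction with Type-III sums
#' of squares under sum-to-zero contrasts, the convention that keeps main
#' effects interpretable in unbalanced designs (cell sizes of 5-9 animals
#' routinely differ). With balanced cells Type III coincides with
#' sequential sums of squares.
#'
#' @param data data.frame with one row per animal: a numeric response
#'   column plus one column per factor
#' @param response name of the response column (default `"density"`)
#' @param factors character vector of 2 or 3 factor column names
#' @param alpha significance level carried into the result (default 0.05)
#' @return object of class `anova_result`: data.frame with columns
#'   `effect`, `F`, `df_num`, `df_den`, `p`, `significant`; the fitted
#'   `lm` object is attached as attribute `fit` for post hoc use
#' @export
factorial_anova <- function(data, response = "density", factors,
                            alpha = 0.05) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (length(factors) < 2 || length(factors) > 3) {
    stop("factors must name 2 or 3 columns", call. = FALSE)
  }
  if (!all(factors %in% names(data))) {
    stop("missing factor column(s): ",
         paste(setdiff(factors, names(data)), collapse = ", "),
         call. = FALSE)
  }
  for (f in factors) data[[f]] <- factor(data[[f]])
  cells <- interaction(data[factors], drop = FALSE)
  tab <- table(cells)
  if (any(tab == 0)) {
    stop("empty design cell(s): ",
         paste(names(tab)[tab == 0], collapse = ", "), call. = FALSE)
  }
  n <- nrow(data)
  n_cells <- length(tab)
  if (n - n_cells <= 0) {
    stop("zero residual degrees of freedom; need replicate animals",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste(response, "~",
                                 paste(factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = contr)
  if (stats::var(data[[response]]) == 0) {
    # constant response: no variance to apportion, every F is 0
    term_labels <- attr(stats::terms(fml), "term.labels")
    df_num <- vapply(term_labels, function(tl) {
      prod(vapply(strsplit(tl, ":", fixed = TRUE)[[1L]],
                  function(f) nlevels(data[[f]]) - 1L, integer(1)))
    }, numeric(1))
    out <- data.frame(effect = term_labels, F = 0, df_num = df_num,
                      df_den = n - n_cells, p = 1, significant = FALSE,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "fit") <- fit
    attr(out, "alpha") <- alpha
    class(out) <- c("anova_result", "data.frame")
    return(out)
  }
  a3 <- car::Anova(fit, type = "III")
  keep <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  df_den <- a3["Residuals", "Df"]
  Fv <- a3[keep, "F value"]
  pv <- a3[keep, "Pr(>F)"]
  # all-constant response: SS are all ~0 and F is 0/0; report F = 0, p = 1
  degenerate <- !is.finite(Fv)
  Fv[degenerate] <- 0
  pv[degenerate] <- 1
  out <- data.frame(effect = rownames(a3)[keep],
                    F = Fv, df_num = a3[keep, "Df"], df_den = df_den,
                    p = pv, significant = pv < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fit") <- fit
  attr(out, "alpha") <- alpha
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Bonferroni-corrected pairwise contrasts from an ANOVA fit
#'
#' Two-sample t contrasts between requested cell pairs using the pooled
#' residual variance of the factorial fit; p-values are multiplied by the
#' number of requested comparisons and capped at 1.
#'
#' @param anova an `anova_result` from [factorial_anova()]
#' @param comparisons list of length-2 character vectors, each naming two
#'   cells as `"level1.level2[.level3]"` in the order of the fitted factors
#'   (the `interaction()` labelling); or a 2-column matrix
#' @param alpha significance level (default: the ANOVA's alpha)
#' @return data.frame with `group_a`, `group_b`, `mean_diff`, `t`, `df`,
#'   `p`, `p_adjusted`, `significant`
#' @export
bonferroni_posthoc <- function(anova, comparisons, alpha = NULL) {
  stopifnot(inherits(anova, "anova_result"))
  fit <- attr(anova, "fit")
  alpha <- alpha %||% attr(anova, "alpha") %||% 0.05
  if (is.matrix(comparisons)) {
    comparisons <- lapply(seq_len(nrow(comparisons)),
                          function(i) comparisons[i, ])
  }
  m <- length(comparisons)
  if (m == 0) {
    return(data.frame(group_a = character(), group_b = character(),
                      mean_diff = numeric(), t = numeric(), df = numeric(),
                      p = numeric(), p_adjusted = numeric(),
                      significant = logical()))
  }
  mf <- stats::model.frame(fit)
  response <- mf[[1L]]
  cells <- interaction(mf[-1L], drop = FALSE)
  cell_means <- tapply(response, cells, mean)
  cell_n <- tapply(response, cells, length)
  s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  df <- stats::df.residual(fit)
  rows <- lapply(comparisons, function(cmp) {
    a <- cmp[1L]; b <- cmp[2L]
    if (!a %in% names(cell_means) || !b %in% names(cell_means)) {
      stop("unknown cell in comparison: ", paste(cmp, collapse = " vs "),
           "; cells are ", paste(names(cell_means), collapse = ", "),
           call. = FALSE)
    }
    diff <- cell_means[[a]] - cell_means[[b]]
    se <- sqrt(s2 * (1 / cell_n[[a]] + 1 / cell_n[[b]]))
    tval <- if (se == 0) 0 else diff / se
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(group_a = a, group_b = b, mean_diff = diff, t = tval,
               df = df, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, m * out$p)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Region-wise factorial ANOVA report for a cohort
#'
#' Runs [factorial_anova()] per region on a long-format cohort. P-values
#' are not corrected across regions (only within post hoc families); add
#' an FDR step downstream if region-level selection is the goal.
#'
#' @param long data.frame with columns `animal`, `group`, `region`,
#'   `density` plus factor columns, or the output of [cohort_long()] with
#'   underscore-delimited group labels and `factors` giving their names
#' @param factors factor column names; if absent from `long`, they are
#'   split out of `group` on underscores
#' @param alpha significance level
#' @return named list of `anova_result`, one per region
#' @export
region_anova_report <- function(long, factors = c("genotype", "treatment",
                                                  "stress"),
                                alpha = 0.05) {
  stopifnot(all(c("region", "density") %in% names(long)))
  if (!all(factors %in% names(long))) {
    parts <- strsplit(long$group, "_", fixed = TRUE)
    if (any(lengths(parts) != length(factors))) {
      stop("group labels do not split into ", length(factors), " factors",
           call. = FALSE)
    }
    for (i in seq_along(factors)) {
      long[[factors[i]]] <- vapply(parts, `[[`, character(1), i)
    }
  }
  regions <- unique(long$region)
  stats::setNames(lapply(regions, function(rg) {
    factorial_anova(long[long$region == rg, , drop = FALSE],
                    response = "density", factors = factors, alpha = alpha)
  }), regions)
}
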