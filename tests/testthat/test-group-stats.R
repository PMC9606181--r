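make_factorial_data <- function(effects = c(genotype = 0, treatment = 0,
                                            stress = 0),
                                n = 8, sd = 1, seed = 1,
                                three_way = TRUE) {
  set.seed(seed)
  g <- expand.grid(genotype = c("WT", "KO"), treatment = c("veh", "dfp"),
                   stress = if (three_way) c("naive", "PST") else "naive",
                   stringsAsFactors = FALSE)
  df <- g[rep(seq_len(nrow(g)), each = n), , drop = FALSE]
  mu <- 0 +
    ifelse(df$genotype == "KO", effects[["genotype"]], 0) +
    ifelse(df$treatment == "dfp", effects[["treatment"]], 0) +
    if (three_way) ifelse(df$stress == "PST", effects[["stress"]], 0) else 0
  df$density <- mu + rnorm(nrow(df), sd = sd)
  df
}

test_that("constant data yields F = 0 and p = 1 for every effect", {
  df <- make_factorial_data(n = 3)
  df$density <- 5
  res <- factorial_anova(df, factors = c("genotype", "treatment", "stress"))
  expect_equal(res$F, rep(0, nrow(res)))
  expect_equal(res$p, rep(1, nrow(res)))
  expect_false(any(res$significant))
})

test_that("a pure main effect is attributed to its factor with hand-computed F", {
  # balanced 2x2, n = 3 per cell, deterministic response with a pure
  # genotype effect and within-cell pattern (-1, 0, 1)
  df <- expand.grid(genotype = c("WT", "KO"), treatment = c("veh", "dfp"),
                    stringsAsFactors = FALSE)
  df <- df[rep(1:4, each = 3), ]
  df$density <- ifelse(df$genotype == "KO", 4, 0) + rep(c(-1, 0, 1), 4)
  res <- factorial_anova(df, factors = c("genotype", "treatment"))
  # hand computation: SS_A = n_per_level * (mean diff/2)^2 * 4 ... with
  # means 0 and 4 over 6 obs each: SS_A = 6 * (2^2) * 2 / 2 = 48;
  # SS_E = sum((-1,0,1)^2) * 4 = 8, df_E = 8 -> MS_E = 1; F_A = 48
  fa <- res$F[res$effect == "genotype"]
  expect_equal(fa, 48)
  expect_equal(res$F[res$effect == "treatment"], 0)
  expect_equal(res$F[res$effect == "genotype:treatment"], 0)
})

test_that("Type-III F matches the least-squares oracle, balanced and unbalanced", {
  df <- make_factorial_data(effects = c(genotype = 1, treatment = 0.5,
                                        stress = 0.2), n = 6, seed = 42)
  res <- factorial_anova(df, factors = c("genotype", "treatment", "stress"))
  oracle <- lstsq_type3_F(df, "density", c("genotype", "treatment", "stress"))
  expect_equal(setNames(res$F, res$effect), oracle, tolerance = 1e-8)

  # unbalanced: remove some animals, Type III still matches the oracle
  dfu <- df[-c(1, 2, 9, 20, 33), ]
  resu <- factorial_anova(dfu, factors = c("genotype", "treatment", "stress"))
  oracleu <- lstsq_type3_F(dfu, "density",
                           c("genotype", "treatment", "stress"))
  expect_equal(setNames(resu$F, resu$effect), oracleu, tolerance = 1e-8)

  # balanced case: Type III coincides with sequential (Type I) sums of squares
  fit <- attr(res, "fit")
  seq_tab <- anova(fit)
  seqF <- seq_tab[rownames(seq_tab) != "Residuals", "F value"]
  expect_equal(res$F, unname(seqF), tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  df <- make_factorial_data(n = 1)
  expect_error(factorial_anova(df, factors = c("genotype", "treatment",
                                               "stress")),
               "residual degrees of freedom")
  df2 <- make_factorial_data(n = 3)
  df2 <- df2[!(df2$genotype == "KO" & df2$treatment == "dfp" &
                 df2$stress == "PST"), ]
  expect_error(factorial_anova(df2, factors = c("genotype", "treatment",
                                                "stress")),
               "KO.dfp.PST")
  expect_error(factorial_anova(df, factors = "genotype"), "2 or 3")
})

test_that("Bonferroni contrasts multiply p by m, cap at 1 and use pooled error", {
  df <- make_factorial_data(effects = c(genotype = 3, treatment = 0,
                                        stress = 0), n = 6, seed = 7,
                            three_way = FALSE)
  res <- factorial_anova(df, factors = c("genotype", "treatment"))
  one <- bonferroni_posthoc(res, list(c("KO.veh", "WT.veh")))
  three <- bonferroni_posthoc(res, list(c("KO.veh", "WT.veh"),
                                        c("KO.dfp", "WT.dfp"),
                                        c("WT.veh", "WT.dfp")))
  expect_equal(one$p_adjusted, one$p)  # m = 1: no correction
  expect_equal(three$p_adjusted, pmin(1, 3 * three$p))
  expect_true(all(three$p_adjusted >= three$p))
  expect_true(all(three$p_adjusted <= 1))
  # identical groups: zero difference, not significant
  same <- bonferroni_posthoc(res, list(c("WT.veh", "WT.veh")))
  expect_equal(same$mean_diff, 0)
  expect_false(same$significant)
  # empty request: empty result
  none <- bonferroni_posthoc(res, list())
  expect_equal(nrow(none), 0)
  # t uses pooled residual variance
  s2 <- sum(residuals(attr(res, "fit"))^2) / df.residual(attr(res, "fit"))
  mf <- model.frame(attr(res, "fit"))
  cells <- interaction(mf[-1])
  mdiff <- mean(mf$density[cells == "KO.veh"]) -
    mean(mf$density[cells == "WT.veh"])
  expect_equal(one$t, mdiff / sqrt(s2 * (1 / 6 + 1 / 6)))
})

test_that("planted effects are detected with high power, nulls at nominal rate", {
  reps <- 200
  # power: genotype shift of 3 SEM (sd/sqrt(n) units) at n = 8 per cell
  n <- 8
  shift <- 3 * 1 / sqrt(n)
  hits <- 0
  nulls <- 0
  for (r in seq_len(reps)) {
    df <- make_factorial_data(effects = c(genotype = shift, treatment = 0,
                                          stress = 0),
                              n = n, seed = 1000 + r)
    res <- factorial_anova(df, factors = c("genotype", "treatment",
                                           "stress"))
    if (res$p[res$effect == "genotype"] < 0.05) hits <- hits + 1
    # the treatment effect is null in the same fits
    if (res$p[res$effect == "treatment"] < 0.05) nulls <- nulls + 1
  }
  expect_gte(hits / reps, 0.8)
  ci <- qbinom(c(0.025, 0.975), reps, 0.05)
  expect_gte(nulls, ci[1])
  expect_lte(nulls, ci[2])
})

test_that("region-wise reports split factor labels out of group names", {
  regions <- paste0("R", 1:3)
  pl <- planted_structure(setNames(rep(1L, 3), regions),
                          within_module_r = 0.3, between_module_r = 0,
                          base_mean = 100, noise_cv = 0.3)
  des <- study_design(region_names = regions, n_per_cell = 5L, seed = 9)
  long <- cohort_long(generate_cohort(des, pl))
  rep_out <- region_anova_report(long)
  expect_named(rep_out, regions)
  expect_s3_class(rep_out$R1, "anova_result")
  expect_setequal(rep_out$R1$effect,
                  c("genotype", "treatment", "stress",
                    "genotype:treatment", "genotype:stress",
                    "treatment:stress", "genotype:treatment:stress"))
})
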