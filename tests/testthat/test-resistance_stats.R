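boone_pre <- c(51, 69, 0) # 1014 margins (hom-wt, het, hom-mut), n = 120

test_that("RAF matches the published formula on field strata", {
  expect_equal(round(raf(boone_pre), 1), 28.8)
  expect_equal(round(raf(c(14, 10, 86)), 1), 82.7)
  expect_equal(raf(c(0, 50, 0)), 50)
  expect_equal(raf(c(0, 7, 0)), 50)
  expect_error(raf(c(0, 0, 0)), class = "kdr_empty_sample")
})

test_that("RAF is identical from nine-class and three-class representations", {
  counts9 <- setNames(c(5, 2, 1, 7, 3, 0, 2, 1, 4), GENOTYPE_CLASSES_9)
  m1014 <- c(5 + 2 + 1, 7 + 3 + 0, 2 + 1 + 4)
  m918 <- c(5 + 7 + 2, 2 + 3 + 1, 1 + 0 + 4)
  expect_equal(raf(counts9, "1014"), raf(m1014, "1014"))
  expect_equal(raf(counts9, "918"), raf(m918, "918"))
  expect_true(raf(counts9, "1014") >= 0 && raf(counts9, "1014") <= 100)
})

test_that("allele counts double the sample size and split heterozygotes", {
  a <- allele_counts(boone_pre)
  expect_identical(a$n_res + a$n_sus, 240L)
  expect_identical(a$n_res, 69L)
})

test_that("the exact test matches its enumeration examples", {
  expect_equal(fisher_exact(rbind(c(3, 1), c(1, 3)))$p_value, 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(5, 5, 5), c(5, 5, 5)))$p_value, 1,
               tolerance = 1e-12)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 2))), class = "kdr_degenerate_table")
})

test_that("the exact test agrees with brute-force enumeration and fisher.test", {
  set.seed(13)
  for (i in 1:60) {
    k <- sample(2:5, 1)
    tab <- matrix(rpois(2 * k, sample(1:4, 1)), nrow = 2)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    p <- fisher_exact(tab)$p_value
    expect_equal(p, oracle_fisher(tab), tolerance = 1e-9)
    keep <- tab[, colSums(tab) > 0, drop = FALSE]
    expect_equal(p, stats::fisher.test(keep)$p.value, tolerance = 1e-7)
  }
})

test_that("the Monte Carlo fallback approximates the exact p-value", {
  tab <- rbind(c(8, 3, 6), c(2, 7, 4))
  exact <- fisher_exact(tab)$p_value
  mc <- fisher_exact(tab, max_tables = 1, mc_draws = 2e4)
  expect_identical(mc$method, "monte-carlo")
  expect_equal(mc$p_value, exact, tolerance = 0.03)
  # fallback is reproducible through its logged seed
  expect_identical(mc$p_value, fisher_exact(tab, max_tables = 1, mc_draws = 2e4)$p_value)
})

test_that("allele odds ratios reproduce published per-location contrasts", {
  # Kanawha 2019 locus 918
  or <- allele_or(list(n_res = 7, n_sus = 233), list(n_res = 32, n_sus = 174))
  expect_equal(round(or$estimate, 2), 6.12)
  expect_lt(or$p_value, 1e-4)
  # Nashua 2020 locus 918
  or2 <- allele_or(list(n_res = 12, n_sus = 208), list(n_res = 38, n_sus = 38))
  expect_equal(round(or2$estimate, 2), 17.33)
  # identical samples
  or3 <- allele_or(list(n_res = 10, n_sus = 30), list(n_res = 10, n_sus = 30))
  expect_equal(or3$estimate, 1)
  # zero cell triggers the flagged Haldane-Anscombe correction
  expect_warning(or4 <- allele_or(list(n_res = 0, n_sus = 40), list(n_res = 5, n_sus = 35)))
  expect_true(or4$corrected)
  expect_true(is.finite(or4$estimate))
})

test_that("the GLM time coefficient equals the closed-form log odds ratio", {
  adf <- data.frame(
    location = "X", time = c("pre", "post"), n_res = c(7, 32), n_sus = c(233, 174)
  )
  fit <- fit_allele_glm(adf)
  or_raw <- (32 / 174) / (7 / 233)
  expect_equal(unname(exp(coef(fit$glm)["timepost"])), or_raw, tolerance = 1e-8)
  # degenerate pooling: one location collapses onto the single-stratum OR
  expect_equal(pooled_or(fit)$estimate, allele_or(
    list(n_res = 7, n_sus = 233), list(n_res = 32, n_sus = 174))$estimate,
    tolerance = 1e-8)
})

test_that("per-location ORs from the interaction GLM equal raw allele-count ORs", {
  adf <- rbind(
    data.frame(location = "Boone", time = c("pre", "post"),
               n_res = c(69, 51), n_sus = c(171, 43)),
    data.frame(location = "Kanawha", time = c("pre", "post"),
               n_res = c(138, 125), n_sus = c(102, 81)),
    data.frame(location = "Sutherland", time = c("pre", "post"),
               n_res = c(90, 95), n_sus = c(140, 95))
  )
  fit <- fit_allele_glm(adf)
  ors <- location_or(fit)
  expect_equal(round(ors$Boone$estimate, 2), 2.94)
  expect_equal(round(ors$Kanawha$estimate, 2), 1.14)
  expect_equal(round(ors$Sutherland$estimate, 2), 1.56)
  # equal allele frequencies everywhere: all non-intercept coefficients 0
  null_df <- data.frame(
    location = rep(c("A", "B"), each = 2), time = rep(c("pre", "post"), 2),
    n_res = 20, n_sus = 60
  )
  nf <- fit_allele_glm(null_df)
  expect_equal(max(abs(coef(nf$glm)[-1])), 0, tolerance = 1e-10)
})

test_that("pooling is the equal-weight logit average and matches emmeans", {
  adf <- rbind(
    data.frame(location = "Boone", time = c("pre", "post"),
               n_res = c(69, 51), n_sus = c(171, 43)),
    data.frame(location = "Kanawha", time = c("pre", "post"),
               n_res = c(138, 125), n_sus = c(102, 81)),
    data.frame(location = "Sutherland", time = c("pre", "post"),
               n_res = c(90, 95), n_sus = c(140, 95))
  )
  fit <- fit_allele_glm(adf)
  pool <- pooled_or(fit)
  per_loc <- vapply(location_or(fit), `[[`, numeric(1), "estimate")
  expect_equal(pool$estimate, exp(mean(log(per_loc))), tolerance = 1e-10)
  expect_equal(round(pool$estimate, 2), 1.73)

  # independent oracle: emmeans marginal contrast over locations
  em <- emmeans::emmeans(fit$glm, ~ time, weights = "equal")
  ctr <- summary(emmeans::contrast(em, method = list(post_vs_pre = c(-1, 1))))
  expect_equal(pool$estimate, exp(ctr$estimate), tolerance = 1e-8)
  expect_equal(pool$log_se, ctr$SE, tolerance = 1e-8)
})

test_that("pooled OR is permutation-invariant and shrinks toward 1 with a null location", {
  base <- rbind(
    data.frame(location = "A", time = c("pre", "post"), n_res = c(10, 40), n_sus = c(90, 60)),
    data.frame(location = "B", time = c("pre", "post"), n_res = c(30, 45), n_sus = c(70, 55))
  )
  p1 <- pooled_or(fit_allele_glm(base))$estimate
  p2 <- pooled_or(fit_allele_glm(base[c(3, 4, 1, 2), ]))$estimate
  expect_equal(p1, p2, tolerance = 1e-9)
  with_null <- rbind(base, data.frame(location = "C", time = c("pre", "post"),
                                      n_res = c(25, 25), n_sus = c(75, 75)))
  p3 <- pooled_or(fit_allele_glm(with_null))$estimate
  expect_gt(p1, 1)
  expect_lt(abs(log(p3)), abs(log(p1)))
  # numeric-vector pooling is the geometric mean
  expect_equal(pooled_or(c(2.9394, 1.1406, 1.5556))$estimate, 1.734, tolerance = 1e-3)
})

test_that("genotype shifts reproduce the published percentage changes", {
  mor <- genotype_count_table("All locations", 2019, "moribund",
    setNames(c(11, 14, 0, 81, 8, 0, 4, 0, 0), GENOTYPE_CLASSES_9))
  sur <- genotype_count_table("All locations", 2019, "survivor",
    setNames(c(1, 3, 0, 22, 9, 0, 3, 0, 0), GENOTYPE_CLASSES_9))
  sh <- genotype_shift(mor, sur)
  row <- sh[sh$class == "L/F:M/I", ]
  expect_equal(row$pct_a, 6.8)
  expect_equal(row$pct_b, 23.7)
  expect_equal(row$change, 16.9)
  same <- genotype_shift(mor, mor)
  expect_true(all(same$change == 0))
})
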