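test_that("allele counting excludes tablet-only and missing genotypes", {
  coh <- toy_cohort(
    genotypes = list(rs1024905 = c("G/G", "G/C", "C/C", "G/G", ".", "G/C")),
    usage_group = c("user", "user", "user", "tablet_only", "user", "non_user"))
  tab <- count_alleles(coh, "rs1024905")
  expect_equal(unname(tab$counts["user", ]), c(3, 3))
  expect_equal(unname(tab$percent["user", ]), c(50.0, 50.0))
  expect_equal(unname(tab$counts["non_user", ]), c(1, 1))
  expect_error(count_alleles(coh, "rs9999"), "absent")
})

test_that("an empty group is flagged with undefined percentages", {
  coh <- toy_cohort(genotypes = list(rs5443 = c("C/C", "C/T")),
                    usage_group = c("user", "user"))
  tab <- count_alleles(coh, "rs5443")
  expect_true(all(is.na(tab$percent["non_user", ])))
  expect_true("empty_group_non_user" %in% tab$flags)
})

test_that("call rate is the called fraction of all genotyped individuals", {
  g <- c(rep("G/G", 532), rep(".", 13))
  coh <- toy_cohort(genotypes = list(rs1024905 = g),
                    usage_group = rep("user", 545))
  expect_equal(call_rate(coh, "rs1024905"), 532 / 545)
  coh_all <- toy_cohort(genotypes = list(rs1024905 = rep(".", 5)),
                        usage_group = rep("user", 5))
  expect_equal(call_rate(coh_all, "rs1024905"), 0)
})

test_that("the biallelic HWE exact test matches enumeration", {
  expect_equal(hwe_exact_test(c(2, 4, 2)), 1.0)
  expect_lt(hwe_exact_test(c(5, 0, 5)), 0.05)
  expect_equal(hwe_exact_test(c(12, 0, 0)), 1.0)
  # systematic agreement with an independent enumeration oracle, 2n <= 40
  for (n_aa in 0:6) for (n_ab in 0:8) for (n_bb in 0:6) {
    if (n_aa + n_ab + n_bb == 0 || 2 * (n_aa + n_ab + n_bb) > 40) next
    expect_equal(hwe_exact_test(c(n_aa, n_ab, n_bb)),
                 hwe_enum_oracle(n_aa, n_ab, n_bb), tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(c(-1, 2, 3)), "non-negative")
})

test_that("the tri-allelic permutation HWE test is seeded and calibrated", {
  gm <- matrix(c(26, 12, 30, 0, 3, 9, 0, 0, 20), 3, 3, byrow = TRUE)
  p1 <- hwe_exact_test(gm, n_perm = 2000, seed = 4)
  p2 <- hwe_exact_test(gm, n_perm = 2000, seed = 4)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 2001)
  expect_lte(p1, 1)
  # a strongly disequilibrated table is rejected
  gm_bad <- diag(c(30, 30, 30))
  expect_lt(hwe_exact_test(gm_bad, n_perm = 2000, seed = 4), 0.01)
})

test_that("cohort-level HWE testing runs for SNPs and the indel system", {
  coh <- generate_cohort(cohort_config(n_individuals = 600, seed = 31))
  p_snp <- hwe_test_variant(coh, "rs1024905")
  p_tri <- hwe_test_variant(coh, "httlpr", seed = 2, n_perm = 500)
  expect_true(p_snp > 0.001)  # drawn under HWE
  expect_true(p_tri > 0.001)
})

test_that("crude allelic odds ratios reproduce cross-products", {
  tab <- allele_count_table("rs1024905", c("G", "C"), c(435, 379), c(89, 125))
  res <- crude_allelic_or(tab, "C")
  expect_equal(res$odds_ratio, (125 * 435) / (89 * 379), tolerance = 1e-12)
  # identical distributions give OR 1
  tab_eq <- allele_count_table("x", c("A", "B"), c(60, 40), c(30, 20))
  expect_equal(crude_allelic_or(tab_eq, "B")$odds_ratio, 1, tolerance = 1e-12)
  # swapping group labels inverts the OR
  tab_sw <- allele_count_table("x", c("A", "B"), c(89, 125), c(435, 379))
  expect_equal(crude_allelic_or(tab_sw, "B")$odds_ratio,
               1 / res$odds_ratio, tolerance = 1e-12)
  # zero cells get the Haldane-Anscombe correction and a flag
  tab0 <- allele_count_table("x", c("A", "B"), c(50, 0), c(40, 10))
  res0 <- crude_allelic_or(tab0, "B")
  expect_true("haldane_anscombe" %in% res0$flags)
  expect_true(is.finite(res0$odds_ratio))
})

test_that("a saturated additive fit equals the contingency odds ratio", {
  # binary exposure generated from a 2x2 table: logistic OR must equal
  # the cross-product ratio
  counts <- c(a = 18, b = 12, c = 9, d = 21)  # case/exposed layout
  y <- c(rep(1, 30), rep(0, 30))
  x <- c(rep(1, 18), rep(0, 12), rep(1, 9), rep(0, 21))
  fit <- logit_irls(cbind(1, exposure = x), y)
  or_logit <- exp(fit$coef[["exposure"]])
  or_table <- (18 * 21) / (12 * 9)
  expect_equal(or_logit, or_table, tolerance = 1e-8)
})

test_that("IRLS agrees with glm and the brute-force likelihood oracle", {
  df <- logistic_fixture(n = 40, seed = 101)
  X <- cbind(`(Intercept)` = 1, dosage = df$dosage, male = df$male)
  fit <- logit_irls(X, df$y)
  gl <- stats::glm(y ~ dosage + male, family = binomial(), data = df)
  expect_equal(unname(fit$coef), unname(coef(gl)), tolerance = 1e-6)
  oracle <- grid_logit_oracle(X, df$y)
  expect_equal(unname(fit$coef), oracle$coef, tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  # Wald SEs agree with glm's
  expect_equal(unname(fit$se),
               unname(summary(gl)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
})

test_that("degenerate designs are reported, separation is flagged", {
  expect_error(logit_irls(cbind(1, x = 1:4), c(1, 1, 1, 1)), "constant")
  expect_error(logit_irls(cbind(1, a = 1:4, b = 2 * (1:4)), c(0, 1, 0, 1)),
               "singular")
  # perfectly separating exposure
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(1, 10))
  fit <- logit_irls(cbind(1, x = x), y)
  expect_true(fit$separation)
  coh <- toy_cohort(
    genotypes = list(rs5443 = c(rep("C/C", 6), rep("T/T", 6))),
    usage_group = c(rep("user", 6), rep("non_user", 6)))
  res <- additive_logistic(coh, "rs5443", covariates = character(0))
  expect_true("separation" %in% res$flags)
  expect_true(is.na(res$odds_ratio))
})

test_that("additive association on a simulated cohort recovers direction", {
  coh <- generate_cohort(cohort_config(n_individuals = 4000, seed = 19,
                                       tablet_only_fraction = 0))
  res <- additive_logistic(coh, "rs1024905", covariates = "sex",
                           effect_allele = "C")
  expect_gt(res$odds_ratio, 1)  # C is a generating effector allele
  expect_true(res$ci_low <= res$odds_ratio && res$odds_ratio <= res$ci_high)
  expect_equal(as.numeric(res$p_bonferroni), min(1, 5 * res$p))
})

test_that("Wald confidence intervals attain nominal coverage", {
  set.seed(77)
  n <- 2000
  beta1 <- 0.35
  hits <- 0L
  reps <- 300L
  for (r in seq_len(reps)) {
    dos <- rbinom(n, 2, 0.4)
    y <- rbinom(n, 1, plogis(-1 + beta1 * dos))
    fit <- logit_irls(cbind(1, dosage = dos), y)
    ci <- fit$coef[["dosage"]] + c(-1.96, 1.96) * fit$se[["dosage"]]
    if (ci[1] <= beta1 && beta1 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.97)
})

test_that("crude and sex-adjusted ORs converge when sex is independent", {
  coh <- generate_cohort(cohort_config(n_individuals = 12000, seed = 23,
                                       tablet_only_fraction = 0))
  tab <- count_alleles(coh, "rs1024905")
  crude <- crude_allelic_or(tab, "C")$odds_ratio
  adj <- additive_logistic(coh, "rs1024905", covariates = "sex",
                           effect_allele = "C")$odds_ratio
  expect_lt(abs(log(adj) - log(crude)), 0.06)
})

test_that("genotypic model LR statistic matches nested likelihoods", {
  df <- logistic_fixture(n = 60, seed = 202)
  gt <- c("C/C", "C/T", "T/T")[df$dosage + 1]
  coh <- toy_cohort(
    genotypes = list(rs5443 = gt),
    usage_group = ifelse(df$y == 1, "non_user", "user"),
    sex = ifelse(df$male == 1, "male", "female"))
  res <- genotypic_logistic(coh, "rs5443", covariates = "sex")
  expect_equal(res$lrt$df, 2)
  # brute-force nested likelihood difference
  X_full <- cbind(1, het = as.numeric(gt == "C/T"),
                  hom = as.numeric(gt == "T/T"), male = df$male)
  X_null <- cbind(1, male = df$male)
  lr_oracle <- 2 * (grid_logit_oracle(X_full, df$y)$loglik -
                      grid_logit_oracle(X_null, df$y)$loglik)
  expect_equal(res$lrt$statistic, lr_oracle, tolerance = 1e-6)
})

test_that("genotypic model degrades gracefully with missing categories", {
  coh <- toy_cohort(
    genotypes = list(rs5443 = rep("C/C", 8)),
    usage_group = rep(c("user", "non_user"), 4))
  res <- genotypic_logistic(coh, "rs5443")
  expect_true("singular" %in% res$flags)
  df <- logistic_fixture(n = 50, seed = 303)
  gt <- ifelse(df$dosage >= 1, "C/T", "C/C")  # only two genotypes present
  coh2 <- toy_cohort(genotypes = list(rs5443 = gt),
                     usage_group = ifelse(df$y == 1, "non_user", "user"),
                     sex = ifelse(df$male == 1, "male", "female"))
  res2 <- genotypic_logistic(coh2, "rs5443")
  expect_equal(res2$lrt$df, 1)
})

test_that("Bonferroni correction is monotone, capped, and rendered", {
  expect_equal(bonferroni(0.002, 5), 0.010)
  expect_equal(bonferroni(0, 7), 0)
  expect_equal(bonferroni(0.933, 5), 1)
  expect_equal(bonferroni_render(0.933, 5), "> 1.0")
  expect_equal(bonferroni_render(0.048, 5), "0.240")
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni(p, 5)) >= 0))
  expect_true(all(bonferroni(p, 3) <= bonferroni(p, 6)))
  # idempotent at the extremes
  expect_equal(bonferroni(bonferroni(0, 5), 5), 0)
  expect_equal(bonferroni(bonferroni(0.5, 5), 5), 1)
})

test_that("the panel association table carries all variants and recodings", {
  coh <- generate_cohort(cohort_config(n_individuals = 400, seed = 41))
  at <- association_table(coh)
  expect_equal(nrow(at), 6)
  expect_setequal(unique(at$variant), variant_ids())
  expect_true(all(c("biallelic", "collapsed") %in%
                    at$recoding[at$variant == "httlpr"]))
  expect_true(all(at$p_bonferroni >= at$p - 1e-12))
})
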