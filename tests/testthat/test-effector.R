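test_that("effector alleles are the non-user-enriched alleles", {
  tab <- allele_count_table("rs1024905", c("G", "C"), c(435, 379), c(89, 125))
  spec <- identify_effector_alleles(list(rs1024905 = tab))
  expect_equal(spec$effector, "C")
  expect_equal(spec$source, "data_driven")
  # exact tie demands an override
  tie <- allele_count_table("x", c("A", "B"), c(50, 50), c(30, 30))
  expect_error(identify_effector_alleles(list(x = tie)), "tie")
  spec2 <- identify_effector_alleles(list(x = tie), overrides = c(x = "B"))
  expect_equal(spec2$effector, "B")
  expect_equal(spec2$source, "override")
  # overrides beat the data even without a tie
  spec3 <- identify_effector_alleles(list(rs1024905 = tab),
                                     overrides = c(rs1024905 = "G"))
  expect_equal(spec3$effector, "G")
  expect_equal(spec3$source, "override")
})

eff_spec <- c(rs1024905 = "C", rs6724624 = "C", rs5443 = "T",
              rs2651899 = "C", httlpr = "S")

test_that("scores count effector copies with bi-allelic 5-HTTLPR scoring", {
  coh <- toy_cohort(
    genotypes = list(rs1024905 = c("C/C", "G/G", "C/C"),
                     rs6724624 = c("C/C", "C/C", "C/C"),
                     rs5443 = c("C/T", "C/C", "T/T"),
                     rs2651899 = c("T/C", "T/T", "C/C"),
                     httlpr = c("L_A/S", "L_A/L_G", ".")),
    usage_group = c("user", "user", "non_user"))
  sc <- compute_scores(coh, eff_spec)
  # worked example: 2 + 2 + 1 + 1 + 1 = 7
  expect_equal(sc$score[sc$id == "T001"], 7L)
  # L_A/L_G carries no S copy
  expect_equal(sc$score[sc$id == "T002"], 0L + 2L + 0L + 0L + 0L)
  # the individual with a missing genotype is excluded
  expect_false("T003" %in% sc$id)
  # homozygous effector everywhere gives the maximum 10
  coh_max <- toy_cohort(
    genotypes = list(rs1024905 = "C/C", rs6724624 = "C/C", rs5443 = "T/T",
                     rs2651899 = "C/C", httlpr = "S/S"),
    usage_group = "non_user")
  expect_equal(compute_scores(coh_max, eff_spec)$score, 10L)
  expect_error(compute_scores(coh, c(rs9999 = "A")), "absent")
})

test_that("score plus non-effector copies is conserved at 10", {
  coh <- generate_cohort(cohort_config(
    n_individuals = 300, seed = 51,
    missing_rate = c(rs1024905 = 0, rs6724624 = 0, rs5443 = 0,
                     rs2651899 = 0, httlpr = 0)))
  sc <- compute_scores(coh, eff_spec)
  expect_equal(nrow(sc), 300)
  non_eff <- integer(nrow(sc))
  i <- match(sc$id, coh$genotypes$id)
  for (v in names(eff_spec)) {
    g <- coh$genotypes[[v]][i]
    if (v == "httlpr") g <- recode_biallelic(g)
    pairs <- strsplit(g, "/", fixed = TRUE)
    non_eff <- non_eff +
      vapply(pairs, function(a) sum(a != eff_spec[[v]]), integer(1))
  }
  expect_true(all(sc$score + non_eff == 10L))
  expect_true(all(sc$score >= 0 & sc$score <= 10))
})

test_that("adding one effector copy raises the score by exactly one", {
  base <- list(rs1024905 = "G/C", rs6724624 = "C/G", rs5443 = "C/C",
               rs2651899 = "T/T", httlpr = "L_A/S")
  coh <- toy_cohort(genotypes = base, usage_group = "user")
  s0 <- compute_scores(coh, eff_spec)$score
  stepped <- base
  stepped$rs5443 <- "C/T"
  coh2 <- toy_cohort(genotypes = stepped, usage_group = "user")
  expect_equal(compute_scores(coh2, eff_spec)$score, s0 + 1L)
  stepped$httlpr <- "S/S"  # replaces L_A with S: one more effector copy
  coh3 <- toy_cohort(genotypes = stepped, usage_group = "user")
  expect_equal(compute_scores(coh3, eff_spec)$score, s0 + 2L)
})

test_that("the score regression matches the brute-force likelihood oracle", {
  df <- logistic_fixture(n = 60, seed = 404, beta = c(-1.2, 0.3, -0.5))
  set.seed(405)
  ages <- sample(30:70, 60, replace = TRUE)
  coh <- toy_cohort(
    genotypes = list(rs1024905 = rep("G/G", 60)),
    usage_group = ifelse(df$y == 1, "non_user", "user"),
    sex = ifelse(df$male == 1, "male", "female"),
    age = ages)
  scores <- data.frame(id = coh$phenotypes$id, score = df$dosage)
  fit <- score_regression(coh, scores)
  expect_equal(fit$n_complete, 60)
  X <- cbind(1, score = df$dosage, male = df$male,
             age = coh$phenotypes$age)
  oracle <- grid_logit_oracle(X, df$y)
  expect_equal(unname(fit$coefficients[, "estimate"]), oracle$coef,
               tolerance = 1e-4)
})

test_that("a constant score makes the regression design singular", {
  coh <- toy_cohort(
    genotypes = list(rs1024905 = rep("G/G", 20)),
    usage_group = rep(c("user", "non_user"), 10),
    sex = rep(c("male", "female"), 10),
    age = rep(50L, 20))
  scores <- data.frame(id = coh$phenotypes$id, score = rep(3L, 20))
  expect_error(score_regression(coh, scores), "singular|constant")
})

test_that("the fitted score coefficient is positive on generating cohorts", {
  coh <- generate_cohort(cohort_config(
    n_individuals = 6000, seed = 61, tablet_only_fraction = 0,
    missing_rate = c(rs1024905 = 0, rs6724624 = 0, rs5443 = 0,
                     rs2651899 = 0, httlpr = 0)))
  ea <- effector_analysis(coh)
  expect_gt(ea$fit$coefficients["score", "estimate"], 0)
  expect_equal(ea$fit$n_complete,
               sum(coh$phenotypes$usage_group %in% c("user", "non_user")))
  expect_s3_class(ea$spec, "effector_spec")
  expect_named(coef(ea$fit), c("(Intercept)", "score", "male", "age"))
})
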