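qs <- clinical_questions()

test_that("the most-severe rule keeps the maximum under severity order", {
  expect_equal(keep_most_severe(c("1-2", "3-5"), qs$attack_frequency), "3-5")
  expect_equal(keep_most_severe("0-1 m", qs$period_duration), "0-1 m")
  expect_equal(keep_most_severe(c("15-30 min", ">180 min", "30-120 min"),
                                qs$attack_duration), ">180 min")
  expect_true(is.na(keep_most_severe(character(0), qs$attack_frequency)))
  expect_error(keep_most_severe("nonsense", qs$attack_frequency),
               "not a category")
})

test_that("the most-severe rule is idempotent and order-invariant", {
  set.seed(8)
  for (rep in 1:40) {
    q <- qs[[sample(c("attack_frequency", "attack_duration",
                      "period_duration"), 1)]]
    ans <- sample(q$categories, sample(1:3, 1), replace = TRUE)
    r1 <- keep_most_severe(ans, q)
    expect_equal(keep_most_severe(sample(ans), q), r1)
    expect_equal(keep_most_severe(r1, q), r1)
  }
})

test_that("2x2 tables use the Yates correction, larger tables do not", {
  sex <- rbind(user = c(469, 223), non_user = c(94, 66))
  cm <- compare_categorical(sex, question = "sex")
  expect_equal(cm$test, "chisq_yates_2x2")
  expect_equal(round(cm$p, 3), 0.037)
  # hand-computed Yates statistic |ad - bc| - N/2 construction
  a <- 469; b <- 223; c_ <- 94; d <- 66; N <- a + b + c_ + d
  yates <- N * (abs(a * d - b * c_) - N / 2)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
  expect_equal(cm$statistic, yates, tolerance = 1e-10)
  af <- rbind(user = c(35, 279, 272, 102), non_user = c(20, 65, 46, 16))
  cm2 <- compare_categorical(af, question = "attack_frequency")
  expect_equal(cm2$test, "chisq_rxc")
  expect_equal(cm2$df, 3)
  expect_equal(cm2$statistic, 17.2296, tolerance = 1e-4)
  expect_lt(cm2$p, 0.001)
})

test_that("identical distributions give statistic 0 and p 1", {
  tab <- rbind(user = c(40, 60), non_user = c(20, 30))
  cm <- compare_categorical(tab)
  expect_lt(cm$statistic, 0.2)  # Yates-corrected near 0
  tab3 <- rbind(user = c(40, 60, 20), non_user = c(20, 30, 10))
  cm3 <- compare_categorical(tab3)
  expect_equal(cm3$statistic, 0, tolerance = 1e-12)
  expect_equal(cm3$p, 1)
})

test_that("structural zeros error and small expected cells are flagged", {
  expect_error(compare_categorical(rbind(c(0, 0), c(3, 4))),
               "structural zero")
  expect_error(compare_categorical(rbind(c(5, 0), c(3, 0))),
               "structural zero")
  cm <- compare_categorical(rbind(c(3, 2), c(2, 4)))
  expect_true("expected_lt_5" %in% cm$flags)
})

test_that("Wilcoxon comparisons use the exact small-sample distribution", {
  cm <- compare_numeric(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cm$p, 0.1, tolerance = 1e-12)
  expect_true(cm$detail$exact)
  x <- c(12, 15, 17, 19)
  y <- c(11, 13, 22, 25, 30)
  expect_equal(compare_numeric(x, y)$p, wilcoxon_enum_oracle(x, y),
               tolerance = 1e-10)
  expect_equal(compare_numeric(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(compare_numeric(numeric(0), c(1, 2)), "empty")
})

test_that("exact Wilcoxon p-values match full rank enumeration", {
  set.seed(15)
  for (rep in 1:25) {
    nx <- sample(3:6, 1)
    ny <- sample(3:6, 1)
    x <- sample(1:100, nx)
    y <- sample(setdiff(1:100, x), ny)
    expect_equal(compare_numeric(x, y)$p, wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("larger samples switch to the corrected normal approximation", {
  set.seed(30)
  x <- rnorm(30, 0, 1)
  y <- rnorm(30, 0.5, 1)
  cm <- compare_numeric(x, y)
  expect_false(cm$detail$exact)
  # hand-computed normal approximation with continuity correction
  r <- rank(c(x, y))
  U <- sum(r[1:30]) - 30 * 31 / 2
  mu <- 30 * 30 / 2
  sig <- sqrt(30 * 30 * 61 / 12)
  z <- (U - mu - sign(U - mu) * 0.5) / sig
  expect_equal(cm$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("summary table formats group statistics and handles missing", {
  coh <- toy_cohort(
    genotypes = list(rs1024905 = rep("G/G", 3)),
    usage_group = rep("user", 3),
    sex = c("male", "male", "female"),
    age = c(40L, 50L, 60L),
    extra_phen = list(chronic = c("yes", "no", NA),
                      heredity = rep(NA_character_, 3)))
  st <- summary_table(coh)
  expect_equal(st["age", "user"], "50.0 ± 10.0")
  expect_equal(st["male", "user"], "66.7% (2)")
  expect_equal(st["chronic", "user"], "50.0% (1)")
  expect_equal(st["heredity", "user"], "- (0)")
})

test_that("the cohort-level comparison covers the questionnaire", {
  coh <- generate_cohort(cohort_config(n_individuals = 900, seed = 71))
  cc <- clinical_comparison(coh)
  expect_true(all(c("attack_frequency", "attack_duration", "period_duration",
                    "severity_score", "autonomic_symptoms", "smoking",
                    "alcohol_trigger", "specific_triggers",
                    "disease_duration", "chronic", "heredity", "age",
                    "age_at_onset") %in% cc$question))
  expect_true(all(cc$p >= 0 & cc$p <= 1))
  expect_equal(cc$test[cc$question == "age"], "wilcoxon")
  expect_equal(cc$test[cc$question == "chronic"], "chisq_yates_2x2")
  expect_equal(cc$test[cc$question == "attack_frequency"], "chisq_rxc")
  # group-conditional profiles separate users and non-users on the
  # strongly different questions at this sample size
  expect_lt(cc$p[cc$question == "autonomic_symptoms"], 0.2)
})

test_that("per-question percentages sum to 100 within rounding", {
  coh <- generate_cohort(cohort_config(n_individuals = 700, seed = 81))
  cc <- clinical_comparison(coh)
  comps <- attr(cc, "comparisons")
  for (qn in c("attack_frequency", "smoking", "severity_score")) {
    tab <- comps[[qn]]$detail$counts
    for (g in rownames(tab)) {
      pct <- 100 * tab[g, ] / sum(tab[g, ])
      expect_equal(sum(round(pct, 1)), 100, tolerance = 0.11)
    }
  }
})
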