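# Seeded synthetic cohort generator.
#
# Emulates the genotype/phenotype structure of a cluster headache biobank
# cohort grouped by triptan usage: Hardy-Weinberg genotype draws at the
# five candidate variants, usage status from a logistic model on the true
# effector-allele count with sex and age covariates, group-conditional
# clinical questionnaire answers, and MCAR missingness per variant and
# per question.

#' Clinical questionnaire definitions
#'
#' Declares the survey questions the cohort carries, each with its
#' category labels in severity order (least to most severe) where an
#' order exists. Questions flagged `multi` admit multiple ticked answers
#' on the paper questionnaire; analysis keeps the most severe one.
#'
#' @return Named list of question definitions: `id`, `type`
#'   (`categorical` or `numeric`), `categories` (severity order),
#'   `ordered`, `multi`.
#' @export
clinical_questions <- function() {
  q <- function(id, categories, ordered = FALSE, multi = FALSE,
                type = "categorical") {
    list(id = id, type = type, categories = categories,
         ordered = ordered, multi = multi)
  }
  list(
    attack_frequency = q("attack_frequency",
                         c("<1", "1-2", "3-5", ">6"),
                         ordered = TRUE, multi = TRUE),
    attack_duration  = q("attack_duration",
                         c("15-30 min", "30-120 min", "120-180 min", ">180 min"),
                         ordered = TRUE, multi = TRUE),
    period_duration  = q("period_duration",
                         c("0-1 m", "1-2 m", "2-4 m", "4-7 m", "7-12 m", ">12 m"),
                         ordered = TRUE, multi = TRUE),
    severity_score   = q("severity_score",
                         c("2-4S", "5-6S", "7-9S", ">10S"),
                         ordered = TRUE),
    autonomic_symptoms = q("autonomic_symptoms", c("no", "yes")),
    smoking            = q("smoking", c("never", "previous", "current")),
    alcohol_trigger    = q("alcohol_trigger", c("no", "yes")),
    specific_triggers  = q("specific_triggers", c("no", "yes")),
    disease_duration   = q("disease_duration", NULL, type = "numeric")
  )
}

# Group-conditional answer probabilities (and numeric moments), scaled
# from the published cohort's per-group percentages. Tablet-only users
# were not tabulated per question; they reuse the user profile.
default_clinical_profiles <- function() {
  pr <- function(user, non_user, labels, tablet_only = user) {
    list(user = stats::setNames(user / sum(user), labels),
         non_user = stats::setNames(non_user / sum(non_user), labels),
         tablet_only = stats::setNames(tablet_only / sum(tablet_only), labels))
  }
  num <- function(user, non_user, tablet_only = user) {
    list(user = c(mean = user[1], sd = user[2]),
         non_user = c(mean = non_user[1], sd = non_user[2]),
         tablet_only = c(mean = tablet_only[1], sd = tablet_only[2]))
  }
  list(
    attack_frequency = pr(c(5.1, 40.6, 39.5, 14.8),
                          c(13.6, 44.2, 31.3, 10.9),
                          clinical_questions()$attack_frequency$categories),
    attack_duration  = pr(c(14.0, 53.0, 18.1, 14.9),
                          c(17.2, 47.7, 17.2, 17.9),
                          clinical_questions()$attack_duration$categories),
    period_duration  = pr(c(27.0, 30.5, 21.0, 7.4, 5.2, 8.9),
                          c(34.0, 27.1, 20.1, 3.5, 6.3, 9.0),
                          clinical_questions()$period_duration$categories),
    severity_score   = pr(c(7.3, 46.3, 37.4, 8.9),
                          c(8.6, 42.9, 36.4, 12.1),
                          clinical_questions()$severity_score$categories),
    autonomic_symptoms = pr(c(4.9, 95.1), c(11.9, 88.1), c("no", "yes")),
    smoking            = pr(c(32.4, 40.6, 27.0), c(26.3, 51.9, 21.9),
                            c("never", "previous", "current")),
    alcohol_trigger    = pr(c(42.6, 57.4), c(56.6, 43.4), c("no", "yes")),
    specific_triggers  = pr(c(44.0, 56.0), c(52.3, 47.7), c("no", "yes")),
    disease_duration   = num(c(18.3, 13.7), c(17.3, 14.5)),
    age_at_onset       = num(c(31.0, 13.0), c(35.1, 14.7), c(34.4, 14.8)),
    chronic  = list(user = 0.123, non_user = 0.121, tablet_only = 0.171),
    heredity = list(user = 0.131, non_user = 0.083, tablet_only = 0.154)
  )
}

# Per-question non-response rates, matching the published per-question
# response denominators.
default_clinical_missing <- function() {
  c(attack_frequency = 0.020, attack_duration = 0.026,
    period_duration = 0.041, severity_score = 0.101,
    autonomic_symptoms = 0.016, smoking = 0.005,
    alcohol_trigger = 0.033, specific_triggers = 0.034,
    disease_duration = 0.099, age_at_onset = 0.101,
    chronic = 0.006, heredity = 0.031)
}

# Per-variant genotype failure rates implied by the published call
# rates (qPCR SNPs > 98%; PCR-RFLP 97.6%).
default_missing_rates <- function() {
  c(rs1024905 = 4 / 518, rs6724624 = 9 / 518, rs5443 = 5 / 518,
    rs2651899 = 7 / 518, httlpr = 13 / 545)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the published cohort's study conditions: pooled
#' allele frequencies from the reference allele-count tables, the
#' reported usage-model coefficients (0.204 per effector allele, -0.483
#' for males, 0.031 per year of age) with the intercept calibrated so
#' the marginal non-user fraction among triptan-classifiable individuals
#' is 109/518, age drawn from a normal distribution truncated to
#' [18, 90] with mean 50.3 and sd 14.3, 65.6% males, and per-variant
#' missingness implied by the published call rates. Age enters the usage
#' model centered at the (theoretical) cohort mean so the intercept
#' controls the marginal usage rate directly.
#'
#' @param n_individuals cohort size (default 545, the genotyped cohort).
#' @param allele_freqs named list variant -> named allele frequency
#'   vector summing to 1 (tri-allelic 5-HTTLPR has `L_A`, `L_G`, `S`).
#' @param usage_model list with `intercept` (`NULL` = calibrate to
#'   `target_nonuser_fraction`), `coef_score`, `coef_male`, `coef_age`
#'   (log-odds; outcome = non-user).
#' @param effector_alleles named character vector: the generating
#'   (true) effector allele per variant; 5-HTTLPR scored as bi-allelic
#'   `S` copies.
#' @param target_nonuser_fraction marginal P(non-user) used to calibrate
#'   the intercept when `usage_model$intercept` is `NULL`.
#' @param tablet_only_fraction proportion assigned to the tablet-only
#'   group, independent of genotype.
#' @param missing_rate named per-variant genotype missingness
#'   proportions.
#' @param clinical_profiles group-conditional answer probabilities, as
#'   from `default_clinical_profiles()`.
#' @param clinical_missing named per-question non-response proportions.
#' @param age_mean,age_sd,age_range truncated-normal age distribution
#'   (years).
#' @param male_fraction proportion of males.
#' @param multi_answer_rate probability that a multi-tick question
#'   receives a second answer (exercises the most-severe rule).
#' @param unresponsive_fraction fraction of non-users who explicitly
#'   reported having tried triptans without effect.
#' @param seed integer root seed; all component substreams derive from
#'   it in a fixed order.
#' @return Object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 200, seed = 7)
#' cfg$usage_model$intercept
cohort_config <- function(n_individuals = 545,
                          allele_freqs = default_allele_freqs(),
                          usage_model = list(intercept = NULL,
                                             coef_score = 0.204,
                                             coef_male = -0.483,
                                             coef_age = 0.031),
                          effector_alleles = c(rs1024905 = "C",
                                               rs6724624 = "C",
                                               rs5443 = "T",
                                               rs2651899 = "C",
                                               httlpr = "S"),
                          target_nonuser_fraction = 109 / 518,
                          tablet_only_fraction = 27 / 545,
                          missing_rate = default_missing_rates(),
                          clinical_profiles = default_clinical_profiles(),
                          clinical_missing = default_clinical_missing(),
                          age_mean = 50.3, age_sd = 14.3,
                          age_range = c(18, 90),
                          male_fraction = 0.656,
                          multi_answer_rate = 0.05,
                          unresponsive_fraction = 0.10,
                          seed = 1L) {
  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be a positive integer")
  }
  n_individuals <- as.integer(n_individuals)
  for (v in names(allele_freqs)) {
    f <- allele_freqs[[v]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-12) {
      stop("allele frequencies for ", v, " must be non-negative and sum to 1")
    }
  }
  # partial per-variant / per-question overrides keep defaults elsewhere
  mr <- default_missing_rates()
  mr[names(missing_rate)] <- missing_rate
  missing_rate <- mr
  cm <- default_clinical_missing()
  cm[names(clinical_missing)] <- clinical_missing
  clinical_missing <- cm
  props <- c(tablet_only_fraction, male_fraction, multi_answer_rate,
             unresponsive_fraction, target_nonuser_fraction,
             unlist(missing_rate), unlist(clinical_missing))
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  cfg <- structure(list(
    n_individuals = n_individuals, allele_freqs = allele_freqs,
    usage_model = usage_model, effector_alleles = effector_alleles,
    target_nonuser_fraction = target_nonuser_fraction,
    tablet_only_fraction = tablet_only_fraction,
    missing_rate = missing_rate, clinical_profiles = clinical_profiles,
    clinical_missing = clinical_missing, age_mean = age_mean,
    age_sd = age_sd, age_range = age_range,
    male_fraction = male_fraction, multi_answer_rate = multi_answer_rate,
    unresponsive_fraction = unresponsive_fraction,
    seed = as.integer(seed)), class = "cohort_config")
  if (is.null(cfg$usage_model$intercept)) {
    cfg$usage_model$intercept <- calibrate_usage_intercept(cfg)
  }
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n =", x$n_individuals, " seed =", x$seed, "\n")
  um <- x$usage_model
  cat(sprintf("  usage model (non-user): %.4f + %.3f*score %+.3f*male %+.3f*(age - mean)\n",
              um$intercept, um$coef_score, um$coef_male, um$coef_age))
  cat("  tablet-only fraction:", signif(x$tablet_only_fraction, 4), "\n")
  invisible(x)
}

# Mean of a normal truncated to [lo, hi].
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# Inverse-CDF draws from a truncated normal.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Exact pmf of the true effector score (sum of 5 independent
# Binomial(2, f_effector) draws) under the configured frequencies.
score_pmf <- function(cfg) {
  pmf <- 1
  for (v in names(cfg$effector_alleles)) {
    f <- cfg$allele_freqs[[v]]
    eff <- cfg$effector_alleles[[v]]
    fe <- if (v == "httlpr" && eff == "S") {
      f[["S"]]  # bi-allelic scoring: S copies; L_A and L_G both non-effector
    } else {
      f[[eff]]
    }
    pmf <- stats::convolve(pmf, rev(stats::dbinom(0:2, 2, fe)), type = "open")
  }
  pmax(pmf, 0)
}

# Solve the usage-model intercept so the marginal non-user probability
# (over the score pmf, sex, and a quadrature grid on centered age)
# equals the target.
calibrate_usage_intercept <- function(cfg) {
  um <- cfg$usage_model
  pmf <- score_pmf(cfg)
  s <- seq_along(pmf) - 1
  u <- (seq_len(201) - 0.5) / 201
  plo <- stats::pnorm(cfg$age_range[1], cfg$age_mean, cfg$age_sd)
  phi <- stats::pnorm(cfg$age_range[2], cfg$age_mean, cfg$age_sd)
  ages <- stats::qnorm(plo + u * (phi - plo), cfg$age_mean, cfg$age_sd)
  agec <- ages - truncnorm_mean(cfg$age_mean, cfg$age_sd,
                                cfg$age_range[1], cfg$age_range[2])
  marginal <- function(b0) {
    tot <- 0
    for (m in c(0, 1)) {
      wm <- if (m == 1) cfg$male_fraction else 1 - cfg$male_fraction
      eta <- outer(um$coef_score * s, um$coef_age * agec, "+") +
        b0 + um$coef_male * m
      tot <- tot + wm * sum(pmf * rowMeans(stats::plogis(eta)))
    }
    tot
  }
  stats::uniroot(function(b0) marginal(b0) - cfg$target_nonuser_fraction,
                 c(-20, 10), tol = 1e-10)$root
}

#' Generate a synthetic cluster headache cohort
#'
#' Deterministic for a fixed seed: the root seed spawns component
#' substreams in a fixed order (demographics, genotypes, tablet-only
#' assignment, usage, usage delivery forms, clinical answers, genotype
#' missingness, clinical missingness), so regenerating with the same
#' configuration is byte-identical. Genotypes are drawn under
#' Hardy-Weinberg equilibrium (two i.i.d. alleles per variant); usage is
#' Bernoulli with P(non-user) from the configured logistic model on the
#' individual's true effector-allele count, sex, and centered age;
#' clinical answers come from the group-conditional profiles; genotype
#' and questionnaire missingness are MCAR.
#'
#' @param config a [cohort_config()].
#' @return Object of class `ch_cohort`: list with `phenotypes` and
#'   `genotypes` data frames, `variants` ([variant_defs()]), and the
#'   generating `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_individuals = 100, seed = 1))
#' table(coh$phenotypes$usage_group)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_individuals
  um <- cfg$usage_model

  set.seed(cfg$seed)
  ss <- sample.int(.Machine$integer.max - 1L, 8L)

  ids <- sprintf("S%05d", seq_len(n))

  # 1. demographics
  set.seed(ss[1])
  male <- stats::rbinom(n, 1, cfg$male_fraction)
  age <- round(rtruncnorm(n, cfg$age_mean, cfg$age_sd,
                          cfg$age_range[1], cfg$age_range[2]))

  # 2. genotypes under HWE, fixed variant order
  set.seed(ss[2])
  vids <- variant_ids()
  true_geno <- matrix(NA_character_, n, length(vids),
                      dimnames = list(NULL, vids))
  for (v in vids) {
    f <- cfg$allele_freqs[[v]]
    a1 <- sample(names(f), n, replace = TRUE, prob = f)
    a2 <- sample(names(f), n, replace = TRUE, prob = f)
    pair <- cbind(pmin(a1, a2), pmax(a1, a2))
    true_geno[, v] <- paste(pair[, 1], pair[, 2], sep = "/")
  }

  # true effector score (5-HTTLPR: bi-allelic S copies)
  score <- integer(n)
  for (v in names(cfg$effector_alleles)) {
    g <- true_geno[, v]
    eff <- cfg$effector_alleles[[v]]
    alleles <- t(vapply(strsplit(g, "/", fixed = TRUE), identity, character(2)))
    if (v == "httlpr" && eff == "S") {
      alleles[] <- ifelse(alleles == "S", "S", "L")
    }
    score <- score + rowSums(alleles == eff)
  }

  # 3. tablet-only assignment (independent of genotype)
  set.seed(ss[3])
  tablet <- stats::rbinom(n, 1, cfg$tablet_only_fraction) == 1

  # 4. usage from the logistic model
  set.seed(ss[4])
  agec <- age - truncnorm_mean(cfg$age_mean, cfg$age_sd,
                               cfg$age_range[1], cfg$age_range[2])
  eta <- um$intercept + um$coef_score * score + um$coef_male * male +
    um$coef_age * agec
  non_user <- stats::runif(n) < stats::plogis(eta)
  usage_group <- ifelse(tablet, "tablet_only",
                        ifelse(non_user, "non_user", "user"))

  # 5. delivery forms consistent with the grouping rules
  set.seed(ss[5])
  injection <- nasal <- tablet_form <- rep("no", n)
  unresp <- rep("no", n)
  is_user <- usage_group == "user"
  if (any(is_user)) {
    inj <- stats::rbinom(sum(is_user), 1, 0.70)
    nas <- stats::rbinom(sum(is_user), 1, 0.55)
    nas[inj == 0 & nas == 0] <- 1  # users take at least one fast-acting form
    tab <- stats::rbinom(sum(is_user), 1, 0.15)
    injection[is_user] <- ifelse(inj == 1, "yes", "no")
    nasal[is_user] <- ifelse(nas == 1, "yes", "no")
    tablet_form[is_user] <- ifelse(tab == 1, "yes", "no")
  }
  tablet_form[usage_group == "tablet_only"] <- "yes"
  is_nu <- usage_group == "non_user"
  if (any(is_nu)) {
    unresp[is_nu] <- ifelse(
      stats::rbinom(sum(is_nu), 1, cfg$unresponsive_fraction) == 1,
      "yes", "no")
  }

  # 6. clinical answers from group-conditional profiles
  set.seed(ss[6])
  qs <- clinical_questions()
  prof <- cfg$clinical_profiles
  clin <- list()
  for (qn in names(qs)) {
    q <- qs[[qn]]
    if (q$type == "numeric") {
      ans <- numeric(n)
      for (grp in unique(usage_group)) {
        i <- usage_group == grp
        mo <- prof[[qn]][[grp]]
        ans[i] <- round(pmax(rtruncnorm(sum(i), mo[["mean"]], mo[["sd"]],
                                        0, 75), 0))
      }
      clin[[qn]] <- as.integer(ans)
    } else {
      ans <- character(n)
      for (grp in unique(usage_group)) {
        i <- usage_group == grp
        p <- prof[[qn]][[grp]]
        ans[i] <- sample(names(p), sum(i), replace = TRUE, prob = p)
      }
      if (isTRUE(q$multi) && cfg$multi_answer_rate > 0) {
        second <- stats::runif(n) < cfg$multi_answer_rate
        if (any(second)) {
          extra <- character(sum(second))
          k <- 1L
          for (j in which(second)) {
            p <- prof[[qn]][[usage_group[j]]]
            extra[k] <- sample(names(p), 1L, prob = p)
            k <- k + 1L
          }
          ans[second] <- paste(ans[second], extra, sep = ";")
        }
      }
      clin[[qn]] <- ans
    }
  }
  chronic <- heredity <- character(n)
  onset <- integer(n)
  for (grp in unique(usage_group)) {
    i <- usage_group == grp
    chronic[i] <- ifelse(
      stats::rbinom(sum(i), 1, prof$chronic[[grp]]) == 1, "yes", "no")
    heredity[i] <- ifelse(
      stats::rbinom(sum(i), 1, prof$heredity[[grp]]) == 1, "yes", "no")
    mo <- prof$age_at_onset[[grp]]
    onset[i] <- as.integer(round(rtruncnorm(sum(i), mo[["mean"]], mo[["sd"]],
                                            5, 75)))
  }
  onset <- as.integer(pmin(onset, age))

  # 7. genotype missingness (MCAR, per variant)
  set.seed(ss[7])
  geno <- true_geno
  for (v in vids) {
    rate <- cfg$missing_rate[[v]]
    if (!is.null(rate) && rate > 0) {
      geno[stats::runif(n) < rate, v] <- "."
    }
  }

  # 8. clinical missingness (MCAR, per question)
  set.seed(ss[8])
  drop_q <- function(x, qn) {
    rate <- cfg$clinical_missing[[qn]]
    if (!is.null(rate) && rate > 0) x[stats::runif(n) < rate] <- NA
    x
  }
  for (qn in names(clin)) clin[[qn]] <- drop_q(clin[[qn]], qn)
  chronic <- drop_q(chronic, "chronic")
  heredity <- drop_q(heredity, "heredity")
  onset <- drop_q(onset, "age_at_onset")

  phen <- data.frame(
    id = ids,
    sex = ifelse(male == 1, "male", "female"),
    age = as.integer(age),
    age_at_onset = onset,
    usage_group = usage_group,
    triptan_injection = injection,
    triptan_nasal = nasal,
    triptan_tablet = tablet_form,
    tried_triptan_unresponsive = unresp,
    chronic = chronic,
    heredity = heredity,
    stringsAsFactors = FALSE
  )
  for (qn in names(clin)) phen[[qn]] <- clin[[qn]]

  geno_df <- data.frame(id = ids, geno, stringsAsFactors = FALSE)

  structure(list(phenotypes = phen, genotypes = geno_df,
                 variants = variant_defs(), config = cfg),
            class = "ch_cohort")
}

#' @export
print.ch_cohort <- function(x, ...) {
  n <- nrow(x$phenotypes)
  tab <- table(factor(x$phenotypes$usage_group,
                      levels = c("user", "non_user", "tablet_only")),
               useNA = "ifany")
  cat("Cluster headache cohort:", n, "individuals\n")
  cat("  users:", tab[["user"]], " non-users:", tab[["non_user"]],
      " tablet-only:", tab[["tablet_only"]], "\n")
  cat("  variants:", paste(x$variants$variant, collapse = ", "), "\n")
  invisible(x)
}
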