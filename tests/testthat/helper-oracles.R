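# Independent oracles and programmatic fixtures for the test suite.
# Each oracle deliberately avoids the code path it checks.

# Brute-force logistic maximum likelihood by cyclic coordinate grid
# search with shrinking windows: no gradients, no IRLS. The search runs
# in an orthonormalized column basis (QR) so correlated predictors do
# not stall the coordinate sweeps; the likelihood is invariant to the
# reparametrization and the optimum maps back through the R factor.
grid_logit_oracle <- function(X, y, width = 30, rounds = 140, points = 41) {
  X <- as.matrix(X)
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)
  ll <- function(gamma) {
    eta <- drop(Q %*% gamma)
    sum(y * eta - ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30)))))
  }
  gamma <- rep(0, ncol(Q))
  for (r in seq_len(rounds)) {
    for (j in seq_len(ncol(Q))) {
      cand <- gamma[j] + seq(-width, width, length.out = points)
      vals <- vapply(cand, function(b) {
        bb <- gamma; bb[j] <- b; ll(bb)
      }, numeric(1))
      gamma[j] <- cand[which.max(vals)]
    }
    width <- width * 0.82
  }
  list(coef = unname(drop(solve(qr.R(qr_x), gamma))), loglik = ll(gamma))
}

# Exact conditional Hardy-Weinberg p-value by enumeration of all
# genotype configurations compatible with the allele counts, with each
# configuration's probability routed through stats::dmultinom (the
# conditional distribution is free of the allele frequency used).
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (n_a == 0 || n_a == 2 * n) return(1)
  pa <- n_a / (2 * n)
  hw <- c(pa^2, 2 * pa * (1 - pa), (1 - pa)^2)
  rare <- min(n_a, 2 * n - n_a)
  hets <- seq(rare %% 2, rare, by = 2)
  w <- vapply(hets, function(h) {
    stats::dmultinom(c((n_a - h) / 2, h, (2 * n - n_a - h) / 2), prob = hw)
  }, numeric(1))
  w <- w / sum(w)
  obs <- w[match(n_ab, hets)]
  sum(w[w <= obs * (1 + 1e-12)])
}

# Exact two-sample Wilcoxon two-sided p by enumeration of all rank
# assignments (no ties; small samples only).
wilcoxon_enum_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(nx + ny, nx)
  all_ranks <- seq_len(nx + ny)
  u_all <- apply(sets, 2, function(s) sum(all_ranks[s]) - nx * (nx + 1) / 2)
  if (u_obs > nx * ny / 2) {
    p1 <- mean(u_all >= u_obs)
  } else {
    p1 <- mean(u_all <= u_obs)
  }
  min(1, 2 * p1)
}

# Monte-Carlo power of the uncorrected two-proportion chi-square test.
power_sim_oracle <- function(n1, n0, p0, or, nsim, seed) {
  set.seed(seed)
  p1 <- or * p0 / (1 + p0 * (or - 1))
  x1 <- stats::rbinom(nsim, n1, p1)
  x0 <- stats::rbinom(nsim, n0, p0)
  pp <- (x1 + x0) / (n1 + n0)
  se2 <- pp * (1 - pp) * (1 / n1 + 1 / n0)
  stat <- ifelse(se2 == 0, 0, (x1 / n1 - x0 / n0)^2 / se2)
  mean(stat >= stats::qchisq(0.95, 1))
}

# Deterministic logistic regression fixture: dosage + sex covariate.
logistic_fixture <- function(n = 40, seed = 101,
                             beta = c(-0.8, 0.6, -0.4)) {
  set.seed(seed)
  dosage <- sample(0:2, n, replace = TRUE, prob = c(0.36, 0.48, 0.16))
  male <- rbinom(n, 1, 0.6)
  eta <- beta[1] + beta[2] * dosage + beta[3] * male
  y <- rbinom(n, 1, plogis(eta))
  # guarantee both outcomes present
  y[1] <- 0; y[2] <- 1
  data.frame(y = y, dosage = dosage, male = male)
}

# Hand-built micro-cohort for unit tests of counting and regressions.
toy_cohort <- function(genotypes, usage_group,
                       sex = rep("male", length(usage_group)),
                       age = rep(50L, length(usage_group)),
                       extra_phen = NULL) {
  n <- length(usage_group)
  ids <- sprintf("T%03d", seq_len(n))
  ph <- data.frame(id = ids, sex = sex, age = as.integer(age),
                   age_at_onset = NA_integer_, usage_group = usage_group,
                   stringsAsFactors = FALSE)
  if (!is.null(extra_phen)) for (nm in names(extra_phen)) {
    ph[[nm]] <- extra_phen[[nm]]
  }
  gen <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (v in names(genotypes)) gen[[v]] <- genotypes[[v]]
  structure(list(phenotypes = ph, genotypes = gen,
                 variants = triptanscore::variant_defs(), config = NULL),
            class = "ch_cohort")
}

# Printed reference values from the characterised cohort, used as
# frozen expectations (per-group allele percentages, adjusted ORs,
# nominal p-values, Bonferroni pairs, detectable-OR intervals).
published_table2 <- function() {
  list(
    rs1024905 = list(alleles = c("G", "C"), user = c(435, 379),
                     non_user = c(89, 125),
                     user_pct = c(53.4, 46.6), non_user_pct = c(41.6, 58.4),
                     effect = "C", or_adjusted = 1.609, p = 0.002),
    rs6724624 = list(alleles = c("C", "G"), user = c(634, 170),
                     non_user = c(179, 35),
                     user_pct = c(78.9, 21.1), non_user_pct = c(83.6, 16.4),
                     effect = "G", or_adjusted = 0.733, p = 0.129),
    rs5443 = list(alleles = c("C", "T"), user = c(577, 235),
                  non_user = c(152, 62),
                  user_pct = c(71.1, 28.9), non_user_pct = c(71.0, 29.0),
                  effect = "T", or_adjusted = 1.014, p = 0.933),
    rs2651899 = list(alleles = c("T", "C"), user = c(475, 331),
                     non_user = c(128, 88),
                     user_pct = c(58.9, 41.1), non_user_pct = c(59.3, 40.7),
                     effect = "C", or_adjusted = 0.986, p = 0.929),
    httlpr_biallelic = list(alleles = c("L", "S"), user = c(465, 329),
                            non_user = c(110, 106),
                            user_pct = c(58.6, 41.4),
                            non_user_pct = c(50.9, 49.1),
                            effect = "S", or_adjusted = 1.342, p = 0.048),
    httlpr_triallelic = list(alleles = c("L_A", "S*"), user = c(415, 379),
                             non_user = c(101, 115),
                             user_pct = c(52.3, 47.7),
                             non_user_pct = c(46.8, 53.2),
                             effect = "S*", or_adjusted = 1.240, p = 0.158)
  )
}

published_power_intervals <- function() {
  list(rs1024905 = c(0.522, 1.885), rs6724624 = c(0.340, 2.082),
       rs5443 = c(0.466, 1.901), rs2651899 = c(0.513, 1.876),
       httlpr = c(0.513, 1.876))
}
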