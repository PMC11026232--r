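# Per-variant allele counting, Hardy-Weinberg testing, and allelic
# association between genotype and triptan usage. The case group is the
# triptan non-users throughout (the scientific question is what keeps
# patients off triptans), so odds ratios > 1 mean the effect allele is
# enriched in non-users.

round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

usage_groups_analysis <- c("user", "non_user")

# Observed genotype column for a variant under a 5-HTTLPR recoding.
recoded_genotypes <- function(cohort, variant,
                              recoding = c("raw", "biallelic", "collapsed")) {
  recoding <- match.arg(recoding)
  if (!variant %in% names(cohort$genotypes)) {
    stop("variant absent from cohort: ", variant)
  }
  g <- cohort$genotypes[[variant]]
  if (variant == "httlpr" && recoding != "raw") {
    g <- switch(recoding,
                biallelic = recode_biallelic(g),
                collapsed = recode_collapsed(g))
  }
  g
}

recoded_alleles <- function(variant, recoding) {
  if (variant != "httlpr" || recoding == "raw") return(variant_alleles(variant))
  switch(recoding, biallelic = c("L", "S"), collapsed = c("L_A", "S*"))
}

#' Construct an allele count table
#'
#' Builds the allele-by-usage-group count table underlying the allelic
#' association analysis, either directly from counts or via
#' [count_alleles()] from a cohort. Group percentages are computed over
#' called alleles only and rounded half-up to one decimal.
#'
#' @param variant variant id.
#' @param alleles character vector of allele labels.
#' @param user,non_user integer allele counts per group, in `alleles`
#'   order.
#' @param recoding label recording which 5-HTTLPR recoding produced the
#'   table (informational).
#' @return Object of class `allele_count_table`: `variant`, `alleles`,
#'   `counts` (2 x k matrix, rows `user`/`non_user`), `totals`,
#'   `percent` (rounded), `flags`.
#' @export
#' @examples
#' allele_count_table("rs1024905", c("G", "C"), c(435, 379), c(89, 125))
allele_count_table <- function(variant, alleles, user, non_user,
                               recoding = "raw") {
  counts <- rbind(user = as.numeric(user), non_user = as.numeric(non_user))
  colnames(counts) <- alleles
  if (any(counts < 0)) stop("allele counts must be non-negative")
  totals <- rowSums(counts)
  percent <- counts
  flags <- character(0)
  for (g in rownames(counts)) {
    if (totals[g] == 0) {
      percent[g, ] <- NA_real_
      flags <- c(flags, paste0("empty_group_", g))
    } else {
      percent[g, ] <- round_half_up(100 * counts[g, ] / totals[g], 1)
    }
  }
  structure(list(variant = variant, alleles = alleles, counts = counts,
                 totals = totals, percent = percent, recoding = recoding,
                 flags = flags),
            class = "allele_count_table")
}

#' Count alleles by usage group
#'
#' Tabulates allele counts for one variant among triptan users and
#' non-users. Tablet-only and unclassified individuals and missing
#' genotypes are excluded; each called genotype contributes two alleles.
#'
#' @param cohort a `ch_cohort`.
#' @param variant variant id.
#' @param recoding 5-HTTLPR recoding: `"raw"` (tri-allelic),
#'   `"biallelic"` (L/S), or `"collapsed"` (`L_A`/`S*`).
#' @return An [allele_count_table()].
#' @export
count_alleles <- function(cohort, variant,
                          recoding = c("raw", "biallelic", "collapsed")) {
  recoding <- match.arg(recoding)
  g <- recoded_genotypes(cohort, variant, recoding)
  grp <- cohort$phenotypes$usage_group
  keep <- grp %in% usage_groups_analysis & !is.na(g) & g != "."
  alleles <- recoded_alleles(variant, recoding)
  cnt <- function(group) {
    a <- unlist(strsplit(g[keep & grp == group], "/", fixed = TRUE))
    as.numeric(table(factor(a, levels = alleles)))
  }
  allele_count_table(variant, alleles, cnt("user"), cnt("non_user"),
                     recoding = recoding)
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat("Allele counts for", x$variant,
      if (x$recoding != "raw") paste0("(", x$recoding, ")"), "\n")
  for (g in rownames(x$counts)) {
    cat(sprintf("  %-9s %s\n", g, paste(sprintf("%s %.1f%% (%d)", x$alleles,
                                                x$percent[g, ],
                                                as.integer(x$counts[g, ])),
                                        collapse = "  ")))
  }
  invisible(x)
}

#' Genotyping call rate for a variant
#'
#' Fraction of genotyped individuals with a called (non-missing)
#' genotype, over the whole cohort including tablet-only users.
#'
#' @inheritParams count_alleles
#' @return Fraction in `[0, 1]`.
#' @export
call_rate <- function(cohort, variant) {
  g <- recoded_genotypes(cohort, variant, "raw")
  if (length(g) == 0L) stop("cohort has no genotyped individuals")
  mean(!is.na(g) & g != ".")
}

#' Exact and permutation tests of Hardy-Weinberg equilibrium
#'
#' For a biallelic variant, the exact conditional test: given the allele
#' counts, the p-value is the total probability of all heterozygote
#' counts whose conditional probability does not exceed that of the
#' observed count. For a tri-allelic variant (3x3 genotype count
#' matrix), a seeded Monte-Carlo permutation test: alleles are pooled,
#' re-paired at random, and the conditional probability of each permuted
#' genotype table is compared with the observed one;
#' p = (1 + #\{perm <= observed\}) / (1 + n_perm).
#'
#' @param counts biallelic: numeric `(n_AA, n_Aa, n_aa)`; tri-allelic:
#'   3x3 genotype count matrix (upper triangle used).
#' @param n_perm Monte-Carlo permutations for the tri-allelic test.
#' @param seed optional seed for the permutation test.
#' @return p-value.
#' @export
#' @examples
#' hwe_exact_test(c(2, 4, 2))  # 1
#' hwe_exact_test(c(5, 0, 5))  # < 0.05
hwe_exact_test <- function(counts, n_perm = 10000L, seed = NULL) {
  if (is.matrix(counts)) return(hwe_permutation_test(counts, n_perm, seed))
  if (length(counts) != 3L || any(counts < 0)) {
    stop("biallelic counts must be (n_AA, n_Aa, n_aa), non-negative")
  }
  n_aa <- counts[1]; n_ab <- counts[2]; n_bb <- counts[3]
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalised log conditional probabilities
  logp <- vapply(hets, function(h) {
    nr_hom <- (rare - h) / 2
    nc_hom <- (2 * n - rare - h) / 2
    h * log(2) - lfactorial(nr_hom) - lfactorial(h) - lfactorial(nc_hom)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_ab, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  sum(p[p <= p[obs] * (1 + 1e-12)])
}

# log conditional probability of a genotype table given allele counts
log_genotype_prob <- function(gm) {
  n <- sum(gm)
  acounts <- rowSums(gm) + colSums(gm)  # each genotype contributes 2 alleles
  het <- sum(gm) - sum(diag(gm))
  sum(lfactorial(acounts)) + lfactorial(n) + het * log(2) -
    lfactorial(2 * n) - sum(lfactorial(gm[upper.tri(gm, diag = TRUE)]))
}

hwe_permutation_test <- function(gm, n_perm = 10000L, seed = NULL) {
  gm <- as.matrix(gm)
  if (nrow(gm) != ncol(gm)) stop("genotype counts must be a square matrix")
  if (any(gm < 0)) stop("genotype counts must be non-negative")
  # fold to upper triangle
  gm <- gm + t(gm) - diag(diag(gm))
  gm[lower.tri(gm)] <- 0
  k <- nrow(gm)
  labels <- rownames(gm)
  if (is.null(labels)) labels <- as.character(seq_len(k))
  pool <- integer(0)
  for (i in seq_len(k)) for (j in i:k) {
    pool <- c(pool, rep(c(i, j), gm[i, j]))
  }
  n <- length(pool) / 2
  if (n == 0) return(1)
  obs <- log_genotype_prob(gm)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    perm <- matrix(pool[sample.int(length(pool))], ncol = 2)
    pm <- matrix(0, k, k)
    for (r in seq_len(n)) {
      i <- min(perm[r, ]); j <- max(perm[r, ])
      pm[i, j] <- pm[i, j] + 1
    }
    if (log_genotype_prob(pm) <= obs + 1e-9) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Hardy-Weinberg test for a cohort variant
#'
#' Tabulates genotype counts over the full genotyped sample (all usage
#' groups) and applies [hwe_exact_test()] — the exact conditional test
#' for biallelic variants, the seeded permutation test for the
#' tri-allelic 5-HTTLPR system.
#'
#' @inheritParams count_alleles
#' @param seed seed for the tri-allelic permutation test.
#' @param n_perm permutations for the tri-allelic test.
#' @return p-value.
#' @export
hwe_test_variant <- function(cohort, variant, seed = 1L, n_perm = 10000L) {
  g <- recoded_genotypes(cohort, variant, "raw")
  g <- g[!is.na(g) & g != "."]
  alleles <- variant_alleles(variant)
  pairs <- t(vapply(strsplit(g, "/", fixed = TRUE), identity, character(2)))
  if (length(alleles) == 2L) {
    a <- alleles[1]
    dosage <- rowSums(pairs == a)
    counts <- c(sum(dosage == 2), sum(dosage == 1), sum(dosage == 0))
    hwe_exact_test(counts)
  } else {
    gm <- matrix(0L, length(alleles), length(alleles),
                 dimnames = list(alleles, alleles))
    for (r in seq_len(nrow(pairs))) {
      i <- match(pairs[r, 1], alleles); j <- match(pairs[r, 2], alleles)
      gm[min(i, j), max(i, j)] <- gm[min(i, j), max(i, j)] + 1L
    }
    hwe_permutation_test(gm, n_perm = n_perm, seed = seed)
  }
}

new_assoc_result <- function(variant, effect_allele, model, or, ci, p,
                             p_bonferroni = NA_real_, flags = character(0),
                             extra = list()) {
  structure(c(list(variant = variant, effect_allele = effect_allele,
                   model = model, odds_ratio = unname(or),
                   ci_low = unname(ci[1]), ci_high = unname(ci[2]),
                   p = unname(p), p_bonferroni = p_bonferroni,
                   flags = flags), extra),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s association for %s (effect allele %s)\n",
              x$model, x$variant, x$effect_allele %||% "-"))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  if (is.finite(x$odds_ratio %||% NA_real_)) {
    cat(sprintf("  OR %.3f (95%% CI %.2f-%.2f)  P = %.4g", x$odds_ratio,
                x$ci_low, x$ci_high, x$p))
    if (!is.na(x$p_bonferroni)) {
      cat("  Pc =", bonferroni_render(x$p, attr(x$p_bonferroni, "m") %||% 5))
    }
    cat("\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crude allelic odds ratio from a 2x2 allele count table
#'
#' Cross-product odds ratio of carrying the effect allele in non-users
#' versus users, with a Woolf 95% confidence interval
#' (log-OR +/- 1.96 * sqrt(sum of reciprocal cells)). Zero cells receive
#' the Haldane-Anscombe +0.5 correction and are flagged. This is an
#' unadjusted cross-check for the covariate-adjusted logistic estimates,
#' not a replacement.
#'
#' @param table an [allele_count_table()] with two alleles.
#' @param effect_allele allele whose enrichment in non-users is measured.
#' @return An `assoc_result` with model tag `crude_allelic`.
#' @export
#' @examples
#' tab <- allele_count_table("rs1024905", c("G", "C"), c(435, 379), c(89, 125))
#' crude_allelic_or(tab, "C")$odds_ratio  # 1.612
crude_allelic_or <- function(table, effect_allele) {
  stopifnot(inherits(table, "allele_count_table"))
  if (!effect_allele %in% table$alleles) {
    stop("effect allele not in table: ", effect_allele)
  }
  other <- setdiff(table$alleles, effect_allele)
  a <- table$counts["non_user", effect_allele]
  b <- sum(table$counts["non_user", other])
  c_ <- table$counts["user", effect_allele]
  d <- sum(table$counts["user", other])
  flags <- character(0)
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    flags <- "haldane_anscombe"
  }
  or <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  new_assoc_result(table$variant, effect_allele, "crude_allelic", or, ci, p,
                   flags = flags)
}

# Minor allele in the pooled (user + non-user) called sample.
pooled_minor_allele <- function(table) {
  tot <- colSums(table$counts)
  names(tot)[which.min(tot)]
}

# Assemble the complete-case regression frame for one variant.
assoc_frame <- function(cohort, variant, recoding, covariates) {
  g <- recoded_genotypes(cohort, variant, recoding)
  ph <- cohort$phenotypes
  keep <- ph$usage_group %in% usage_groups_analysis & !is.na(g) & g != "."
  df <- data.frame(y = as.numeric(ph$usage_group[keep] == "non_user"),
                   genotype = g[keep], stringsAsFactors = FALSE)
  if ("sex" %in% covariates) {
    df$male <- as.numeric(ph$sex[keep] == "male")
  }
  if ("age" %in% covariates) df$age <- ph$age[keep]
  stats::na.omit(df)
}

#' Additive-model logistic association for one variant
#'
#' Logistic regression of triptan non-usage (case = non-user, control =
#' user) on effect-allele dosage (0/1/2) with optional sex and age
#' covariates, fitted by the in-package IRLS engine. The reported
#' odds ratio is per effect-allele copy with a Wald 95% interval; a
#' likelihood-ratio p-value for the dosage term is also reported.
#'
#' @inheritParams count_alleles
#' @param covariates subset of `c("sex", "age")`.
#' @param effect_allele dosage allele; default is the minor allele in
#'   the pooled called sample.
#' @param m Bonferroni correction factor (number of variants tested).
#' @return An `assoc_result` with model tag `additive_logistic`; on
#'   complete separation the OR is `NA` and the result is flagged.
#' @export
additive_logistic <- function(cohort, variant, covariates = "sex",
                              effect_allele = NULL,
                              recoding = c("raw", "biallelic", "collapsed"),
                              m = 5L) {
  recoding <- match.arg(recoding)
  tab <- count_alleles(cohort, variant, recoding)
  if (is.null(effect_allele)) effect_allele <- pooled_minor_allele(tab)
  df <- assoc_frame(cohort, variant, recoding, covariates)
  alleles <- strsplit(df$genotype, "/", fixed = TRUE)
  dosage <- vapply(alleles, function(a) sum(a == effect_allele), numeric(1))
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  for (cv in intersect(c("sex", "age"), covariates)) {
    X <- cbind(X, if (cv == "sex") df$male else df$age)
    colnames(X)[ncol(X)] <- if (cv == "sex") "male" else "age"
  }
  fit <- logit_irls(X, df$y)
  if (fit$separation) {
    return(new_assoc_result(variant, effect_allele, "additive_logistic",
                            NA_real_, c(NA_real_, NA_real_), NA_real_,
                            flags = "separation",
                            extra = list(n = fit$n, fit = fit)))
  }
  wt <- wald_table(fit)
  null_fit <- logit_irls(X[, setdiff(colnames(X), "dosage"), drop = FALSE],
                         df$y)
  lrt <- lr_test(fit, null_fit, df = 1)
  p <- wt["dosage", "p"]
  pb <- bonferroni(p, m)
  attr(pb, "m") <- m
  new_assoc_result(variant, effect_allele, "additive_logistic",
                   exp(wt["dosage", "estimate"]),
                   exp(wt["dosage", c("lo", "hi")]), p, pb,
                   extra = list(p_lrt = lrt$p, n = fit$n, fit = fit,
                                counts = tab))
}

#' Genotypic-model logistic association for one variant
#'
#' Logistic regression with genotype as indicator contrasts against the
#' reference homozygote (homozygote of the variant's reference allele,
#' or the most common genotype if that homozygote is absent). Reports
#' per-genotype Wald statistics and a likelihood-ratio p-value for the
#' genotype block (2 df when all three genotypes are present; fewer when
#' a category is empty). A genotype constant across individuals makes
#' the design singular; the result is flagged rather than fitted.
#'
#' @inheritParams additive_logistic
#' @return An `assoc_result` with model tag `genotypic_logistic`,
#'   carrying `genotype_table` (per-contrast Wald rows) and `lrt`.
#' @export
genotypic_logistic <- function(cohort, variant, covariates = "sex",
                               recoding = c("raw", "biallelic", "collapsed")) {
  recoding <- match.arg(recoding)
  df <- assoc_frame(cohort, variant, recoding, covariates)
  levs <- names(sort(table(df$genotype), decreasing = TRUE))
  ref_allele <- recoded_alleles(variant, recoding)[1]
  ref_hom <- paste(ref_allele, ref_allele, sep = "/")
  ref <- if (ref_hom %in% levs) ref_hom else levs[1]
  contrasts <- setdiff(levs, ref)
  if (length(contrasts) == 0L) {
    return(new_assoc_result(variant, NULL, "genotypic_logistic", NA_real_,
                            c(NA_real_, NA_real_), NA_real_,
                            flags = "singular",
                            extra = list(n = nrow(df))))
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(df)))
  for (gl in contrasts) {
    X <- cbind(X, as.numeric(df$genotype == gl))
    colnames(X)[ncol(X)] <- gl
  }
  for (cv in intersect(c("sex", "age"), covariates)) {
    X <- cbind(X, if (cv == "sex") df$male else df$age)
    colnames(X)[ncol(X)] <- if (cv == "sex") "male" else "age"
  }
  fit <- logit_irls(X, df$y)
  if (fit$separation) {
    return(new_assoc_result(variant, NULL, "genotypic_logistic", NA_real_,
                            c(NA_real_, NA_real_), NA_real_,
                            flags = "separation",
                            extra = list(n = fit$n, fit = fit)))
  }
  null_fit <- logit_irls(X[, !colnames(X) %in% contrasts, drop = FALSE], df$y)
  lrt <- lr_test(fit, null_fit, df = length(contrasts))
  wt <- wald_table(fit)
  new_assoc_result(variant, NULL, "genotypic_logistic", NA_real_,
                   c(NA_real_, NA_real_), lrt$p,
                   extra = list(reference = ref,
                                genotype_table = wt[contrasts, , drop = FALSE],
                                lrt = lrt, n = fit$n, fit = fit))
}

#' Bonferroni correction
#'
#' Multiplies a nominal p-value by the number of tests and caps at 1.
#' [bonferroni_render()] gives the conventional display form, printing
#' `"> 1.0"` when the uncapped product exceeds 1.
#'
#' @param p nominal p-value(s) in `[0, 1]`.
#' @param m number of tests (default 5, the variant panel size).
#' @return Corrected p-value(s).
#' @export
#' @examples
#' bonferroni(0.002, 5)        # 0.010
#' bonferroni_render(0.933, 5) # "> 1.0"
bonferroni <- function(p, m = 5L) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' @rdname bonferroni
#' @export
bonferroni_render <- function(p, m = 5L) {
  raw <- m * p
  ifelse(raw > 1, "> 1.0", formatC(raw, digits = 3, format = "f"))
}

#' Allelic association summary for the full variant panel
#'
#' Runs the additive logistic association (sex-adjusted by default) for
#' the four SNPs and both 5-HTTLPR recodings, producing the standard
#' per-variant results table: per-group allele percentages and counts,
#' OR with 95% CI, nominal and Bonferroni-corrected p. The bi-allelic and
#' tri-allelic 5-HTTLPR analyses share one slot in the correction factor
#' (m = 5 variants, not 6 models).
#'
#' @inheritParams additive_logistic
#' @return Data frame, one row per variant/model.
#' @export
association_table <- function(cohort, covariates = "sex", m = 5L) {
  specs <- list(
    list(variant = "rs1024905", recoding = "raw"),
    list(variant = "rs6724624", recoding = "raw"),
    list(variant = "rs5443", recoding = "raw"),
    list(variant = "rs2651899", recoding = "raw"),
    list(variant = "httlpr", recoding = "biallelic"),
    list(variant = "httlpr", recoding = "collapsed")
  )
  specs <- Filter(function(sp) sp$variant %in% names(cohort$genotypes), specs)
  rows <- lapply(specs, function(sp) {
    res <- additive_logistic(cohort, sp$variant, covariates = covariates,
                             recoding = sp$recoding, m = m)
    tab <- count_alleles(cohort, sp$variant, sp$recoding)
    eff <- res$effect_allele
    data.frame(
      variant = sp$variant, recoding = sp$recoding, effect_allele = eff,
      effect_users_pct = tab$percent["user", eff],
      effect_users_n = as.integer(tab$counts["user", eff]),
      effect_nonusers_pct = tab$percent["non_user", eff],
      effect_nonusers_n = as.integer(tab$counts["non_user", eff]),
      odds_ratio = res$odds_ratio, ci_low = res$ci_low,
      ci_high = res$ci_high, p = res$p,
      p_bonferroni = as.numeric(res$p_bonferroni),
      p_bonferroni_rendered = bonferroni_render(res$p, m),
      n = res$n, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
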