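# Cumulative genetic effector score: an unweighted count of "effector"
# allele copies across the five-variant panel, where the effector allele
# of a variant is the one more common in triptan non-users. The score is
# analysed as a continuous predictor of non-usage in a logistic
# regression with sex and age covariates.

#' Identify effector alleles from per-variant allele count tables
#'
#' For each variant the effector allele is the allele with the higher
#' frequency among triptan non-users. Exact frequency ties are an error
#' unless an explicit override resolves them; overrides always win over
#' the data-driven choice and are tagged as such (the panel's rs6724624
#' assignment is the canonical example: C is kept as the effector allele
#' on cohort evidence even though migraine literature implicates G).
#' For the 5-HTTLPR system pass the bi-allelic (L/S) table so that S is
#' assessed against the pooled L class, with both `L_A` and `L_G`
#' non-effector.
#'
#' @param tables named list of [allele_count_table()] objects (two
#'   alleles each), one per scored variant.
#' @param overrides optional named character vector variant -> allele.
#' @param rationale optional named character vector documenting each
#'   override.
#' @return Object of class `effector_spec`: data frame with `variant`,
#'   `effector`, `source` (`data_driven` or `override`), `rationale`.
#' @export
#' @examples
#' tab <- allele_count_table("rs1024905", c("G", "C"), c(435, 379), c(89, 125))
#' identify_effector_alleles(list(rs1024905 = tab))
identify_effector_alleles <- function(tables, overrides = NULL,
                                      rationale = NULL) {
  rows <- lapply(names(tables), function(v) {
    tab <- tables[[v]]
    if (!is.null(overrides) && v %in% names(overrides)) {
      al <- overrides[[v]]
      if (!al %in% tab$alleles) stop("override allele not in table for ", v)
      return(data.frame(variant = v, effector = al, source = "override",
                        rationale = rationale[[v]] %||% "",
                        stringsAsFactors = FALSE))
    }
    freq_nu <- tab$counts["non_user", ] / sum(tab$counts["non_user", ])
    freq_u <- tab$counts["user", ] / sum(tab$counts["user", ])
    enrich <- freq_nu - freq_u
    if (max(enrich) - min(enrich) < 1e-12) {
      stop("tied allele frequencies between groups for ", v,
           ": supply an explicit override")
    }
    data.frame(variant = v, effector = names(enrich)[which.max(enrich)],
               source = "data_driven", rationale = "",
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("effector_spec", "data.frame"))
}

#' Per-individual cumulative effector scores
#'
#' Sums effector-allele copies (0/1/2 per variant) across the scored
#' variants. The 5-HTTLPR genotype is recoded bi-allelically first, so S
#' copies are counted and the `L_A`/`L_G` distinction is discarded.
#' Individuals missing a genotype at any scored variant are excluded
#' from the output.
#'
#' @param cohort a `ch_cohort`.
#' @param spec an `effector_spec` (or named character vector
#'   variant -> effector allele).
#' @return Data frame `id`, `score` for complete individuals; the score
#'   ranges over `0 .. 2 * n_variants`.
#' @export
compute_scores <- function(cohort, spec) {
  if (inherits(spec, "effector_spec")) {
    eff <- stats::setNames(spec$effector, spec$variant)
  } else {
    eff <- spec
  }
  miss <- setdiff(names(eff), names(cohort$genotypes))
  if (length(miss)) stop("spec variants absent from cohort: ",
                         paste(miss, collapse = ", "))
  n <- nrow(cohort$genotypes)
  score <- integer(n)
  complete <- rep(TRUE, n)
  for (v in names(eff)) {
    g <- cohort$genotypes[[v]]
    if (v == "httlpr" && eff[[v]] %in% c("S", "L")) {
      g <- recode_biallelic(g)
    }
    called <- !is.na(g) & g != "."
    complete <- complete & called
    pairs <- strsplit(g[called], "/", fixed = TRUE)
    score[called] <- score[called] +
      vapply(pairs, function(a) sum(a == eff[[v]]), integer(1))
  }
  data.frame(id = cohort$genotypes$id[complete],
             score = score[complete], stringsAsFactors = FALSE)
}

#' Logistic regression of triptan non-usage on the effector score
#'
#' Fits non-usage (case = non-user, control = user) on the continuous
#' effector score with male sex and age (years, uncentered) as
#' covariates, using the shared IRLS engine. Tablet-only and
#' unclassified individuals, and individuals without a complete score,
#' are excluded.
#'
#' @param cohort a `ch_cohort`.
#' @param scores data frame `id`, `score` from [compute_scores()].
#' @param covariates subset of `c("sex", "age")` (default both).
#' @return Object of class `effector_fit`: `coefficients` matrix
#'   (estimate, se, z, p, lo, hi per term), `n_complete`, `fit`.
#' @export
score_regression <- function(cohort, scores, covariates = c("sex", "age")) {
  ph <- cohort$phenotypes
  i <- match(ph$id, scores$id)
  keep <- !is.na(i) & ph$usage_group %in% usage_groups_analysis
  df <- data.frame(y = as.numeric(ph$usage_group[keep] == "non_user"),
                   score = scores$score[i[keep]])
  if ("sex" %in% covariates) df$male <- as.numeric(ph$sex[keep] == "male")
  if ("age" %in% covariates) df$age <- ph$age[keep]
  df <- stats::na.omit(df)
  if (nrow(df) <= ncol(df)) {
    stop("too few complete cases (", nrow(df), ") for the score regression")
  }
  X <- as.matrix(cbind(`(Intercept)` = 1, df[setdiff(names(df), "y")]))
  fit <- logit_irls(X, df$y)
  if (fit$separation) stop("complete separation in the score regression")
  structure(list(coefficients = wald_table(fit), n_complete = nrow(df),
                 fit = fit),
            class = "effector_fit")
}

#' @export
print.effector_fit <- function(x, ...) {
  cat("Effector-score logistic regression (case = triptan non-user)\n")
  cat("  complete cases:", x$n_complete, "\n")
  ct <- x$coefficients
  for (r in rownames(ct)) {
    cat(sprintf("  %-12s %8.4f (se %.4f)  P = %.4g\n", r,
                ct[r, "estimate"], ct[r, "se"], ct[r, "p"]))
  }
  invisible(x)
}

#' @export
summary.effector_fit <- function(object, ...) {
  list(coefficients = object$coefficients, n_complete = object$n_complete,
       loglik = object$fit$loglik, converged = object$fit$converged)
}

#' @export
coef.effector_fit <- function(object, ...) {
  object$coefficients[, "estimate"]
}

#' Full effector-score analysis for a cohort
#'
#' Convenience driver: builds the per-variant bi-allelic count tables,
#' identifies effector alleles (data-driven, with optional overrides),
#' computes scores, and fits the covariate-adjusted regression.
#'
#' @inheritParams score_regression
#' @param overrides optional named character vector variant -> allele.
#' @param variants variants to score (default the full 5-variant panel).
#' @return List with `spec`, `scores`, `fit`.
#' @export
effector_analysis <- function(cohort, overrides = NULL,
                              variants = variant_ids(),
                              covariates = c("sex", "age")) {
  tables <- lapply(stats::setNames(variants, variants), function(v) {
    count_alleles(cohort, v,
                  recoding = if (v == "httlpr") "biallelic" else "raw")
  })
  spec <- identify_effector_alleles(tables, overrides = overrides)
  scores <- compute_scores(cohort, spec)
  fit <- score_regression(cohort, scores, covariates = covariates)
  list(spec = spec, scores = scores, fit = fit)
}
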