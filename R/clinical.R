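# Clinical-feature comparison between triptan users and non-users:
# categorical questions by chi-square (Yates-corrected for 2x2 tables),
# numeric ones by the two-sample Wilcoxon rank-sum test. Multiple ticked
# answers on severity-ordered questions are resolved by keeping the most
# severe; missing answers are excluded question by question.

#' Resolve multiple ticked answers by severity
#'
#' When a participant ticked several categories of a severity-ordered
#' question (e.g. two attack-frequency bands), the analysis keeps the
#' most severe answer: the maximum under the question's declared
#' category order (highest frequency, longest duration). The operation
#' is idempotent and invariant to the order of the input answers; an
#' empty answer list is missing.
#'
#' @param answers character vector of ticked categories (possibly
#'   length 0 or `NA`).
#' @param question a question definition from [clinical_questions()].
#' @return Single category label, or `NA` for no answer.
#' @export
#' @examples
#' q <- clinical_questions()$attack_frequency
#' keep_most_severe(c("1-2", "3-5"), q)  # "3-5"
keep_most_severe <- function(answers, question) {
  answers <- answers[!is.na(answers)]
  if (length(answers) == 0L) return(NA_character_)
  r <- match(answers, question$categories)
  if (anyNA(r)) {
    stop("answer not a category of ", question$id, ": ",
         paste(answers[is.na(r)], collapse = ", "))
  }
  question$categories[max(r)]
}

new_group_comparison <- function(question, test, statistic, df, p,
                                 flags = character(0), detail = NULL) {
  structure(list(question = question, test = test, statistic = statistic,
                 df = df, p = p, flags = flags, detail = detail),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, ", x$question, x$test))
  if (!is.na(x$statistic)) {
    cat(sprintf("statistic %.3f%s, ", x$statistic,
                if (!is.na(x$df)) paste0(" (", x$df, " df)") else ""))
  }
  cat("P =", format.pval(x$p, digits = 3), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ","), "\n")
  invisible(x)
}

#' Chi-square comparison of a group-by-category count table
#'
#' Pearson chi-square on an r x c contingency table of answer counts by
#' usage group: with Yates continuity correction for 2x2 tables,
#' uncorrected otherwise, on (r-1)(c-1) degrees of freedom. A zero row
#' or column total makes an expected cell structurally zero and is an
#' error; any expected cell below 5 sets the `expected_lt_5` flag.
#'
#' @param counts integer matrix, rows = groups, columns = categories.
#' @param question optional question id for labelling.
#' @return A `group_comparison`.
#' @export
#' @examples
#' compare_categorical(rbind(user = c(469, 223), non_user = c(94, 66)))
compare_categorical <- function(counts, question = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least a 2x2 table")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("structural zero: a row or column total is 0")
  }
  two_by_two <- nrow(counts) == 2L && ncol(counts) == 2L
  ct <- suppressWarnings(stats::chisq.test(counts, correct = two_by_two))
  flags <- if (any(ct$expected < 5)) "expected_lt_5" else character(0)
  new_group_comparison(question %||% "categorical",
                       if (two_by_two) "chisq_yates_2x2" else "chisq_rxc",
                       unname(ct$statistic), unname(ct$parameter), ct$p.value,
                       flags = flags, detail = list(counts = counts,
                                                    expected = ct$expected))
}

#' Wilcoxon rank-sum comparison of a numeric feature
#'
#' Two-sample Wilcoxon rank-sum test between users and non-users: the
#' exact distribution when the combined sample size is at most 50 and
#' there are no ties, otherwise the normal approximation with continuity
#' correction.
#'
#' @param values_users,values_nonusers numeric vectors (NAs dropped).
#' @param question optional question id for labelling.
#' @return A `group_comparison`.
#' @export
#' @examples
#' compare_numeric(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
compare_numeric <- function(values_users, values_nonusers, question = NULL) {
  x <- values_users[!is.na(values_users)]
  y <- values_nonusers[!is.na(values_nonusers)]
  if (length(x) == 0L || length(y) == 0L) stop("a group is empty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 50 && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  new_group_comparison(question %||% "numeric", "wilcoxon",
                       unname(wt$statistic), NA_real_, wt$p.value,
                       detail = list(n = c(length(x), length(y)),
                                     exact = exact))
}

mean_sd_str <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return("-")
  sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
}

pct_n_str <- function(flag) {
  flag <- flag[!is.na(flag)]
  if (length(flag) == 0L) return("- (0)")
  k <- sum(flag == "yes")
  sprintf("%.1f%% (%d)", round_half_up(100 * k / length(flag), 1), k)
}

#' Demographic and clinical summary by usage group
#'
#' Mean +/- standard deviation (n - 1 denominator) for numeric fields
#' and percentage (count) excluding missing for binary fields, for the
#' whole cohort and each usage group including tablet-only users.
#'
#' @param cohort a `ch_cohort`.
#' @return Data frame of formatted summaries, one column per group.
#' @export
summary_table <- function(cohort) {
  ph <- cohort$phenotypes
  groups <- list(all = rep(TRUE, nrow(ph)),
                 user = ph$usage_group %in% "user",
                 non_user = ph$usage_group %in% "non_user",
                 tablet_only = ph$usage_group %in% "tablet_only")
  row_for <- function(f) vapply(groups, function(i) f(ph[i, ]), character(1))
  out <- rbind(
    n = vapply(groups, function(i) as.character(sum(i)), character(1)),
    age = row_for(function(d) mean_sd_str(d$age)),
    age_at_onset = row_for(function(d) mean_sd_str(d$age_at_onset)),
    male = row_for(function(d) pct_n_str(ifelse(d$sex == "male", "yes", "no"))),
    chronic = row_for(function(d) pct_n_str(d$chronic)),
    heredity = row_for(function(d) pct_n_str(d$heredity))
  )
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Resolve a question column (possibly ";"-joined multi answers) to one
# category per individual.
resolve_answers <- function(col, question) {
  vapply(col, function(a) {
    if (is.na(a) || a == "." || a == "") return(NA_character_)
    keep_most_severe(strsplit(a, ";", fixed = TRUE)[[1]], question)
  }, character(1), USE.NAMES = FALSE)
}

#' Clinical-features comparison between triptan users and non-users
#'
#' Reproduces the standard clinical comparison: every categorical
#' question is cross-tabulated (after most-severe resolution and missing
#' exclusion) and tested by chi-square (Yates-corrected for 2x2);
#' numeric questions, plus age and age at onset, use the Wilcoxon
#' rank-sum test; chronicity and heredity enter as yes/no tables.
#' Categories with no answers in either group are dropped from a
#' question's table before testing.
#'
#' @param cohort a `ch_cohort`.
#' @param questions question definitions (default [clinical_questions()]).
#' @return Data frame with `question`, `test`, `statistic`, `df`, `p`,
#'   `flags`, `n`; the per-question `group_comparison` objects are
#'   attached as the `comparisons` attribute.
#' @export
clinical_comparison <- function(cohort, questions = clinical_questions()) {
  ph <- cohort$phenotypes
  users <- ph$usage_group %in% "user"
  nonusers <- ph$usage_group %in% "non_user"
  comparisons <- list()

  add_cat <- function(id, col_user, col_nonuser, categories) {
    tab <- rbind(user = table(factor(col_user, levels = categories)),
                 non_user = table(factor(col_nonuser, levels = categories)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    comparisons[[id]] <<- compare_categorical(tab, question = id)
  }

  for (qn in names(questions)) {
    q <- questions[[qn]]
    if (!qn %in% names(ph)) next
    if (q$type == "numeric") {
      comparisons[[qn]] <- compare_numeric(ph[[qn]][users], ph[[qn]][nonusers],
                                           question = qn)
    } else {
      ans <- resolve_answers(ph[[qn]], q)
      add_cat(qn, ans[users & !is.na(ans)], ans[nonusers & !is.na(ans)],
              q$categories)
    }
  }
  for (qn in c("chronic", "heredity")) {
    add_cat(qn, ph[[qn]][users], ph[[qn]][nonusers], c("no", "yes"))
  }
  comparisons$age <- compare_numeric(ph$age[users], ph$age[nonusers],
                                     question = "age")
  comparisons$age_at_onset <- compare_numeric(ph$age_at_onset[users],
                                              ph$age_at_onset[nonusers],
                                              question = "age_at_onset")
  out <- do.call(rbind, lapply(names(comparisons), function(id) {
    cm <- comparisons[[id]]
    data.frame(question = id, test = cm$test,
               statistic = cm$statistic %||% NA_real_,
               df = cm$df %||% NA_real_, p = min(cm$p, 1),
               flags = paste(cm$flags, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  attr(out, "comparisons") <- comparisons
  out
}
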