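# Tri-allelic 5-HTTLPR/rs25531 genotype calling from BcnI restriction
# fragment band patterns.
#
# Each allele digests to a constant pair (126 bp, 62 bp) plus diagnostic
# fragments: L_A -> 341; L_G -> 174 + 167; S -> 298. On a gel the
# constant fragments appear once regardless of genotype, so expected
# band sets are the deduplicated union of the per-allele fragment sets.

httlpr_alleles <- c("L_A", "L_G", "S")

allele_fragments <- list(
  L_A = c(341L, 126L, 62L),
  L_G = c(174L, 167L, 126L, 62L),
  S   = c(298L, 126L, 62L)
)

constant_fragments <- c(126L, 62L)

# the 174/167 pair differs by 7 bp, below agarose resolution: one
# observed band within tolerance of both may satisfy both
doublet_fragments <- c(174L, 167L)

# All 6 unordered diploid genotypes over {L_A, L_G, S}.
httlpr_genotypes <- function() {
  g <- list()
  for (i in 1:3) for (j in i:3) {
    g[[length(g) + 1L]] <- c(httlpr_alleles[i], httlpr_alleles[j])
  }
  g
}

#' Expected gel band lengths for a 5-HTTLPR/rs25531 diploid genotype
#'
#' Returns the set of BcnI restriction-fragment lengths expected on a gel
#' for an unordered allele pair over \{`L_A`, `L_G`, `S`\}. Fragments
#' shared between the two alleles (always the constant 126 bp and 62 bp
#' pair; also the diagnostic fragments in a homozygote) run as a single
#' band and appear once.
#'
#' @param genotype character vector of two alleles, e.g. `c("L_A", "S")`,
#'   or a string `"L_A/S"`.
#' @return Sorted decreasing integer vector of distinct band lengths (bp).
#' @export
#' @examples
#' expected_bands(c("L_A", "L_A"))  # 341 126 62
#' expected_bands("L_G/S")          # 298 174 167 126 62
expected_bands <- function(genotype) {
  g <- as_allele_pair(genotype)
  sort(unique(c(allele_fragments[[g[1]]], allele_fragments[[g[2]]])),
       decreasing = TRUE)
}

as_allele_pair <- function(genotype) {
  if (length(genotype) == 1L && grepl("/", genotype, fixed = TRUE)) {
    genotype <- strsplit(genotype, "/", fixed = TRUE)[[1]]
  }
  if (length(genotype) != 2L || !all(genotype %in% httlpr_alleles)) {
    stop("genotype must be an unordered pair over {",
         paste(httlpr_alleles, collapse = ", "), "}")
  }
  sort(genotype)
}

# Does observed length o match expected length e at relative tolerance?
band_matches <- function(o, e, tolerance) abs(o - e) <= tolerance * e

#' Call a 5-HTTLPR/rs25531 genotype from an observed band pattern
#'
#' Matches observed fragment lengths against the expected band sets of
#' the six diploid genotypes at a relative length tolerance (default
#' ±4%). A call requires the constant 126/62 bp digestion-control bands,
#' every expected band of the genotype observed, and every observed band
#' explained. The 174/167 bp `L_G` doublet co-migrates on agarose, so a
#' single observed band within tolerance of both satisfies both.
#'
#' An otherwise clean `L_G/S` pattern carrying an extra band at 341 bp is
#' called `L_G/S` but flagged `sequencing_required`: the extra band
#' suggests a hidden `L_A` allele and the sample should be confirmed by
#' Sanger sequencing before use in association analysis.
#'
#' @param pattern positive numeric vector of observed fragment lengths
#'   (bp), duplicates allowed, or a list with `sample_id` and
#'   `fragment_lengths`.
#' @param tolerance relative matching tolerance in `[0, 0.1]`
#'   (default 0.04).
#' @return Object of class `triallelic_call`: list with `genotype`
#'   (length-2 character or `NULL` for no-call) and `flags` (character
#'   subset of `sequencing_required`, `unmatched_bands`,
#'   `missing_constant_bands`).
#' @export
#' @examples
#' call_genotype(c(341, 298, 126, 62))            # L_A/S
#' call_genotype(c(298, 174, 167, 126, 62, 341))  # L_G/S + sequencing_required
call_genotype <- function(pattern, tolerance = 0.04) {
  if (is.list(pattern)) pattern <- pattern$fragment_lengths
  if (length(pattern) == 0L) stop("empty band pattern")
  if (!is.numeric(pattern) || any(pattern <= 0)) {
    stop("fragment lengths must be positive numbers")
  }
  if (tolerance < 0 || tolerance > 0.1) {
    stop("tolerance must lie in [0, 0.1]")
  }
  obs <- unique(as.numeric(pattern))

  new_call <- function(genotype, flags) {
    structure(list(genotype = genotype, flags = flags),
              class = "triallelic_call")
  }

  if (!all(vapply(constant_fragments, function(e) {
    any(band_matches(obs, e, tolerance))
  }, logical(1)))) {
    return(new_call(NULL, "missing_constant_bands"))
  }

  genotypes <- httlpr_genotypes()
  all_expected_present <- logical(length(genotypes))
  unexplained <- vector("list", length(genotypes))
  for (k in seq_along(genotypes)) {
    exp_bands <- expected_bands(genotypes[[k]])
    all_expected_present[k] <- all(vapply(exp_bands, function(e) {
      any(band_matches(obs, e, tolerance))
    }, logical(1)))
    explained <- vapply(obs, function(o) {
      any(band_matches(o, exp_bands, tolerance))
    }, logical(1))
    unexplained[[k]] <- obs[!explained]
  }

  clean <- which(all_expected_present &
                   lengths(unexplained) == 0L)
  if (length(clean) == 1L) {
    return(new_call(genotypes[[clean]], character(0)))
  }
  if (length(clean) > 1L) {
    # ambiguous under a wide tolerance; refuse to call
    return(new_call(NULL, "unmatched_bands"))
  }

  # No clean fit: a genotype complete except for an extra 341 bp band it
  # does not itself predict (the L_G/S + 341 situation) is called but
  # flagged for Sanger confirmation, since the extra band suggests a
  # hidden L_A allele.
  pending <- which(all_expected_present & vapply(seq_along(genotypes),
    function(k) {
      extra <- unexplained[[k]]
      length(extra) > 0L &&
        all(band_matches(extra, 341L, tolerance)) &&
        !any(band_matches(expected_bands(genotypes[[k]]), 341L, tolerance))
    }, logical(1)))
  if (length(pending) == 1L) {
    return(new_call(genotypes[[pending]], "sequencing_required"))
  }
  new_call(NULL, "unmatched_bands")
}

#' @export
print.triallelic_call <- function(x, ...) {
  g <- if (is.null(x$genotype)) "no-call" else paste(x$genotype, collapse = "/")
  f <- if (length(x$flags)) paste(x$flags, collapse = ",") else "none"
  cat("5-HTTLPR/rs25531 call:", g, " flags:", f, "\n")
  invisible(x)
}

#' Recode a tri-allelic 5-HTTLPR genotype to the bi-allelic L/S model
#'
#' The bi-allelic model considers only the presence (`L`) or absence
#' (`S`) of the 43 bp promoter insertion: both `L_A` and `L_G` map to
#' `L`, and `S` stays `S`.
#'
#' @param genotype allele pair over \{`L_A`, `L_G`, `S`\} (vector or
#'   `"A/B"` string); vectors of strings are recoded element-wise.
#' @return Genotype in the same form over \{`L`, `S`\}.
#' @export
#' @examples
#' recode_biallelic("L_A/L_G")  # "L/L"
recode_biallelic <- function(genotype) {
  recode_httlpr(genotype, c(L_A = "L", L_G = "L", S = "S"))
}

#' Recode a tri-allelic 5-HTTLPR genotype to the collapsed functional model
#'
#' The collapsed tri-allelic model groups the low-expressing `L_G` allele
#' with `S` (both reduce serotonin-transporter transcription), leaving
#' `L_A` as the high-expressing class: `L_A` maps to `L_A`, while `L_G`
#' and `S` map to `S*`.
#'
#' @inheritParams recode_biallelic
#' @return Genotype in the same form over \{`L_A`, `S*`\}.
#' @export
#' @examples
#' recode_collapsed("L_G/S")  # "S*/S*"
recode_collapsed <- function(genotype) {
  recode_httlpr(genotype, c(L_A = "L_A", L_G = "S*", S = "S*"))
}

recode_httlpr <- function(genotype, map) {
  if (is.character(genotype) && length(genotype) != 2L) {
    # element-wise over "A/B" strings (missing passes through)
    return(vapply(genotype, function(g) {
      if (is.na(g) || g == ".") return(if (is.na(g)) NA_character_ else ".")
      p <- as_allele_pair(g)
      paste(sort(unname(map[p])), collapse = "/")
    }, character(1), USE.NAMES = FALSE))
  }
  one <- length(genotype) == 1L
  p <- as_allele_pair(genotype)
  out <- sort(unname(map[p]))
  if (one) paste(out, collapse = "/") else out
}

#' Call 5-HTTLPR genotypes for a table of band patterns
#'
#' Vectorised driver over a band table as produced by gel reading: one
#' row per sample with a comma-separated list of fragment lengths.
#'
#' @param bands data frame with columns `sample_id` and `lengths`
#'   (comma-separated bp values), or a named list of numeric vectors.
#' @param tolerance relative matching tolerance (default 0.04).
#' @return Data frame with `sample_id`, `genotype` (`"A/B"` or `"."`),
#'   `flags` (comma-separated).
#' @export
call_rflp_table <- function(bands, tolerance = 0.04) {
  if (is.data.frame(bands)) {
    ids <- bands$sample_id
    pats <- lapply(strsplit(as.character(bands$lengths), ","), as.numeric)
  } else {
    ids <- names(bands)
    pats <- bands
  }
  calls <- lapply(pats, call_genotype, tolerance = tolerance)
  data.frame(
    sample_id = ids,
    genotype = vapply(calls, function(cl) {
      if (is.null(cl$genotype)) "." else paste(cl$genotype, collapse = "/")
    }, character(1)),
    flags = vapply(calls, function(cl) paste(cl$flags, collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE
  )
}
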