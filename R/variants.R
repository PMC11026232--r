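#' Variant definitions for the five-candidate triptan-usage panel
#'
#' The panel comprises four biallelic SNPs genotyped by TaqMan qPCR
#' (rs1024905, rs6724624, rs5443, rs2651899) and the tri-allelic
#' 5-HTTLPR/rs25531 promoter system of the serotonin transporter gene,
#' genotyped by PCR-RFLP with BcnI. The 5-HTTLPR alleles are the long
#' allele carrying rs25531-A (`L_A`), the long allele carrying rs25531-G
#' (`L_G`), and the short allele (`S`) lacking the 43 bp insertion.
#'
#' Genomic positions are placeholders on the correct chromosomes: the
#' pipeline never uses coordinates analytically, they exist only so the
#' VCF export is well-formed.
#'
#' @return A data frame with one row per variant: `variant`, `alleles`
#'   (comma-separated, reference allele first), `triallelic`, `chrom`,
#'   `pos` (placeholder).
#' @export
#' @examples
#' variant_defs()
variant_defs <- function() {
  data.frame(
    variant    = c("rs1024905", "rs6724624", "rs5443", "rs2651899", "httlpr"),
    alleles    = c("G,C", "C,G", "C,T", "T,C", "L_A,L_G,S"),
    triallelic = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    chrom      = c("12", "2", "12", "1", "17"),
    pos        = c(1024905L, 6724624L, 5443L, 2651899L, 4795541L),
    stringsAsFactors = FALSE
  )
}

#' @rdname variant_defs
#' @export
variant_ids <- function() variant_defs()$variant

# Allele lists per variant, reference allele first.
variant_alleles <- function(variant) {
  defs <- variant_defs()
  i <- match(variant, defs$variant)
  if (is.na(i)) stop("unknown variant: ", variant)
  strsplit(defs$alleles[i], ",", fixed = TRUE)[[1]]
}

#' Published cohort allele counts for the candidate variants
#'
#' Allele counts by triptan-usage group from the Swedish cluster headache
#' cohort in which the panel was characterised (users vs non-users,
#' tablet-only users excluded). The 5-HTTLPR system appears twice: as the
#' bi-allelic L/S recoding and as the collapsed tri-allelic recoding
#' (`L_A` vs `S*`, where `S*` pools `L_G` with `S`).
#'
#' These counts serve as the default calibration of the synthetic cohort
#' generator and as a worked reference dataset for the counting,
#' odds-ratio and correction machinery.
#'
#' @return Named list; each element has `alleles` and an integer matrix
#'   `counts` with rows `user`, `non_user`.
#' @export
#' @examples
#' reference_allele_counts()$rs1024905
reference_allele_counts <- function() {
  tab <- function(alleles, user, non_user) {
    m <- rbind(user = user, non_user = non_user)
    colnames(m) <- alleles
    list(alleles = alleles, counts = m)
  }
  list(
    rs1024905         = tab(c("G", "C"),    c(435L, 379L), c(89L, 125L)),
    rs6724624         = tab(c("C", "G"),    c(634L, 170L), c(179L, 35L)),
    rs5443            = tab(c("C", "T"),    c(577L, 235L), c(152L, 62L)),
    rs2651899         = tab(c("T", "C"),    c(475L, 331L), c(128L, 88L)),
    httlpr_biallelic  = tab(c("L", "S"),    c(465L, 329L), c(110L, 106L)),
    httlpr_triallelic = tab(c("L_A", "S*"), c(415L, 379L), c(101L, 115L))
  )
}

#' Default allele frequencies pooled across usage groups
#'
#' Pooled (users + non-users) allele frequencies computed from
#' [reference_allele_counts()]. For the tri-allelic 5-HTTLPR system the
#' `L_A` frequency comes from the collapsed tri-allelic table and the
#' `L_G` frequency is the difference between the bi-allelic `L` count and
#' the `L_A` count, the only decomposition the published tables admit.
#'
#' @return Named list mapping variant id to a named frequency vector
#'   summing to 1.
#' @export
#' @examples
#' default_allele_freqs()$rs1024905
default_allele_freqs <- function() {
  rc <- reference_allele_counts()
  pool <- function(x) {
    tot <- colSums(x$counts)
    tot / sum(tot)
  }
  bi  <- colSums(rc$httlpr_biallelic$counts)   # L, S
  tri <- colSums(rc$httlpr_triallelic$counts)  # L_A, S*
  n   <- sum(bi)
  la  <- tri[["L_A"]]
  lg  <- bi[["L"]] - la
  list(
    rs1024905 = pool(rc$rs1024905),
    rs6724624 = pool(rc$rs6724624),
    rs5443    = pool(rc$rs5443),
    rs2651899 = pool(rc$rs2651899),
    httlpr    = c(L_A = la / n, L_G = lg / n, S = bi[["S"]] / n)
  )
}

# Parse "A/B" genotype strings into a 2-column character matrix.
# "." (missing) rows become NA/NA. Validates alleles against the
# variant's allele set; errors name the offending entry.
parse_genotypes <- function(g, variant, ids = NULL) {
  alleles <- variant_alleles(variant)
  out <- matrix(NA_character_, nrow = length(g), ncol = 2)
  ok <- !is.na(g) & g != "." & g != ""
  if (any(ok)) {
    parts <- strsplit(g[ok], "/", fixed = TRUE)
    bad <- vapply(parts, function(p) length(p) != 2 || !all(p %in% alleles), logical(1))
    if (any(bad)) {
      i <- which(ok)[which(bad)[1]]
      lab <- if (!is.null(ids)) paste0(" (id ", ids[i], ")") else ""
      stop("malformed genotype '", g[i], "' for ", variant, lab)
    }
    out[ok, ] <- t(vapply(parts, identity, character(2)))
  }
  out
}

format_genotype <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), ".", paste(a1, a2, sep = "/"))
}
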