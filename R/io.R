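# Readers, writers, and pipeline orchestration: tab-separated genotype
# and phenotype tables with "." for missing, a VCF v4.3 export of the
# four biallelic SNPs, YAML generator configurations, and a single
# driver running every analysis stage with exclusion accounting.

phenotype_numeric_cols <- c("age", "age_at_onset", "disease_duration")
usage_cols <- c("triptan_injection", "triptan_nasal", "triptan_tablet",
                "tried_triptan_unresponsive")

# Grouping rules: regular use of a fast-acting form (injection or nasal
# spray) makes a user; triptans only as tablets makes a tablet-only
# user; an answered survey with no triptan use (including those who
# tried triptans without effect) makes a non-user; no usable answer
# leaves the individual unclassified (NA).
derive_usage_group <- function(ph) {
  inj <- ph$triptan_injection
  nas <- ph$triptan_nasal
  tab <- ph$triptan_tablet
  answered <- function(x) !is.na(x) & x != "."
  any_answer <- answered(inj) | answered(nas) | answered(tab) |
    answered(ph$tried_triptan_unresponsive)
  ifelse(!any_answer, NA_character_,
         ifelse(inj %in% "yes" | nas %in% "yes", "user",
                ifelse(tab %in% "yes", "tablet_only", "non_user")))
}

write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.numeric(x)) x <- as.character(x)
    x[is.na(x)] <- "."
    out[[j]] <- x
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, na.strings = NULL)
}

#' Write a cohort to genotype/phenotype TSVs and a SNP VCF
#'
#' Emits `<prefix>_genotypes.tsv` (id plus one `"A/B"` column per
#' variant, `"."` missing), `<prefix>_phenotypes.tsv` (all survey
#' fields, `"."` missing), and `<prefix>_snps.vcf`, a VCF v4.3 with GT
#' calls for the four biallelic SNPs only — the tri-allelic 5-HTTLPR
#' indel system has no faithful biallelic VCF representation and stays
#' in the TSV.
#'
#' @param cohort a `ch_cohort`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, prefix = "cohort") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, paste0(prefix, "_genotypes.tsv")),
    phenotypes = file.path(dir, paste0(prefix, "_phenotypes.tsv")),
    vcf = file.path(dir, paste0(prefix, "_snps.vcf"))
  )
  write_tsv(cohort$genotypes, paths[["genotypes"]])
  write_tsv(cohort$phenotypes, paths[["phenotypes"]])
  write_snp_vcf(cohort, paths[["vcf"]])
  invisible(paths)
}

write_snp_vcf <- function(cohort, path) {
  defs <- cohort$variants[!cohort$variants$triallelic, ]
  ids <- cohort$genotypes$id
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.3",
    "##source=triptanscore",
    "##comment=positions are nominal placeholders; the pipeline is position-agnostic",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("##contig=<ID=", unique(defs$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t")
  ), con)
  defs <- defs[order(defs$chrom, defs$pos), ]
  for (k in seq_len(nrow(defs))) {
    v <- defs$variant[k]
    al <- variant_alleles(v)
    g <- cohort$genotypes[[v]]
    gt <- vapply(g, function(x) {
      if (is.na(x) || x == ".") return("./.")
      p <- strsplit(x, "/", fixed = TRUE)[[1]]
      paste(match(p, al) - 1L, collapse = "/")
    }, character(1), USE.NAMES = FALSE)
    writeLines(paste(c(defs$chrom[k], defs$pos[k], v, al[1], al[2], ".",
                       "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
}

#' Read a cohort from genotype and phenotype TSVs
#'
#' Inverse of [write_cohort()] for the TSV pair. Genotype tokens are
#' validated against each variant's allele set (errors name the row);
#' `"."` is missing throughout; the usage group is re-derived from the
#' triptan-usage answers (fast-acting form -> user, tablets only ->
#' tablet-only, answered but none -> non-user, no answer -> NA).
#'
#' @param genotype_path,phenotype_path paths to the TSVs.
#' @return A `ch_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(genotype_path, phenotype_path) {
  gen <- read_tsv(genotype_path)
  ph <- read_tsv(phenotype_path)
  if (anyDuplicated(gen$id)) stop("duplicated ids in genotype table")
  if (anyDuplicated(ph$id)) stop("duplicated ids in phenotype table")
  if (!identical(gen$id, ph$id)) {
    stop("genotype and phenotype tables list different individuals")
  }
  vids <- intersect(variant_ids(), names(gen))
  for (v in vids) {
    parse_genotypes(gen[[v]], v, ids = gen$id)  # validation only
  }
  for (cl in intersect(phenotype_numeric_cols, names(ph))) {
    x <- ph[[cl]]
    x[x == "."] <- NA
    bad <- !is.na(x) & is.na(suppressWarnings(as.numeric(x)))
    if (any(bad)) {
      stop("non-numeric value '", x[bad][1], "' in column ", cl,
           " (id ", ph$id[bad][1], ")")
    }
    ph[[cl]] <- as.integer(x)
  }
  for (cl in setdiff(names(ph), c("id", phenotype_numeric_cols))) {
    ph[[cl]][ph[[cl]] == "."] <- NA
  }
  ph$usage_group <- derive_usage_group(ph)
  structure(list(phenotypes = ph, genotypes = gen,
                 variants = variant_defs(), config = NULL),
            class = "ch_cohort")
}

#' Read or write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [cohort_config()].
#' @return `read_generator_config()` returns a `cohort_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$allele_freqs <- lapply(raw$allele_freqs, unlist)
  raw$effector_alleles <- unlist(raw$effector_alleles)
  raw$missing_rate <- unlist(raw$missing_rate)
  raw$clinical_missing <- unlist(raw$clinical_missing)
  defaults <- formals(cohort_config)
  args <- raw[intersect(names(raw), names(defaults))]
  do.call(cohort_config, args)
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, path) {
  x <- unclass(config)
  x$clinical_profiles <- NULL  # regenerated from defaults on read
  as_map <- function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v)
    else if (is.list(v)) lapply(v, as_map)
    else v
  }
  yaml::write_yaml(lapply(x, as_map), path, precision = 15)
  invisible(path)
}

#' Run the full triptan-usage analysis pipeline
#'
#' Orchestrates every stage on one cohort: simulate (from a
#' [cohort_config()]) or read (from TSV paths), optionally call
#' 5-HTTLPR genotypes from a band table, then allelic association,
#' effector-score regression, clinical comparison, and the
#' detectable-OR power panel. Reports are written as TSV/JSON under
#' `out_dir` together with a JSON log recording the seed and the count
#' retained at every exclusion step; reruns of the same configuration
#' are byte-identical.
#'
#' @param config a `cohort_config` (mutually exclusive with paths).
#' @param genotype_path,phenotype_path cohort TSVs (mutually exclusive
#'   with `config`).
#' @param bands_path optional RFLP band TSV (`sample_id`, `lengths`);
#'   calls replace the cohort's 5-HTTLPR genotypes, with
#'   sequencing-required and failed calls set to missing.
#' @param out_dir report directory.
#' @param m Bonferroni correction factor.
#' @param score_variants variants entering the effector score; the full
#'   5-variant panel is required unless this is overridden explicitly.
#' @param effector_overrides optional named vector variant -> allele.
#' @param power_freqs named control allele frequencies for the power
#'   panel.
#' @param tolerance RFLP band-matching tolerance.
#' @return Report bundle (list), invisibly; components `cohort`,
#'   `association`, `effector`, `clinical`, `power`, `log`, `paths`.
#' @export
run_pipeline <- function(config = NULL, genotype_path = NULL,
                         phenotype_path = NULL, bands_path = NULL,
                         out_dir, m = 5L, score_variants = NULL,
                         effector_overrides = NULL,
                         power_freqs = reference_control_freqs(),
                         tolerance = 0.04) {
  from_config <- !is.null(config)
  from_files <- !is.null(genotype_path) || !is.null(phenotype_path)
  if (from_config == from_files) {
    stop("supply exactly one of: a generator config, or genotype/phenotype paths")
  }
  cohort <- if (from_config) generate_cohort(config) else {
    read_cohort(genotype_path, phenotype_path)
  }
  if (!is.null(bands_path)) {
    calls <- call_rflp_table(read_tsv(bands_path), tolerance = tolerance)
    usable <- calls$genotype != "." & calls$flags == ""
    i <- match(cohort$genotypes$id, calls$sample_id)
    hit <- !is.na(i)
    cohort$genotypes$httlpr[hit] <-
      ifelse(usable[i[hit]], calls$genotype[i[hit]], ".")
  }

  if (is.null(score_variants)) {
    missing_panel <- setdiff(variant_ids(), names(cohort$genotypes))
    if (length(missing_panel)) {
      stop("effector score requires the full 5-variant panel (missing: ",
           paste(missing_panel, collapse = ", "),
           "); override score_variants to proceed with fewer")
    }
    score_variants <- variant_ids()
  }

  grp <- cohort$phenotypes$usage_group
  assoc <- association_table(cohort, m = m)
  eff <- effector_analysis(cohort, overrides = effector_overrides,
                           variants = score_variants)
  clin <- clinical_comparison(cohort)
  pow <- detectable_or_panel(n_cases = sum(grp %in% "non_user"),
                             control_case_ratio =
                               sum(grp %in% "user") /
                               max(sum(grp %in% "non_user"), 1),
                             freqs = power_freqs)
  present <- intersect(variant_ids(), names(cohort$genotypes))
  hwe <- vapply(present, function(v) {
    hwe_test_variant(cohort, v, seed = (cohort$config$seed %||% 1L) + 1L)
  }, numeric(1))

  log <- list(
    seed = cohort$config$seed %||% NA_integer_,
    n_total = nrow(cohort$phenotypes),
    n_users = sum(grp %in% "user"),
    n_nonusers = sum(grp %in% "non_user"),
    n_tablet_only = sum(grp %in% "tablet_only"),
    n_unclassified = sum(is.na(grp)),
    call_rates = vapply(present, function(v) call_rate(cohort, v),
                        numeric(1)),
    hwe_p = hwe,
    n_score_complete = eff$fit$n_complete
  )
  stopifnot(log$n_users + log$n_nonusers + log$n_tablet_only +
              log$n_unclassified == log$n_total)

  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    association = file.path(out_dir, "association.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    effector = file.path(out_dir, "effector.json"),
    power = file.path(out_dir, "power.json"),
    log = file.path(out_dir, "run_log.json")
  )
  write_tsv(assoc, paths[["association"]])
  write_tsv(clin, paths[["clinical"]])
  ct <- eff$fit$coefficients
  jsonlite::write_json(list(
    effector_spec = eff$spec,
    coefficients = as.data.frame(cbind(term = rownames(ct),
                                       as.data.frame(ct))),
    n_complete = eff$fit$n_complete
  ), paths[["effector"]], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(pow, paths[["power"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA)

  invisible(list(cohort = cohort, association = assoc, effector = eff,
                 clinical = clin, power = pow, log = log, paths = paths))
}
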