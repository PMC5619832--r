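# Domain types, readers, allele harmonization and BMI-category derivation.
#
# Conventions: 1-based positions throughout; dosages are real values in [0, 2]
# counting copies of the counted allele (after harmonization, the
# BMI-increasing risk allele); TSV means tab-separated with a header row and
# "NA" as the missing sentinel.

#' Construct a variant summary table
#'
#' Validates and types a GWAS consortium summary table: one row per SNP
#' with chromosome, 1-based position, effect/other allele, per-allele effect
#' on BMI (kg/m^2 per effect allele) and association p-value.
#'
#' @param snp_id Character vector of SNP identifiers (unique).
#' @param chromosome Character (or coercible) chromosome labels.
#' @param position Integer 1-based positions.
#' @param effect_allele,other_allele Single-character alleles (A/C/G/T).
#' @param beta Per-allele effect of the effect allele on BMI.
#' @param pvalue Association p-values in (0, 1].
#' @return A `data.frame` of class `pleio_variants`.
#' @export
variant_table <- function(snp_id, chromosome, position, effect_allele,
                          other_allele, beta, pvalue) {
  snp_id <- as.character(snp_id)
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id in variant table: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  }
  position <- as.integer(position)
  if (any(position < 1L)) stop("positions must be >= 1 (1-based)")
  effect_allele <- toupper(as.character(effect_allele))
  other_allele <- toupper(as.character(other_allele))
  if (any(nchar(effect_allele) != 1L) || any(nchar(other_allele) != 1L)) {
    stop("alleles must be single characters")
  }
  if (any(effect_allele == other_allele)) {
    stop("effect_allele must differ from other_allele")
  }
  pvalue <- as.numeric(pvalue)
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    stop("pvalue must lie in (0, 1]")
  }
  out <- data.frame(
    snp_id = snp_id,
    chromosome = as.character(chromosome),
    position = position,
    effect_allele = effect_allele,
    other_allele = other_allele,
    beta = as.numeric(beta),
    pvalue = pvalue,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pleio_variants", "data.frame")
  out
}

#' Read a variant summary table from TSV
#'
#' Expects columns `snp_id, chr, pos, effect_allele, other_allele, beta,
#' pvalue`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `pleio_variants` data frame (see [variant_table()]).
#' @export
read_variants <- function(path) {
  raw <- read_tsv_checked(path, c("snp_id", "chr", "pos", "effect_allele",
                                  "other_allele", "beta", "pvalue"))
  variant_table(raw$snp_id, raw$chr, raw$pos, raw$effect_allele,
                raw$other_allele, raw$beta, raw$pvalue)
}

#' Read an external validation summary table from TSV
#'
#' TAG-style per-SNP replication summary: columns `snp_id, direction,
#' pvalue`, with `direction` one of `positive`/`negative`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Data frame with columns snp_id, direction, pvalue.
#' @export
read_external_summary <- function(path) {
  raw <- read_tsv_checked(path, c("snp_id", "direction", "pvalue"))
  direction <- tolower(as.character(raw$direction))
  if (!all(direction %in% c("positive", "negative"))) {
    stop("external summary direction must be 'positive' or 'negative'")
  }
  pvalue <- as.numeric(raw$pvalue)
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1)) {
    stop("external summary pvalue must lie in (0, 1]")
  }
  data.frame(snp_id = as.character(raw$snp_id), direction = direction,
             pvalue = pvalue, stringsAsFactors = FALSE)
}

# internal: read a TSV and require columns
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE, quote = "",
                           comment.char = "")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing required columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  raw
}

#' Construct a dosage matrix
#'
#' @param dosages Numeric matrix, rows = individuals, columns = SNPs; values
#'   in \[0, 2\] or NA.
#' @param sample_ids,snp_ids Row and column identifiers.
#' @return Numeric matrix of class `pleio_dosages` with dimnames set.
#' @export
dosage_matrix <- function(dosages, sample_ids = rownames(dosages),
                          snp_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids) || is.null(snp_ids)) {
    stop("sample_ids and snp_ids are required")
  }
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage outside [0, 2] at sample '%s', SNP '%s'",
                 sample_ids[bad[1L]], snp_ids[bad[2L]]))
  }
  dimnames(dosages) <- list(as.character(sample_ids), as.character(snp_ids))
  class(dosages) <- c("pleio_dosages", class(dosages))
  dosages
}

#' Read allele dosages from VCF or TSV
#'
#' For VCF (v4.2) input the per-genotype `DS` field is preferred; when absent
#' the hard `GT` call is converted to an ALT-allele count. Imputed dosages
#' are retained as real values, never rounded to best-guess genotypes. The
#' counted allele is the VCF ALT allele; use [harmonize_alleles()] to orient
#' dosages to the risk allele.
#'
#' For TSV input the first column must be `sample_id` and each remaining
#' column one SNP, values in \[0, 2\] or NA.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param missing_policy How to handle missing/unparseable genotypes:
#'   `"drop_sample"` (default), `"drop_snp"`, or `"error"`.
#' @return A list with elements `dosages` (a [dosage_matrix()]) and, for VCF
#'   input, `counted_alleles` (data frame snp_id, counted_allele,
#'   other_allele giving the ALT/REF pair per site).
#' @export
read_dosages <- function(path, format = c("tsv", "vcf"),
                         missing_policy = c("drop_sample", "drop_snp",
                                            "error")) {
  format <- match.arg(format)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tsv") {
    raw <- read_tsv_checked(path, "sample_id")
    mat <- as.matrix(raw[, setdiff(names(raw), "sample_id"), drop = FALSE])
    if (!is.numeric(mat)) stop("parse error: non-numeric dosage values in ",
                               path)
    dos <- dosage_matrix(mat, sample_ids = raw$sample_id)
    list(dosages = apply_missing_policy(dos, missing_policy),
         counted_alleles = NULL)
  } else {
    read_dosages_vcf(path, missing_policy)
  }
}

read_dosages_vcf <- function(path, missing_policy) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop("multi-allelic VCF records are not supported (line for ",
         paste(fix[multi, "ID"], collapse = ", "), ")")
  }
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix[no_id, "CHROM"], ":", fix[no_id, "POS"])
  fmt <- v@gt[, 1L]
  has_ds <- all(vapply(strsplit(fmt, ":"), function(f) "DS" %in% f,
                       logical(1)))
  if (has_ds) {
    dsm <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dsm <- apply(gt, c(1, 2), gt_to_count)
  }
  # vcfR returns sites x samples; orient to samples x SNPs
  dsm <- t(dsm)
  colnames(dsm) <- ids
  dos <- dosage_matrix(dsm)
  list(dosages = apply_missing_policy(dos, missing_policy),
       counted_alleles = data.frame(snp_id = ids,
                                    counted_allele = toupper(alt),
                                    other_allele = toupper(fix[, "REF"]),
                                    stringsAsFactors = FALSE))
}

# "0/1" or "0|1" -> ALT allele count; anything unparseable -> NA
gt_to_count <- function(g) {
  if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
  alleles <- strsplit(g, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  suppressWarnings(n <- as.integer(alleles))
  if (any(is.na(n)) || any(n > 1L)) return(NA_real_)
  sum(n)
}

apply_missing_policy <- function(dos, policy) {
  if (!anyNA(dos)) return(dos)
  if (policy == "error") {
    bad <- which(is.na(unclass(dos)), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing dosage at sample '%s', SNP '%s' (policy = error)",
                 rownames(dos)[bad[1L]], colnames(dos)[bad[2L]]))
  }
  if (policy == "drop_sample") {
    keep <- rowSums(is.na(dos)) == 0L
    message(sum(!keep), " sample(s) dropped for missing dosages")
    out <- unclass(dos)[keep, , drop = FALSE]
  } else {
    keep <- colSums(is.na(dos)) == 0L
    message(sum(!keep), " SNP(s) dropped for missing dosages")
    out <- unclass(dos)[, keep, drop = FALSE]
  }
  dosage_matrix(out)
}

#' Derive the 4-level BMI category
#'
#' Categories: 1 underweight (BMI < 18.5), 2 normal (18.5 <= BMI < 25),
#' 3 overweight (25 <= BMI < 30), 4 obese (BMI >= 30). Intervals are
#' half-open, closed below.
#'
#' @param bmi Numeric BMI in kg/m^2, strictly positive.
#' @return Integer vector in 1..4.
#' @export
derive_bmi_category <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("bmi must be finite and > 0")
  }
  findInterval(bmi, c(18.5, 25, 30)) + 1L
}

#' Construct/validate a phenotype-covariate table
#'
#' Required columns: `sample_id, age, sex, study_site, pc1, pc2, pc3, pc4,
#' case_status, smoking_category, pack_years, bmi`. `smoking_category` is
#' normalized to one of never/ex/current (for binary smoking data, "ever" is
#' accepted and kept as its own level). `bmi_category` is derived via
#' [derive_bmi_category()]. Pack-years must be missing if and only if the
#' subject is a never-smoker.
#'
#' @param df Data frame with the columns above.
#' @param packyears_policy For never-smokers carrying a pack-years value:
#'   `"error"` (default) or `"coerce"` (set to NA, with a message).
#' @return Data frame of class `pleio_pheno` with typed columns and
#'   `bmi_category` filled in.
#' @export
pheno_table <- function(df, packyears_policy = c("error", "coerce")) {
  packyears_policy <- match.arg(packyears_policy)
  required <- c("sample_id", "age", "sex", "study_site", "pc1", "pc2", "pc3",
                "pc4", "case_status", "smoking_category", "pack_years", "bmi")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing phenotype columns: ", paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  out$sample_id <- as.character(out$sample_id)
  out$age <- as.numeric(out$age)
  out$sex <- as.integer(out$sex)
  if (!all(out$sex %in% c(0L, 1L))) stop("sex must be binary 0/1")
  out$study_site <- as.character(out$study_site)
  out$case_status <- as.integer(out$case_status)
  if (!all(out$case_status %in% c(0L, 1L))) {
    stop("case_status must be binary 0/1")
  }
  sm <- tolower(as.character(out$smoking_category))
  sm[sm %in% c("former", "ex-smoker")] <- "ex"
  sm[sm %in% c("current-smoker", "smoker")] <- "current"
  if (!all(sm %in% c("never", "ex", "current", "ever"))) {
    stop("smoking_category must be one of never/ex/current (or ever)")
  }
  out$smoking_category <- sm
  out$pack_years <- as.numeric(out$pack_years)
  bad_never <- sm == "never" & !is.na(out$pack_years)
  if (any(bad_never)) {
    if (packyears_policy == "error") {
      stop(sum(bad_never),
           " never-smoker(s) with non-missing pack_years; set ",
           "packyears_policy = 'coerce' to blank them")
    }
    message(sum(bad_never), " never-smoker pack_years value(s) set to NA")
    out$pack_years[bad_never] <- NA_real_
  }
  bad_ever <- sm != "never" & is.na(out$pack_years)
  if (any(bad_ever)) {
    stop(sum(bad_ever), " ever-smoker(s) with missing pack_years")
  }
  if (any(!is.na(out$pack_years) & out$pack_years < 0)) {
    stop("pack_years must be non-negative")
  }
  out$bmi <- as.numeric(out$bmi)
  out$bmi_category <- derive_bmi_category(out$bmi)
  class(out) <- c("pleio_pheno", "data.frame")
  out
}

#' Read a phenotype-covariate table from TSV
#'
#' @inheritParams pheno_table
#' @param path Path to a tab-separated file with a header row.
#' @return A `pleio_pheno` data frame (see [pheno_table()]).
#' @export
read_phenotypes <- function(path, packyears_policy = c("error", "coerce")) {
  raw <- read_tsv_checked(path, c("sample_id", "age", "sex", "study_site",
                                  "pc1", "pc2", "pc3", "pc4", "case_status",
                                  "smoking_category", "pack_years", "bmi"))
  pheno_table(raw, packyears_policy = match.arg(packyears_policy))
}

#' Harmonize variants and dosages to the risk-allele orientation
#'
#' Two normalizations, applied per SNP: (1) if the file's counted allele is
#' the variant's `other_allele`, flip the dosage (`2 - dosage`); (2) if
#' `beta < 0`, swap effect/other alleles, negate beta, and flip the dosage.
#' Afterwards every beta is >= 0 and every dosage counts copies of the
#' BMI-increasing risk allele. Input is assumed positive-strand;
#' strand-ambiguous A/T and C/G variants are rejected unless
#' `allow_ambiguous = TRUE`.
#'
#' @param variants A [variant_table()].
#' @param dosages A [dosage_matrix()] with columns covering the variants.
#' @param counted_alleles Optional data frame `snp_id, counted_allele,
#'   other_allele` describing which allele the dosage file counted (returned
#'   by [read_dosages()] for VCF input). If NULL the counted allele is
#'   assumed to be the variant's effect allele.
#' @param allow_ambiguous Allow A/T and C/G variants (with a warning).
#' @return List with harmonized `variants` and `dosages`.
#' @export
harmonize_alleles <- function(variants, dosages, counted_alleles = NULL,
                              allow_ambiguous = FALSE) {
  missing_snp <- setdiff(variants$snp_id, colnames(dosages))
  if (length(missing_snp)) {
    stop("variants missing from dosage matrix: ",
         paste(missing_snp, collapse = ", "))
  }
  ambiguous <- (variants$effect_allele == "A" & variants$other_allele == "T") |
    (variants$effect_allele == "T" & variants$other_allele == "A") |
    (variants$effect_allele == "C" & variants$other_allele == "G") |
    (variants$effect_allele == "G" & variants$other_allele == "C")
  if (any(ambiguous)) {
    msg <- paste("strand-ambiguous A/T or C/G variant(s):",
                 paste(variants$snp_id[ambiguous], collapse = ", "))
    if (!allow_ambiguous) stop(msg) else warning(msg)
  }
  dos <- unclass(dosages)
  if (!is.null(counted_alleles)) {
    idx <- match(variants$snp_id, counted_alleles$snp_id)
    if (anyNA(idx)) {
      stop("counted_alleles missing entries for: ",
           paste(variants$snp_id[is.na(idx)], collapse = ", "))
    }
    counted <- toupper(counted_alleles$counted_allele[idx])
    other <- toupper(counted_alleles$other_allele[idx])
    same <- counted == variants$effect_allele & other == variants$other_allele
    swapped <- counted == variants$other_allele &
      other == variants$effect_allele
    bad <- !(same | swapped)
    if (any(bad)) {
      stop("allele pair mismatch (neither same nor swapped) for: ",
           paste(variants$snp_id[bad], collapse = ", "))
    }
    for (j in which(swapped)) {
      dos[, variants$snp_id[j]] <- 2 - dos[, variants$snp_id[j]]
    }
  }
  neg <- variants$beta < 0
  if (any(neg)) {
    tmp <- variants$effect_allele[neg]
    variants$effect_allele[neg] <- variants$other_allele[neg]
    variants$other_allele[neg] <- tmp
    variants$beta[neg] <- -variants$beta[neg]
    for (j in which(neg)) {
      dos[, variants$snp_id[j]] <- 2 - dos[, variants$snp_id[j]]
    }
  }
  list(variants = variants, dosages = dosage_matrix(dos))
}

#' Write a result table to TSV or JSON
#'
#' Column order is preserved as given; numeric columns are written at a fixed
#' number of significant digits so round-trips reproduce printed precision.
#'
#' @param results Data frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits Significant digits for numeric columns (default 10).
#' @return Invisibly, `path`.
#' @export
write_table <- function(results, path, format = c("tsv", "json"),
                        digits = 10) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], signif, digits = digits)
  if (format == "tsv") {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
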