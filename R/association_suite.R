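# Covariate-adjusted association analyses of BMI, the BMI genetic risk
# score, and smoking behaviour. Each analysis hard-codes the conventional
# adjustment set as its default (they differ between analyses on purpose:
# pooled partial correlations additionally adjust for disease status,
# stratified ones do not) and exposes overrides.

# internal: align a GRS to the phenotype rows by sample id
align_grs <- function(grs, pheno) {
  scores <- if (inherits(grs, "grs_result")) grs$scores else grs
  if (is.null(names(scores))) stop("GRS scores must be named by sample_id")
  idx <- match(pheno$sample_id, names(scores))
  if (anyNA(idx)) {
    stop(sum(is.na(idx)), " phenotype row(s) missing a GRS value")
  }
  as.numeric(scores[idx])
}

# internal: never-referenced two-group contrast of y between the rows in
# `in_a` (coded 1) and `in_b` (coded 0), adjusted for covariates
two_group_contrast <- function(y, in_a, in_b, cov_terms, label) {
  if (!any(in_a) || !any(in_b)) {
    stop("contrast '", label, "': a compared category is absent")
  }
  keep <- in_a | in_b
  terms <- c(list(.grp = as.numeric(in_a[keep])),
             lapply(cov_terms, function(v) v[keep]))
  fit <- fit_linear(y[keep], terms)
  est <- fit$coefficients[[".grp"]]
  se <- fit$standard_errors[[".grp"]]
  crit <- stats::qnorm(0.975)
  out <- assoc_row(est, est - crit * se, est + crit * se, wald_p(est, se),
                   fit$n_used, names_of(cov_terms))
  cbind(data.frame(contrast = label, stringsAsFactors = FALSE), out)
}

#' BMI by smoking category: adjusted means and never-referenced contrasts
#'
#' Adjusted mean BMI for never-, ex- and current smokers (cell-means model
#' with centered covariates) plus pairwise contrasts against never-smokers,
#' adjusted for age, sex and study site.
#'
#' @param pheno A `pleio_pheno` data frame.
#' @param covariate_names Adjustment set (default age, sex, study_site).
#' @param by_case_status Also return one result set per case/control
#'   stratum.
#' @return List with `means` ([adjusted_group_means()] output) and
#'   `contrasts` (one row per comparison); with `by_case_status`, a named
#'   list of such lists (`pooled`, `cases`, `controls`).
#' @export
bmi_by_smoking_category <- function(pheno,
                                    covariate_names = c("age", "sex",
                                                        "study_site"),
                                    by_case_status = FALSE) {
  if (by_case_status) {
    return(list(
      pooled = bmi_by_smoking_category(pheno, covariate_names),
      cases = bmi_by_smoking_category(pheno[pheno$case_status == 1L, ],
                                      covariate_names),
      controls = bmi_by_smoking_category(pheno[pheno$case_status == 0L, ],
                                         covariate_names)))
  }
  cov_terms <- covariate_terms_from_pheno(pheno, covariate_names)
  sm <- pheno$smoking_category
  if (length(unique(sm)) < 2L) stop("need >= 2 smoking categories")
  means <- adjusted_group_means(pheno$bmi, sm, cov_terms)
  others <- setdiff(sort(unique(sm)), "never")
  contrasts <- do.call(rbind, lapply(others, function(g) {
    two_group_contrast(pheno$bmi, sm == g, sm == "never", cov_terms,
                       paste0(g, "_vs_never"))
  }))
  list(means = means, contrasts = contrasts)
}

#' GRS across BMI categories: adjusted means and trend test
#'
#' Adjusted mean GRS within each 4-level BMI category, plus a trend test
#' treating the category code 1..4 as a continuous variable. Default
#' adjustment: age, sex, study site, four genetic PCs, smoking category and
#' pack-years (pack-years enters as 0 for never-smokers so the term is
#' defined on all rows).
#'
#' @param grs A `grs_result` or named numeric vector of scores.
#' @param pheno A `pleio_pheno` data frame.
#' @param covariate_names Adjustment set.
#' @return List with `means` (per BMI category) and `trend` (single-row
#'   trend-test result).
#' @export
grs_vs_bmi_categories <- function(grs, pheno,
                                  covariate_names = c("age", "sex",
                                                      "study_site", "pc1",
                                                      "pc2", "pc3", "pc4",
                                                      "smoking_category",
                                                      "pack_years")) {
  score <- align_grs(grs, pheno)
  if (length(unique(pheno$bmi_category)) < 2L) {
    stop("only one BMI category represented")
  }
  ph <- pheno
  if ("pack_years" %in% covariate_names) {
    ph$pack_years <- ifelse(is.na(ph$pack_years), 0, ph$pack_years)
  }
  cov_terms <- covariate_terms_from_pheno(ph, covariate_names)
  means <- adjusted_group_means(score, sprintf("bmi_cat%d",
                                               ph$bmi_category), cov_terms)
  trend <- trend_test(score, ph$bmi_category, cov_terms)
  list(means = means, trend = trend)
}

#' GRS by smoking category: never-referenced (and ex-vs-current) contrasts
#'
#' Linear regressions of the GRS on smoking-group indicators adjusted for
#' age, sex, study site and four PCs, optionally also for BMI. Returns the
#' comparisons ever vs never, ex vs never, current vs never, and ex vs
#' current, each fitted on the rows of the two compared groups.
#'
#' @param grs A `grs_result` or named numeric score vector.
#' @param pheno A `pleio_pheno` data frame.
#' @param adjust_bmi Add BMI to the adjustment set.
#' @param covariate_names Base adjustment set.
#' @return Data frame, one row per contrast.
#' @export
grs_vs_smoking_category <- function(grs, pheno, adjust_bmi = FALSE,
                                    covariate_names = c("age", "sex",
                                                        "study_site", "pc1",
                                                        "pc2", "pc3",
                                                        "pc4")) {
  score <- align_grs(grs, pheno)
  if (adjust_bmi) covariate_names <- c(covariate_names, "bmi")
  cov_terms <- covariate_terms_from_pheno(pheno, covariate_names)
  sm <- pheno$smoking_category
  ever <- sm != "never"
  rows <- list(
    two_group_contrast(score, ever, sm == "never", cov_terms,
                       "ever_vs_never"))
  if (any(sm == "ex")) {
    rows$exn <- two_group_contrast(score, sm == "ex", sm == "never",
                                   cov_terms, "ex_vs_never")
  }
  if (any(sm == "current")) {
    rows$cn <- two_group_contrast(score, sm == "current", sm == "never",
                                  cov_terms, "current_vs_never")
  }
  if (any(sm == "ex") && any(sm == "current")) {
    rows$ec <- two_group_contrast(score, sm == "ex", sm == "current",
                                  cov_terms, "ex_vs_current")
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# internal: run partial_correlation over requested strata of ever-smokers
partialcorr_by_strata <- function(x_all, pheno, yname, strata, cov_pooled,
                                  cov_stratified, min_n) {
  smokers <- pheno$smoking_category != "never" & !is.na(pheno$pack_years)
  run_one <- function(rows, label, covariate_names) {
    if (sum(rows) < min_n) {
      warning("stratum '", label, "' below minimum n (", sum(rows), " < ",
              min_n, "); skipped")
      return(NULL)
    }
    ph <- pheno[rows, , drop = FALSE]
    res <- partial_correlation(x_all[rows], ph[[yname]],
                               covariate_terms_from_pheno(
                                 ph, covariate_names))
    cbind(data.frame(stratum = label, stringsAsFactors = FALSE), res)
  }
  out <- list()
  if ("all" %in% strata) {
    out$all <- run_one(smokers, "all", cov_pooled)
  }
  if ("by_smoking_category" %in% strata) {
    out$cur <- run_one(smokers & pheno$smoking_category == "current",
                       "current", cov_pooled)
    out$ex <- run_one(smokers & pheno$smoking_category == "ex", "ex",
                      cov_pooled)
  }
  if ("by_case_status" %in% strata) {
    out$cases <- run_one(smokers & pheno$case_status == 1L, "cases",
                         cov_stratified)
    out$controls <- run_one(smokers & pheno$case_status == 0L, "controls",
                            cov_stratified)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Partial correlation of the GRS with pack-years among smokers
#'
#' Pearson correlation of GRS and pack-years residuals after adjustment for
#' age, sex, BMI, study site and the four PCs — plus disease status for the
#' pooled and smoking-category analyses (the case/control strata drop it).
#'
#' @param grs A `grs_result` or named numeric score vector.
#' @param pheno A `pleio_pheno` data frame.
#' @param strata Any of `"all"`, `"by_smoking_category"`,
#'   `"by_case_status"`.
#' @param min_n Minimum stratum size (default 30); smaller strata are
#'   skipped with a warning.
#' @return Data frame with one row per computed stratum.
#' @export
grs_packyears_partialcorr <- function(grs, pheno,
                                      strata = c("all",
                                                 "by_smoking_category",
                                                 "by_case_status"),
                                      min_n = 30) {
  strata <- match.arg(strata, several.ok = TRUE)
  score <- align_grs(grs, pheno)
  base <- c("age", "sex", "bmi", "study_site", "pc1", "pc2", "pc3", "pc4")
  partialcorr_by_strata(score, pheno, "pack_years", strata,
                        cov_pooled = c(base, "case_status"),
                        cov_stratified = base, min_n = min_n)
}

#' Partial correlation of BMI with pack-years among smokers
#'
#' Adjusted for age, sex and study site, plus disease status in analyses
#' that pool cases and controls.
#'
#' @inheritParams grs_packyears_partialcorr
#' @return Data frame with one row per computed stratum.
#' @export
bmi_packyears_partialcorr <- function(pheno,
                                      strata = c("all",
                                                 "by_smoking_category",
                                                 "by_case_status"),
                                      min_n = 30) {
  strata <- match.arg(strata, several.ok = TRUE)
  base <- c("age", "sex", "study_site")
  partialcorr_by_strata(pheno$bmi, pheno, "pack_years", strata,
                        cov_pooled = c(base, "case_status"),
                        cov_stratified = base, min_n = min_n)
}
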