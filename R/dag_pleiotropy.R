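# Causal-network pleiotropy scan: enumerate the twelve DAGs over
# {G (SNP), B (BMI), P (smoking node)}, score each with the two-regression
# AIC
#
#   AIC(dag) = -2 logLik(model for B) - 2 logLik(model for P)
#              + 2 * number of edges among {G, B, P},
#
# take the minimum AIC within each of the four categories, and call a SNP
# pleiotropic when the category-4 (G->B and G->P both present) minimum beats
# the best of categories 1-3 by at least delta (default 2).

#' Enumerate the twelve causal DAGs over {G, B, P}
#'
#' G is exogenous (never an outcome). The DAGs fall into four categories by
#' which direct genetic edges are present: category 1 has none (ids 1-3),
#' category 2 has G->B only (ids 4-6), category 3 has G->P only (ids 7-9),
#' and category 4 — the pleiotropic models — has both (ids 10-12). Within a
#' category the three DAGs differ in the between-phenotype edge: none, B->P,
#' or P->B (so e.g. DAG 8 is G->P->B).
#'
#' @return List of 12 `dag_spec` objects, each with `dag_id`, `edges`
#'   (2-column matrix from/to), and `category`.
#' @export
enumerate_dags <- function() {
  e <- function(...) {
    pairs <- list(...)
    if (!length(pairs)) {
      return(matrix(character(0), ncol = 2,
                    dimnames = list(NULL, c("from", "to"))))
    }
    m <- do.call(rbind, pairs)
    dimnames(m) <- list(NULL, c("from", "to"))
    m
  }
  edge_sets <- list(
    e(),                                          # 1
    e(c("B", "P")),                               # 2
    e(c("P", "B")),                               # 3
    e(c("G", "B")),                               # 4
    e(c("G", "B"), c("B", "P")),                  # 5
    e(c("G", "B"), c("P", "B")),                  # 6
    e(c("G", "P")),                               # 7
    e(c("G", "P"), c("P", "B")),                  # 8
    e(c("G", "P"), c("B", "P")),                  # 9
    e(c("G", "B"), c("G", "P")),                  # 10
    e(c("G", "B"), c("G", "P"), c("B", "P")),     # 11
    e(c("G", "B"), c("G", "P"), c("P", "B"))      # 12
  )
  lapply(seq_along(edge_sets), function(i) {
    edges <- edge_sets[[i]]
    gb <- any(edges[, "from"] == "G" & edges[, "to"] == "B")
    gp <- any(edges[, "from"] == "G" & edges[, "to"] == "P")
    category <- if (!gb && !gp) 1L else if (gb && !gp) 2L else
      if (!gb && gp) 3L else 4L
    structure(list(dag_id = i, edges = edges, category = category),
              class = "dag_spec")
  })
}

#' @export
print.dag_spec <- function(x, ...) {
  lab <- if (nrow(x$edges)) {
    paste(paste0(x$edges[, "from"], "->", x$edges[, "to"]), collapse = ", ")
  } else "(no edges)"
  cat(sprintf("<DAG %d, category %d: %s>\n", x$dag_id, x$category, lab))
  invisible(x)
}

# internal: does dag contain the directed edge from -> to?
has_edge <- function(dag, from, to) {
  any(dag$edges[, "from"] == from & dag$edges[, "to"] == to)
}

# internal: structural parents of a node among {G, B, P}
parents_of <- function(dag, node) {
  unname(dag$edges[dag$edges[, "to"] == node, "from"])
}

#' Likelihood-equivalence classes of the twelve DAGs
#'
#' Under the all-continuous (linear-Gaussian) trio, DAGs 2 ({B->P}) and 3
#' ({P->B}) are likelihood-equivalent, as are DAGs 11 and 12 (both genetic
#' edges plus either phenotype-phenotype direction): the Gaussian chain-rule
#' factorization gives them identical maximized likelihoods and equal edge
#' counts. With a binary smoking node the logistic factorization is not
#' symmetric, so no equivalences are claimed.
#'
#' @param dags Output of [enumerate_dags()].
#' @param smoking_mode `"continuous_packyears"` or `"binary_status"`.
#' @return List of integer vectors partitioning 1..12.
#' @export
equivalence_classes <- function(dags = enumerate_dags(),
                                smoking_mode = "continuous_packyears") {
  ids <- vapply(dags, `[[`, integer(1), "dag_id")
  if (smoking_mode == "binary_status") {
    warning("binary smoking node: logistic factorization is asymmetric; ",
            "returning singleton classes")
    return(lapply(ids, identity))
  }
  classes <- list(c(2L, 3L), c(11L, 12L))
  singles <- setdiff(ids, unlist(classes))
  c(lapply(singles, identity), classes)[order(c(singles, 2L, 11L))]
}

#' Regression models implied by one DAG
#'
#' One model per phenotype node: the node regressed on the shared covariates
#' plus its structural parents among {G, B, P}. G is exogenous and never an
#' outcome.
#'
#' @param dag A `dag_spec`.
#' @param covariate_names Character vector naming the adjustment covariates.
#' @return List with `bmi_predictors` and `smoking_predictors`, each the
#'   covariate names followed by any of `"P"`/`"B"`/`"G"` parents.
#' @export
models_for_dag <- function(dag, covariate_names) {
  list(bmi_predictors = c(covariate_names, parents_of(dag, "B")),
       smoking_predictors = c(covariate_names, parents_of(dag, "P")))
}

# internal: assemble the covariate term list once per scan
covariate_terms_from_pheno <- function(pheno, covariate_names) {
  terms <- list()
  for (nm in covariate_names) {
    if (!nm %in% names(pheno)) {
      stop("covariate '", nm, "' not in phenotype table")
    }
    terms[[nm]] <- pheno[[nm]]
  }
  terms
}

#' AIC of one DAG for one SNP
#'
#' Fits the two node regressions implied by the DAG (Gaussian for BMI and
#' for continuous pack-years; Bernoulli for a binary smoking node) and
#' returns `-2 logLik(B model) - 2 logLik(P model) + 2 * edges`, with edges
#' counted only among {G, B, P} — covariate terms are common to all twelve
#' models and cancel from every AIC difference.
#'
#' @param dag A `dag_spec`.
#' @param snp_dosage Numeric dosage vector for the focal SNP.
#' @param bmi Numeric BMI vector.
#' @param smoking Numeric smoking-node vector (pack-years, or 0/1).
#' @param covariate_terms Named list of covariate vectors.
#' @param smoking_mode `"continuous_packyears"` or `"binary_status"`.
#' @return The AIC (single numeric).
#' @export
score_dag <- function(dag, snp_dosage, bmi, smoking, covariate_terms,
                      smoking_mode = "continuous_packyears") {
  fits <- fit_dag_models(dag, snp_dosage, bmi, smoking, covariate_terms,
                         smoking_mode, cache = new.env(parent = emptyenv()))
  -2 * fits$b$loglik - 2 * fits$p$loglik + 2 * nrow(dag$edges)
}

# internal: fit the two node models with memoisation across DAGs — only the
# parent set matters, so twelve DAGs need at most 4 + 4 distinct fits.
fit_dag_models <- function(dag, snp_dosage, bmi, smoking, covariate_terms,
                           smoking_mode, cache) {
  node_fit <- function(node) {
    parents <- sort(parents_of(dag, node))
    key <- paste0(node, ":", paste(parents, collapse = ""))
    if (!is.null(cache[[key]])) return(cache[[key]])
    extra <- list()
    for (p in parents) {
      extra[[p]] <- switch(p, G = snp_dosage, B = bmi, P = smoking)
    }
    terms <- c(covariate_terms, extra)
    y <- if (node == "B") bmi else smoking
    fit <- if (node == "P" && smoking_mode == "binary_status") {
      fit_logistic(y, terms)
    } else {
      fit_linear(y, terms)
    }
    cache[[key]] <- fit
    fit
  }
  list(b = node_fit("B"), p = node_fit("P"))
}

#' Classify one SNP across the twelve DAGs
#'
#' Scores all twelve DAGs, takes the minimum AIC per category, assigns the
#' argmin category (ties broken toward the lower category index), and
#' computes the pleiotropy margin: the best (smallest) of the category 1-3
#' minima minus the category-4 minimum. The SNP is called pleiotropic when
#' the margin is at least `delta`, i.e. the best pleiotropic model beats
#' every non-pleiotropic category by `delta` AIC units. The candidate flag
#' additionally requires nominal association (p < 0.05) between the SNP and
#' the smoking phenotype in a single-SNP regression with the association
#' adjustment set (by default the DAG covariates plus case status).
#'
#' @param snp_dosage Numeric dosage vector.
#' @param bmi,smoking Phenotype vectors (rows already restricted and
#'   complete-case).
#' @param covariate_terms Named list of covariates for the DAG regressions.
#' @param assoc_covariate_terms Covariates for the candidate association
#'   regression; defaults to `covariate_terms`.
#' @param smoking_mode `"continuous_packyears"` or `"binary_status"`.
#' @param delta AIC margin required for a pleiotropy call (default 2).
#' @return One-row data frame: aic_dag1..aic_dag12, min_aic_cat1..4,
#'   assigned_category, pleiotropy_margin, pleiotropy_call, assoc_beta,
#'   assoc_p, candidate.
#' @export
classify_snp <- function(snp_dosage, bmi, smoking, covariate_terms,
                         assoc_covariate_terms = covariate_terms,
                         smoking_mode = "continuous_packyears", delta = 2) {
  dags <- enumerate_dags()
  cache <- new.env(parent = emptyenv())
  aic <- vapply(dags, function(d) {
    fits <- fit_dag_models(d, snp_dosage, bmi, smoking, covariate_terms,
                           smoking_mode, cache)
    -2 * fits$b$loglik - 2 * fits$p$loglik + 2 * nrow(d$edges)
  }, numeric(1))
  cats <- vapply(dags, `[[`, integer(1), "category")
  min_cat <- vapply(1:4, function(c) min(aic[cats == c]), numeric(1))
  assigned <- which.min(min_cat)  # which.min takes the first = lowest index
  margin <- min(min_cat[1:3]) - min_cat[4]
  call <- margin >= delta
  assoc_fit <- if (smoking_mode == "binary_status") {
    fit_logistic(smoking, c(assoc_covariate_terms, list(G = snp_dosage)))
  } else {
    fit_linear(smoking, c(assoc_covariate_terms, list(G = snp_dosage)))
  }
  assoc_beta <- unname(assoc_fit$coefficients[["G"]])
  assoc_p <- unname(assoc_fit$pvalues[["G"]])
  out <- data.frame(t(aic))
  names(out) <- paste0("aic_dag", 1:12)
  out <- cbind(out, data.frame(t(min_cat)))
  names(out)[13:16] <- paste0("min_aic_cat", 1:4)
  out$assigned_category <- as.integer(assigned)
  out$pleiotropy_margin <- margin
  out$pleiotropy_call <- call
  out$assoc_beta <- assoc_beta
  out$assoc_p <- assoc_p
  out$candidate <- call && assoc_p < 0.05
  out
}

#' Scan a SNP panel for pleiotropy
#'
#' Runs [classify_snp()] for every SNP against one of the two trios:
#' `"bmi_packyears"` (continuous pack-years; rows restricted to ever-smokers
#' because pack-years is undefined for never-smokers) or
#' `"bmi_smoking_status"` (binary ever/never node, all rows). DAG
#' regressions adjust for age, sex, study site and the four genetic PCs;
#' the candidate association regression additionally adjusts for lung-cancer
#' case status. Per-SNP fitting failures are logged and the scan continues.
#'
#' @param dosages A [dosage_matrix()] (harmonized to risk alleles).
#' @param variants A [variant_table()] covering the dosage columns (used for
#'   genomic ordering of the output).
#' @param pheno A `pleio_pheno` data frame.
#' @param trio `"bmi_packyears"` or `"bmi_smoking_status"`.
#' @param delta AIC margin for the pleiotropy call (default 2).
#' @param covariate_names Adjustment set for the DAG regressions.
#' @param assoc_covariate_names Adjustment set for the candidate association
#'   regression.
#' @param smokers_only For the pack-years trio, restrict to ever-smokers
#'   (default TRUE).
#' @return Data frame of class `dag_score_table`, one row per scored SNP in
#'   genomic order, with the [classify_snp()] columns plus snp_id; attribute
#'   `category_counts` tabulates assigned categories, `failures` lists
#'   unclassifiable SNPs with reasons.
#' @export
run_pleiotropy_scan <- function(dosages, variants, pheno,
                                trio = c("bmi_packyears",
                                         "bmi_smoking_status"),
                                delta = 2,
                                covariate_names = c("age", "sex",
                                                    "study_site", "pc1",
                                                    "pc2", "pc3", "pc4"),
                                assoc_covariate_names = c(covariate_names,
                                                          "case_status"),
                                smokers_only = TRUE) {
  trio <- match.arg(trio)
  snp_ids <- intersect(variants$snp_id, colnames(dosages))
  ord <- order(variants$chromosome[match(snp_ids, variants$snp_id)],
               variants$position[match(snp_ids, variants$snp_id)])
  snp_ids <- snp_ids[ord]
  if (trio == "bmi_packyears") {
    keep <- pheno$smoking_category != "never" & !is.na(pheno$pack_years)
    if (!smokers_only) keep <- !is.na(pheno$pack_years)
    smoking_mode <- "continuous_packyears"
  } else {
    keep <- rep(TRUE, nrow(pheno))
    smoking_mode <- "binary_status"
  }
  ph <- pheno[keep, , drop = FALSE]
  dos <- unclass(dosages)[keep, , drop = FALSE]
  smoking <- if (trio == "bmi_packyears") ph$pack_years else
    as.numeric(ph$smoking_category != "never")
  cov_terms <- covariate_terms_from_pheno(ph, covariate_names)
  assoc_terms <- covariate_terms_from_pheno(ph, assoc_covariate_names)
  rows <- list()
  failures <- list()
  for (s in snp_ids) {
    res <- tryCatch(
      classify_snp(dos[, s], ph$bmi, smoking, cov_terms, assoc_terms,
                   smoking_mode, delta),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[s]] <- conditionMessage(res)
      message("SNP ", s, " unclassifiable: ", conditionMessage(res))
    } else {
      rows[[s]] <- cbind(data.frame(snp_id = s, stringsAsFactors = FALSE),
                         res)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
  else {
    empty <- classify_skeleton()
    empty
  }
  counts <- vapply(1:4, function(c)
    sum(out$assigned_category == c, na.rm = TRUE), integer(1))
  names(counts) <- paste0("category", 1:4)
  attr(out, "category_counts") <- counts
  attr(out, "failures") <- failures
  attr(out, "trio") <- trio
  attr(out, "n_used") <- nrow(ph)
  class(out) <- c("dag_score_table", "data.frame")
  out
}

# internal: zero-row scan result with the full schema
classify_skeleton <- function() {
  cols <- c("snp_id", paste0("aic_dag", 1:12), paste0("min_aic_cat", 1:4),
            "assigned_category", "pleiotropy_margin", "pleiotropy_call",
            "assoc_beta", "assoc_p", "candidate")
  out <- as.data.frame(stats::setNames(
    c(list(character(0)), replicate(16, numeric(0), simplify = FALSE),
      list(integer(0), numeric(0), logical(0), numeric(0), numeric(0),
           logical(0))),
    cols), stringsAsFactors = FALSE)
  out
}
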