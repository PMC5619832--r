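# Genetic-risk-score construction: p-value selection, greedy LD/distance
# pruning (standard clumping convention: best p-value first), and the
# weighted / unweighted score.

#' Select variants by association p-value
#'
#' Keeps variants with `pvalue` strictly below the threshold (a variant at
#' exactly the threshold is excluded).
#'
#' @param variants A [variant_table()].
#' @param threshold P-value threshold in (0, 1); default 1e-5. Use 5e-8 for
#'   a genome-wide-significant score.
#' @return The selected subset, original order preserved.
#' @export
select_by_pvalue <- function(variants, threshold = 1e-5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  variants[variants$pvalue < threshold, , drop = FALSE]
}

#' Greedy LD and distance pruning
#'
#' Variants are visited in ascending p-value order (ties by chromosome then
#' position) and accepted only if, against every previously kept variant,
#' the squared Pearson correlation of dosages is below `r2_max` AND the two
#' sit on different chromosomes or at least `min_distance_bp` apart. This is
#' the usual clumping rule: the most significant SNP in a correlated,
#' nearby cluster survives.
#'
#' @param variants A [variant_table()].
#' @param dosages A [dosage_matrix()] with a column per candidate; r^2 is
#'   computed in-sample from these dosages.
#' @param r2_max Squared-correlation ceiling (default 0.2).
#' @param min_distance_bp Minimum within-chromosome separation (default
#'   500000, i.e. 500 kb).
#' @return Kept variants in genomic order (chromosome, then position).
#' @export
prune_variants <- function(variants, dosages, r2_max = 0.2,
                           min_distance_bp = 500000) {
  missing_snp <- setdiff(variants$snp_id, colnames(dosages))
  if (length(missing_snp)) {
    stop("dosage column missing for: ", paste(missing_snp, collapse = ", "))
  }
  if (nrow(variants) == 0L) return(variants)
  ord <- order(variants$pvalue, variants$chromosome, variants$position)
  v <- variants[ord, , drop = FALSE]
  dos <- unclass(dosages)
  kept <- integer(0)
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (k in kept) {
      r <- stats::cor(dos[, v$snp_id[i]], dos[, v$snp_id[k]])
      r2 <- if (is.na(r)) 0 else r^2
      near <- v$chromosome[i] == v$chromosome[k] &&
        abs(v$position[i] - v$position[k]) < min_distance_bp
      if (r2 >= r2_max || near) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- v[kept, , drop = FALSE]
  out[order(out$chromosome, out$position), , drop = FALSE]
}

#' Compute the genetic risk score
#'
#' `score_i = sum_j w_j * dosage_ij` over the selected variants, with
#' `w_j = 1` (unweighted) or `w_j = beta_j` (weighted, the per-allele GWAS
#' effect). Dosages must already be harmonized so every beta is >= 0 and
#' dosages count risk alleles. Samples with any missing dosage among the
#' score SNPs are dropped and reported.
#'
#' @param dosages A [dosage_matrix()].
#' @param variants A [variant_table()] of the score SNPs (harmonized).
#' @param mode `"unweighted"` or `"weighted"`.
#' @return A list of class `grs_result`: `scores` (named numeric vector),
#'   `mode`, `n_snps_used`, `dropped_samples`.
#' @export
compute_grs <- function(dosages, variants,
                        mode = c("unweighted", "weighted")) {
  mode <- match.arg(mode)
  if (any(variants$beta < 0)) {
    stop("internal invariant violated: negative beta after harmonization")
  }
  missing_snp <- setdiff(variants$snp_id, colnames(dosages))
  if (length(missing_snp)) {
    stop("dosage column missing for: ", paste(missing_snp, collapse = ", "))
  }
  dos <- unclass(dosages)[, variants$snp_id, drop = FALSE]
  complete <- rowSums(is.na(dos)) == 0L
  dropped <- rownames(dos)[!complete]
  if (length(dropped)) {
    message(length(dropped), " sample(s) dropped from GRS for missing ",
            "dosages")
  }
  w <- if (mode == "unweighted") rep(1, nrow(variants)) else variants$beta
  scores <- as.numeric(dos[complete, , drop = FALSE] %*% w)
  names(scores) <- rownames(dos)[complete]
  structure(list(scores = scores, mode = mode,
                 n_snps_used = nrow(variants),
                 dropped_samples = dropped),
            class = "grs_result")
}

#' @export
print.grs_result <- function(x, ...) {
  cat(sprintf("<grs_result: %s, %d SNPs, %d samples scored>\n",
              x$mode, x$n_snps_used, length(x$scores)))
  invisible(x)
}

#' Build a GRS from summary statistics and dosages
#'
#' The full construction used for the BMI score: select variants below the
#' p-value threshold, prune by LD and distance, then sum risk-allele
#' dosages (weighted or unweighted).
#'
#' @inheritParams compute_grs
#' @inheritParams prune_variants
#' @param p_threshold Selection p-value threshold (default 1e-5).
#' @return A `grs_result` with an extra element `variants_used`.
#' @export
build_grs <- function(dosages, variants, mode = c("unweighted", "weighted"),
                      p_threshold = 1e-5, r2_max = 0.2,
                      min_distance_bp = 500000) {
  selected <- select_by_pvalue(variants, p_threshold)
  kept <- prune_variants(selected, dosages, r2_max, min_distance_bp)
  res <- compute_grs(dosages, kept, match.arg(mode))
  res$variants_used <- kept
  res
}
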