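# Synthetic cohort generator: Hardy-Weinberg genotypes with optional lag-1
# LD, epidemiological covariates, and trio phenotypes (BMI + a smoking node)
# generated under any of the twelve causal DAGs over {G, B, P}.
#
# Seed discipline: one master seed, independent named substreams per
# component (genotypes / covariates / phenotypes), so e.g. changing n_snps
# never perturbs the covariate draws.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort. Defaults are
#' chosen to resemble a lung-cancer case-control consortium cohort: BMI
#' around 26.5 kg/m^2 (SD 4.8), pack-years around 40 (SD 28), age 62 (SD 10),
#' roughly three quarters ever-smokers and half cases.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of SNPs.
#' @param maf_range Minor-allele-frequency range (low, high), in (0, 0.5].
#' @param ld_rho Lag-1 latent haplotype correlation in \[0, 1); 0 gives
#'   independent SNPs.
#' @param n_sites Number of study sites (>= 1).
#' @param dag_assignment Integer vector (length `n_snps`, recycled from
#'   length 1) of generating DAG ids in 1..12 per SNP. All assigned DAGs
#'   must agree on the between-phenotype edge (B->P, P->B, or neither);
#'   genetic edges are additive across SNPs.
#' @param beta_gb Direct SNP effect on BMI, kg/m^2 per risk allele.
#' @param beta_gp Direct SNP effect on the smoking node (pack-years per
#'   allele, or log-odds per allele in binary mode).
#' @param beta_bp Structural effect of BMI on the smoking node (per kg/m^2).
#' @param beta_pb Structural effect of the smoking node on BMI (kg/m^2 per
#'   pack-year, or per ever-smoking indicator in binary mode).
#' @param cov_effects_b,cov_effects_p Named numeric vectors of covariate
#'   effects on BMI and on the smoking node; recognized names are `age`
#'   (centered at 62) and `sex`.
#' @param mu_b,mu_p Intercepts: mean BMI and mean pack-years at the covariate
#'   center.
#' @param sd_b,sd_p Residual SDs of BMI and of continuous pack-years (> 0).
#' @param smoking_mode `"continuous_packyears"` (pack-years is the Gaussian
#'   smoking node) or `"binary_status"` (ever/never is a Bernoulli node with
#'   a logistic structural equation).
#' @param smoking_intercept Logit-scale intercept of the binary smoking
#'   node; the default gives roughly 75% ever-smokers.
#' @param p_never,p_ex_given_ever Smoking-category frequencies used in
#'   continuous mode to label never / ex / current smokers.
#' @param prevalence Case proportion for the case-control status covariate.
#' @param truncate_packyears Truncate continuous pack-years at 0 (default
#'   off: the unbounded Gaussian matches the linear-model likelihood used in
#'   DAG scoring).
#' @param seed Master seed (integer).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_snps = 1L,
                       maf_range = c(0.05, 0.5), ld_rho = 0,
                       n_sites = 3L, dag_assignment = 1L,
                       beta_gb = 0.15, beta_gp = 1.0,
                       beta_bp = 0.02, beta_pb = 0.02,
                       cov_effects_b = c(age = 0.02, sex = 0.5),
                       cov_effects_p = c(age = 0.3, sex = 5),
                       mu_b = 26.5, mu_p = 40,
                       sd_b = 4.8, sd_p = 28,
                       smoking_mode = c("continuous_packyears",
                                        "binary_status"),
                       smoking_intercept = 1.1,
                       p_never = 0.25, p_ex_given_ever = 0.5,
                       prevalence = 0.5,
                       truncate_packyears = FALSE,
                       seed = 1L) {
  smoking_mode <- match.arg(smoking_mode)
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be (low, high) within (0, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must lie in [0, 1)")
  if (sd_b <= 0 || sd_p <= 0) stop("noise SDs must be > 0")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  dag_assignment <- as.integer(rep_len(dag_assignment, n_snps))
  if (!all(dag_assignment %in% 1:12)) {
    stop("dag_assignment ids must be in 1..12")
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range), ld_rho = ld_rho,
    n_sites = as.integer(n_sites), dag_assignment = dag_assignment,
    beta_gb = beta_gb, beta_gp = beta_gp, beta_bp = beta_bp,
    beta_pb = beta_pb, cov_effects_b = cov_effects_b,
    cov_effects_p = cov_effects_p, mu_b = mu_b, mu_p = mu_p,
    sd_b = sd_b, sd_p = sd_p, smoking_mode = smoking_mode,
    smoking_intercept = smoking_intercept, p_never = p_never,
    p_ex_given_ever = p_ex_given_ever, prevalence = prevalence,
    truncate_packyears = truncate_packyears, seed = as.integer(seed)),
    class = "sim_config")
}

# internal: named substream seeds below 2^31, derived from the master seed
substream_seed <- function(seed, stream) {
  offset <- c(genotypes = 101L, covariates = 211L, phenotypes = 307L)[stream]
  (as.integer(seed) %% 2000000000L) + offset
}

#' Simulate Hardy-Weinberg genotype dosages
#'
#' Each SNP's MAF is drawn uniformly from `maf_range`; per individual, two
#' haplotypes carry the minor allele wherever a latent standard normal falls
#' below the MAF quantile. With `ld_rho > 0` the latent values follow a
#' lag-1 autoregression along the SNP index, producing local LD while
#' preserving per-SNP Hardy-Weinberg frequencies.
#'
#' @param config A [sim_config()].
#' @return A [dosage_matrix()] (`n_individuals` x `n_snps`), values 0/1/2,
#'   counting minor-allele copies; columns named `snp_1 ...`, rows
#'   `id_1 ...`. An attribute `maf` carries the drawn frequencies.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  rho <- config$ld_rho
  set.seed(substream_seed(config$seed, "genotypes"))
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- matrix(stats::rnorm(n * m), n, m)
    if (rho > 0 && m > 1L) {
      for (j in 2:m) z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    }
    dos <- dos + (z < rep(thr, each = n))
  }
  out <- dosage_matrix(dos,
                       sample_ids = paste0("id_", seq_len(n)),
                       snp_ids = paste0("snp_", seq_len(m)))
  attr(out, "maf") <- maf
  out
}

#' Simulate epidemiological covariates
#'
#' Age ~ Normal(62, 10) truncated to \[30, 90\]; sex ~ Bernoulli(0.5); study
#' site uniform over `n_sites`; four genetic principal components ~
#' Normal(0, 1); case status ~ Bernoulli(`prevalence`). Case-control
#' ascertainment is not modelled: case status is an independent covariate,
#' matching an analysis that adjusts for disease status rather than
#' modelling sampling.
#'
#' @param config A [sim_config()].
#' @return Data frame with sample_id, age, sex, study_site, pc1..pc4,
#'   case_status.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  set.seed(substream_seed(config$seed, "covariates"))
  # inverse-CDF truncated normal
  plo <- stats::pnorm(30, 62, 10)
  phi <- stats::pnorm(90, 62, 10)
  age <- stats::qnorm(stats::runif(n, plo, phi), 62, 10)
  data.frame(
    sample_id = paste0("id_", seq_len(n)),
    age = age,
    sex = stats::rbinom(n, 1L, 0.5),
    study_site = paste0("site", sample.int(config$n_sites, n,
                                           replace = TRUE)),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
    case_status = stats::rbinom(n, 1L, config$prevalence),
    stringsAsFactors = FALSE
  )
}

# internal: covariate linear predictor for one phenotype node
cov_lp <- function(covariates, effects) {
  lp <- numeric(nrow(covariates))
  if ("age" %in% names(effects)) lp <- lp + effects[["age"]] *
      (covariates$age - 62)
  if ("sex" %in% names(effects)) lp <- lp + effects[["sex"]] * covariates$sex
  lp
}

#' Simulate trio phenotypes under the assigned DAGs
#'
#' Generates BMI (`B`) and the smoking node (`P`) in the topological order
#' of the assigned causal structure: each node is its covariate effects plus
#' structural-parent effects plus Gaussian noise (continuous node) or a
#' Bernoulli draw on the logit scale (binary smoking node). Genetic edges
#' are additive over all SNPs whose assigned DAG carries that edge; the
#' between-phenotype edge must be shared by all assigned DAGs.
#'
#' In continuous mode the pack-years node is generated for every individual
#' as the structural variable; the observed `pack_years` column is masked to
#' NA for individuals labelled never-smokers (smoking-category labels are
#' drawn independently from `p_never` / `p_ex_given_ever`). In binary mode
#' the smoking node itself is the ever/never category and `pack_years` is a
#' descriptive draw for ever-smokers only.
#'
#' @param genotypes A [dosage_matrix()] from [simulate_genotypes()].
#' @param covariates Covariate data frame from [simulate_covariates()].
#' @param config The same [sim_config()].
#' @return A `pleio_pheno` data frame (covariates plus smoking_category,
#'   pack_years, bmi, bmi_category). Attribute `latent_packyears` carries
#'   the unmasked continuous smoking node.
#' @export
simulate_phenotypes <- function(genotypes, covariates, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  dags <- enumerate_dags()
  assigned <- dags[config$dag_assignment]
  bp_types <- vapply(assigned, function(d) {
    if (has_edge(d, "B", "P")) "bp" else if (has_edge(d, "P", "B")) "pb"
    else "none"
  }, character(1))
  if (length(unique(bp_types)) > 1L) {
    stop("all assigned DAGs must share the same B-P edge orientation")
  }
  bp <- bp_types[1L]
  G <- unclass(genotypes)
  gb_edge <- vapply(assigned, function(d) has_edge(d, "G", "B"), logical(1))
  gp_edge <- vapply(assigned, function(d) has_edge(d, "G", "P"), logical(1))
  gb <- if (any(gb_edge)) G[, gb_edge, drop = FALSE] %*%
    rep(config$beta_gb, sum(gb_edge)) else numeric(n)
  gp <- if (any(gp_edge)) G[, gp_edge, drop = FALSE] %*%
    rep(config$beta_gp, sum(gp_edge)) else numeric(n)
  lp_b <- config$mu_b + cov_lp(covariates, config$cov_effects_b) + gb
  set.seed(substream_seed(config$seed, "phenotypes"))
  if (config$smoking_mode == "continuous_packyears") {
    lp_p <- config$mu_p + cov_lp(covariates, config$cov_effects_p) + gp
    if (bp == "pb") {
      P <- as.numeric(lp_p) + stats::rnorm(n, 0, config$sd_p)
      B <- as.numeric(lp_b) + config$beta_pb * (P - config$mu_p) +
        stats::rnorm(n, 0, config$sd_b)
    } else if (bp == "bp") {
      B <- as.numeric(lp_b) + stats::rnorm(n, 0, config$sd_b)
      P <- as.numeric(lp_p) + config$beta_bp * (B - config$mu_b) +
        stats::rnorm(n, 0, config$sd_p)
    } else {
      B <- as.numeric(lp_b) + stats::rnorm(n, 0, config$sd_b)
      P <- as.numeric(lp_p) + stats::rnorm(n, 0, config$sd_p)
    }
    if (config$truncate_packyears) P <- pmax(P, 0)
    u <- stats::runif(n)
    cat3 <- ifelse(u < config$p_never, "never",
                   ifelse(u < config$p_never + (1 - config$p_never) *
                            config$p_ex_given_ever, "ex", "current"))
    pack_years <- ifelse(cat3 == "never", NA_real_, P)
    smoking_category <- cat3
  } else {
    # binary smoking node via a logistic structural equation
    lp_p <- config$smoking_intercept +
      cov_lp(covariates, config$cov_effects_p / 10) + gp
    if (bp == "bp") {
      B <- as.numeric(lp_b) + stats::rnorm(n, 0, config$sd_b)
      pr <- stats::plogis(as.numeric(lp_p) + config$beta_bp *
                            (B - config$mu_b))
      P <- stats::rbinom(n, 1L, pr)
    } else {
      pr <- stats::plogis(as.numeric(lp_p))
      P <- stats::rbinom(n, 1L, pr)
      B <- as.numeric(lp_b) +
        (if (bp == "pb") config$beta_pb * P else 0) +
        stats::rnorm(n, 0, config$sd_b)
    }
    smoking_category <- ifelse(P == 1L, "ever", "never")
    pack_years <- ifelse(P == 1L,
                         pmax(stats::rnorm(n, config$mu_p, config$sd_p), 0),
                         NA_real_)
  }
  out <- covariates
  out$smoking_category <- smoking_category
  out$pack_years <- pack_years
  out$bmi <- as.numeric(B)
  out$bmi_category <- derive_bmi_category(pmax(out$bmi, 1e-6))
  class(out) <- c("pleio_pheno", "data.frame")
  attr(out, "latent_packyears") <-
    if (config$smoking_mode == "continuous_packyears") as.numeric(P) else
      as.numeric(P)
  out
}

#' Simulate a full dataset
#'
#' Convenience wrapper: genotypes, covariates and phenotypes from one
#' [sim_config()], plus a matching variant summary table (positions spaced
#' 1 Mb apart on one chromosome, per-SNP beta equal to the generating BMI
#' effect for SNPs with a G->B edge and a small positive placeholder
#' otherwise, p-values set well below genome-wide selection thresholds) and
#' the per-SNP true DAG id.
#'
#' @param config A [sim_config()].
#' @return List with `dosages`, `pheno`, `variants`, `truth` (data frame
#'   snp_id, dag_id), and `config`.
#' @export
simulate_dataset <- function(config) {
  dos <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  pheno <- simulate_phenotypes(dos, cov, config)
  m <- config$n_snps
  dags <- enumerate_dags()
  gb_edge <- vapply(dags[config$dag_assignment],
                    function(d) has_edge(d, "G", "B"), logical(1))
  variants <- variant_table(
    snp_id = colnames(dos),
    chromosome = "1",
    position = seq_len(m) * 1000000L,
    effect_allele = "A", other_allele = "G",
    beta = ifelse(gb_edge, abs(config$beta_gb), 0.01),
    pvalue = rep(1e-8, m)
  )
  list(dosages = dos, pheno = pheno, variants = variants,
       truth = data.frame(snp_id = colnames(dos),
                          dag_id = config$dag_assignment,
                          stringsAsFactors = FALSE),
       config = config)
}
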