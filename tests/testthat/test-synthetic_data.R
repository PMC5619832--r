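# Synthetic cohort generator: HWE, determinism, stream separation, and the
# causal structure of the generated phenotypes.

test_that("genotypes follow Hardy-Weinberg frequencies", {
  cfg <- sim_config(n_individuals = 100000, n_snps = 1,
                    maf_range = c(0.5, 0.5), seed = 5)
  dos <- unclass(simulate_genotypes(cfg))
  freqs <- tabulate(dos[, 1] + 1L, 3) / nrow(dos)
  # binomial 3-SD envelopes around (0.25, 0.5, 0.25)
  for (k in 1:3) {
    p <- c(0.25, 0.5, 0.25)[k]
    expect_lt(abs(freqs[k] - p), 3 * sqrt(p * (1 - p) / 1e5))
  }
})

test_that("ld_rho = 0 gives independent SNPs; ld_rho > 0 correlates them", {
  cfg0 <- sim_config(n_individuals = 10000, n_snps = 50, ld_rho = 0,
                     seed = 8)
  dos0 <- unclass(simulate_genotypes(cfg0))
  r2 <- vapply(seq(1, 49, by = 2), function(j)
    cor(dos0[, j], dos0[, j + 1])^2, numeric(1))
  expect_lt(mean(r2), 0.01)

  cfg1 <- sim_config(n_individuals = 10000, n_snps = 50, ld_rho = 0.9,
                     seed = 8)
  dos1 <- unclass(simulate_genotypes(cfg1))
  r2_ld <- vapply(1:49, function(j) cor(dos1[, j], dos1[, j + 1])^2,
                  numeric(1))
  expect_gt(mean(r2_ld), 0.3)
  # marginal HWE is preserved under LD
  maf_hat <- colMeans(dos1) / 2
  maf <- attr(simulate_genotypes(cfg1), "maf")
  expect_lt(max(abs(maf_hat - maf)), 0.02)
})

test_that("the full dataset is a pure function of the config", {
  cfg <- sim_config(n_individuals = 500, n_snps = 5, dag_assignment = 10,
                    seed = 12)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(unclass(d1$dosages), unclass(d2$dosages))
  expect_identical(d1$pheno, d2$pheno)
})

test_that("covariate draws are isolated from the genotype stream", {
  c1 <- sim_config(n_individuals = 400, n_snps = 2, seed = 3)
  c2 <- sim_config(n_individuals = 400, n_snps = 40, seed = 3)
  expect_identical(simulate_covariates(c1), simulate_covariates(c2))
  # single site collapses to a constant column
  c3 <- sim_config(n_individuals = 100, n_sites = 1, seed = 3)
  expect_equal(length(unique(simulate_covariates(c3)$study_site)), 1L)
})

test_that("age follows the truncated normal it claims", {
  cfg <- sim_config(n_individuals = 10000, seed = 19)
  age <- simulate_covariates(cfg)$age
  expect_true(all(age >= 30 & age <= 90))
  # truncated-normal mean oracle: mu + sd * (phi(a) - phi(b)) / (Phi(b) - Phi(a))
  a <- (30 - 62) / 10; b <- (90 - 62) / 10
  mu_tr <- 62 + 10 * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  sd_emp <- sd(age)
  expect_lt(abs(mean(age) - mu_tr), 3 * sd_emp / sqrt(10000))
})

test_that("structural coefficients propagate along the DAG paths", {
  # DAG 1: no genetic effect — slope of BMI on G centred at zero
  slopes <- vapply(1:50, function(r) {
    d <- trio_sim(800, 1, seed = r)
    fit_linear(d$pheno$bmi, list(G = unclass(d$dosages)[, 1]))$coefficients[["G"]]
  }, numeric(1))
  expect_lt(abs(mean(slopes)), 3 * sd(slopes) / sqrt(50))

  # DAG 10: direct G->B effect recovered by adjusted regression
  d10 <- trio_sim(5000, 10, seed = 77, beta_gb = 2.4)
  ph <- d10$pheno
  f <- fit_linear(ph$bmi, c(list(G = unclass(d10$dosages)[, 1]),
                            cov_terms_of(ph)))
  expect_lt(abs(f$coefficients[["G"]] - 2.4),
            3 * f$standard_errors[["G"]])

  # DAG 8 (G -> P -> B): marginal BMI-on-G slope is the path product
  # beta_gp * beta_pb; conditioning on P removes it
  d8 <- trio_sim(8000, 8, seed = 78, beta_gp = 14, beta_pb = 0.05)
  ph8 <- d8$pheno
  g <- unclass(d8$dosages)[, 1]
  f_marg <- fit_linear(ph8$bmi, c(list(G = g), cov_terms_of(ph8)))
  expect_lt(abs(f_marg$coefficients[["G"]] - 14 * 0.05),
            3 * f_marg$standard_errors[["G"]])
  f_cond <- fit_linear(ph8$bmi, c(list(G = g, P = ph8$pack_years),
                                  cov_terms_of(ph8)))
  expect_lt(abs(f_cond$coefficients[["G"]]),
            3 * f_cond$standard_errors[["G"]])
})

test_that("every implied d-separation shows a near-zero partial correlation", {
  dags <- enumerate_dags()
  n <- 6000
  for (dag_id in c(1, 4, 5, 8, 10, 12)) {
    d <- trio_sim(n, dag_id, seed = 100 + dag_id,
                  beta_gb = 2.4, beta_gp = 14, beta_bp = 0.1,
                  beta_pb = 0.05)
    vars <- list(G = unclass(d$dosages)[, 1], B = d$pheno$bmi,
                 P = d$pheno$pack_years)
    base_cov <- cov_terms_of(d$pheno)
    for (ci in implied_cis(dags[[dag_id]])) {
      cond <- base_cov
      for (s in ci$S) cond[[s]] <- vars[[s]]
      res <- partial_correlation(vars[[ci$x]], vars[[ci$y]], cond)
      expect_lt(abs(res$estimate), 3 / sqrt(n),
                label = sprintf("DAG %d: %s _||_ %s | {%s}, r", dag_id,
                                ci$x, ci$y, paste(ci$S, collapse = ",")))
    }
  }
})

test_that("refitting the generating regressions recovers the coefficients", {
  # one representative per category with a phenotype-phenotype edge each way
  cases <- list(list(id = 5, par_b = "G", par_p = "B"),
                list(id = 6, par_b = c("G", "P"), par_p = character(0)),
                list(id = 8, par_b = "P", par_p = "G"),
                list(id = 11, par_b = "G", par_p = c("G", "B")))
  truth <- c(G_b = 2.4, P_b = 0.05, G_p = 14, B_p = 0.1)
  for (cs in cases) {
    d <- trio_sim(5000, cs$id, seed = 200 + cs$id, beta_gb = 2.4,
                  beta_gp = 14, beta_bp = 0.1, beta_pb = 0.05)
    vars <- list(G = unclass(d$dosages)[, 1], B = d$pheno$bmi,
                 P = d$pheno$pack_years)
    for (node in c("b", "p")) {
      pars <- cs[[paste0("par_", node)]]
      if (!length(pars)) next
      y <- if (node == "b") vars$B else vars$P
      f <- fit_linear(y, c(vars[pars], cov_terms_of(d$pheno)))
      for (p in pars) {
        expect_lt(abs(f$coefficients[[p]] -
                        truth[[paste0(p, "_", node)]]),
                  3 * f$standard_errors[[p]],
                  label = sprintf("DAG %d, %s <- %s", cs$id, node, p))
      }
    }
  }
})

test_that("binary smoking mode produces a logistic smoking node", {
  cfg <- sim_config(n_individuals = 4000, n_snps = 1, dag_assignment = 7,
                    beta_gp = 0.4, smoking_mode = "binary_status",
                    seed = 33)
  dos <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  ph <- simulate_phenotypes(dos, cov, cfg)
  expect_setequal(unique(ph$smoking_category), c("never", "ever"))
  expect_true(all(is.na(ph$pack_years[ph$smoking_category == "never"])))
  expect_true(all(!is.na(ph$pack_years[ph$smoking_category == "ever"])))
  y <- as.numeric(ph$smoking_category == "ever")
  f <- fit_logistic(y, list(G = unclass(dos)[, 1]))
  expect_lt(abs(f$coefficients[["G"]] - 0.4), 3 * f$standard_errors[["G"]])
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(100, maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(100, maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(100, ld_rho = 1), "ld_rho")
  expect_error(sim_config(100, sd_b = 0), "SDs")
  expect_error(sim_config(100, dag_assignment = 13), "1..12")
  # conflicting phenotype-phenotype edges across SNPs are refused
  cfg <- sim_config(400, n_snps = 2, dag_assignment = c(5, 6), seed = 1)
  dos <- simulate_genotypes(cfg)
  cov <- simulate_covariates(cfg)
  expect_error(simulate_phenotypes(dos, cov, cfg), "B-P edge")
})
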