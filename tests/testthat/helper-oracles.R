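# Independent oracles used across the suite. These stay deliberately
# brute-force / closed-form so they never share code with the implementation
# they check.

# d-separation on a 3-node DAG by exhaustive path enumeration: paths between
# x and y are the direct edge (never blocked) or the length-2 path through
# the third node m, blocked given S iff m is a non-collider in S, or a
# collider not in S (with 3 nodes a collider has no other descendants).
dsep <- function(dag, x, y, S) {
  edges <- dag$edges
  has <- function(a, b) any(edges[, "from"] == a & edges[, "to"] == b)
  if (has(x, y) || has(y, x)) return(FALSE)
  m <- setdiff(c("G", "B", "P"), c(x, y))
  xm <- has(x, m) || has(m, x)
  my <- has(m, y) || has(y, m)
  if (!(xm && my)) return(TRUE)          # no path at all
  collider <- has(x, m) && has(y, m)
  if (collider) !(m %in% S) else (m %in% S)
}

# every conditional independence among {G,B,P} implied by a 3-node DAG,
# as rows (x, y, conditioning set "" or the third node)
implied_cis <- function(dag) {
  out <- list()
  pairs <- list(c("G", "B"), c("G", "P"), c("B", "P"))
  for (pr in pairs) {
    third <- setdiff(c("G", "B", "P"), pr)
    for (S in list(character(0), third)) {
      if (dsep(dag, pr[1], pr[2], S)) {
        out[[length(out) + 1L]] <- list(x = pr[1], y = pr[2], S = S)
      }
    }
  }
  out
}

# closed-form first-order partial correlation
pcor1_oracle <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# normal-equations OLS
ols_oracle <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Gaussian ML log-likelihood from residual sum of squares
gaussian_loglik_oracle <- function(rss, n) {
  -(n / 2) * (log(2 * pi * rss / n) + 1)
}

# brute-force GRS
grs_oracle <- function(dos, weights) {
  vapply(seq_len(nrow(dos)), function(i) sum(dos[i, ] * weights),
         numeric(1))
}

# exhaustive pairwise check that all kept variants satisfy both pruning
# constraints and every rejected variant violates at least one against a
# kept variant with smaller (or equal, earlier in greedy order) p-value
check_pruning <- function(kept, all_variants, dos, r2_max, min_dist) {
  kid <- kept$snp_id
  for (i in seq_len(nrow(kept))) {
    for (j in seq_len(nrow(kept))) {
      if (i >= j) next
      r2 <- cor(dos[, kid[i]], dos[, kid[j]])^2
      same_chr <- kept$chromosome[i] == kept$chromosome[j]
      d <- abs(kept$position[i] - kept$position[j])
      if (r2 >= r2_max || (same_chr && d < min_dist)) return(FALSE)
    }
  }
  rejected <- all_variants[!all_variants$snp_id %in% kid, , drop = FALSE]
  for (i in seq_len(nrow(rejected))) {
    viol <- FALSE
    for (j in seq_len(nrow(kept))) {
      if (kept$pvalue[j] > rejected$pvalue[i]) next  # kept later in order
      r2 <- cor(dos[, rejected$snp_id[i]], dos[, kept$snp_id[j]])^2
      same_chr <- rejected$chromosome[i] == kept$chromosome[j]
      d <- abs(rejected$position[i] - kept$position[j])
      if (r2 >= r2_max || (same_chr && d < min_dist)) { viol <- TRUE; break }
    }
    if (!viol) return(FALSE)
  }
  TRUE
}

# standard small simulated trio used by several files: continuous mode,
# everyone a smoker so pack-years is observed on all rows
trio_sim <- function(n, dag_id, seed, beta_gb = 2.4, beta_gp = 14,
                     beta_bp = 0.02, beta_pb = 0.02, n_snps = 1) {
  cfg <- sim_config(n_individuals = n, n_snps = n_snps,
                    dag_assignment = dag_id, beta_gb = beta_gb,
                    beta_gp = beta_gp, beta_bp = beta_bp, beta_pb = beta_pb,
                    p_never = 0, n_sites = 2, seed = seed)
  simulate_dataset(cfg)
}

# covariate term list for the standard adjustment set
cov_terms_of <- function(ph, extra = character(0)) {
  nm <- c("age", "sex", "study_site", "pc1", "pc2", "pc3", "pc4", extra)
  out <- list()
  for (x in nm) out[[x]] <- ph[[x]]
  out
}

# tiny deterministic dosage fixture for pruning worked examples
pruning_fixture <- function() {
  n <- 200
  A <- rep(c(0, 1, 2, 1), n / 4)
  B <- A
  flip <- seq(1, n, by = 5)                 # weaken correlation to r2 ~ 0.5
  B[flip] <- 2 - B[flip]
  set.seed(99)
  C <- sample(A)                            # near-independent permutation
  dos <- dosage_matrix(cbind(rsA = A, rsB = B, rsC = C),
                       sample_ids = paste0("s", 1:n))
  v <- variant_table(c("rsA", "rsB", "rsC"), "1",
                     c(100000, 350000, 700000), c("A", "A", "A"),
                     c("G", "G", "G"), c(0.1, 0.1, 0.1),
                     c(1e-8, 1e-7, 1e-6))
  list(dosages = dos, variants = v)
}
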