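# Shared fixtures and independent oracles for the test suite.

# A minimal canonical summary-statistics table.
make_gwas <- function(snp_id, beta, se, pval, ea = "A", oa = "G",
                      eaf = 0.3, n = 7174, chrom = "1",
                      pos = seq(1e6, by = 5e7, length.out = length(snp_id))) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
             ea = ea, oa = oa, eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

# A harmonized instrument table drawn directly (bypassing file I/O):
# true ratio theta, per-variant exposure effects and noise.
make_harmonized <- function(j, theta = 0.2, seed = 1,
                            gamma = NULL, se_exp = 0.02, se_out = 0.02,
                            alpha = 0, eaf = NULL,
                            n_exp = 7174, n_out = 16043) {
  set.seed(seed)
  if (is.null(gamma)) gamma <- runif(j, 0.1, 0.3) * sample(c(-1, 1), j, TRUE)
  if (is.null(eaf)) eaf <- runif(j, 0.1, 0.5)
  se_exp <- rep_len(se_exp, j)
  se_out <- rep_len(se_out, j)
  # pleiotropy is directional on the exposure-increasing allele
  alpha <- rep_len(alpha, j) * sign(gamma)
  data.frame(
    snp_id = sprintf("rs%04d", seq_len(j)),
    chrom = "1", pos = as.integer(seq(1e6, by = 4e7, length.out = j)),
    ea = "A", oa = "G",
    beta_exp = rnorm(j, gamma, se_exp), se_exp = se_exp,
    pval_exp = 1e-10, eaf_exp = eaf, n_exp = n_exp,
    beta_out = rnorm(j, theta * gamma + alpha, se_out), se_out = se_out,
    pval_out = 0.5, eaf_out = eaf, n_out = n_out,
    flipped = FALSE, palindromic = FALSE,
    stringsAsFactors = FALSE
  )
}

# Quadratic-time brute-force Benjamini-Hochberg: adjusted p for rank i is
# min over j >= i of min(1, m * p_(j) / j), mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, min(1, m * sorted[j] / j))
    adj[i] <- min(vals)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Textbook DerSimonian-Laird oracle, written independently of dl_meta().
dl_oracle <- function(b, s) {
  w <- s^-2
  mu_fe <- sum(w * b) / sum(w)
  Q <- sum(w * (b - mu_fe)^2)
  k <- length(b)
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / denom)
  wr <- 1 / (s^2 + tau2)
  list(beta = sum(wr * b) / sum(wr), se = sqrt(1 / sum(wr)), tau2 = tau2)
}

# Fixed-effect inverse-variance meta-analysis of the Wald ratios:
# the independent oracle for the IVW estimator.
ivw_meta_oracle <- function(tab) {
  r <- tab$beta_out / tab$beta_exp
  s <- tab$se_out / abs(tab$beta_exp)
  w <- 1 / s^2
  list(beta = sum(w * r) / sum(w), se = sqrt(1 / sum(w)))
}

# Simulate one study replicate and return the harmonized discovery table.
sim_harmonized <- function(truth) {
  sim <- simulate_two_sample(truth)
  harmonize(sim$discovery$exposure, sim$discovery$outcome)
}

# A multi-lipid study with planted causal exposures: each lipid gets its
# own instruments; outcome tables stack all lipids' variants (disjoint
# snp_id sets) so one shared outcome GWAS serves every exposure.
# Instrument effects span a wide range (MR-Egger's slope is identified
# by the spread of the exposure effects) and the causal effect is small
# enough that true signal rarely trips the outcome-association filter.
make_study <- function(n_lipids = 8, causal = c(1, 4, 6), theta = 0.1,
                       j_snps = 10, seed = 1000) {
  exposures <- list()
  outcome_disc <- NULL
  outcome_repl <- NULL
  for (i in seq_len(n_lipids)) {
    th <- if (i %in% causal) theta else 0
    truth <- simulation_truth(theta = th, j_snps = j_snps,
                              seed = seed + i,
                              gamma_range = c(0.15, 0.5),
                              maf_range = c(0.2, 0.5))
    sim <- simulate_two_sample(truth)
    id <- sprintf("lipid%02d", i)
    relabel <- function(tab) {
      tab$snp_id <- sprintf("%s_%s", id, tab$snp_id)
      tab
    }
    exposures[[id]] <- list(discovery = relabel(sim$discovery$exposure),
                            replication = relabel(sim$replication$exposure))
    outcome_disc <- rbind(outcome_disc, relabel(sim$discovery$outcome))
    outcome_repl <- rbind(outcome_repl, relabel(sim$replication$outcome))
  }
  list(exposures = exposures, outcome_disc = outcome_disc,
       outcome_repl = outcome_repl, causal = sprintf("lipid%02d", causal))
}
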