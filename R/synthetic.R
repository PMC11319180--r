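#' Effective sample size of a case-control GWAS
#'
#' `4 / (1/cases + 1/controls)` — the equivalent balanced sample size
#' governing the sampling variance of log-odds-ratio effect estimates.
#'
#' @param cases,controls Case and control counts.
#' @return Effective sample size.
#' @export
effective_n <- function(cases, controls) {
  4 / (1 / cases + 1 / controls)
}

#' Ground truth for a two-cohort, two-sample simulation
#'
#' Fixes every quantity the generator needs: the true causal effect,
#' per-variant instrument effects, allele frequencies, horizontal
#' pleiotropy, cohort sample sizes and the RNG seed. The defaults mirror
#' a lipid-species exposure GWAS of ~7,000 individuals against
#' hemorrhagic-stroke outcome GWAS: `n_exp = 7174` per cohort and
#' outcome effective sample sizes from 4,056/371,717 (discovery) and
#' 1,935/471,578 (replication) case/control designs. Instrument effects
#' are drawn with magnitude uniform on \[0.12, 0.30\] (SD units, sized
#' to reach genome-wide significance at the exposure sample size) and
#' random sign; minor-allele frequencies uniform on \[0.05, 0.5\].
#'
#' @param theta True causal effect (log-OR per SD of exposure).
#' @param j_snps Number of true instruments.
#' @param seed Master integer seed (required; every draw derives from
#'   it).
#' @param gamma Optional vector of true per-variant exposure effects
#'   (length `j_snps`); drawn if `NULL`.
#' @param maf Optional vector of minor-allele frequencies; drawn if
#'   `NULL`.
#' @param gamma_range Magnitude range for drawn instrument effects.
#' @param maf_range Range for drawn minor-allele frequencies.
#' @param pleiotropy `"none"`, `"balanced"` (mean-zero) or
#'   `"directional"` (mean `alpha_mu`).
#' @param alpha_mu,alpha_sd Mean and SD of per-variant pleiotropic
#'   effects on the outcome (used when `pleiotropy != "none"`).
#' @param n_exp,n_out Length-2 vectors: exposure and outcome (effective)
#'   sample sizes for the discovery and replication cohorts.
#' @param n_null_snps Non-associated background variants per table.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(theta = 0, j_snps = 30, seed,
                             gamma = NULL, maf = NULL,
                             gamma_range = c(0.12, 0.30),
                             maf_range = c(0.05, 0.5),
                             pleiotropy = c("none", "balanced",
                                            "directional"),
                             alpha_mu = 0.05, alpha_sd = 0.02,
                             n_exp = c(7174, 7174),
                             n_out = c(effective_n(4056, 371717),
                                       effective_n(1935, 471578)),
                             n_null_snps = 0) {
  pleiotropy <- match.arg(pleiotropy)
  stopifnot(all(n_exp > 0), all(n_out > 0), j_snps >= 1)
  truth <- with_preserved_seed(seed, {
    if (is.null(maf)) maf <- runif(j_snps, maf_range[1], maf_range[2])
    if (is.null(gamma))
      gamma <- sample(c(-1, 1), j_snps, replace = TRUE) *
        runif(j_snps, gamma_range[1], gamma_range[2])
    alpha <- switch(pleiotropy,
                    none = rep(0, j_snps),
                    balanced = rnorm(j_snps, 0, alpha_sd),
                    directional = rnorm(j_snps, alpha_mu, alpha_sd))
    # one derived sub-seed per output table (4 tables: 2 roles x 2 cohorts)
    table_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
    list(theta = theta, j_snps = j_snps, gamma = gamma, maf = maf,
         alpha = alpha, pleiotropy = pleiotropy,
         n_exp = n_exp, n_out = n_out, n_null_snps = n_null_snps,
         seed = seed, table_seeds = table_seeds)
  })
  class(truth) <- "simulation_truth"
  truth
}

# Build one simulated association table. True effects `mu` per variant;
# sampling se from the allele-frequency/sample-size closed form.
.sim_table <- function(mu, maf, n, ids, chrom, pos, ea, oa, seed) {
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  beta <- with_preserved_seed(seed, rnorm(length(mu), mu, se))
  pval <- 2 * pnorm(-abs(beta / se))
  pval <- pmax(pval, .Machine$double.xmin)  # keep within (0, 1]
  data.frame(snp_id = ids, chrom = chrom, pos = pos, ea = ea, oa = oa,
             eaf = maf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

#' Simulate two-cohort, two-sample GWAS summary statistics
#'
#' Generates four canonical summary-statistics tables (exposure and
#' outcome, for a discovery and a replication cohort) from a
#' [simulation_truth()]. Per variant `j` the exposure effect is drawn
#' from `normal(gamma_j, se_exp_j)` with
#' `se = 1/sqrt(2 n maf (1 - maf))`; the outcome effect from
#' `normal(theta * gamma_j + alpha_j, se_out_j)` with independent noise
#' (two-sample independence). Background variants have `gamma = 0`.
#' Variant identities, effects and frequencies are shared across
#' cohorts; sampling noise is cohort-specific. Variants are placed on
#' alternating chromosomes 20 Mb apart so they survive distance-only
#' clumping, with non-palindromic allele pairs.
#'
#' @param truth A `simulation_truth`.
#' @return A list with `discovery` and `replication` (each a list of
#'   `exposure` and `outcome` tables) and `truth`.
#' @export
simulate_two_sample <- function(truth) {
  stopifnot(inherits(truth, "simulation_truth"))
  j_tot <- truth$j_snps + truth$n_null_snps
  ids <- sprintf("rs%07d", seq_len(j_tot))
  chrom <- as.character(rep_len(1:22, j_tot))
  pos <- 1000000L + 20000000L * (seq_len(j_tot) - 1L) %/% 22L
  ea <- rep_len(c("A", "C"), j_tot)
  oa <- rep_len(c("G", "T"), j_tot)
  maf <- c(truth$maf,
           if (truth$n_null_snps)
             rep_len(truth$maf, truth$n_null_snps) else numeric(0))
  gamma <- c(truth$gamma, rep(0, truth$n_null_snps))
  alpha <- c(truth$alpha, rep(0, truth$n_null_snps))
  # pleiotropic shifts are expressed on the exposure-increasing allele
  # (the orientation MR-Egger uses), so "directional" means directional
  # after orientation regardless of each variant's reported sign
  mu_out <- truth$theta * gamma + sign(gamma) * alpha

  build <- function(cohort_idx, role) {
    k <- (cohort_idx - 1L) * 2L + if (role == "exposure") 1L else 2L
    if (role == "exposure") {
      .sim_table(gamma, maf, truth$n_exp[cohort_idx], ids, chrom, pos,
                 ea, oa, truth$table_seeds[k])
    } else {
      .sim_table(mu_out, maf, truth$n_out[cohort_idx], ids, chrom, pos,
                 ea, oa, truth$table_seeds[k])
    }
  }
  list(discovery = list(exposure = build(1L, "exposure"),
                        outcome = build(1L, "outcome")),
       replication = list(exposure = build(2L, "exposure"),
                          outcome = build(2L, "outcome")),
       truth = truth)
}

#' Write a simulation to disk in the canonical TSV dialect
#'
#' Writes the four summary-statistics tables plus a YAML sidecar
#' recording the ground truth.
#'
#' @param sim Result of [simulate_two_sample()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (cohort in c("discovery", "replication")) {
    for (role in c("exposure", "outcome")) {
      p <- file.path(dir, paste0(cohort, "_", role, ".tsv"))
      write_summary_stats(sim[[cohort]][[role]], p)
      paths <- c(paths, p)
    }
  }
  truth_path <- file.path(dir, "truth.yaml")
  tr <- sim$truth
  yaml::write_yaml(list(theta = tr$theta, j_snps = tr$j_snps,
                        gamma = as.numeric(tr$gamma),
                        maf = as.numeric(tr$maf),
                        alpha = as.numeric(tr$alpha),
                        pleiotropy = tr$pleiotropy,
                        n_exp = as.numeric(tr$n_exp),
                        n_out = as.numeric(tr$n_out),
                        n_null_snps = tr$n_null_snps, seed = tr$seed),
                   truth_path)
  invisible(c(paths, truth_path))
}

#' Plant an outlier variant in a simulated outcome table
#'
#' Displaces the chosen variant's outcome effect by
#' `displacement_in_se` standard errors — a ground-truth pleiotropic
#' outlier for exercising MR-PRESSO and leave-one-out diagnostics. The
#' planted truth is recorded in the `"planted"` attribute and, when
#' `sidecar` is given, in a YAML sidecar file.
#'
#' @param sim Result of [simulate_two_sample()].
#' @param snp_index Row index of the variant to displace.
#' @param displacement_in_se Shift in units of the variant's outcome
#'   standard error.
#' @param cohort `"discovery"` (default) or `"replication"`.
#' @param sidecar Optional path for a YAML record of the planted truth.
#' @return The modified simulation list.
#' @export
plant_outlier <- function(sim, snp_index, displacement_in_se,
                          cohort = "discovery", sidecar = NULL) {
  tab <- sim[[cohort]]$outcome
  if (snp_index < 1L || snp_index > nrow(tab))
    stop("invalid snp_index: ", snp_index)
  shift <- displacement_in_se * tab$se[snp_index]
  tab$beta[snp_index] <- tab$beta[snp_index] + shift
  tab$pval[snp_index] <-
    2 * pnorm(-abs(tab$beta[snp_index] / tab$se[snp_index]))
  sim[[cohort]]$outcome <- tab
  planted <- list(snp_id = tab$snp_id[snp_index], snp_index = snp_index,
                  displacement_in_se = displacement_in_se,
                  cohort = cohort)
  attr(sim, "planted") <- planted
  if (!is.null(sidecar)) yaml::write_yaml(planted, sidecar)
  sim
}
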