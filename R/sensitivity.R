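#' Cochran's Q heterogeneity test
#'
#' Q is the weighted sum of squared deviations of the per-variant Wald
#' ratios from the fixed-effect IVW estimate, with weights `1/se^2`;
#' under homogeneity Q follows a chi-square distribution with J - 1
#' degrees of freedom.
#'
#' @param set An `instrument_set` or harmonized table (>= 2 instruments).
#' @return A list with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(set) {
  tab <- .set_table(set)
  if (nrow(tab) < 2L) stop("Cochran's Q requires >= 2 instruments")
  r <- .ratios(tab)
  beta <- sum(r$weight * r$ratio) / sum(r$weight)
  q <- sum(r$weight * (r$ratio - beta)^2)
  df <- nrow(tab) - 1L
  list(q_stat = q, q_df = df, q_p = pchisq(q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept row of the MR-Egger fit; an intercept
#' distinguishable from zero (t test, J - 2 df) indicates average
#' directional pleiotropy across the instruments.
#'
#' @param set An `instrument_set` or harmonized table (>= 3 instruments).
#' @return A list with `intercept`, `intercept_se`, `intercept_p`.
#' @export
egger_intercept_test <- function(set) {
  fit <- mr_egger(set)
  list(intercept = fit$egger_intercept,
       intercept_se = fit$egger_intercept_se,
       intercept_p = fit$egger_intercept_p)
}

# Leave-one-out IVW slopes of beta_out on beta_exp through the origin
# (equivalently IVW over Wald ratios), vectorised: x, y, w are J-vectors.
.loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal pleiotropy by comparing the observed residual sum
#' of squares (each variant's outcome effect against the leave-one-out
#' IVW prediction, weights `1/se_out^2`) with its distribution under a
#' no-pleiotropy parametric null: in each of `n_sim` seeded simulations
#' the exposure and outcome effects are redrawn from
#' `normal(expected, se)` and the RSS recomputed. The global p is the
#' fraction of simulated RSS at or above the observed one. Per-variant
#' outlier p-values compare each variant's observed residual
#' contribution with its simulated distribution, Bonferroni-adjusted
#' against `outlier_alpha`. When outliers are found, the distortion test
#' compares the change in the IVW estimate after removing them with the
#' changes after removing random variant subsets of the same size.
#'
#' With fewer than four instruments the test is not identifiable and
#' every field is returned as `NA` (not an error).
#'
#' @param set An `instrument_set` or harmonized table.
#' @param n_sim Number of null simulations (default 1000).
#' @param seed Integer seed (required).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @return A list with `presso_rss`, `presso_global_p`,
#'   `presso_outliers` (a `data.frame` with `snp_id`, `p`, `p_adj`,
#'   `outlier`), and `presso_distortion_p`.
#' @export
mr_presso <- function(set, n_sim = 1000, seed, outlier_alpha = 0.05) {
  tab <- .set_table(set)
  j <- nrow(tab)
  if (j < 4L) {
    return(list(presso_rss = NA_real_, presso_global_p = NA_real_,
                presso_outliers = NULL, presso_distortion_p = NA_real_))
  }
  x <- tab$beta_exp
  y <- tab$beta_out
  w <- 1 / tab$se_out^2
  b_loo <- .loo_slopes(x, y, w)
  contrib_obs <- w * (y - b_loo * x)^2
  rss_obs <- sum(contrib_obs)

  with_preserved_seed(seed, {
    # simulate under the no-pleiotropy model: expected outcome effect of
    # variant j is its LOO slope times its exposure effect
    xs <- matrix(rnorm(n_sim * j, mean = rep(x, each = n_sim),
                       sd = rep(tab$se_exp, each = n_sim)), n_sim, j)
    ys <- matrix(rnorm(n_sim * j, mean = rep(b_loo * x, each = n_sim),
                       sd = rep(tab$se_out, each = n_sim)), n_sim, j)
    wm <- matrix(rep(w, each = n_sim), n_sim, j)
    sxy <- rowSums(wm * xs * ys)
    sxx <- rowSums(wm * xs^2)
    b_loo_sim <- (sxy - wm * xs * ys) / (sxx - wm * xs^2)
    contrib_sim <- wm * (ys - b_loo_sim * xs)^2
    rss_sim <- rowSums(contrib_sim)
    global_p <- mean(rss_sim >= rss_obs)

    p_snp <- colMeans(contrib_sim >=
                        matrix(rep(contrib_obs, each = n_sim), n_sim, j))
    p_adj <- pmin(1, p_snp * j)
    outliers <- data.frame(snp_id = tab$snp_id, p = p_snp, p_adj = p_adj,
                           outlier = p_adj < outlier_alpha,
                           stringsAsFactors = FALSE)

    distortion_p <- NA_real_
    n_out <- sum(outliers$outlier)
    if (n_out > 0L && n_out < j - 1L) {
      full <- sum(w * x * y) / sum(w * x^2)
      keep <- !outliers$outlier
      corrected <- sum((w * x * y)[keep]) / sum((w * x^2)[keep])
      d_obs <- abs(corrected - full)
      d_null <- vapply(seq_len(n_sim), function(s) {
        drop_idx <- sample.int(j, n_out)
        sub <- setdiff(seq_len(j), drop_idx)
        abs(sum((w * x * y)[sub]) / sum((w * x^2)[sub]) - full)
      }, numeric(1))
      distortion_p <- mean(d_null >= d_obs)
    }

    list(presso_rss = rss_obs, presso_global_p = global_p,
         presso_outliers = outliers, presso_distortion_p = distortion_p)
  })
}

#' Steiger directionality test
#'
#' Compares the exposure variance explained by the instrument set
#' (summed per-variant R-squared) with the outcome variance explained by
#' the same variants (same formula on the outcome effects, on the
#' log-odds scale for binary outcomes). `direction` is `TRUE` when the
#' instruments explain more variance in the exposure — the causal
#' direction assumed by the design. The p-value is a two-sided z test
#' comparing the implied correlations `sqrt(R2)` via Fisher's z
#' transform given the two sample sizes.
#'
#' @param set An `instrument_set` or harmonized table (>= 2 instruments)
#'   with `eaf_exp` (and ideally `eaf_out`) available.
#' @param n_exp,n_out Sample sizes; default to the table's `n_exp` /
#'   `n_out` columns.
#' @return A list with `steiger_p`, `steiger_direction`, `r2_exp`,
#'   `r2_out`.
#' @export
steiger_test <- function(set, n_exp = NULL, n_out = NULL) {
  tab <- .set_table(set)
  if (is.null(n_exp)) n_exp <- tab$n_exp[1L]
  if (is.null(n_out)) n_out <- tab$n_out[1L]
  if (is.na(n_exp) || is.na(n_out))
    stop("steiger_test requires exposure and outcome sample sizes")
  eaf_out <- if (!is.null(tab$eaf_out) && !any(is.na(tab$eaf_out)))
    tab$eaf_out else tab$eaf_exp
  r2_exp <- sum(strength_stats(tab$beta_exp, tab$se_exp, tab$eaf_exp,
                               n_exp, k = 1L)$r2)
  r2_out <- sum(strength_stats(tab$beta_out, tab$se_out, eaf_out,
                               n_out, k = 1L)$r2)
  z1 <- atanh(sqrt(min(r2_exp, 0.999999)))
  z2 <- atanh(sqrt(min(r2_out, 0.999999)))
  z <- (z1 - z2) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(steiger_p = 2 * pnorm(-abs(z)),
       steiger_direction = r2_exp > r2_out,
       r2_exp = r2_exp, r2_out = r2_out)
}

#' Leave-one-out stability analysis
#'
#' Re-runs the IVW estimate J times, omitting each variant in turn. The
#' set is flagged stable when every re-run keeps the sign of the
#' full-set estimate and no single omission moves the estimate outside
#' the full-set 95% confidence interval. The containment check uses the
#' fixed-effect interval: a heterogeneity-inflated
#' (multiplicative-random-effects) interval widens by exactly the factor
#' an outlier contributes to Q, so it can never flag the omission of a
#' single outlier and would make the rule vacuous.
#'
#' @param set An `instrument_set` or harmonized table (>= 3 instruments).
#' @param variant IVW variant for the re-runs and the reference
#'   interval: `"FE"` (default) or `"MRE"`.
#' @return A list with `loo` (a `data.frame`: `snp_id`, `beta`, `se`,
#'   `pvalue`) and `stable`.
#' @export
leave_one_out <- function(set, variant = c("FE", "MRE")) {
  variant <- match.arg(variant)
  set <- as_instrument_set(set)
  tab <- set$instruments
  j <- nrow(tab)
  if (j < 3L) stop("leave-one-out requires >= 3 instruments")
  full <- mr_ivw(set, variant = variant)
  rows <- lapply(seq_len(j), function(i) {
    sub <- as_instrument_set(tab[-i, , drop = FALSE],
                             set$exposure_id, set$outcome_id)
    est <- mr_ivw(sub, variant = variant)
    data.frame(snp_id = tab$snp_id[i], beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  ci_low <- full$beta - .z95 * full$se
  ci_high <- full$beta + .z95 * full$se
  stable <- all(sign(loo$beta) == sign(full$beta)) &&
    all(loo$beta >= ci_low & loo$beta <= ci_high)
  list(loo = loo, stable = stable, full_beta = full$beta,
       full_ci = c(ci_low, ci_high))
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Assembles Cochran's Q, the MR-Egger intercept test (>= 3
#' instruments), MR-PRESSO (>= 4 instruments; `NA` fields below that),
#' the Steiger directionality test, and leave-one-out stability into a
#' single report.
#'
#' @param set An eligible `instrument_set`.
#' @param n_sim MR-PRESSO null simulations.
#' @param seed Integer seed for MR-PRESSO (required).
#' @param outlier_alpha MR-PRESSO outlier level.
#' @return An object of class `sensitivity_report` (a named list).
#' @export
sensitivity_report <- function(set, n_sim = 1000, seed,
                               outlier_alpha = 0.05) {
  set <- as_instrument_set(set)
  if (!set$eligible) stop("ineligible instrument set")
  j <- nrow(set$instruments)
  q <- cochran_q(set)
  egger <- if (j >= 3L) egger_intercept_test(set) else
    list(intercept = NA_real_, intercept_se = NA_real_,
         intercept_p = NA_real_)
  presso <- mr_presso(set, n_sim = n_sim, seed = seed,
                      outlier_alpha = outlier_alpha)
  steiger <- steiger_test(set)
  loo <- if (j >= 3L) leave_one_out(set) else list(loo = NULL, stable = NA)
  structure(c(list(exposure_id = set$exposure_id,
                   outcome_id = set$outcome_id, n_snp = j),
              q, egger, presso, steiger, loo),
            class = "sensitivity_report")
}

#' One-row summary of a sensitivity report
#'
#' Mirrors the published sensitivity-table layout (`Q`, `Q_p`, `Int`,
#' `Int_p`, `RSS`, `PRESSO_p`, `Steiger_p`, `D`); the direction flag is
#' rendered `"T"`/`"F"` and unavailable cells are `NA`.
#'
#' @param report A `sensitivity_report`.
#' @return A one-row `data.frame`.
#' @export
sensitivity_row <- function(report) {
  data.frame(exposure = report$exposure_id, outcome = report$outcome_id,
             nsnp = report$n_snp, Q = report$q_stat, Q_p = report$q_p,
             Int = report$intercept, Int_p = report$intercept_p,
             RSS = report$presso_rss, PRESSO_p = report$presso_global_p,
             Steiger_p = report$steiger_p,
             D = ifelse(report$steiger_direction, "T", "F"),
             loo_stable = report$stable,
             stringsAsFactors = FALSE)
}
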