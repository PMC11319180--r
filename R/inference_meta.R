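#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up BH adjusted p-values, capped at 1, returned in the
#' input order. Inputs must lie in (0, 1].
#'
#' @param pvalues Numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Candidate decision rule for one exposure-outcome pair
#'
#' Operationalises the study's candidate-selection rule: an exposure is
#' a candidate when its headline IVW estimate is nominally significant,
#' all available estimators agree in effect direction, no heterogeneity
#' (Cochran's Q p > alpha), no directional pleiotropy (Egger intercept
#' p > alpha and MR-PRESSO global p > alpha, the latter vacuously
#' satisfied when PRESSO is unavailable), the Steiger test supports the
#' exposure-to-outcome direction, and the leave-one-out analysis is
#' stable. FDR-level significance (`fdr_sig`) is recorded alongside but
#' does not gate candidacy.
#'
#' @param estimates Per-method estimate table from [mr_estimate_all()].
#' @param sens A `sensitivity_report` for the same pair.
#' @param fdr_adjusted_p BH-adjusted headline IVW p-value.
#' @param ivw_method Which IVW row drives `ivw_sig` (default the
#'   headline rule: MRE under significant heterogeneity, FE otherwise).
#' @param alpha Significance level (default 0.05).
#' @return A one-row `data.frame` of class `candidate_decision` with all
#'   component booleans and the final `candidate` flag.
#' @export
candidate_filter <- function(estimates, sens, fdr_adjusted_p,
                             ivw_method = NULL, alpha = 0.05) {
  if (is.null(ivw_method))
    ivw_method <- if (!is.na(sens$q_p) && sens$q_p < alpha) "IVW_MRE"
      else "IVW_FE"
  ivw <- estimates[estimates$method == ivw_method, , drop = FALSE]
  if (nrow(ivw) != 1L) stop("IVW estimate not found in `estimates`")
  dir_methods <- estimates$method %in% c("IVW_FE", "IVW_MRE", "EGGER",
                                         "WMEDIAN", "WMODE")
  signs <- sign(estimates$beta[dir_methods])
  direction_consistent <- length(unique(signs[signs != 0])) <= 1L

  ivw_sig <- ivw$pvalue < alpha
  q_pass <- is.na(sens$q_p) || sens$q_p > alpha
  intercept_pass <- is.na(sens$intercept_p) || sens$intercept_p > alpha
  presso_pass <- is.na(sens$presso_global_p) ||
    sens$presso_global_p > alpha
  steiger_pass <- isTRUE(sens$steiger_direction)
  loo_pass <- is.na(sens$stable) || isTRUE(sens$stable)

  out <- data.frame(
    exposure = sens$exposure_id, outcome = sens$outcome_id,
    ivw_method = ivw_method, ivw_beta = ivw$beta, ivw_p = ivw$pvalue,
    fdr_p = fdr_adjusted_p,
    ivw_sig = ivw_sig, fdr_sig = fdr_adjusted_p < alpha,
    direction_consistent = direction_consistent,
    q_pass = q_pass, intercept_pass = intercept_pass,
    presso_pass = presso_pass, steiger_pass = steiger_pass,
    loo_pass = loo_pass,
    candidate = ivw_sig && direction_consistent && q_pass &&
      intercept_pass && presso_pass && steiger_pass && loo_pass,
    stringsAsFactors = FALSE
  )
  class(out) <- c("candidate_decision", class(out))
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-study log odds ratios: fixed weights `1/se^2` give the
#' heterogeneity statistic `Q_meta`; the between-study variance is
#' `tau2 = max(0, (Q_meta - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; the
#' pooled estimate reweights each study by `1/(se^2 + tau2)`. The pooled
#' p-value is a two-sided normal test and the odds-ratio scale is
#' obtained by exponentiation.
#'
#' @param study_betas,study_ses Per-study log-OR estimates and standard
#'   errors (at least two studies, `se > 0`).
#' @param labels Optional study labels.
#' @return A list of class `meta_result` with `study_betas`,
#'   `study_ses`, `q_meta`, `tau2`, `beta_pooled`, `se_pooled`,
#'   `p_pooled`, `or_pooled`, `ci_low`, `ci_high`, `weights_pct`.
#' @export
dl_meta <- function(study_betas, study_ses, labels = NULL) {
  k <- length(study_betas)
  if (k < 2L) stop("meta-analysis requires at least two studies")
  if (any(study_ses <= 0)) stop("study standard errors must be > 0")
  w <- 1 / study_ses^2
  b_fe <- sum(w * study_betas) / sum(w)
  q <- sum(w * (study_betas - b_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (study_ses^2 + tau2)
  beta <- sum(w_re * study_betas) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  structure(list(
    labels = if (is.null(labels)) paste0("study", seq_len(k)) else labels,
    study_betas = study_betas, study_ses = study_ses,
    q_meta = q, tau2 = tau2,
    beta_pooled = beta, se_pooled = se,
    p_pooled = 2 * pnorm(-abs(beta / se)),
    or_pooled = exp(beta),
    ci_low = exp(beta - .z95 * se),
    ci_high = exp(beta + .z95 * se),
    weights_pct = 100 * w_re / sum(w_re)
  ), class = "meta_result")
}

#' Recover a two-sided p-value from a printed OR and 95% CI
#'
#' Under the normal approximation, the log-scale standard error is
#' `(log(ci_high) - log(ci_low)) / (2 * 1.959964)` and the p-value the
#' two-sided normal tail of `log(or) / se`. Used to verify the internal
#' consistency of reported `p; OR (95% CI)` triplets.
#'
#' @param or_point Odds-ratio point estimate.
#' @param ci_low,ci_high 95% confidence limits, `0 < ci_low < or_point <
#'   ci_high`.
#' @return Two-sided p-value.
#' @export
p_from_or_ci <- function(or_point, ci_low, ci_high) {
  if (any(!(0 < ci_low & ci_low < or_point & or_point < ci_high)))
    stop("require 0 < ci_low < or_point < ci_high")
  se <- (log(ci_high) - log(ci_low)) / (2 * .z95)
  z <- log(or_point) / se
  2 * pnorm(-abs(z))
}

#' Reference worked-example estimates
#'
#' A table of reported `p; OR (95% CI)` triplets (discovery and
#' meta-analysis rows for lipid-species exposures against intracerebral
#' and subarachnoid hemorrhage) used as worked examples for the
#' normal-approximation utilities: each row's p-value should be
#' recoverable from its OR and confidence limits. Values are stored as
#' printed (character), so their decimal precision is preserved; a
#' p-value of `"<0.001"` is a printed upper bound.
#'
#' @return A `data.frame` with character columns `exposure`, `outcome`,
#'   `analysis`, `p`, `or`, `ci_low`, `ci_high`.
#' @export
reference_estimates <- function() {
  path <- system.file("extdata", "reference_estimates.tsv",
                      package = "lipidmr", mustWork = TRUE)
  utils::read.delim(path, colClasses = "character")
}

#' P-value range implied by a rounded OR and 95% CI
#'
#' Reported `p; OR (95% CI)` triplets print the odds ratio and limits to
#' a few decimals, which limits how precisely the p-value can be
#' recovered. Given the values *as printed* (character, so trailing
#' zeros count), this propagates a half-unit-in-the-last-place
#' perturbation of each number through [p_from_or_ci()] over all corner
#' combinations and returns the attainable p-value range. A printed p is
#' internally consistent when it falls inside (or, for a printed bound
#' like `<0.001`, when the range's minimum is below the bound).
#'
#' @param or_point,ci_low,ci_high Printed values as character strings
#'   (e.g. `"1.10"`).
#' @return Numeric vector `c(p_min, p_max)`.
#' @export
p_from_or_ci_range <- function(or_point, ci_low, ci_high) {
  half_ulp <- function(s) {
    d <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0L
    0.5 * 10^(-d)
  }
  vals <- as.numeric(c(or_point, ci_low, ci_high))
  ulps <- vapply(c(or_point, ci_low, ci_high), half_ulp, numeric(1))
  ps <- numeric(0)
  for (o in vals[1] + c(-1, 1) * ulps[1])
    for (l in vals[2] + c(-1, 1) * ulps[2])
      for (h in vals[3] + c(-1, 1) * ulps[3])
        if (0 < l && l < o && o < h)
          ps <- c(ps, p_from_or_ci(o, l, h))
  range(ps)
}

#' Per-study and pooled forest table for candidate exposures
#'
#' @param meta_results Named list of `meta_result` objects, one per
#'   candidate exposure (names `exposure|outcome` or any label).
#' @param decisions A `data.frame` of candidate decisions
#'   ([candidate_filter()] rows); only rows with `candidate = TRUE` are
#'   rendered.
#' @return A `data.frame` with per-study rows plus one pooled row per
#'   candidate (`exposure, outcome, cohort, beta, se, or, ci_low,
#'   ci_high, weight_pct, pooled`); header-only when no candidates.
#' @export
forest_table <- function(meta_results, decisions) {
  empty <- data.frame(exposure = character(0), outcome = character(0),
                      cohort = character(0), beta = numeric(0),
                      se = numeric(0), or = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      weight_pct = numeric(0), pooled = logical(0),
                      stringsAsFactors = FALSE)
  if (is.null(decisions) || !nrow(decisions)) return(empty)
  cand <- decisions[decisions$candidate, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    key <- paste(cand$exposure[i], cand$outcome[i], sep = "|")
    m <- meta_results[[key]]
    if (is.null(m)) return(NULL)
    k <- length(m$study_betas)
    rbind(
      data.frame(exposure = cand$exposure[i], outcome = cand$outcome[i],
                 cohort = m$labels, beta = m$study_betas,
                 se = m$study_ses, or = exp(m$study_betas),
                 ci_low = exp(m$study_betas - .z95 * m$study_ses),
                 ci_high = exp(m$study_betas + .z95 * m$study_ses),
                 weight_pct = m$weights_pct, pooled = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(exposure = cand$exposure[i], outcome = cand$outcome[i],
                 cohort = "pooled", beta = m$beta_pooled,
                 se = m$se_pooled, or = m$or_pooled,
                 ci_low = m$ci_low, ci_high = m$ci_high,
                 weight_pct = 100, pooled = TRUE,
                 stringsAsFactors = FALSE)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
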