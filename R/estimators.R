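#' Per-variant Wald ratio
#'
#' The elementary building block of two-sample MR: the causal effect
#' implied by one variant, `beta_out / beta_exp`, with first-order
#' standard error `se_out / |beta_exp|`.
#'
#' @param beta_exp,beta_out Exposure and outcome effects (vectorised).
#' @param se_out Outcome standard error.
#' @return A `data.frame` with columns `ratio` and `se`.
#' @export
wald_ratio <- function(beta_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) stop("wald_ratio undefined for beta_exp = 0")
  data.frame(ratio = beta_out / beta_exp, se = se_out / abs(beta_exp))
}

.set_table <- function(set) {
  set <- as_instrument_set(set)
  set$instruments
}

.ratios <- function(tab) {
  w <- wald_ratio(tab$beta_exp, tab$beta_out, tab$se_out)
  w$weight <- 1 / w$se^2
  w$snp_id <- tab$snp_id
  w
}

.mr_row <- function(method, beta, se, n_snp,
                    pvalue = 2 * pnorm(-abs(beta / se)),
                    df = NULL, egger_intercept = NA_real_,
                    egger_intercept_se = NA_real_,
                    egger_intercept_p = NA_real_) {
  if (!is.null(df)) pvalue <- 2 * pt(-abs(beta / se), df = df)
  if (is.na(pvalue)) pvalue <- 1  # beta = 0 with se = 0
  data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
             pvalue = pvalue, or_point = exp(beta),
             ci_low = exp(beta - .z95 * se),
             ci_high = exp(beta + .z95 * se),
             egger_intercept = egger_intercept,
             egger_intercept_se = egger_intercept_se,
             egger_intercept_p = egger_intercept_p,
             stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted estimator
#'
#' Pools the per-variant Wald ratios with weights `1/se^2`. The
#' fixed-effect variant (`"FE"`) uses `se = (sum w)^(-1/2)`; the
#' multiplicative-random-effects variant (`"MRE"`) scales that standard
#' error by `max(1, sqrt(Q/(J-1)))` with Cochran's Q over the ratios, so
#' it never undercuts the fixed-effect error.
#'
#' @param set An `instrument_set` or harmonized instrument table with at
#'   least two instruments.
#' @param variant `"FE"` or `"MRE"`.
#' @return A one-row MR-estimate `data.frame` (`method`, `n_snp`,
#'   `beta`, `se`, `pvalue`, `or_point`, `ci_low`, `ci_high`, ...).
#' @export
mr_ivw <- function(set, variant = c("FE", "MRE")) {
  variant <- match.arg(variant)
  tab <- .set_table(set)
  if (nrow(tab) < 2L) stop("IVW requires at least two instruments")
  r <- .ratios(tab)
  beta <- sum(r$weight * r$ratio) / sum(r$weight)
  se <- sqrt(1 / sum(r$weight))
  if (variant == "MRE") {
    q <- sum(r$weight * (r$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (nrow(tab) - 1L)))
  }
  .mr_row(paste0("IVW_", variant), beta, se, nrow(tab))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects (weights `1/se_out^2`) with a free intercept, each instrument
#' oriented so its exposure effect is non-negative. The slope is the
#' causal estimate; the intercept estimates the average directional
#' pleiotropy. Standard errors use the multiplicative random-effects
#' convention (residual sigma floored at 1) and p-values the t
#' distribution with J - 2 degrees of freedom.
#'
#' @param set An `instrument_set` or harmonized table with at least
#'   three instruments.
#' @return A one-row MR-estimate `data.frame` including
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(set) {
  tab <- .set_table(set)
  j <- nrow(tab)
  if (j < 3L) stop("MR-Egger requires at least three instruments")
  flip <- sign(tab$beta_exp)
  flip[flip == 0] <- 1
  x <- tab$beta_exp * flip
  y <- tab$beta_out * flip
  if (length(unique(x)) == 1L)
    stop("degenerate design: all exposure effects equal")
  w <- 1 / tab$se_out^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  scale <- if (sigma > 0) 1 / min(1, sigma) else 0
  est <- coef(sm)
  b <- est["x", "Estimate"]
  b_se <- est["x", "Std. Error"] * scale
  a <- est["(Intercept)", "Estimate"]
  a_se <- est["(Intercept)", "Std. Error"] * scale
  a_p <- if (a_se == 0) as.numeric(a != 0) else 2 * pt(-abs(a / a_se), j - 2)
  if (a_p == 0 && a == 0) a_p <- 1
  row <- .mr_row("EGGER", b, b_se, j, df = j - 2,
                 egger_intercept = a, egger_intercept_se = a_se,
                 egger_intercept_p = a_p)
  if (b_se == 0) row$pvalue <- as.numeric(b == 0)  # exact fit guard
  if (row$pvalue == 0 && b == 0) row$pvalue <- 1
  row
}

# Weighted median of `values` with weights `w` under the midpoint
# cumulative-weight convention, interpolating to cumulative weight 0.5.
.weighted_median <- function(values, w) {
  ord <- order(values)
  v <- values[ord]
  wn <- w[ord] / sum(w)
  s <- cumsum(wn) - wn / 2
  if (0.5 <= s[1L]) return(v[1L])
  if (0.5 >= s[length(s)]) return(v[length(s)])
  stats::approx(s, v, xout = 0.5, ties = "ordered")$y
}

.boot_se <- function(tab, estimator, n_boot, seed) {
  with_preserved_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(tab), tab$beta_exp, tab$se_exp)
      by <- rnorm(nrow(tab), tab$beta_out, tab$se_out)
      estimator(bx, by, tab$se_out)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted-median estimator
#'
#' The causal estimate is the weighted median of the per-variant Wald
#' ratios (weights `1/se^2`, midpoint cumulative-weight convention with
#' linear interpolation), consistent when at least half the weight comes
#' from valid instruments. The standard error is a seeded parametric
#' bootstrap: exposure and outcome effects are redrawn from
#' `normal(beta, se)` and the weighted median recomputed.
#'
#' @param set An `instrument_set` or harmonized table (>= 2 instruments).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap (required).
#' @return A one-row MR-estimate `data.frame`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed) {
  tab <- .set_table(set)
  if (nrow(tab) < 2L) stop("weighted median requires >= 2 instruments")
  r <- .ratios(tab)
  beta <- .weighted_median(r$ratio, r$weight)
  est_fun <- function(bx, by, so) {
    rr <- by / bx
    .weighted_median(rr, (bx / so)^2)
  }
  se <- .boot_se(tab, est_fun, n_boot, seed)
  .mr_row("WMEDIAN", beta, se, nrow(tab))
}

# Modified Silverman bandwidth on the ratio estimates; zero when the
# ratios carry no usable spread (sd and mad both zero).
.mode_bandwidth <- function(ratios, phi) {
  cand <- c(sd(ratios), mad(ratios))
  cand <- cand[is.finite(cand) & cand > 0]
  if (!length(cand)) return(0)
  phi * 0.9 * min(cand) * length(ratios)^(-1 / 5)
}

.mode_point <- function(ratios, w, phi, grid_n) {
  h <- .mode_bandwidth(ratios, phi)
  if (!is.finite(h) || h <= 0) {
    # degenerate spread: return the distinct value carrying most weight
    by_val <- tapply(w, ratios, sum)
    return(as.numeric(names(by_val))[which.max(by_val)])
  }
  grid <- seq(min(ratios), max(ratios), length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * dnorm((x - ratios) / h)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Weighted-mode estimator
#'
#' Kernel-smoothed weighted empirical density of the Wald ratios (normal
#' kernel; bandwidth `phi` times a modified Silverman rule; weights
#' `1/se^2`), evaluated on a fixed grid spanning the ratio range; the
#' estimate is the density argmax. Consistent when the largest group of
#' instruments sharing a causal effect is valid. Standard error by
#' seeded parametric bootstrap.
#'
#' @param set An `instrument_set` or harmonized table (>= 3 instruments).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed (required).
#' @param grid_n Density evaluation grid size (default 512).
#' @return A one-row MR-estimate `data.frame`.
#' @export
mr_weighted_mode <- function(set, phi = 1, n_boot = 1000, seed,
                             grid_n = 512L) {
  tab <- .set_table(set)
  if (nrow(tab) < 3L) stop("weighted mode requires >= 3 instruments")
  r <- .ratios(tab)
  beta <- .mode_point(r$ratio, r$weight, phi, grid_n)
  est_fun <- function(bx, by, so) {
    rr <- by / bx
    .mode_point(rr, (bx / so)^2, phi, grid_n)
  }
  se <- .boot_se(tab, est_fun, n_boot, seed)
  .mr_row("WMODE", beta, se, nrow(tab))
}

#' Headline IVW estimate
#'
#' Returns the multiplicative-random-effects IVW estimate when
#' Cochran's Q is significant (`q_p < alpha`) and the fixed-effect
#' estimate otherwise.
#'
#' @param set An `instrument_set` or harmonized table.
#' @param alpha Heterogeneity significance level (default 0.05).
#' @return A one-row MR-estimate `data.frame`.
#' @export
mr_ivw_headline <- function(set, alpha = 0.05) {
  q <- cochran_q(set)
  mr_ivw(set, variant = if (q$q_p < alpha) "MRE" else "FE")
}

#' Run the full estimator battery on one instrument set
#'
#' Computes IVW fixed-effect, IVW multiplicative-random-effects,
#' MR-Egger (when >= 3 instruments), weighted median, and weighted mode
#' (when >= 3 instruments), with odds ratios and 95% confidence limits
#' by exponentiation.
#'
#' @param set An eligible `instrument_set` (>= 2 instruments).
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param seed Integer seed for the bootstraps (required).
#' @param phi Weighted-mode bandwidth multiplier.
#' @return A `data.frame` with one row per available method.
#' @export
mr_estimate_all <- function(set, n_boot = 1000, seed, phi = 1) {
  set <- as_instrument_set(set)
  if (!set$eligible) stop("ineligible instrument set (fewer than two SNPs)")
  j <- nrow(set$instruments)
  rows <- list(mr_ivw(set, "FE"), mr_ivw(set, "MRE"))
  if (j >= 3L) rows <- c(rows, list(mr_egger(set)))
  rows <- c(rows, list(mr_weighted_median(set, n_boot, seed)))
  if (j >= 3L) rows <- c(rows, list(mr_weighted_mode(set, phi, n_boot, seed)))
  out <- do.call(rbind, rows)
  out$exposure <- set$exposure_id
  out$outcome <- set$outcome_id
  rownames(out) <- NULL
  out[, c("exposure", "outcome", setdiff(names(out),
                                         c("exposure", "outcome")))]
}
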