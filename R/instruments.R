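#' Genome-wide significance filter for instrument candidates
#'
#' Keeps records with `pval < threshold` (strict), preserving input
#' order. The conventional instrument threshold is 5e-8.
#'
#' @param records Canonical summary-statistics `data.frame`.
#' @param threshold P-value threshold in (0,1).
#' @return The filtered `data.frame`.
#' @export
select_by_pvalue <- function(records, threshold = 5e-8) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold < 1)
  out <- records[!is.na(records$pval) & records$pval < threshold, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

.ld_r2 <- function(ld, a, b) {
  if (is.function(ld)) {
    r2 <- tryCatch(ld(a, b), error = function(e) NA_real_)
    if (is.na(r2) || !is.numeric(r2)) {
      warning("LD lookup failed for pair ", a, "/", b,
              "; treating r2 = 1 (conservative removal)")
      r2 <- 1
    }
    return(r2)
  }
  # sparse TSV-style table (snp_a, snp_b, r2); absent pair means r2 = 0
  hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
  if (any(hit)) max(ld$r2[hit]) else 0
}

#' Greedy LD clumping of instrument candidates
#'
#' Repeatedly promotes the remaining record with the smallest p-value
#' (ties broken by lexicographically smaller `snp_id`) to index SNP and
#' removes every other remaining record on the same chromosome within
#' `window_kb` of it whose LD r-squared with the index exceeds `r2_max`.
#' Without an LD source the clump runs in distance-only mode and removes
#' all same-chromosome records within the window. The result is the set
#' of index SNPs sorted by chromosome and position, and is independent of
#' the input row order.
#'
#' @param records Canonical summary-statistics `data.frame`; `chrom` and
#'   `pos` must be present when `ld` is `NULL`.
#' @param r2_max LD r-squared threshold above which a neighbour is
#'   removed (default 0.001).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param ld Optional LD source: either a `data.frame` with columns
#'   `snp_a`, `snp_b`, `r2` (absent pairs count as r2 = 0) or a function
#'   `(snp_a, snp_b) -> r2`. A failing lookup is reported and treated as
#'   r2 = 1.
#' @return The retained index records, sorted by position.
#' @export
clump <- function(records, r2_max = 0.001, window_kb = 10000, ld = NULL) {
  if (nrow(records) <= 1L) return(records)
  if (is.null(ld) && (any(is.na(records$chrom)) || any(is.na(records$pos))))
    stop("distance-only clumping requires chrom and pos on every record")
  ord <- order(records$pval, records$snp_id)
  remaining <- records[ord, , drop = FALSE]
  kept <- list()
  while (nrow(remaining) > 0L) {
    index <- remaining[1L, , drop = FALSE]
    kept[[length(kept) + 1L]] <- index
    remaining <- remaining[-1L, , drop = FALSE]
    if (nrow(remaining) == 0L) break
    near <- remaining$chrom == index$chrom &
      abs(remaining$pos - index$pos) <= window_kb * 1000
    near[is.na(near)] <- FALSE
    if (is.null(ld)) {
      drop <- near
    } else {
      drop <- near
      drop[near] <- vapply(remaining$snp_id[near],
                           function(s) .ld_r2(ld, index$snp_id, s) > r2_max,
                           logical(1))
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength: variance explained and F statistic
#'
#' Computes, per variant, the proportion of exposure variance explained
#' \deqn{R^2 = \frac{2\beta^2 f(1-f)}{2\beta^2 f(1-f) + 2\,se^2 N f(1-f)}}
#' with \eqn{f = \min(eaf, 1-eaf)} the minor-allele frequency, and the
#' instrument F statistic
#' \deqn{F = \frac{R^2}{1-R^2}\cdot\frac{N-k-1}{k}}
#' where `N` is the exposure sample size and `k` the number of
#' instruments in the set.
#'
#' @param beta,se Per-variant effect and standard error (vectorised).
#' @param eaf Effect-allele frequency; required (the minor-allele
#'   frequency enters both formulas).
#' @param n Exposure sample size; must exceed `k + 1`.
#' @param k Instrument count for the exposure.
#' @return A `data.frame` with columns `r2` and `f_stat`.
#' @export
strength_stats <- function(beta, se, eaf, n, k = 1L) {
  if (any(is.na(eaf))) stop("strength_stats requires eaf on every record")
  if (any(n <= k + 1)) stop("sample size n must exceed k + 1")
  maf <- pmin(eaf, 1 - eaf)
  num <- 2 * beta^2 * maf * (1 - maf)
  den <- num + 2 * se^2 * n * maf * (1 - maf)
  r2 <- ifelse(num == 0, 0, num / den)
  f_stat <- r2 / (1 - r2) * (n - k - 1) / k
  data.frame(r2 = r2, f_stat = f_stat)
}

#' Exclude instruments associated with the outcome
#'
#' Removes harmonized instruments whose outcome association p-value is
#' below `threshold` (strict), so that instruments plausibly act on the
#' outcome only through the exposure.
#'
#' @param instruments Harmonized instrument `data.frame`
#'   (see [harmonize()]).
#' @param outcome_p Outcome p-values per instrument; defaults to the
#'   `pval_out` column. Must be available for every instrument.
#' @param threshold Exclusion threshold (default 5e-5).
#' @return Filtered `data.frame`; removed `snp_id`s in attribute
#'   `"removed"`.
#' @export
exclude_outcome_associated <- function(instruments,
                                       outcome_p = instruments$pval_out,
                                       threshold = 5e-5) {
  if (length(outcome_p) != nrow(instruments) || any(is.na(outcome_p)))
    stop("an outcome p-value is required for every instrument")
  drop <- outcome_p < threshold
  out <- instruments[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- instruments$snp_id[drop]
  out
}

#' Default instrument-selection configuration
#'
#' @param p_exposure Exposure significance threshold (default 5e-8).
#' @param clump_r2 LD r-squared clumping threshold (default 0.001).
#' @param clump_kb Clumping window in kb (default 10000).
#' @param p_outcome_exclude Outcome-association exclusion threshold
#'   (default 5e-5).
#' @param f_policy `"flag"` (default) records weak instruments
#'   (F <= 10) without removing them; `"exclude"` drops them.
#' @param palindrome_policy,eaf_window Passed to [harmonize()].
#' @return A named list of thresholds.
#' @export
instrument_config <- function(p_exposure = 5e-8, clump_r2 = 0.001,
                              clump_kb = 10000, p_outcome_exclude = 5e-5,
                              f_policy = c("flag", "exclude"),
                              palindrome_policy = "drop_ambiguous",
                              eaf_window = 0.08) {
  list(p_exposure = p_exposure, clump_r2 = clump_r2, clump_kb = clump_kb,
       p_outcome_exclude = p_outcome_exclude,
       f_policy = match.arg(f_policy),
       palindrome_policy = palindrome_policy, eaf_window = eaf_window)
}

#' Build the instrument set for one exposure-outcome pair
#'
#' Runs the full instrument-selection cascade: genome-wide significance
#' filter, greedy LD clumping, allele harmonization against the outcome,
#' outcome-association exclusion, and instrument-strength statistics
#' (with `k` equal to the final instrument count). Weak instruments
#' (F <= 10) are flagged, or removed when `config$f_policy = "exclude"`.
#' The set is eligible for MR when at least two instruments survive.
#'
#' @param exposure_gwas,outcome_gwas Canonical summary-statistics tables.
#' @param config See [instrument_config()].
#' @param exposure_id,outcome_id Labels carried into downstream tables.
#' @param ld Optional LD source passed to [clump()].
#' @return An object of class `instrument_set`: a list with
#'   `exposure_id`, `outcome_id`, `instruments` (harmonized table with
#'   `r2`, `f_stat`, `weak` columns), `eligible`, and `attrition`
#'   (per-stage counts).
#' @export
build_instrument_set <- function(exposure_gwas, outcome_gwas,
                                 config = instrument_config(),
                                 exposure_id = "exposure",
                                 outcome_id = "outcome", ld = NULL) {
  stages <- list()
  note <- function(stage, n_in, n_out) {
    stages[[length(stages) + 1L]] <<-
      data.frame(stage = stage, n_in = n_in, n_removed = n_in - n_out,
                 n_out = n_out, stringsAsFactors = FALSE)
  }

  sig <- select_by_pvalue(exposure_gwas, config$p_exposure)
  note("significance", nrow(exposure_gwas), nrow(sig))

  clumped <- if (nrow(sig)) {
    clump(sig, r2_max = config$clump_r2, window_kb = config$clump_kb,
          ld = ld)
  } else sig
  note("clumping", nrow(sig), nrow(clumped))

  harm <- harmonize(clumped, outcome_gwas,
                    palindrome_policy = config$palindrome_policy,
                    eaf_window = config$eaf_window)
  note("harmonization", nrow(clumped), nrow(harm))

  kept <- if (nrow(harm)) {
    exclude_outcome_associated(harm, threshold = config$p_outcome_exclude)
  } else harm
  note("outcome_exclusion", nrow(harm), nrow(kept))

  if (nrow(kept)) {
    k <- nrow(kept)
    st <- strength_stats(kept$beta_exp, kept$se_exp, kept$eaf_exp,
                         kept$n_exp, k = k)
    kept$r2 <- st$r2
    kept$f_stat <- st$f_stat
    kept$weak <- st$f_stat <= 10
    if (config$f_policy == "exclude" && any(kept$weak)) {
      kept <- kept[!kept$weak, , drop = FALSE]
      if (nrow(kept)) {
        st <- strength_stats(kept$beta_exp, kept$se_exp, kept$eaf_exp,
                             kept$n_exp, k = nrow(kept))
        kept$r2 <- st$r2
        kept$f_stat <- st$f_stat
        kept$weak <- st$f_stat <= 10
      }
    }
    note("weak_instruments", k, nrow(kept))
  } else {
    kept$r2 <- numeric(0)
    kept$f_stat <- numeric(0)
    kept$weak <- logical(0)
    note("weak_instruments", 0L, 0L)
  }
  rownames(kept) <- NULL

  structure(list(
    exposure_id = exposure_id,
    outcome_id = outcome_id,
    instruments = kept,
    eligible = nrow(kept) >= 2L,
    attrition = do.call(rbind, stages)
  ), class = "instrument_set")
}

#' Coerce a harmonized instrument table to an `instrument_set`
#'
#' @param x A harmonized instrument `data.frame` or an existing
#'   `instrument_set`.
#' @param exposure_id,outcome_id Labels for a bare table.
#' @return An `instrument_set`.
#' @export
as_instrument_set <- function(x, exposure_id = "exposure",
                              outcome_id = "outcome") {
  if (inherits(x, "instrument_set")) return(x)
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 instruments = x, eligible = nrow(x) >= 2L,
                 attrition = NULL),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> ", x$exposure_id, " -> ", x$outcome_id, ": ",
      nrow(x$instruments), " instrument(s), ",
      if (x$eligible) "eligible" else "ineligible", "\n", sep = "")
  invisible(x)
}
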