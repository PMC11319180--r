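# Canonical column order for summary-statistics tables.
.canonical_cols <- c("snp_id", "chrom", "pos", "ea", "oa", "eaf",
                     "beta", "se", "pval", "n")
.required_fields <- c("snp_id", "effect_allele", "other_allele",
                      "beta", "se", "pvalue")
.valid_alleles <- c("A", "C", "G", "T")

# canonical field name -> canonical header
.field_to_header <- c(snp_id = "snp_id", chrom = "chrom", pos = "pos",
                      effect_allele = "ea", other_allele = "oa",
                      eaf = "eaf", beta = "beta", se = "se",
                      pvalue = "pval", n = "n")

#' Read GWAS summary statistics into the canonical table
#'
#' Reads a tab- or comma-delimited summary-statistics file with a header
#' row and returns one row per variant in the package's canonical layout
#' (`snp_id, chrom, pos, ea, oa, eaf, beta, se, pval, n`). Rows violating
#' the record invariants (alleles not in A/C/G/T or equal, `se <= 0`,
#' `eaf` outside \[0,1\], `pval` outside (0,1\], `pos < 1`) are dropped and
#' reported with their file line numbers in the `"rejects"` attribute.
#' Optional fields (`eaf`, `n`, `chrom`, `pos`) that are unmapped or empty
#' are recorded as `NA`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   to the file's headers, e.g. `c(snp_id = "rsid", beta = "b", ...)`.
#'   Must cover `snp_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pvalue`; `eaf`, `n`, `chrom`, `pos` are optional. `NULL` (default)
#'   assumes the canonical headers.
#' @return A `data.frame` with the canonical columns, attribute
#'   `"rejects"` (a `data.frame` with `line`, `snp_id`, `reason`).
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- data.table::fread(path, header = TRUE, sep = "auto",
                           colClasses = "character", data.table = FALSE,
                           na.strings = c("NA", ""))
  if (is.null(column_map)) {
    column_map <- .field_to_header
  }
  missing_req <- setdiff(.required_fields, names(column_map))
  if (length(missing_req) > 0L) {
    stop("column_map does not cover required field(s): ",
         paste(missing_req, collapse = ", "))
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent) > 0L) {
    stop("header is missing mapped column(s): ",
         paste(absent, collapse = ", "))
  }

  n_rows <- nrow(raw)
  get_col <- function(field) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]]
    else rep(NA_character_, n_rows)
  }
  out <- data.frame(
    snp_id = get_col("snp_id"),
    chrom  = get_col("chrom"),
    pos    = suppressWarnings(as.integer(get_col("pos"))),
    ea     = toupper(get_col("effect_allele")),
    oa     = toupper(get_col("other_allele")),
    eaf    = suppressWarnings(as.numeric(get_col("eaf"))),
    beta   = suppressWarnings(as.numeric(get_col("beta"))),
    se     = suppressWarnings(as.numeric(get_col("se"))),
    pval   = suppressWarnings(as.numeric(get_col("pvalue"))),
    n      = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n_rows)
  flag <- function(bad, why) {
    ifelse(bad & is.na(reason), why, reason)
  }
  reason <- flag(is.na(out$snp_id) | out$snp_id == "", "missing snp_id")
  reason <- flag(!(out$ea %in% .valid_alleles), "invalid effect_allele")
  reason <- flag(!(out$oa %in% .valid_alleles), "invalid other_allele")
  reason <- flag(!is.na(out$ea) & !is.na(out$oa) & out$ea == out$oa,
                 "effect_allele equals other_allele")
  reason <- flag(is.na(out$beta), "missing beta")
  reason <- flag(is.na(out$se) | out$se <= 0, "se not > 0")
  reason <- flag(is.na(out$pval) | out$pval <= 0 | out$pval > 1,
                 "pvalue outside (0,1]")
  reason <- flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1),
                 "eaf outside [0,1]")
  reason <- flag(!is.na(out$pos) & out$pos < 1, "pos < 1")

  bad <- !is.na(reason)
  rejects <- data.frame(line = which(bad) + 1L,  # +1 for the header row
                        snp_id = out$snp_id[bad],
                        reason = reason[bad],
                        stringsAsFactors = FALSE)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) stop("zero valid rows in ", path)
  attr(out, "rejects") <- rejects
  out
}

#' Write a canonical summary-statistics table
#'
#' @param x Canonical summary-statistics `data.frame`.
#' @param path Output path; written tab-separated with the canonical
#'   header.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  data.table::fwrite(x[, intersect(.canonical_cols, names(x))],
                     path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) {
  unname(.complement[ea] == oa)
}

#' Harmonize exposure and outcome associations onto one effect allele
#'
#' Matches exposure and outcome records by `snp_id` and expresses both
#' effects on the exposure's effect allele. Outcome records whose alleles
#' are swapped relative to the exposure have `beta` negated and `eaf`
#' replaced by `1 - eaf`; records matching only after strand complement
#' are complemented first and marked `flipped`. Palindromic variants
#' (A/T or C/G) are handled per `palindrome_policy`:
#' \describe{
#'   \item{`"drop_all"`}{every palindromic variant is dropped;}
#'   \item{`"keep"`}{aligned by allele labels like any other variant;}
#'   \item{`"drop_ambiguous"`}{kept only when both allele frequencies are
#'     informative, lie outside `[0.5 - eaf_window, 0.5 + eaf_window]`
#'     and agree in direction after label alignment (default).}
#' }
#'
#' @param exposure,outcome Canonical summary-statistics `data.frame`s
#'   (see [read_summary_stats()]); `snp_id` must be unique within each.
#' @param palindrome_policy One of `"drop_ambiguous"`, `"drop_all"`,
#'   `"keep"`.
#' @param eaf_window Half-width of the ambiguity window around 0.5 used
#'   by `"drop_ambiguous"` (default 0.08).
#' @return A `data.frame` of harmonized instruments with columns
#'   `snp_id, chrom, pos, ea, oa, beta_exp, se_exp, pval_exp, eaf_exp,
#'   n_exp, beta_out, se_out, pval_out, eaf_out, n_out, flipped,
#'   palindromic`, plus attributes `"drops"` (`snp_id`, `reason`) and
#'   `"drop_counts"` (named integer vector by reason).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "drop_all",
                                            "keep"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  for (nm in c("exposure", "outcome")) {
    tab <- get(nm)
    if (anyDuplicated(tab$snp_id)) {
      stop("duplicate snp_id in ", nm, " collection: ",
           paste(unique(tab$snp_id[duplicated(tab$snp_id)]), collapse = ", "))
    }
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  exp_m <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  out_m <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  n <- length(shared)
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  beta_out <- out_m$beta
  eaf_out <- out_m$eaf
  flipped <- rep(FALSE, n)
  palin <- .is_palindromic(exp_m$ea, exp_m$oa)

  o_ea <- out_m$ea
  o_oa <- out_m$oa
  same <- o_ea == exp_m$ea & o_oa == exp_m$oa
  swap <- o_ea == exp_m$oa & o_oa == exp_m$ea
  c_ea <- unname(.complement[o_ea])
  c_oa <- unname(.complement[o_oa])
  comp_same <- !same & !swap & c_ea == exp_m$ea & c_oa == exp_m$oa
  comp_swap <- !same & !swap & c_ea == exp_m$oa & c_oa == exp_m$ea

  incompatible <- !(same | swap | comp_same | comp_swap)
  keep[incompatible] <- FALSE
  reason[incompatible] <- "incompatible_alleles"

  do_swap <- swap | comp_swap
  beta_out[do_swap] <- -beta_out[do_swap]
  eaf_out[do_swap] <- 1 - eaf_out[do_swap]
  flipped <- do_swap | comp_same

  if (palindrome_policy == "drop_all") {
    drop_p <- palin & keep
    keep[drop_p] <- FALSE
    reason[drop_p] <- "palindromic"
  } else if (palindrome_policy == "drop_ambiguous") {
    informative <- !is.na(exp_m$eaf) & !is.na(eaf_out) &
      abs(exp_m$eaf - 0.5) > eaf_window & abs(eaf_out - 0.5) > eaf_window &
      sign(exp_m$eaf - 0.5) == sign(eaf_out - 0.5)
    drop_p <- palin & keep & !informative
    keep[drop_p] <- FALSE
    reason[drop_p] <- "palindromic_ambiguous"
  }

  res <- data.frame(
    snp_id = shared,
    chrom = exp_m$chrom,
    pos = exp_m$pos,
    ea = exp_m$ea,
    oa = exp_m$oa,
    beta_exp = exp_m$beta,
    se_exp = exp_m$se,
    pval_exp = exp_m$pval,
    eaf_exp = exp_m$eaf,
    n_exp = exp_m$n,
    beta_out = beta_out,
    se_out = out_m$se,
    pval_out = out_m$pval,
    eaf_out = eaf_out,
    n_out = out_m$n,
    flipped = flipped,
    palindromic = palin,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(res) <- NULL

  drops <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                      stringsAsFactors = FALSE)
  attr(res, "drops") <- drops
  attr(res, "drop_counts") <-
    if (nrow(drops)) table(drops$reason) else integer(0)
  res
}

#' Write the harmonization drop log
#'
#' @param harmonized Result of [harmonize()].
#' @param path Output TSV path (columns `snp_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(harmonized, path) {
  data.table::fwrite(attr(harmonized, "drops"), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}
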