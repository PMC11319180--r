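#' Assemble a pipeline configuration
#'
#' Bundles everything one full study run needs: per-exposure summary
#' statistics, discovery and replication outcome statistics, the
#' instrument-selection thresholds, bootstrap/PRESSO settings and the
#' master seed. Tables may be given as in-memory canonical data frames
#' or as file paths (read via [read_summary_stats()]).
#'
#' @param exposures Named list: exposure id -> either a single canonical
#'   table / path (used for both cohorts) or a list with `discovery` and
#'   `replication` entries.
#' @param outcome_discovery,outcome_replication Canonical outcome tables
#'   or paths.
#' @param outcome_id Outcome label.
#' @param instrument_cfg See [instrument_config()].
#' @param seed Master integer seed (required; drives every bootstrap and
#'   resampling test).
#' @param n_boot Bootstrap resamples for weighted median/mode.
#' @param n_sim MR-PRESSO null simulations.
#' @param alpha Significance level for all decision thresholds.
#' @param out_dir Optional directory; when set, [run_pipeline()] writes
#'   its TSV outputs and run log there.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(exposures, outcome_discovery,
                            outcome_replication, outcome_id = "outcome",
                            instrument_cfg = instrument_config(),
                            seed, n_boot = 1000, n_sim = 1000,
                            alpha = 0.05, out_dir = NULL) {
  stopifnot(is.list(exposures), length(exposures) > 0,
            !is.null(names(exposures)))
  structure(list(exposures = exposures,
                 outcome_discovery = outcome_discovery,
                 outcome_replication = outcome_replication,
                 outcome_id = outcome_id,
                 instrument_cfg = instrument_cfg,
                 seed = as.integer(seed), n_boot = n_boot, n_sim = n_sim,
                 alpha = alpha, out_dir = out_dir),
            class = "pipeline_config")
}

.load_table <- function(x) {
  if (is.character(x)) read_summary_stats(x) else x
}

.exposure_table <- function(entry, cohort) {
  if (is.list(entry) && !is.data.frame(entry)) .load_table(entry[[cohort]])
  else .load_table(entry)
}

# Analyse one exposure against one outcome table; returns NULL rows when
# the instrument set is ineligible.
.analyse_pair <- function(exposure_tab, outcome_tab, exposure_id,
                          outcome_id, cfg, seed) {
  set <- build_instrument_set(exposure_tab, outcome_tab,
                              config = cfg$instrument_cfg,
                              exposure_id = exposure_id,
                              outcome_id = outcome_id)
  if (!set$eligible) {
    return(list(set = set, estimates = NULL, sens = NULL,
                message = sprintf(
                  "%s vs %s skipped: fewer than two SNPs (%d)",
                  exposure_id, outcome_id, nrow(set$instruments))))
  }
  estimates <- mr_estimate_all(set, n_boot = cfg$n_boot, seed = seed)
  sens <- sensitivity_report(set, n_sim = cfg$n_sim, seed = seed + 1L,
                             outlier_alpha = cfg$alpha)
  list(set = set, estimates = estimates, sens = sens, message = NULL)
}

#' Run the full discovery-replication-meta study design
#'
#' For every exposure: builds the discovery instrument set, runs the
#' five-estimator battery and the full sensitivity suite; applies
#' Benjamini-Hochberg FDR across exposures to the headline IVW
#' p-values; applies the candidate decision rule on the discovery
#' cohort. Candidates are then re-analysed on the replication outcome
#' (instruments re-selected independently) and their discovery and
#' replication headline IVW estimates pooled by DerSimonian-Laird
#' random-effects meta-analysis. Failures in one exposure are logged and
#' the run continues.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `estimates`,
#'   `sensitivity`, `decisions`, `replication`, `meta` (named list of
#'   `meta_result`), `forest`, `attrition`, `log`. When
#'   `config$out_dir` is set the tables are also written as TSVs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  out_disc <- .load_table(cfg$outcome_discovery)
  out_repl <- .load_table(cfg$outcome_replication)
  exposure_ids <- sort(names(cfg$exposures))  # order-invariant results
  log_lines <- character(0)
  note <- function(msg) log_lines <<- c(log_lines, msg)
  note(sprintf("lipidmr %s | seed %d | %d exposure(s) | outcome %s",
               as.character(utils::packageVersion("lipidmr")),
               cfg$seed, length(exposure_ids), cfg$outcome_id))

  disc <- list()
  for (i in seq_along(exposure_ids)) {
    id <- exposure_ids[i]
    res <- tryCatch(
      .analyse_pair(.exposure_table(cfg$exposures[[id]], "discovery"),
                    out_disc, id, cfg$outcome_id, cfg,
                    seed = cfg$seed + 13L * i),
      error = function(e) list(set = NULL, estimates = NULL, sens = NULL,
                               message = sprintf("%s failed: %s", id,
                                                 conditionMessage(e))))
    if (!is.null(res$message)) note(res$message)
    disc[[id]] <- res
  }

  analysed <- names(disc)[!vapply(disc, function(r) is.null(r$estimates),
                                  logical(1))]
  estimates <- do.call(rbind, c(lapply(disc[analysed],
                                       function(r) r$estimates),
                                list(make.row.names = FALSE)))
  sens_tab <- do.call(rbind, c(lapply(disc[analysed], function(r)
    sensitivity_row(r$sens)), list(make.row.names = FALSE)))
  attrition <- do.call(rbind, c(lapply(analysed, function(id) {
    a <- disc[[id]]$set$attrition
    a$exposure <- id
    a
  }), list(make.row.names = FALSE)))

  # FDR across exposures (per outcome) on the headline IVW p-values
  decisions <- NULL
  if (length(analysed)) {
    headline_p <- vapply(analysed, function(id) {
      r <- disc[[id]]
      m <- if (!is.na(r$sens$q_p) && r$sens$q_p < cfg$alpha) "IVW_MRE"
        else "IVW_FE"
      r$estimates$pvalue[r$estimates$method == m]
    }, numeric(1))
    fdr_p <- bh_fdr(headline_p)
    decisions <- do.call(rbind, c(lapply(seq_along(analysed), function(i) {
      id <- analysed[i]
      candidate_filter(disc[[id]]$estimates, disc[[id]]$sens,
                       fdr_adjusted_p = fdr_p[i], alpha = cfg$alpha)
    }), list(make.row.names = FALSE)))
  }

  # replication + meta-analysis of discovery candidates
  replication <- NULL
  meta <- list()
  if (!is.null(decisions) && any(decisions$candidate)) {
    cand_ids <- decisions$exposure[decisions$candidate]
    repl_rows <- list()
    for (id in cand_ids) {
      i <- match(id, exposure_ids)
      res <- tryCatch(
        .analyse_pair(.exposure_table(cfg$exposures[[id]], "replication"),
                      out_repl, id, cfg$outcome_id, cfg,
                      seed = cfg$seed + 13L * i + 7L),
        error = function(e) list(estimates = NULL,
                                 message = sprintf(
                                   "replication %s failed: %s", id,
                                   conditionMessage(e))))
      if (!is.null(res$message)) note(res$message)
      if (is.null(res$estimates)) next
      m_repl <- if (!is.na(res$sens$q_p) && res$sens$q_p < cfg$alpha)
        "IVW_MRE" else "IVW_FE"
      repl <- res$estimates[res$estimates$method == m_repl, ]
      repl_rows[[id]] <- repl
      d <- decisions[decisions$exposure == id, ]
      disc_est <- disc[[id]]$estimates[
        disc[[id]]$estimates$method == d$ivw_method, ]
      meta[[paste(id, cfg$outcome_id, sep = "|")]] <-
        dl_meta(c(disc_est$beta, repl$beta), c(disc_est$se, repl$se),
                labels = c("discovery", "replication"))
    }
    replication <- if (length(repl_rows))
      do.call(rbind, c(repl_rows, list(make.row.names = FALSE))) else NULL
  }

  forest <- forest_table(meta, decisions)
  note(sprintf("%d analysed, %d candidate(s), %d meta-analysed",
               length(analysed),
               if (is.null(decisions)) 0L else sum(decisions$candidate),
               length(meta)))

  result <- structure(list(estimates = estimates, sensitivity = sens_tab,
                           decisions = decisions,
                           replication = replication, meta = meta,
                           forest = forest, attrition = attrition,
                           log = log_lines),
                      class = "pipeline_result")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) if (!is.null(x))
      data.table::fwrite(x, file.path(cfg$out_dir, f), sep = "\t",
                         na = "NA", quote = FALSE)
    wr(estimates, "estimates.tsv")
    wr(sens_tab, "sensitivity.tsv")
    wr(decisions, "candidates.tsv")
    wr(replication, "replication.tsv")
    wr(forest, "forest.tsv")
    wr(attrition, "attrition.tsv")
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (line in x$log) cat(" ", line, "\n")
  invisible(x)
}
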