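# Orchestration of the bidirectional analysis: per-pair select -> harmonize
# -> estimate, sensitivity suites, and family-wise Bonferroni correction.

#' Describe one exposure -> outcome analysis
#'
#' @param direction `"forward"` or `"reverse"`; a label recording which
#'   arm of the bidirectional design the analysis belongs to.
#' @param exposure_id,outcome_id Names of the exposure and outcome tables in
#'   the data registry; they must differ (two-sample design).
#' @param p_threshold,r2_max Instrument-selection options, see
#'   [select_instruments()].
#' @param palindrome_policy,eaf_window Harmonization options, see
#'   [harmonize()].
#' @param ivw_mode `"fixed"` or `"random"`, see [ivw()].
#' @param presso_n_sim,n_boot Simulation sizes for MR-PRESSO and the median
#'   bootstrap.
#' @param seed RNG seed for the stochastic sensitivity estimators.
#' @param subset Optional subset rule applied after selection: a list
#'   `list(type = "p_max"|"keep"|"drop", value = ...)`.
#' @param sensitivity Attach the Egger / median / Q / MR-PRESSO blocks
#'   (default `TRUE`); turn off for cheap main-estimate-only runs inside
#'   large replicate simulations.
#' @param label Free-text label (e.g. a sensitivity-selection id).
#' @return An `analysis_spec` list.
#' @export
analysis_spec <- function(direction, exposure_id, outcome_id,
                          p_threshold = 5e-8, r2_max = 0.2,
                          palindrome_policy = "infer_by_eaf",
                          eaf_window = 0.08, ivw_mode = "fixed",
                          presso_n_sim = 1000, n_boot = 1000, seed = 1,
                          subset = NULL, sensitivity = TRUE,
                          label = "main") {
  stopifnot(direction %in% c("forward", "reverse"))
  if (identical(exposure_id, outcome_id)) {
    stop("exposure and outcome tables must differ (two-sample design)",
         call. = FALSE)
  }
  structure(list(direction = direction, exposure_id = exposure_id,
                 outcome_id = outcome_id, p_threshold = p_threshold,
                 r2_max = r2_max, palindrome_policy = palindrome_policy,
                 eaf_window = eaf_window, ivw_mode = ivw_mode,
                 presso_n_sim = presso_n_sim, n_boot = n_boot, seed = seed,
                 subset = subset, sensitivity = sensitivity, label = label),
            class = "analysis_spec")
}

#' Bundle summary-statistics tables and an LD table into a registry
#'
#' @param tables Named list of [sumstats] tables; names are the ids that
#'   [analysis_spec()] refers to.
#' @param ld An [ld_table] shared by all traits (or `NULL`).
#' @return A `data_registry` list.
#' @export
data_registry <- function(tables, ld = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)),
            all(nzchar(names(tables))))
  structure(list(tables = tables, ld = ld), class = "data_registry")
}

#' Run one MR analysis end to end
#'
#' Executes instrument selection, optional subsetting, harmonization and
#' estimation for one spec. The main estimate is the Wald ratio when a
#' single instrument survives and IVW otherwise; Egger, the weighted
#' median and Cochran's Q are attached when at least 3 instruments are
#' available and MR-PRESSO when at least 4. Zero surviving instruments
#' yield a "not analyzable" row, not an error.
#'
#' @param spec An [analysis_spec()].
#' @param registry A [data_registry()].
#' @return A `results_row` list; see [results_table()] for the tabular view.
#' @export
run_analysis <- function(spec, registry) {
  stopifnot(inherits(spec, "analysis_spec"), inherits(registry, "data_registry"))
  exp_tab <- registry$tables[[spec$exposure_id]]
  out_tab <- registry$tables[[spec$outcome_id]]
  if (is.null(exp_tab) || is.null(out_tab)) {
    stop("registry is missing table '",
         if (is.null(exp_tab)) spec$exposure_id else spec$outcome_id, "'",
         call. = FALSE)
  }
  inst <- select_instruments(exp_tab, registry$ld,
                             p_threshold = spec$p_threshold,
                             r2_max = spec$r2_max)
  if (!is.null(spec$subset)) {
    inst <- switch(spec$subset$type,
      p_max = subset_instruments(inst, p_max = spec$subset$value),
      keep  = subset_instruments(inst, keep = spec$subset$value),
      drop  = subset_instruments(inst, drop = spec$subset$value),
      stop("unknown subset type: ", spec$subset$type, call. = FALSE)
    )
  }
  harm <- harmonize(inst, out_tab, policy = spec$palindrome_policy,
                    eaf_window = spec$eaf_window)
  n <- nrow(harm)

  row <- list(spec = spec,
              exposure = attr(exp_tab, "trait_id"),
              outcome = attr(out_tab, "trait_id"),
              source = attr(exp_tab, "source_id"),
              n_selected = nrow(inst), n_snps = n,
              f_stats = attr(inst, "f_stats"),
              drop_log = attr(harm, "drop_log"),
              pairs = harm,
              main = NULL, egger = NULL, median = NULL, q = NULL,
              presso = NULL, analyzable = n >= 1)

  if (n >= 1) {
    row$main <- if (n == 1) wald_ratio(harm[1, ]) else
      ivw(harm, mode = spec$ivw_mode)
  }
  if (isTRUE(spec$sensitivity)) {
    if (n >= 3) {
      row$egger <- egger(harm)
      row$median <- median_estimate(harm, weighted = TRUE,
                                    n_boot = spec$n_boot, seed = spec$seed)
      row$q <- cochran_q(harm, reference = row$main)
    }
    if (n >= 4) {
      row$presso <- mr_presso(harm, n_sim = spec$presso_n_sim,
                              seed = spec$seed)
    }
  }
  structure(row, class = "results_row")
}

#' @export
print.results_row <- function(x, ...) {
  cat(sprintf("[%s] %s -> %s (%s): %d instrument(s)\n",
              x$spec$direction, x$exposure, x$outcome,
              x$spec$label, x$n_snps))
  if (x$analyzable) print(x$main) else cat("  not analyzable\n")
  invisible(x)
}

#' Run a suite of sensitivity analyses
#'
#' Repeats an analysis under a set of instrument-subset rules: more
#' stringent LD pruning (`r2_max`), tightened significance (`p_max`),
#' keep-lists (replicated or annotation-based selections) and drop-lists
#' (cross-trait or pleiotropy exclusions).
#'
#' @param spec The base [analysis_spec()].
#' @param suite Named list; each entry is
#'   `list(type = "r2_max"|"p_max"|"keep"|"drop", value = ...)`.
#' @param registry A [data_registry()].
#' @return A list of `results_row`, one per suite entry, labelled by the
#'   suite names.
#' @export
run_sensitivity_suite <- function(spec, suite, registry) {
  stopifnot(is.list(suite), !is.null(names(suite)))
  lapply(stats::setNames(names(suite), names(suite)), function(nm) {
    entry <- suite[[nm]]
    s <- spec
    s$label <- nm
    if (identical(entry$type, "r2_max")) {
      s$r2_max <- entry$value
    } else {
      s$subset <- entry
    }
    run_analysis(s, registry)
  })
}

#' Bonferroni threshold for a bidirectional analysis family
#'
#' `alpha / (n_forward + n_reverse)`: the family counts every analysis in
#' both directions.
#'
#' @param n_forward,n_reverse Analysis counts per direction (non-negative,
#'   not both zero).
#' @param alpha Family-wise error rate (default 0.05).
#' @return The per-analysis significance threshold.
#' @examples
#' bonferroni_threshold(10, 8)  # 0.05 / 18 = 2.78e-3
#' @export
bonferroni_threshold <- function(n_forward, n_reverse, alpha = 0.05) {
  stopifnot(n_forward >= 0, n_reverse >= 0, alpha > 0, alpha < 1)
  total <- n_forward + n_reverse
  if (total == 0) stop("at least one analysis is required", call. = FALSE)
  alpha / total
}

#' Tabulate analysis rows
#'
#' Flattens `results_row` objects into the fixed column layout used by
#' [write_results()].
#'
#' @param rows A list of `results_row` (a single row is accepted).
#' @return A `results_table` data.frame.
#' @export
results_table <- function(rows) {
  if (inherits(rows, "results_row")) rows <- list(rows)
  out <- lapply(rows, function(x) {
    main <- x$main
    eg <- x$egger
    data.frame(
      direction = x$spec$direction,
      exposure = x$exposure,
      outcome = x$outcome,
      source = x$source %||% NA_character_,
      method = if (is.null(main)) NA_character_ else main$method,
      n_snps = x$n_snps,
      estimate = if (is.null(main)) NA_real_ else main$estimate,
      se = if (is.null(main)) NA_real_ else main$se,
      ci_low = if (is.null(main)) NA_real_ else main$ci_low,
      ci_high = if (is.null(main)) NA_real_ else main$ci_high,
      pvalue = if (is.null(main)) NA_real_ else main$pvalue,
      egger_slope = if (is.null(eg) || !eg$feasible) NA_real_ else
        eg$slope$estimate,
      egger_intercept = if (is.null(eg) || !eg$feasible) NA_real_ else
        eg$intercept$estimate,
      q_p = if (is.null(x$q)) NA_real_ else x$q$pvalue,
      presso_global_p = if (is.null(x$presso)) NA_real_ else
        x$presso$global_p,
      significant = NA,
      label = x$spec$label,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("results_table", "data.frame")
  res
}

#' Flag family-wise significance
#'
#' Marks each row significant when its main p-value is strictly below the
#' family threshold; rows without a p-value (not analyzable) get `NA`.
#'
#' @param tab A `results_table` (or anything [results_table()] accepts).
#' @param threshold Per-analysis threshold, e.g. from
#'   [bonferroni_threshold()].
#' @return The table with its `significant` column filled in.
#' @export
flag_significance <- function(tab, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  if (!is.data.frame(tab)) tab <- results_table(tab)
  tab$significant <- ifelse(is.na(tab$pvalue), NA, tab$pvalue < threshold)
  tab
}

#' Run a full bidirectional analysis family
#'
#' Convenience wrapper: runs every spec, tabulates, computes the Bonferroni
#' threshold from the declared per-direction analysis counts (defaulting to
#' the counts of specs actually run) and flags significance.
#'
#' @param specs List of [analysis_spec()].
#' @param registry A [data_registry()].
#' @param alpha Family-wise error rate.
#' @param n_forward,n_reverse Declared family sizes per direction; default
#'   to the number of forward/reverse specs. They are configurable because
#'   the accounting of "analysis units" may differ from the number of
#'   dataset pairs run (e.g. one trait measured in several studies counted
#'   once).
#' @return List with `rows` (results_row list), `table` (flagged
#'   `results_table`) and `threshold`.
#' @export
run_family <- function(specs, registry, alpha = 0.05,
                       n_forward = NULL, n_reverse = NULL) {
  dirs <- vapply(specs, `[[`, character(1), "direction")
  nf <- n_forward %||% sum(dirs == "forward")
  nr <- n_reverse %||% sum(dirs == "reverse")
  thr <- bonferroni_threshold(nf, nr, alpha)
  rows <- lapply(specs, run_analysis, registry = registry)
  tab <- flag_significance(results_table(rows), thr)
  list(rows = rows, table = tab, threshold = thr)
}
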