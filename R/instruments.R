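# Instrument selection: genome-wide significance filter, greedy LD pruning,
# per-SNP F statistics, cross-trait independence screening and subsetting.

#' Select genetic instruments for an exposure
#'
#' Keeps SNPs with association `pvalue < p_threshold` and prunes them to
#' mutual linkage-disequilibrium independence with a greedy pass: candidates
#' are sorted by ascending p-value (ties broken lexicographically by rsid)
#' and a candidate is retained iff its known R-squared with every
#' already-retained SNP is below `r2_max`.
#'
#' @param stats A [sumstats] table for the exposure.
#' @param ld An [ld_table] of pairwise R-squared, or `NULL`.
#' @param p_threshold Significance cutoff (default the genome-wide
#'   `5e-8`); strict inequality.
#' @param r2_max Pruning threshold (default `0.2`); a retained pair must
#'   have known R-squared strictly below it.
#' @param unknown_ld Policy for pairs absent from `ld`: `"independent"`
#'   (default; treated as R-squared 0) or `"dependent"` (conservatively
#'   treated as failing the pruning threshold).
#' @return An `instrument_set`: the retained subset of `stats` with
#'   attributes `p_threshold`, `r2_max` and `f_stats` (named per-rsid
#'   F statistics, see [f_statistic()]).
#' @export
select_instruments <- function(stats, ld = NULL, p_threshold = 5e-8,
                               r2_max = 0.2,
                               unknown_ld = c("independent", "dependent")) {
  unknown_ld <- match.arg(unknown_ld)
  stopifnot(p_threshold > 0, p_threshold < 1, r2_max > 0, r2_max <= 1)
  d <- as.data.frame(stats)
  d <- d[d$pvalue < p_threshold, , drop = FALSE]
  d <- d[order(d$pvalue, d$rsid), , drop = FALSE]
  keep <- logical(nrow(d))
  retained <- character(0)
  for (i in seq_len(nrow(d))) {
    r2 <- ld_r2(ld, d$rsid[i], retained)
    r2[is.na(r2)] <- if (unknown_ld == "independent") 0 else Inf
    if (all(r2 < r2_max)) {
      keep[i] <- TRUE
      retained <- c(retained, d$rsid[i])
    }
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  .instrument_set(d, stats, p_threshold, r2_max)
}

.instrument_set <- function(d, parent, p_threshold, r2_max,
                            subset_spec = NULL) {
  f <- if (nrow(d)) f_statistic(d$beta, d$se) else numeric(0)
  names(f) <- d$rsid
  structure(d,
            trait_id = attr(parent, "trait_id"),
            source_id = attr(parent, "source_id"),
            p_threshold = p_threshold,
            r2_max = r2_max,
            f_stats = f,
            subset_spec = subset_spec,
            class = c("instrument_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> trait '%s': %d instrument(s), p < %g, R2 < %g\n",
              attr(x, "trait_id"), nrow(x),
              attr(x, "p_threshold"), attr(x, "r2_max")))
  if (nrow(x)) {
    f <- attr(x, "f_stats")
    cat(sprintf("  F statistic range: %.1f - %.1f\n", min(f), max(f)))
  }
  invisible(x)
}

#' Single-instrument F statistic
#'
#' Instrument strength as the squared z-score, `F = (beta / se)^2`; the
#' single-SNP approximation of the first-stage F statistic.
#'
#' @param beta,se Numeric vectors; `se` must be positive.
#' @return Numeric vector of F statistics.
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be finite and > 0", call. = FALSE)
  }
  (beta / se)^2
}

#' Cross-trait instrument overlap report
#'
#' Lists every pair of instruments drawn from different sets that is either
#' the same SNP or in known LD at or above `r2_max` — the input to the
#' sensitivity analysis that excludes variants selected for several traits.
#'
#' @param sets A list of two or more `instrument_set` objects.
#' @param ld An [ld_table] or `NULL`.
#' @param r2_max Conflict threshold (default 0.2); identical rsids count as
#'   R-squared 1.
#' @return A data.frame with columns `rsid_a`, `trait_a`, `rsid_b`,
#'   `trait_b`, `r2`; zero rows when the sets are independent.
#' @export
cross_trait_overlap <- function(sets, ld = NULL, r2_max = 0.2) {
  stopifnot(is.list(sets), length(sets) >= 2)
  out <- list()
  for (i in seq_len(length(sets) - 1)) {
    for (j in seq(i + 1, length(sets))) {
      a <- sets[[i]]; b <- sets[[j]]
      if (!nrow(a) || !nrow(b)) next
      grid <- expand.grid(ia = seq_len(nrow(a)), ib = seq_len(nrow(b)))
      r2 <- ld_r2(ld, a$rsid[grid$ia], b$rsid[grid$ib])
      hit <- !is.na(r2) & r2 >= r2_max
      if (any(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          rsid_a = a$rsid[grid$ia[hit]],
          trait_a = attr(a, "trait_id"),
          rsid_b = b$rsid[grid$ib[hit]],
          trait_b = attr(b, "trait_id"),
          r2 = r2[hit],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(rsid_a = character(0), trait_a = character(0),
                      rsid_b = character(0), trait_b = character(0),
                      r2 = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Subset an instrument set
#'
#' Applies exactly one subset rule: tightening the significance threshold
#' (`p_max`), restricting to a keep-list of rsids (replication- or
#' annotation-based selections), or removing a drop-list of rsids
#' (e.g. cross-trait or pleiotropy exclusions).
#'
#' @param set An `instrument_set`.
#' @param p_max Tightened p-value cutoff (strict), e.g. `1e-10` or `1e-20`.
#' @param keep Character vector of rsids to retain.
#' @param drop Character vector of rsids to remove.
#' @return A filtered `instrument_set`; its `subset_spec` attribute records
#'   which rule was applied. A keep-list disjoint from the set yields an
#'   empty set with a warning.
#' @export
subset_instruments <- function(set, p_max = NULL, keep = NULL, drop = NULL) {
  given <- c(p = !is.null(p_max), keep = !is.null(keep), drop = !is.null(drop))
  if (sum(given) != 1) {
    stop("supply exactly one of `p_max`, `keep`, `drop`", call. = FALSE)
  }
  d <- as.data.frame(set)
  if (!is.null(p_max)) {
    stopifnot(p_max > 0, p_max < 1)
    d <- d[d$pvalue < p_max, , drop = FALSE]
    spec <- list(type = "p_max", value = p_max)
    p_thr <- min(attr(set, "p_threshold"), p_max)
  } else if (!is.null(keep)) {
    d <- d[d$rsid %in% keep, , drop = FALSE]
    if (!nrow(d)) {
      warning("keep-list shares no rsid with the instrument set; ",
              "returning an empty set", call. = FALSE)
    }
    spec <- list(type = "keep", value = keep)
    p_thr <- attr(set, "p_threshold")
  } else {
    d <- d[!(d$rsid %in% drop), , drop = FALSE]
    spec <- list(type = "drop", value = drop)
    p_thr <- attr(set, "p_threshold")
  }
  rownames(d) <- NULL
  .instrument_set(d, set, p_thr, attr(set, "r2_max"), subset_spec = spec)
}
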