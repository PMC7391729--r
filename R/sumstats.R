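# Summary-statistic tables: the format boundary for the whole pipeline.
#
# A `sumstats` object is a data.frame with one validated row per SNP and the
# canonical columns rsid, effect_allele, other_allele, beta, se, pvalue, eaf,
# n (eaf and n may be NA: several published metabolite GWAS omit them).

.SUMSTATS_REQUIRED <- c("rsid", "effect_allele", "other_allele",
                        "beta", "se", "pvalue")
.SUMSTATS_OPTIONAL <- c("eaf", "n", "chrom", "pos")
.VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics table
#'
#' @param x A data.frame with at least the columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue`; optionally `eaf`, `n`, `chrom`,
#'   `pos`. Alleles are uppercased; rows are validated against the per-SNP
#'   invariants (single-nucleotide alleles, `se > 0`, `pvalue` in (0, 1],
#'   `eaf` in (0, 1) when present, unique rsids).
#' @param trait_id Trait label, e.g. `"kynurenine"` or `"eGFR"`.
#' @param source_id Study label, e.g. `"shin2014"`.
#' @param strict If `TRUE` (default) any invalid row is an error naming the
#'   offending rsid; if `FALSE` invalid rows are dropped and counted in
#'   `attr(, "n_dropped")`.
#' @return A `sumstats` object (a data.frame).
#' @export
sumstats <- function(x, trait_id, source_id = NA_character_, strict = TRUE) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(.SUMSTATS_REQUIRED, names(x))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in setdiff(.SUMSTATS_OPTIONAL, names(x))) {
    x[[col]] <- if (col %in% c("rsid", "chrom")) NA_character_ else NA_real_
  }
  x <- x[, c(.SUMSTATS_REQUIRED, .SUMSTATS_OPTIONAL)]
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("beta", "se", "pvalue", "eaf", "n", "pos")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  bad <- .sumstats_problems(x)
  if (length(bad$idx)) {
    if (strict) {
      stop("invalid summary-statistic row(s): ",
           paste(sprintf("%s (%s)", x$rsid[bad$idx], bad$why), collapse = "; "),
           call. = FALSE)
    }
    x <- x[-bad$idx, , drop = FALSE]
  }
  dup <- duplicated(x$rsid)
  if (any(dup)) {
    if (strict) {
      stop("duplicate rsid(s): ",
           paste(unique(x$rsid[dup]), collapse = ", "), call. = FALSE)
    }
    x <- x[!dup, , drop = FALSE]
  }
  n_dropped <- length(bad$idx) + sum(dup)
  if (!strict && n_dropped > 0) {
    message(sprintf("sumstats('%s'): dropped %d invalid row(s)",
                    trait_id, n_dropped))
  }
  rownames(x) <- NULL
  structure(x,
            trait_id = trait_id,
            source_id = source_id,
            n_dropped = n_dropped,
            class = c("sumstats", "data.frame"))
}

# Indices (and reasons) of rows violating the SnpRecord invariants.
.sumstats_problems <- function(x) {
  why <- character(nrow(x))
  flag <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    why[cond & why == ""] <<- reason
  }
  flag(is.na(x$rsid) | x$rsid == "", "missing rsid")
  flag(!(x$effect_allele %in% .VALID_ALLELES), "invalid effect allele")
  flag(!(x$other_allele %in% .VALID_ALLELES), "invalid other allele")
  flag(x$effect_allele == x$other_allele, "identical alleles")
  flag(!is.finite(x$beta), "non-finite beta")
  flag(!is.finite(x$se) | x$se <= 0, "se must be > 0")
  flag(!is.finite(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1,
       "pvalue outside (0, 1]")
  has_eaf <- !is.na(x$eaf)
  why[has_eaf & (x$eaf <= 0 | x$eaf >= 1) & why == ""] <- "eaf outside (0, 1)"
  list(idx = which(why != ""), why = why[why != ""])
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> trait '%s' (source %s): %d SNP(s)\n",
              attr(x, "trait_id"), attr(x, "source_id"), nrow(x)))
  print(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-delimited file with a header line and maps its columns onto
#' the canonical per-SNP fields. The mapping is supplied by the caller
#' because published studies use heterogeneous headers.
#'
#' @param path Path to a tab-delimited file.
#' @param trait_id,source_id Labels attached to the table.
#' @param column_map Named character vector mapping canonical field names
#'   (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`, and
#'   optionally `eaf`, `n`, `chrom`, `pos`) to column names in the file.
#'   `NULL` assumes the file already uses the canonical names.
#' @param strict Validation mode, see [sumstats()].
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_id, source_id = NA_character_,
                          column_map = NULL, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE)
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent)) {
      stop("mapped column(s) absent from file header: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    raw <- raw[, unname(column_map), drop = FALSE]
    names(raw) <- names(column_map)
  }
  sumstats(raw, trait_id = trait_id, source_id = source_id, strict = strict)
}

#' Read a pairwise LD table
#'
#' Long-format tab-delimited file with columns `rsid_a`, `rsid_b`, `r2`.
#' The lookup is symmetric; a pair absent from the table is "unknown" and
#' handled by the caller's policy.
#'
#' @param path Path to the LD file.
#' @return An `ld_table` object.
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(d) == 0) return(ld_table())
  ld_table(d)
}

#' Construct a pairwise LD lookup table
#'
#' @param pairs `NULL` (empty table) or a data.frame with columns `rsid_a`,
#'   `rsid_b`, `r2` (each R-squared in `[0, 1]`). Duplicate pairs with
#'   conflicting `r2` are an error.
#' @return An `ld_table` object supporting symmetric lookup via [ld_r2()].
#' @export
ld_table <- function(pairs = NULL) {
  env <- new.env(parent = emptyenv())
  obj <- structure(list(env = env, n_pairs = 0L), class = "ld_table")
  if (is.null(pairs) || nrow(pairs) == 0) return(obj)
  need <- c("rsid_a", "rsid_b", "r2")
  if (!all(need %in% names(pairs))) {
    stop("LD table needs columns rsid_a, rsid_b, r2", call. = FALSE)
  }
  r2 <- as.numeric(pairs$r2)
  if (any(!is.finite(r2) | r2 < 0 | r2 > 1)) {
    stop("LD r2 values must lie in [0, 1]", call. = FALSE)
  }
  a <- as.character(pairs$rsid_a)
  b <- as.character(pairs$rsid_b)
  if (any(a == b)) stop("LD table must not contain self pairs", call. = FALSE)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  for (i in seq_along(key)) {
    old <- get0(key[i], envir = env, inherits = FALSE)
    if (!is.null(old) && old != r2[i]) {
      stop("conflicting r2 for pair ", a[i], "/", b[i], call. = FALSE)
    }
    assign(key[i], r2[i], envir = env)
  }
  obj$n_pairs <- length(ls(env))
  obj
}

#' Symmetric LD lookup
#'
#' @param ld An `ld_table` (or `NULL`, meaning no LD information).
#' @param a,b Character vectors of rsids, recycled to common length.
#' @return Numeric vector of R-squared values; `NA` where the pair is
#'   unknown; 1 where `a == b`.
#' @export
ld_r2 <- function(ld, a, b) {
  if (length(a) == 0 || length(b) == 0) return(numeric(0))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- rep(NA_real_, n)
  out[a == b] <- 1
  if (!is.null(ld) && any(a != b)) {
    idx <- which(a != b)
    key <- paste(pmin(a[idx], b[idx]), pmax(a[idx], b[idx]), sep = "\r")
    hit <- mget(key, envir = ld$env, ifnotfound = list(NA_real_))
    out[idx] <- unlist(hit, use.names = FALSE)
  }
  out
}

#' @export
print.ld_table <- function(x, ...) {
  cat(sprintf("<ld_table> %d known pair(s)\n", x$n_pairs))
  invisible(x)
}

#' Write a summary-statistics table
#'
#' Tab-delimited with the canonical column names; [read_sumstats()] on the
#' written file (no `column_map` needed) reproduces the table.
#'
#' @param stats A [sumstats] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  data.table::fwrite(as.data.frame(stats), path, sep = "\t", quote = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a results table
#'
#' Serializes analysis rows to a tab-delimited file with a deterministic
#' column order and fixed numeric rendering: estimates and standard errors
#' to 4 significant digits, p-values in scientific notation with two
#' decimals (e.g. `6.26E-04`).
#'
#' @param rows A `results_table` data.frame (see [results_table()]) or a
#'   list of rows produced by [run_analysis()].
#' @param path Output file path.
#' @return Invisibly, the formatted character data.frame written.
#' @export
write_results <- function(rows, path) {
  tab <- if (is.data.frame(rows)) rows else results_table(rows)
  cols <- .RESULTS_COLUMNS
  miss <- setdiff(cols, names(tab))
  for (m in miss) tab[[m]] <- NA
  tab <- tab[, cols, drop = FALSE]
  out <- tab
  est_cols <- c("estimate", "se", "ci_low", "ci_high",
                "egger_slope", "egger_intercept")
  for (col in est_cols) out[[col]] <- .fmt_est(tab[[col]])
  for (col in c("pvalue", "q_p", "presso_global_p")) {
    out[[col]] <- .fmt_p(tab[[col]])
  }
  out$significant <- ifelse(is.na(tab$significant), "NA",
                            ifelse(tab$significant, "TRUE", "FALSE"))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing", call. = FALSE)
  })
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(out)
}

.RESULTS_COLUMNS <- c("direction", "exposure", "outcome", "source", "method",
                      "n_snps", "estimate", "se", "ci_low", "ci_high",
                      "pvalue", "egger_slope", "egger_intercept", "q_p",
                      "presso_global_p", "significant")

# 4 significant digits, plain notation.
.fmt_est <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 4), format = "fg", flag = "#"))
}

# Table-1 style "6.26E-04".
.fmt_p <- function(x) ifelse(is.na(x), "NA", sprintf("%.2E", x))
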