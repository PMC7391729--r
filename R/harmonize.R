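# Allele harmonization: align outcome associations to the exposure's
# effect-allele orientation before any causal estimation.

#' Construct harmonized effect-size pairs directly
#'
#' Mostly useful in tests and simulations; [harmonize()] is the normal
#' entry point. Validates the per-pair invariants (`sx > 0`, `sy > 0`,
#' unique rsids).
#'
#' @param rsid,bx,sx,by,sy Parallel vectors: SNP id, exposure effect and SE,
#'   outcome effect (aligned to the exposure's effect allele) and SE.
#' @param status Per-pair harmonization status label.
#' @param exposure_id,outcome_id Trait labels.
#' @return A `harmonized_pairs` data.frame.
#' @export
harmonized_pairs <- function(rsid, bx, sx, by, sy, status = "aligned",
                             exposure_id = NA_character_,
                             outcome_id = NA_character_) {
  d <- data.frame(rsid = as.character(rsid), bx = bx, sx = sx, by = by,
                  sy = sy, status = rep_len(status, length(rsid)),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$rsid)) stop("duplicate rsids", call. = FALSE)
  if (any(d$sx <= 0) || any(d$sy <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  structure(d,
            exposure_id = exposure_id,
            outcome_id = outcome_id,
            drop_log = data.frame(rsid = character(0), reason = character(0),
                                  stringsAsFactors = FALSE),
            class = c("harmonized_pairs", "data.frame"))
}

#' Harmonize exposure instruments with outcome summary statistics
#'
#' For each instrument present in the outcome table the outcome effect is
#' re-expressed per copy of the exposure's effect allele:
#'
#' * identical allele pair, same orientation — kept as is (`aligned`);
#' * identical pair, swapped orientation — outcome beta negated and eaf
#'   reflected (`sign_flipped`);
#' * pair matches only after complementing both outcome alleles — strand
#'   flip applied, then the two cases above (`strand_flipped`);
#' * palindromic SNP (A/T or G/C, strand unresolvable from alleles) —
#'   resolved per `policy`;
#' * anything else — dropped with reason `mismatch`; instruments absent
#'   from the outcome table are dropped with reason `missing`.
#'
#' @param instruments An `instrument_set` (or `sumstats`) for the exposure.
#' @param outcome A [sumstats] table for the outcome.
#' @param policy Palindromic-SNP policy: `"infer_by_eaf"` (default) aligns
#'   by matching the minor-allele side when both effect-allele frequencies
#'   are available and outside `0.5 +/- eaf_window`, otherwise drops the
#'   SNP (`ambiguous`); `"drop_all"` drops every palindromic SNP;
#'   `"keep_as_is"` trusts the reported strands.
#' @param eaf_window Half-width of the frequency ambiguity band around 0.5
#'   (default 0.08, i.e. drop when either eaf falls in `[0.42, 0.58]`).
#' @return A `harmonized_pairs` data.frame with columns `rsid`, `bx`, `sx`,
#'   `by`, `sy`, `status`; dropped instruments are recorded in
#'   `attr(, "drop_log")`.
#' @export
harmonize <- function(instruments, outcome,
                      policy = c("infer_by_eaf", "drop_all", "keep_as_is"),
                      eaf_window = 0.08) {
  policy <- match.arg(policy)
  stopifnot(eaf_window >= 0, eaf_window < 0.5)
  ex <- as.data.frame(instruments)
  out <- as.data.frame(outcome)
  o_idx <- match(ex$rsid, out$rsid)

  kept <- vector("list", nrow(ex))
  dropped <- list()
  drop <- function(rsid, reason) {
    dropped[[length(dropped) + 1L]] <<-
      data.frame(rsid = rsid, reason = reason, stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(ex))) {
    if (is.na(o_idx[i])) { drop(ex$rsid[i], "missing"); next }
    o <- out[o_idx[i], ]
    h <- .harmonize_one(ex$effect_allele[i], ex$other_allele[i],
                        o$effect_allele, o$other_allele,
                        ex$eaf[i], o$eaf, policy, eaf_window)
    if (!is.null(h$reason)) { drop(ex$rsid[i], h$reason); next }
    kept[[i]] <- data.frame(
      rsid = ex$rsid[i], bx = ex$beta[i], sx = ex$se[i],
      by = h$sign * o$beta, sy = o$se, status = h$status,
      stringsAsFactors = FALSE
    )
  }

  kept <- kept[!vapply(kept, is.null, logical(1))]
  d <- if (length(kept)) do.call(rbind, kept) else
    data.frame(rsid = character(0), bx = numeric(0), sx = numeric(0),
               by = numeric(0), sy = numeric(0), status = character(0),
               stringsAsFactors = FALSE)
  rownames(d) <- NULL
  drop_log <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(rsid = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  structure(d,
            exposure_id = attr(instruments, "trait_id"),
            outcome_id = attr(outcome, "trait_id"),
            policy = policy,
            eaf_window = eaf_window,
            drop_log = drop_log,
            class = c("harmonized_pairs", "data.frame"))
}

# Resolve one allele configuration. Returns list(sign=, status=) for a kept
# pair or list(reason=) for a dropped one.
.harmonize_one <- function(xe, xo, ye, yo, eaf_x, eaf_y, policy, eaf_window) {
  if (.is_palindromic(xe, xo)) {
    # outcome alleles must be the same palindromic pair (complementing a
    # palindrome reproduces it, so strand cannot be told from the labels)
    if (!setequal(c(ye, yo), c(xe, xo))) return(list(reason = "mismatch"))
    literal_sign <- if (ye == xe) 1 else -1
    if (policy == "drop_all") return(list(reason = "palindromic"))
    if (policy == "keep_as_is") {
      return(list(sign = literal_sign, status = "palindromic_kept"))
    }
    # infer_by_eaf
    if (is.na(eaf_x) || is.na(eaf_y)) return(list(reason = "ambiguous"))
    eaf_y_lit <- if (literal_sign == 1) eaf_y else 1 - eaf_y
    near <- abs(c(eaf_x, eaf_y_lit) - 0.5) <= eaf_window
    if (any(near)) return(list(reason = "ambiguous"))
    s <- if ((eaf_x - 0.5) * (eaf_y_lit - 0.5) > 0) literal_sign else
      -literal_sign
    return(list(sign = s, status = "palindromic_kept"))
  }
  if (ye == xe && yo == xo) return(list(sign = 1, status = "aligned"))
  if (ye == xo && yo == xe) return(list(sign = -1, status = "sign_flipped"))
  yec <- unname(.COMPLEMENT[ye]); yoc <- unname(.COMPLEMENT[yo])
  if (yec == xe && yoc == xo) return(list(sign = 1, status = "strand_flipped"))
  if (yec == xo && yoc == xe) return(list(sign = -1, status = "strand_flipped"))
  list(reason = "mismatch")
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  dl <- attr(x, "drop_log")
  cat(sprintf("<harmonized_pairs> %s -> %s: %d pair(s), %d dropped\n",
              attr(x, "exposure_id") %||% "?", attr(x, "outcome_id") %||% "?",
              nrow(x), nrow(dl)))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(dl)) {
    cat("dropped:", paste(sprintf("%s(%s)", dl$rsid, dl$reason),
                          collapse = ", "), "\n")
  }
  invisible(x)
}
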