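# MR-PRESSO: simulation-based residual-sum-of-squares test for horizontal
# pleiotropy (global), per-SNP outlier detection, and an outlier-corrected
# IVW estimate.

#' MR-PRESSO pleiotropy residual sum of squares and outlier test
#'
#' For each instrument `i` the leave-one-out IVW estimate `theta_(-i)` is
#' computed and the weighted squared residual
#' `RSS_i = w_i * (by_i - theta_(-i) * bx_i)^2` (first-order weights
#' `w_i = bx_i^2 / sy_i^2`) measured; the observed global statistic is
#' `sum(RSS_i)`. A null distribution is built from `n_sim` parametric
#' simulations drawing `bx_i* ~ N(bx_i, sx_i)` and
#' `by_i* ~ N(theta_(-i) * bx_i, sy_i)` and recomputing the statistic.
#' Empirical p-values use the add-one rule `(1 + #exceedances) / (n_sim + 1)`.
#' Per-SNP outlier p-values are Bonferroni-corrected by the instrument
#' count before comparison with `outlier_alpha`; the corrected estimate is
#' the IVW estimate on the non-outlier subset.
#'
#' A distortion test (is the corrected estimate unusually far from the full
#' one, relative to removals of random subsets of the same size?) is
#' reported for information only.
#'
#' @param pairs Harmonized pairs; at least 4 required.
#' @param n_sim Number of parametric simulations (default 1000; fewer than
#'   100 is a configuration error — the empirical p would be too coarse).
#' @param seed Mandatory RNG seed (restored on exit).
#' @param outlier_alpha Family-wise level for outlier flagging
#'   (default 0.05).
#' @param distortion Run the informational distortion test (default `TRUE`).
#' @return A `presso_result` with `rss_obs`, `global_p`, `outlier_p`
#'   (named per-rsid), `outliers`, `corrected` (an `mr_estimate`, or `NULL`
#'   when no non-outlier remains), `distortion_p`, `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed, outlier_alpha = 0.05,
                      distortion = TRUE) {
  if (missing(seed) || is.null(seed)) {
    stop("mr_presso requires an explicit `seed`", call. = FALSE)
  }
  if (n_sim < 100) {
    stop("n_sim must be >= 100 (empirical p-value too coarse)",
         call. = FALSE)
  }
  d <- .as_pairs(pairs)
  d <- d[d$bx != 0, , drop = FALSE]
  n <- nrow(d)
  if (n < 4) stop("mr_presso needs at least 4 pairs", call. = FALSE)
  rsid <- if (!is.null(d$rsid)) d$rsid else sprintf("snp%02d", seq_len(n))

  w <- d$bx^2 / d$sy^2
  r <- d$by / d$bx
  s1 <- sum(w * r); s0 <- sum(w)
  theta_loo <- (s1 - w * r) / (s0 - w)
  rss_i <- w * (d$by - theta_loo * d$bx)^2
  rss_obs <- sum(rss_i)

  sims <- with_seed(seed, {
    bx_star <- matrix(stats::rnorm(n * n_sim, d$bx, d$sx), nrow = n)
    by_star <- matrix(stats::rnorm(n * n_sim, theta_loo * d$bx, d$sy),
                      nrow = n)
    w_star <- bx_star^2 / d$sy^2
    r_star <- by_star / bx_star
    s1_star <- colSums(w_star * r_star)
    s0_star <- colSums(w_star)
    theta_star <- (rep(s1_star, each = n) - w_star * r_star) /
      (rep(s0_star, each = n) - w_star)
    rss_star <- w_star * (by_star - theta_star * bx_star)^2
    list(per_snp = rss_star, global = colSums(rss_star))
  })

  global_p <- (1 + sum(sims$global >= rss_obs)) / (n_sim + 1)
  outlier_p <- (1 + rowSums(sims$per_snp >= rss_i)) / (n_sim + 1)
  names(outlier_p) <- rsid
  outliers <- rsid[outlier_p * n < outlier_alpha]

  keep <- !(rsid %in% outliers)
  corrected <- if (any(keep)) {
    ce <- ivw(d[keep, , drop = FALSE])
    ce$method <- "IVW (outlier-corrected)"
    ce
  } else NULL

  distortion_p <- NA_real_
  if (distortion && length(outliers) > 0 && any(keep)) {
    full <- ivw(d)$estimate
    d_obs <- full - corrected$estimate
    k <- sum(keep)
    n_draw <- min(n_sim, 500L)
    d_null <- with_seed(seed + 1L, {
      vapply(seq_len(n_draw), function(b) {
        idx <- sample.int(n, k)
        full - ivw(d[idx, , drop = FALSE])$estimate
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_draw + 1)
  }

  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 corrected = corrected, distortion_p = distortion_p,
                 n_sim = n_sim, seed = seed, n_snps = n),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS = %.4g, p = %s (%d sims)\n",
              x$rss_obs, .fmt_p(x$global_p), x$n_sim))
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected)) print(x$corrected)
    if (!is.na(x$distortion_p)) {
      cat(sprintf("  distortion p = %s (informational)\n",
                  .fmt_p(x$distortion_p)))
    }
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}
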