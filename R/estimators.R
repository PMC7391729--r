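# MR estimators: Wald ratio, IVW, Egger regression, weighted/simple median,
# Cochran's Q. MR-PRESSO lives in presso.R.

#' Construct an MR estimate
#'
#' Applies the package's reporting convention: 95% normal interval and,
#' unless `pvalue` is supplied (Egger uses a t reference), a two-sided
#' normal p-value. See [ci_and_p()].
#'
#' @param method Estimator label.
#' @param estimate,se Point estimate and standard error.
#' @param n_snps Number of instruments used.
#' @param pvalue Optional p-value overriding the normal default.
#' @return An `mr_estimate` list.
#' @export
mr_estimate <- function(method, estimate, se, n_snps, pvalue = NULL) {
  cp <- ci_and_p(estimate, se)
  structure(list(method = method, estimate = estimate, se = se,
                 ci_low = cp$ci_low, ci_high = cp$ci_high,
                 pvalue = pvalue %||% cp$pvalue, n_snps = n_snps),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: %.4g (SE %.4g), 95%% CI (%.4g; %.4g), p = %s, nSNP = %d\n",
              x$method, x$estimate, x$se, x$ci_low, x$ci_high,
              .fmt_p(x$pvalue), x$n_snps))
  invisible(x)
}

.as_pairs <- function(pairs) {
  d <- as.data.frame(pairs)
  need <- c("bx", "sx", "by", "sy")
  if (!all(need %in% names(d))) {
    stop("harmonized pairs need columns bx, sx, by, sy", call. = FALSE)
  }
  d
}

#' Wald ratio estimate from a single instrument
#'
#' `estimate = by / bx`. The first-order delta-method standard error is
#' `sy / |bx|`; the second-order one adds the uncertainty of the exposure
#' effect, `sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)`.
#'
#' @param pair One harmonized pair (a one-row data.frame or a list with
#'   `bx`, `sx`, `by`, `sy`).
#' @param order `"first"` (default) or `"second"` delta-method expansion.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(pair, order = c("first", "second")) {
  order <- match.arg(order)
  bx <- pair$bx; sx <- pair$sx; by <- pair$by; sy <- pair$sy
  stopifnot(length(bx) == 1)
  if (bx == 0) stop("instrument has no exposure effect (bx = 0)",
                    call. = FALSE)
  est <- by / bx
  se <- if (order == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  mr_estimate("Wald ratio", est, se, n_snps = 1L)
}

#' Inverse variance weighted estimate
#'
#' Combines per-instrument Wald ratios `r_i = by_i / bx_i` with first-order
#' weights `w_i = bx_i^2 / sy_i^2`; algebraically the weighted least-squares
#' slope of `by` on `bx` through the origin. With a single pair it reduces
#' exactly to the first-order Wald ratio.
#'
#' @param pairs Harmonized pairs ([harmonize()] output or
#'   [harmonized_pairs()]); pairs with `bx = 0` are excluded with a message.
#' @param mode `"fixed"` (default): `se = 1 / sqrt(sum(w))`;
#'   `"random"` (multiplicative random effects): fixed-effect `se`
#'   inflated by `sqrt(max(1, Q / (n - 1)))`.
#' @return An `mr_estimate`.
#' @export
ivw <- function(pairs, mode = c("fixed", "random")) {
  mode <- match.arg(mode)
  d <- .as_pairs(pairs)
  if (any(d$bx == 0)) {
    message(sprintf("ivw: excluding %d pair(s) with bx = 0",
                    sum(d$bx == 0)))
    d <- d[d$bx != 0, , drop = FALSE]
  }
  n <- nrow(d)
  if (n < 1) stop("ivw needs at least one pair with bx != 0", call. = FALSE)
  w <- d$bx^2 / d$sy^2
  r <- d$by / d$bx
  if (n == 1) {
    # exact reduction to the first-order Wald ratio
    est <- r
    se <- d$sy / abs(d$bx)
  } else {
    est <- sum(w * r) / sum(w)
    se <- 1 / sqrt(sum(w))
  }
  if (mode == "random" && n >= 2) {
    q <- sum(w * (r - est)^2)
    se <- se * sqrt(max(1, q / (n - 1)))
  }
  lab <- if (mode == "fixed") "IVW" else "IVW (multiplicative random effects)"
  mr_estimate(lab, est, se, n_snps = n)
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with an intercept and weights
#' `1 / sy^2`, after orienting every pair so that `bx >= 0`. The slope is
#' the pleiotropy-adjusted causal estimate; a non-zero intercept indicates
#' average directional pleiotropy. Standard errors come from the weighted
#' regression and p-values use a t reference on `n - 2` degrees of freedom.
#'
#' @param pairs Harmonized pairs; at least 3 are required, otherwise a
#'   not-feasible result is returned (rendered `NA` downstream).
#' @return An `egger_result` with components `slope` (an `mr_estimate`),
#'   `intercept` (estimate, se, pvalue), `df` and `feasible`.
#' @export
egger <- function(pairs) {
  d <- .as_pairs(pairs)
  n <- nrow(d)
  if (n < 3) {
    return(structure(list(feasible = FALSE, n_snps = n, slope = NULL,
                          intercept = NULL, df = NA_integer_),
                     class = "egger_result"))
  }
  flip <- sign(d$bx); flip[flip == 0] <- 1
  x <- flip * d$bx
  y <- flip * d$by
  w <- 1 / d$sy^2
  fit <- stats::lm(y ~ x, weights = w)
  cf <- summary(fit)$coefficients
  df <- n - 2L
  slope_p <- 2 * stats::pt(-abs(cf["x", "t value"]), df)
  int_p <- 2 * stats::pt(-abs(cf["(Intercept)", "t value"]), df)
  structure(list(
    feasible = TRUE,
    n_snps = n,
    slope = mr_estimate("MR-Egger", cf["x", "Estimate"],
                        cf["x", "Std. Error"], n_snps = n, pvalue = slope_p),
    intercept = list(estimate = cf["(Intercept)", "Estimate"],
                     se = cf["(Intercept)", "Std. Error"],
                     pvalue = int_p),
    df = df
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("MR-Egger: NA (not feasible, %d instrument(s) < 3)\n",
                x$n_snps))
    return(invisible(x))
  }
  print(x$slope)
  cat(sprintf("  intercept: %.4g (SE %.4g), p = %s [df = %d]\n",
              x$intercept$estimate, x$intercept$se,
              .fmt_p(x$intercept$pvalue), x$df))
  invisible(x)
}

#' Median-based estimate
#'
#' Simple or weighted median of the per-instrument ratio estimates. The
#' weighted median interpolates the ratio at which the cumulative
#' normalized inverse-variance weight crosses one half; with equal weights
#' it coincides with the simple median. The standard error is the standard
#' deviation of the estimate over `n_boot` parametric bootstrap draws of
#' `(bx_i, by_i)` from their normal sampling distributions.
#'
#' @param pairs Harmonized pairs; at least 3 required, otherwise a
#'   not-feasible result (`NULL` estimate, `feasible = FALSE` attribute) is
#'   returned.
#' @param weighted Use inverse-variance weights (default `TRUE`).
#' @param n_boot Bootstrap replicates for the SE (default 5000).
#' @param seed RNG seed for the bootstrap (restored on exit).
#' @return An `mr_estimate`, or a not-feasible `egger_result`-style stub
#'   when fewer than 3 pairs are available.
#' @export
median_estimate <- function(pairs, weighted = TRUE, n_boot = 5000,
                            seed = NULL) {
  d <- .as_pairs(pairs)
  n <- nrow(d)
  if (n < 3) {
    return(structure(list(feasible = FALSE, n_snps = n),
                     class = "mr_not_feasible"))
  }
  est <- .weighted_median_point(d, weighted)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      db <- d
      db$bx <- stats::rnorm(n, d$bx, d$sx)
      db$by <- stats::rnorm(n, d$by, d$sy)
      .weighted_median_point(db, weighted)
    }, numeric(1))
  })
  lab <- if (weighted) "Weighted median" else "Simple median"
  mr_estimate(lab, est, stats::sd(boots), n_snps = n)
}

# Point estimate: interpolated weighted median of the ratio estimates.
.weighted_median_point <- function(d, weighted) {
  r <- d$by / d$bx
  w <- if (weighted) d$bx^2 / d$sy^2 else rep(1, length(r))
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i * (r_i - theta)^2)` over the per-instrument ratio estimates
#' with first-order IVW weights, referred to a chi-square distribution on
#' `n - 1` degrees of freedom.
#'
#' @param pairs Harmonized pairs (at least 2).
#' @param reference The pooled estimate the ratios are compared against; an
#'   `mr_estimate` or a number. Defaults to the fixed-effect IVW estimate.
#' @return A `q_result` list with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(pairs, reference = NULL) {
  d <- .as_pairs(pairs)
  d <- d[d$bx != 0, , drop = FALSE]
  n <- nrow(d)
  if (n < 2) stop("cochran_q needs at least 2 pairs", call. = FALSE)
  theta <- if (is.null(reference)) ivw(d)$estimate
           else if (inherits(reference, "mr_estimate")) reference$estimate
           else as.numeric(reference)
  w <- d$bx^2 / d$sy^2
  r <- d$by / d$bx
  q <- sum(w * (r - theta)^2)
  structure(list(q = q, df = n - 1L,
                 pvalue = stats::pchisq(q, df = n - 1, lower.tail = FALSE)),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %s\n",
              x$q, x$df, .fmt_p(x$pvalue)))
  invisible(x)
}
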