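# Shared internal helpers and the normal-approximation CI/p convention.

# 97.5% normal quantile used for every 95% interval in the package.
.Z95 <- 1.959964

#' Normal-approximation confidence interval and p-value
#'
#' The reporting convention used throughout: a 95% interval
#' `estimate +/- 1.959964 * se` and a two-sided p-value
#' `2 * pnorm(-abs(estimate / se))`.
#'
#' @param estimate Numeric estimate(s).
#' @param se Positive standard error(s), recycled against `estimate`.
#' @return A list with components `ci_low`, `ci_high` and `pvalue`.
#' @examples
#' ci_and_p(-0.16, 0.03)
#' @export
ci_and_p <- function(estimate, se) {
  if (!is.numeric(estimate) || !is.numeric(se)) {
    stop("`estimate` and `se` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("`se` must be finite and > 0", call. = FALSE)
  }
  list(
    ci_low  = estimate - .Z95 * se,
    ci_high = estimate + .Z95 * se,
    pvalue  = 2 * stats::pnorm(-abs(estimate / se))
  )
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA complement for single-nucleotide alleles.
.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) unname(.COMPLEMENT[a1] == a2)
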