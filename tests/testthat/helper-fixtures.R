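# Builders shared across the test files. All fixtures are constructed in
# code; nothing is read from disk except what a test itself writes.

# Quick sumstats table; defaults give valid, non-palindromic SNPs.
mk_stats <- function(n = 3, trait_id = "trait", source_id = "study",
                     rsid = sprintf("rs%03d", seq_len(n)),
                     effect_allele = rep("A", n), other_allele = rep("G", n),
                     beta = rep(0.1, n), se = rep(0.01, n),
                     pvalue = rep(1e-10, n), eaf = rep(0.3, n),
                     nn = rep(1000, n), strict = TRUE) {
  sumstats(data.frame(rsid = rsid, effect_allele = effect_allele,
                      other_allele = other_allele, beta = beta, se = se,
                      pvalue = pvalue, eaf = eaf, n = nn,
                      stringsAsFactors = FALSE),
           trait_id = trait_id, source_id = source_id, strict = strict)
}

# Random harmonized pairs around a true ratio theta; invalid instruments
# (direct outcome effects) can be planted via `alpha`.
mk_pairs <- function(n, theta = 0.2, sx = 0.01, sy = 0.02,
                     alpha = rep(0, n), seed = NULL) {
  gen <- function() {
    gamma <- runif(n, 0.1, 0.4) * sample(c(-1, 1), n, replace = TRUE)
    bx <- rnorm(n, gamma, sx)
    by <- rnorm(n, theta * gamma + alpha, sy)
    harmonized_pairs(sprintf("rs%03d", seq_len(n)), bx, rep(sx, n), by,
                     rep(sy, n))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Independent oracle: weighted least squares by explicit normal equations.
# Returns coefficients, their SEs (dispersion estimated on n - p df) and
# t statistics. `intercept = FALSE` fits through the origin.
oracle_wls <- function(x, y, w, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  W <- diag(w, nrow = length(w))
  xtwx <- t(X) %*% W %*% X
  coef <- solve(xtwx, t(X) %*% W %*% y)
  resid <- y - X %*% coef
  df <- length(y) - ncol(X)
  sigma2 <- sum(w * resid^2) / df
  se <- unname(sqrt(diag(sigma2 * solve(xtwx))))
  list(coef = as.vector(coef), se = se, df = df,
       t = as.vector(coef) / se)
}

# Write a small tab-delimited file and return its path.
write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
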