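# Wald ratio, IVW, Egger, median, Cochran's Q and the CI/p convention.

test_that("Wald ratio arithmetic and delta-method orders", {
  pair <- harmonized_pairs("rs1", bx = 0.5, sx = 0.02, by = 0.1, sy = 0.05)
  w1 <- wald_ratio(pair)
  expect_equal(w1$estimate, 0.2)
  expect_equal(w1$se, 0.1)
  expect_equal(w1$n_snps, 1)

  w2 <- wald_ratio(pair, order = "second")
  expect_equal(w2$se, sqrt(0.05^2 / 0.5^2 + 0.1^2 * 0.02^2 / 0.5^4))
  expect_gt(w2$se, w1$se)

  null <- wald_ratio(harmonized_pairs("rs1", 0.5, 0.02, 0, 0.05))
  expect_equal(null$estimate, 0)
  expect_equal(null$pvalue, 1)

  expect_error(wald_ratio(harmonized_pairs("rs1", 0, 0.02, 0.1, 0.05)),
               "no exposure effect")
})

test_that("second-order Wald SE matches a Monte-Carlo delta-method oracle", {
  bx <- 0.5; sx <- 0.02; by <- 0.1; sy <- 0.05
  mc_sd <- withr::with_seed(101, {
    sd(rnorm(1e6, by, sy) / rnorm(1e6, bx, sx))
  })
  w2 <- wald_ratio(harmonized_pairs("rs1", bx, sx, by, sy),
                   order = "second")
  expect_equal(w2$se, mc_sd, tolerance = 0.02)
})

test_that("IVW reduces to the Wald ratio and scales with duplicated pairs", {
  pair <- harmonized_pairs("rs1", 0.5, 0.02, 0.1, 0.05)
  w <- wald_ratio(pair)
  i1 <- ivw(pair)
  expect_equal(i1$estimate, w$estimate)
  expect_equal(i1$se, w$se)

  two <- harmonized_pairs(c("rs1", "rs2"), c(0.5, 0.5), 0.02, c(0.1, 0.1),
                          0.05)
  i2 <- ivw(two)
  expect_equal(i2$estimate, i1$estimate)
  expect_equal(i2$se, i1$se / sqrt(2))
})

test_that("IVW and Egger match brute-force weighted least squares on 50 random fixtures", {
  withr::with_seed(202, {
    for (rep in 1:50) {
      n <- sample(4:30, 1)
      d <- mk_pairs(n, theta = runif(1, -0.5, 0.5), sx = 0.02, sy = 0.05,
                    alpha = rnorm(n, 0, 0.02))
      # IVW == WLS of by on bx through the origin, weights 1/sy^2
      o <- oracle_wls(d$bx, d$by, 1 / d$sy^2, intercept = FALSE)
      i <- ivw(d)
      expect_equal(i$estimate, o$coef[1], tolerance = 1e-10)

      # Egger == WLS with intercept after orienting bx >= 0
      flip <- ifelse(d$bx < 0, -1, 1)
      oe <- oracle_wls(flip * d$bx, flip * d$by, 1 / d$sy^2,
                       intercept = TRUE)
      e <- egger(d)
      expect_equal(e$slope$estimate, oe$coef[2], tolerance = 1e-8)
      expect_equal(e$intercept$estimate, oe$coef[1], tolerance = 1e-8)
      expect_equal(e$slope$se, oe$se[2], tolerance = 1e-8)
      expect_equal(e$intercept$se, oe$se[1], tolerance = 1e-8)
      expect_equal(e$slope$pvalue, 2 * pt(-abs(oe$t[2]), n - 2),
                   tolerance = 1e-8)
    }
  })
})

test_that("Egger recovers exact affine relations and refuses n < 3", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  sx <- rep(0.01, 4); sy <- c(0.02, 0.03, 0.02, 0.05)
  exact <- harmonized_pairs(sprintf("rs%d", 1:4), bx, sx, 0.3 * bx, sy)
  e <- egger(exact)
  expect_equal(e$slope$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept$estimate, 0, tolerance = 1e-10)

  affine <- harmonized_pairs(sprintf("rs%d", 1:4), bx, sx,
                             0.05 + 0.3 * bx, sy)
  e2 <- egger(affine)
  expect_equal(e2$slope$estimate, 0.3, tolerance = 1e-10)
  expect_equal(e2$intercept$estimate, 0.05, tolerance = 1e-10)

  small <- harmonized_pairs(c("rs1", "rs2"), c(0.1, 0.2), 0.01,
                            c(0.02, 0.04), 0.02)
  enf <- egger(small)
  expect_false(enf$feasible)
  expect_null(enf$slope)
})

test_that("median estimators: point values and degenerate weights", {
  # ratios 0.1, 0.2, 0.3 with equal weights -> 0.2
  d <- harmonized_pairs(sprintf("rs%d", 1:3), bx = c(1, 1, 1), sx = 0.01,
                        by = c(0.1, 0.2, 0.3), sy = 0.05)
  m <- median_estimate(d, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(m$estimate, 0.2)

  # equal weights: weighted mode == simple mode on any fixture
  withr::with_seed(303, {
    for (rep in 1:5) {
      n <- sample(c(3, 5, 8), 1)
      d <- harmonized_pairs(sprintf("rs%d", seq_len(n)), bx = rep(0.4, n),
                            sx = 0.01, by = rnorm(n, 0.1, 0.1),
                            sy = rep(0.03, n))
      mw <- median_estimate(d, weighted = TRUE, n_boot = 100, seed = rep)
      ms <- median_estimate(d, weighted = FALSE, n_boot = 100, seed = rep)
      expect_equal(mw$estimate, ms$estimate)
    }
  })

  expect_false(median_estimate(d[1:2, ], n_boot = 100, seed = 1)$feasible)
})

test_that("weighted median recovers truth with 60% valid instruments", {
  theta <- 0.25
  hits <- withr::with_seed(404, {
    vapply(1:200, function(rep) {
      n <- 10
      alpha <- c(rep(0, 6), runif(4, 0.05, 0.15))  # 40% invalid
      d <- mk_pairs(n, theta = theta, sx = 0.01, sy = 0.02, alpha = alpha)
      m <- median_estimate(d, weighted = TRUE, n_boot = 400,
                           seed = 5000 + rep)
      abs(m$estimate - theta) <= 3 * m$se
    }, logical(1))
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Cochran's Q: exact zero, permutation invariance, null calibration", {
  d <- harmonized_pairs(sprintf("rs%d", 1:4), bx = c(0.1, 0.2, 0.3, 0.4),
                        sx = 0.01, by = 0.3 * c(0.1, 0.2, 0.3, 0.4),
                        sy = 0.05)
  q <- cochran_q(d)
  expect_equal(q$q, 0)
  expect_equal(q$pvalue, 1)
  expect_equal(q$df, 3)

  dd <- mk_pairs(8, seed = 11)
  q1 <- cochran_q(dd)
  q2 <- cochran_q(dd[sample(8), ])
  expect_equal(q1$q, q2$q)

  # under a homogeneous null the p-values are uniform (KS at alpha = 0.01)
  pvals <- withr::with_seed(505, {
    vapply(1:2000, function(i) {
      n <- 12
      gamma <- runif(n, 0.15, 0.4)
      sy <- 0.03
      # exact ratio homogeneity: only outcome noise, fixed bx
      d <- harmonized_pairs(sprintf("rs%d", 1:n), gamma, 1e-6,
                            rnorm(n, 0.2 * gamma, sy), sy)
      cochran_q(d, reference = ivw(d))$pvalue
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ci_and_p reproduces printed interval bounds and the null centre", {
  # estimate (SE) pairs -> printed 95% bounds where rounding permits
  expect_equal(round(ci_and_p(-0.16, 0.03)$ci_low, 2), -0.22)
  expect_equal(round(ci_and_p(-0.26, 0.06)$ci_low, 2), -0.38)
  expect_equal(round(ci_and_p(-0.05, 0.07)$ci_low, 2), -0.19)
  expect_equal(round(ci_and_p(-0.05, 0.07)$ci_high, 2), 0.09)

  cp <- ci_and_p(0, 0.3)
  expect_equal(cp$pvalue, 1)
  expect_equal(cp$ci_low, -cp$ci_high)
  expect_error(ci_and_p(0.1, 0), "se")
})

test_that("mr_estimate invariants: CI arithmetic and normal p", {
  withr::with_seed(77, {
    est <- rnorm(20); se <- runif(20, 0.01, 1)
    for (i in 1:20) {
      m <- mr_estimate("x", est[i], se[i], 5L)
      expect_equal(m$ci_low, est[i] - 1.959964 * se[i], tolerance = 1e-12)
      expect_equal(m$ci_high, est[i] + 1.959964 * se[i], tolerance = 1e-12)
      expect_true(m$ci_low <= m$estimate && m$estimate <= m$ci_high)
      expect_equal(m$pvalue, 2 * pnorm(-abs(est[i] / se[i])))
    }
  })
})

test_that("scale and sign equivariance of the estimators", {
  d <- mk_pairs(8, theta = 0.3, seed = 21)
  c_ <- 3.7
  scale_y <- d; scale_y$by <- c_ * d$by; scale_y$sy <- c_ * d$sy
  scale_x <- d; scale_x$bx <- c_ * d$bx; scale_x$sx <- c_ * d$sx
  neg_y <- d; neg_y$by <- -d$by

  for (f in list(ivw, function(p) egger(p)$slope)) {
    base <- f(d)
    expect_equal(f(scale_y)$estimate, c_ * base$estimate)
    expect_equal(f(scale_y)$se, c_ * base$se)
    expect_equal(f(scale_x)$estimate, base$estimate / c_)
    expect_equal(f(neg_y)$estimate, -base$estimate)
    expect_equal(f(neg_y)$pvalue, base$pvalue)
  }
})

test_that("multiplicative random-effects IVW inflates the SE under heterogeneity only", {
  hom <- harmonized_pairs(sprintf("rs%d", 1:5), bx = rep(0.3, 5),
                          sx = 0.01, by = rep(0.06, 5), sy = 0.03)
  expect_equal(ivw(hom, mode = "random")$se, ivw(hom)$se)  # Q < df

  het <- mk_pairs(10, theta = 0.2, sy = 0.01,
                  alpha = rnorm(10, 0, 0.1), seed = 31)
  fixed <- ivw(het); random <- ivw(het, mode = "random")
  q <- cochran_q(het, fixed)
  expect_equal(random$se, fixed$se * sqrt(q$q / 9))
  expect_gt(random$se, fixed$se)
  expect_equal(random$estimate, fixed$estimate)
})
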