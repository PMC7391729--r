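# Synthetic two-sample GWAS generator with known ground truth.
#
# Structural model: for SNP dosages G_j (Binomial(2, maf_j)), confounder U
# and noise e (standard normal),
#   X = sum_j gamma_j G_j + c_x U + e_x
#   Y = theta X + sum_j alpha_j G_j + c_y U + e_y
# with noise variances scaled so X and Y have unit variance in expectation.
# Exposure and outcome associations are measured in two independent samples
# (marginal simple regression per SNP, the GWAS convention), exactly the
# two-sample design the estimators assume.

#' Configure a two-sample GWAS simulation
#'
#' @param m Number of candidate SNPs.
#' @param n_exposure,n_outcome Sizes of the two non-overlapping samples.
#' @param h2x Variance of the exposure explained by the SNPs jointly
#'   (`[0, 1)`); per-SNP effects `gamma` are drawn standard normal and
#'   rescaled to this budget (`h2x = 0` gives all-null SNPs).
#' @param theta True causal effect of exposure on outcome.
#' @param maf_range Minor-allele-frequency bounds, within `(0, 0.5]`.
#' @param pleio_frac Fraction of SNPs given direct (horizontally
#'   pleiotropic) outcome effects.
#' @param pleio_mean,pleio_sd Normal distribution of those direct effects,
#'   expressed relative to the exposure-increasing allele; mean 0 is
#'   balanced pleiotropy, non-zero is directional.
#' @param confounder_x,confounder_y Loadings of the shared confounder.
#' @param n_outliers Number of SNPs given large direct effects sized for
#'   outlier-detection tests: `outlier_mult` times the SNP's expected
#'   outcome standard error (so the ratio estimate shifts by about
#'   `outlier_mult` residual SDs).
#' @param outlier_mult Outlier direct-effect multiplier (default 8).
#' @param gamma_dist `"normal"` (default): per-SNP exposure effects drawn
#'   standard normal before rescaling, giving a realistic spread of
#'   instrument strengths; `"fixed"`: equal-magnitude effects (random
#'   sign), giving uniformly strong instruments that all survive
#'   genome-wide selection.
#' @param ld_blocks Optional list of `list(size =, r =)` blocks of adjacent
#'   SNPs with pairwise haplotype correlation `r` (individual mode only;
#'   the realized genotype R-squared is attenuated relative to `r`).
#' @param palindrome_frac Fraction of SNPs given palindromic (A/T or G/C)
#'   allele pairs.
#' @param swap_frac Fraction of outcome-table rows reported with
#'   effect/other allele orientation swapped.
#' @param flip_frac Fraction of outcome-table rows reported on the
#'   opposite strand.
#' @param mode `"individual"` (default): summary statistics computed from
#'   simulated individual-level data, so beta, se, p, eaf and LD are
#'   mutually coherent. `"asymptotic"`: effect estimates drawn directly
#'   from their normal sampling distributions
#'   (`se = 1 / sqrt(n * 2 maf (1 - maf))` for unit-variance traits) —
#'   much faster, for large-replicate property tests; `ld_blocks` is
#'   ignored in this mode.
#' @param seed Mandatory seed for the shared parameters;
#'   `exposure_seed`/`outcome_seed` (defaults `seed + 1`, `seed + 2`)
#'   drive the two samples' independent noise streams.
#' @param exposure_seed,outcome_seed Optional stream overrides.
#' @return A `sim_config` list.
#' @export
sim_config <- function(m, n_exposure, n_outcome, h2x, theta,
                       maf_range = c(0.05, 0.5), pleio_frac = 0,
                       pleio_mean = 0, pleio_sd = 0, confounder_x = 0,
                       confounder_y = 0, n_outliers = 0, outlier_mult = 8,
                       gamma_dist = c("normal", "fixed"),
                       ld_blocks = NULL, palindrome_frac = 0.1,
                       swap_frac = 0.25, flip_frac = 0.15,
                       mode = c("individual", "asymptotic"), seed,
                       exposure_seed = NULL, outcome_seed = NULL) {
  mode <- match.arg(mode)
  gamma_dist <- match.arg(gamma_dist)
  if (missing(seed) || is.null(seed)) {
    stop("sim_config requires an explicit `seed`", call. = FALSE)
  }
  stopifnot(m >= 1, n_exposure >= 10, n_outcome >= 10,
            h2x >= 0, h2x < 1, pleio_frac >= 0, pleio_frac <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], n_outliers >= 0,
            n_outliers <= m)
  if (h2x + confounder_x^2 >= 1) {
    stop("infeasible variance budget: h2x + confounder_x^2 must be < 1",
         call. = FALSE)
  }
  structure(list(m = m, n_exposure = n_exposure, n_outcome = n_outcome,
                 h2x = h2x, theta = theta, maf_range = maf_range,
                 pleio_frac = pleio_frac, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, confounder_x = confounder_x,
                 confounder_y = confounder_y, n_outliers = n_outliers,
                 outlier_mult = outlier_mult, gamma_dist = gamma_dist,
                 ld_blocks = ld_blocks,
                 palindrome_frac = palindrome_frac, swap_frac = swap_frac,
                 flip_frac = flip_frac, mode = mode, seed = seed,
                 exposure_seed = exposure_seed %||% (seed + 1L),
                 outcome_seed = outcome_seed %||% (seed + 2L)),
            class = "sim_config")
}

#' Simulate a two-sample GWAS
#'
#' @param config A [sim_config()].
#' @return A list with components `exposure` and `outcome` ([sumstats]
#'   tables), `ld` (an [ld_table]; realized genotype R-squared at or above
#'   0.01 in individual mode), and `truth` (per-SNP `gamma`, `alpha`,
#'   `theta`, `mafs`, `outlier_ids`, `pleio_ids`, allele assignment) —
#'   the truth is for tests only, estimators never see it.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  shared <- with_seed(cfg$seed, .sim_shared_params(cfg))
  if (cfg$mode == "individual") {
    ex <- with_seed(cfg$exposure_seed,
                    .sim_sample_individual(cfg, shared, role = "exposure"))
    out <- with_seed(cfg$outcome_seed,
                     .sim_sample_individual(cfg, shared, role = "outcome"))
    ld <- ex$ld
  } else {
    ex <- with_seed(cfg$exposure_seed, .sim_sample_asymptotic(cfg, shared,
                                                              "exposure"))
    out <- with_seed(cfg$outcome_seed, .sim_sample_asymptotic(cfg, shared,
                                                              "outcome"))
    ld <- ld_table()
  }
  exposure <- .report_sumstats(shared, ex, trait_id = "exposure",
                               source_id = "sim_exposure_study",
                               swap = rep(FALSE, cfg$m),
                               flip = rep(FALSE, cfg$m))
  outcome <- .report_sumstats(shared, out, trait_id = "outcome",
                              source_id = "sim_outcome_study",
                              swap = shared$swap, flip = shared$flip)
  list(exposure = exposure, outcome = outcome, ld = ld,
       truth = list(gamma = shared$gamma, alpha = shared$alpha,
                    theta = cfg$theta, mafs = shared$mafs,
                    outlier_ids = shared$outlier_ids,
                    pleio_ids = shared$pleio_ids,
                    rsid = shared$rsid, a1 = shared$a1, a2 = shared$a2))
}

# Parameters shared by both samples (drawn under the config's main seed).
.sim_shared_params <- function(cfg) {
  m <- cfg$m
  rsid <- sprintf("rs%05d", seq_len(m))
  mafs <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  v <- 2 * mafs * (1 - mafs)

  gamma <- if (identical(cfg$gamma_dist, "fixed")) {
    sample(c(-1, 1), m, replace = TRUE)
  } else {
    stats::rnorm(m)
  }
  if (cfg$h2x > 0) {
    gamma <- gamma * sqrt(cfg$h2x / sum(v * gamma^2))
  } else {
    gamma <- rep(0, m)
  }

  alpha <- rep(0, m)
  pleio_ids <- character(0)
  n_pleio <- round(cfg$pleio_frac * m)
  if (n_pleio > 0) {
    idx <- sample.int(m, n_pleio)
    # direct effects are expressed relative to the exposure-increasing
    # allele: a non-zero mean then acts directionally on the ratio scale
    # instead of cancelling across arbitrary allele codings
    orient <- sign(gamma[idx]); orient[orient == 0] <- 1
    alpha[idx] <- orient * stats::rnorm(n_pleio, cfg$pleio_mean, cfg$pleio_sd)
    pleio_ids <- rsid[idx]
  }
  outlier_ids <- character(0)
  if (cfg$n_outliers > 0) {
    # spare the pleiotropic SNPs so the two mechanisms stay distinguishable
    pool <- setdiff(seq_len(m), match(pleio_ids, rsid))
    idx <- sample(pool, min(cfg$n_outliers, length(pool)))
    se_y_expect <- sqrt(1 / (cfg$n_outcome * v[idx]))
    alpha[idx] <- cfg$outlier_mult * se_y_expect *
      sample(c(-1, 1), length(idx), replace = TRUE)
    outlier_ids <- rsid[idx]
  }

  al <- .assign_allele_pairs(m, cfg$palindrome_frac)
  list(rsid = rsid, mafs = mafs, v = v, gamma = gamma, alpha = alpha,
       pleio_ids = pleio_ids, outlier_ids = outlier_ids,
       a1 = al$a1, a2 = al$a2,
       swap = stats::runif(m) < cfg$swap_frac,
       flip = stats::runif(m) < cfg$flip_frac)
}

# Random allele pairs; a1 is the counted (true effect) allele.
.assign_allele_pairs <- function(m, palindrome_frac) {
  bases <- c("A", "C", "G", "T")
  pal <- stats::runif(m) < palindrome_frac
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- character(m)
  a2[pal] <- unname(.COMPLEMENT[a1[pal]])
  for (i in which(!pal)) {
    a2[i] <- sample(setdiff(bases, c(a1[i], .COMPLEMENT[a1[i]])), 1)
  }
  list(a1 = a1, a2 = a2)
}

# Genotype matrix with optional compound-symmetric LD blocks (latent
# Gaussian haplotypes thresholded at the allele frequency).
.sim_genotypes <- function(n, mafs, ld_blocks) {
  m <- length(mafs)
  g <- matrix(stats::rbinom(n * m, 2, rep(mafs, each = n)), nrow = n)
  if (!is.null(ld_blocks)) {
    at <- 1L
    for (blk in ld_blocks) {
      size <- blk$size; r <- blk$r
      idx <- seq.int(at, length.out = size)
      if (max(idx) > m) stop("ld_blocks exceed m", call. = FALSE)
      for (hap in 1:2) {
        common <- stats::rnorm(n)
        z <- sqrt(r) * matrix(common, n, size) +
          sqrt(1 - r) * matrix(stats::rnorm(n * size), n, size)
        alle <- sweep(z, 2, stats::qnorm(1 - mafs[idx]), `>`)
        if (hap == 1) block_g <- alle else block_g <- block_g + alle
      }
      g[, idx] <- block_g
      at <- at + size
    }
  }
  g
}

# One sample's summary statistics from individual-level data.
.sim_sample_individual <- function(cfg, shared, role) {
  n <- if (role == "exposure") cfg$n_exposure else cfg$n_outcome
  g <- .sim_genotypes(n, shared$mafs, cfg$ld_blocks)
  u <- stats::rnorm(n)
  sd_ex <- sqrt(1 - cfg$h2x - cfg$confounder_x^2)
  x <- as.vector(g %*% shared$gamma) + cfg$confounder_x * u +
    stats::rnorm(n, sd = sd_ex)
  trait <- if (role == "exposure") {
    x
  } else {
    v <- shared$v
    var_extra <- cfg$theta^2 + sum(v * shared$alpha^2) +
      2 * cfg$theta * sum(v * shared$gamma * shared$alpha) +
      cfg$confounder_y^2 + 2 * cfg$theta * cfg$confounder_x * cfg$confounder_y
    sd_ey2 <- 1 - var_extra
    if (sd_ey2 <= 1e-6) {
      stop("infeasible variance budget on the outcome side", call. = FALSE)
    }
    cfg$theta * x + as.vector(g %*% shared$alpha) +
      cfg$confounder_y * u + stats::rnorm(n, sd = sqrt(sd_ey2))
  }
  stats_tab <- .marginal_stats(g, trait)
  out <- list(beta = stats_tab$beta, se = stats_tab$se, p = stats_tab$p,
              eaf = colMeans(g) / 2, n = n)
  if (role == "exposure") {
    r2 <- stats::cor(g)^2
    keep <- which(upper.tri(r2) & r2 >= 0.01, arr.ind = TRUE)
    out$ld <- if (nrow(keep)) {
      ld_table(data.frame(rsid_a = shared$rsid[keep[, 1]],
                          rsid_b = shared$rsid[keep[, 2]],
                          r2 = pmin(r2[keep], 1)))
    } else {
      ld_table()
    }
  }
  out
}

# Per-SNP marginal simple regression of trait on dosage, vectorized.
.marginal_stats <- function(g, trait) {
  n <- nrow(g)
  gc <- sweep(g, 2, colMeans(g))
  tc <- trait - mean(trait)
  sxx <- colSums(gc^2)
  sxx[sxx == 0] <- NA_real_
  beta <- as.vector(crossprod(gc, tc)) / sxx
  rss <- sum(tc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  z <- beta / se
  list(beta = beta, se = se, p = pmax(2 * stats::pnorm(-abs(z)), 1e-320))
}

# One sample's summary statistics drawn from the asymptotic sampling
# distribution of the marginal estimates (independent SNPs).
.sim_sample_asymptotic <- function(cfg, shared, role) {
  n <- if (role == "exposure") cfg$n_exposure else cfg$n_outcome
  mean_beta <- if (role == "exposure") shared$gamma else
    cfg$theta * shared$gamma + shared$alpha
  se <- sqrt(1 / (n * shared$v))
  beta <- stats::rnorm(cfg$m, mean_beta, se)
  z <- beta / se
  list(beta = beta, se = se, p = pmax(2 * stats::pnorm(-abs(z)), 1e-320),
       eaf = shared$mafs, n = n)
}

# Assemble a reported sumstats table, applying orientation swaps and strand
# flips to exercise harmonization (swap negates beta and reflects eaf;
# flip complements the reported alleles and changes no number).
.report_sumstats <- function(shared, sample_stats, trait_id, source_id,
                             swap, flip) {
  ea <- ifelse(swap, shared$a2, shared$a1)
  oa <- ifelse(swap, shared$a1, shared$a2)
  ea <- ifelse(flip, unname(.COMPLEMENT[ea]), ea)
  oa <- ifelse(flip, unname(.COMPLEMENT[oa]), oa)
  beta <- ifelse(swap, -sample_stats$beta, sample_stats$beta)
  eaf <- ifelse(swap, 1 - sample_stats$eaf, sample_stats$eaf)
  eaf <- pmin(pmax(eaf, 1e-6), 1 - 1e-6)
  sumstats(data.frame(rsid = shared$rsid, effect_allele = ea,
                      other_allele = oa, beta = beta, se = sample_stats$se,
                      pvalue = sample_stats$p, eaf = eaf,
                      n = sample_stats$n, stringsAsFactors = FALSE),
           trait_id = trait_id, source_id = source_id)
}

#' Bundled fixture registry emulating the study regimes
#'
#' A deterministic synthetic stand-in for the real multi-study setting:
#' one complex kidney-function-like trait (`"egfr"`) with 79 independent
#' genome-wide-significant SNPs (75 primaries plus 4 tags in mild LD,
#' R-squared 0.1, with their primaries) measured at meta-analysis scale
#' (n = 133,413), and four metabolite-like traits with 1, 2, 5 and 22
#' planted instruments at metabolite-GWAS sample sizes (n = 1,960-7,824;
#' per-instrument F statistics in the tens-to-hundreds). The true causal
#' structure is reverse-only: the complex trait lowers every metabolite
#' (theta = -0.2) while no metabolite affects the complex trait. One
#' instrument is shared between two metabolite traits to exercise the
#' cross-trait overlap screen. Summary statistics are drawn in asymptotic
#' mode; all tables carry allele swaps, strand flips and palindromic SNPs.
#'
#' @param seed Seed; the registry is deterministic given it.
#' @return A [data_registry()] whose `truth` attribute records the planted
#'   parameters (for tests only).
#' @export
make_fixture_registry <- function(seed = 1) {
  with_seed(seed, .build_fixture_registry())
}

.build_fixture_registry <- function() {
  traits <- list(
    egfr   = list(n = 133413L, k = 0L),
    met_1  = list(n = 1960L,  k = 1L),
    met_2  = list(n = 2050L,  k = 2L),
    met_5  = list(n = 7824L,  k = 5L),
    met_22 = list(n = 7824L,  k = 22L)
  )
  n_egfr_primary <- 75L
  n_egfr_tag <- 4L
  n_met <- sum(vapply(traits[-1], `[[`, integer(1), "k"))
  n_null <- 20L
  m <- n_egfr_primary + n_egfr_tag + n_met + n_null
  rsid <- sprintf("rs%05d", seq_len(m))

  idx_egfr <- seq_len(n_egfr_primary + n_egfr_tag)
  at <- n_egfr_primary + n_egfr_tag
  idx_met <- list()
  for (tn in names(traits)[-1]) {
    k <- traits[[tn]]$k
    idx_met[[tn]] <- seq.int(at + 1L, at + k)
    at <- at + k
  }
  # shared instrument: met_22's last own SNP also drives met_5
  shared_snp <- idx_met$met_22[length(idx_met$met_22)]
  idx_inst <- c(list(egfr = idx_egfr), idx_met)
  idx_inst$met_5 <- c(idx_inst$met_5, shared_snp)

  mafs <- stats::runif(m, 0.05, 0.5)
  mafs[unlist(idx_met)] <- stats::runif(n_met, 0.08, 0.38)
  v <- 2 * mafs * (1 - mafs)

  # per-trait genotype effects (gamma), sized by target z-scores
  gamma <- sapply(names(traits), function(tn) rep(0, m))
  se_at <- function(n) sqrt(1 / (n * v))
  z_egfr <- stats::runif(n_egfr_primary + n_egfr_tag, 8, 15)
  gamma[idx_egfr, "egfr"] <- z_egfr * se_at(traits$egfr$n)[idx_egfr] *
    sample(c(-1, 1), length(idx_egfr), replace = TRUE)
  for (tn in names(idx_met)) {
    ii <- idx_met[[tn]]
    z <- stats::runif(length(ii), 6, 11.6)
    gamma[ii, tn] <- z * se_at(traits[[tn]]$n)[ii] *
      sample(c(-1, 1), length(ii), replace = TRUE)
  }
  gamma[shared_snp, "met_5"] <- gamma[shared_snp, "met_22"]

  # causal structure: egfr -> each metabolite, theta = -0.2; no forward
  theta_rev <- -0.2
  mean_beta <- gamma
  for (tn in names(idx_met)) {
    mean_beta[, tn] <- gamma[, tn] + theta_rev * gamma[, "egfr"]
  }

  al <- .assign_allele_pairs(m, palindrome_frac = 0.1)
  tables <- list()
  tix <- 0L
  for (tn in names(traits)) {
    tix <- tix + 1L
    n <- traits[[tn]]$n
    se <- se_at(n)
    beta <- stats::rnorm(m, mean_beta[, tn], se)
    # construction guarantee: planted instruments are genome-wide
    # significant (redraw the rare borderline draws; the z-score floors
    # make this a mild truncation)
    ii <- idx_inst[[tn]]
    for (tries in 1:50) {
      weak <- ii[2 * stats::pnorm(-abs(beta[ii] / se[ii])) >= 5e-8]
      if (!length(weak)) break
      beta[weak] <- stats::rnorm(length(weak), mean_beta[weak, tn], se[weak])
    }
    p <- pmax(2 * stats::pnorm(-abs(beta / se)), 1e-320)
    swap <- stats::runif(m) < 0.25
    flip <- stats::runif(m) < 0.15
    shared <- list(rsid = rsid, a1 = al$a1, a2 = al$a2)
    src <- if (tn == "egfr") "synth_kidney_gwas" else "synth_metab_gwas"
    tables[[tn]] <- .report_sumstats(
      shared, list(beta = beta, se = se, p = p, eaf = mafs, n = n),
      trait_id = tn, source_id = src, swap = swap, flip = flip
    )
  }

  # planted LD: tag SNPs sit in mild LD with the first primaries
  tag_idx <- seq.int(n_egfr_primary + 1L, n_egfr_primary + n_egfr_tag)
  ld <- ld_table(data.frame(rsid_a = rsid[seq_len(n_egfr_tag)],
                            rsid_b = rsid[tag_idx],
                            r2 = rep(0.1, n_egfr_tag)))

  reg <- data_registry(tables, ld = ld)
  attr(reg, "truth") <- list(
    theta_reverse = theta_rev, theta_forward = 0,
    gamma = gamma, mafs = mafs, rsid = rsid,
    egfr_instruments = rsid[idx_egfr],
    met_instruments = lapply(idx_inst[-1], function(ii) rsid[ii]),
    shared_instrument = rsid[shared_snp],
    tag_pairs = data.frame(primary = rsid[seq_len(n_egfr_tag)],
                           tag = rsid[tag_idx], r2 = 0.1)
  )
  reg
}
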