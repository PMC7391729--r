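# Allele harmonization: orientation, strand flips, palindromic policy.

# Independent oracle: classify one exposure/outcome allele configuration by
# direct set comparison (no shared code with .harmonize_one).
oracle_harmonize <- function(xe, xo, ye, yo) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  if (comp[[xe]] == xo) {
    if (setequal(c(ye, yo), c(xe, xo))) return("palindromic")
    return("mismatch")
  }
  if (identical(c(ye, yo), c(xe, xo))) return(list(sign = 1))
  if (identical(c(ye, yo), c(xo, xe))) return(list(sign = -1))
  if (identical(unname(comp[c(ye, yo)]), c(xe, xo))) return(list(sign = 1))
  if (identical(unname(comp[c(ye, yo)]), c(xo, xe))) return(list(sign = -1))
  "mismatch"
}

harmonize_one_snp <- function(xe, xo, ye, yo, by = 0.1, eaf_x = 0.2,
                              eaf_y = 0.2, policy = "infer_by_eaf") {
  inst <- mk_stats(1, rsid = "rs1", effect_allele = xe, other_allele = xo,
                   beta = 0.5, eaf = eaf_x)
  inst <- select_instruments(inst, p_threshold = 1e-6)
  out <- mk_stats(1, rsid = "rs1", trait_id = "out", effect_allele = ye,
                  other_allele = yo, beta = by, eaf = eaf_y)
  harmonize(inst, out, policy = policy)
}

test_that("basic orientation cases", {
  h <- harmonize_one_snp("A", "G", "A", "G", by = 0.1)
  expect_equal(h$by, 0.1)
  expect_equal(h$status, "aligned")

  h <- harmonize_one_snp("A", "G", "G", "A", by = 0.1)
  expect_equal(h$by, -0.1)
  expect_equal(h$status, "sign_flipped")

  h <- harmonize_one_snp("A", "G", "T", "C", by = 0.1)  # strand flip
  expect_equal(h$by, 0.1)
  expect_equal(h$status, "strand_flipped")

  # irreconcilable alleles
  h <- harmonize_one_snp("A", "G", "A", "C")
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "drop_log")$reason, "mismatch")

  # instrument absent from outcome
  inst <- select_instruments(mk_stats(1, rsid = "rsX"),
                             p_threshold = 1e-6)
  h <- harmonize(inst, mk_stats(1, rsid = "rsY", trait_id = "out"))
  expect_equal(attr(h, "drop_log")$reason, "missing")
})

test_that("every allele-pair configuration matches the exhaustive oracle", {
  bases <- c("A", "C", "G", "T")
  for (xpair in list(c("A", "G"), c("C", "A"), c("A", "T"), c("G", "C"))) {
    for (ye in bases) for (yo in setdiff(bases, ye)) {
      expected <- oracle_harmonize(xpair[1], xpair[2], ye, yo)
      # clearly-resolvable frequencies so infer_by_eaf keeps palindromes
      h <- harmonize_one_snp(xpair[1], xpair[2], ye, yo, by = 0.1,
                             eaf_x = 0.2, eaf_y = 0.2)
      info <- paste(c(xpair, ye, yo), collapse = "/")
      if (identical(expected, "mismatch")) {
        expect_equal(nrow(h), 0, info = info)
        expect_equal(attr(h, "drop_log")$reason, "mismatch", info = info)
      } else if (identical(expected, "palindromic")) {
        expect_equal(h$status, "palindromic_kept", info = info)
        # eaf 0.2 on both sides: minor-allele sides agree iff the literal
        # orientations agree, so the sign equals the literal sign
        expect_equal(abs(h$by), 0.1, info = info)
      } else {
        expect_equal(h$by, expected$sign * 0.1, info = info)
      }
    }
  }
})

test_that("palindromic policy: drop_all, eaf inference, ambiguity window", {
  # inside the ambiguity window -> dropped(ambiguous)
  h <- harmonize_one_snp("A", "T", "A", "T", eaf_x = 0.49, eaf_y = 0.50)
  expect_equal(attr(h, "drop_log")$reason, "ambiguous")

  # missing eaf -> ambiguous
  h <- harmonize_one_snp("A", "T", "A", "T", eaf_x = NA, eaf_y = 0.2)
  expect_equal(attr(h, "drop_log")$reason, "ambiguous")

  # clear frequencies, same minor side -> kept without sign change
  h <- harmonize_one_snp("A", "T", "A", "T", by = 0.3, eaf_x = 0.2,
                         eaf_y = 0.25)
  expect_equal(h$by, 0.3)
  # opposite minor side -> the outcome was measured on the other strand
  # orientation; sign flips
  h <- harmonize_one_snp("A", "T", "A", "T", by = 0.3, eaf_x = 0.2,
                         eaf_y = 0.75)
  expect_equal(h$by, -0.3)

  # drop_all drops regardless of frequency clarity
  h <- harmonize_one_snp("A", "T", "A", "T", eaf_x = 0.2, eaf_y = 0.2,
                         policy = "drop_all")
  expect_equal(attr(h, "drop_log")$reason, "palindromic")

  # keep_as_is trusts reported strands
  h <- harmonize_one_snp("G", "C", "C", "G", by = 0.2, eaf_x = NA,
                         eaf_y = NA, policy = "keep_as_is")
  expect_equal(h$by, -0.2)
  expect_equal(h$status, "palindromic_kept")
})

test_that("involution: harmonizing aligned output changes nothing", {
  sim <- simulate_two_sample(sim_config(m = 40, n_exposure = 6000,
                                        n_outcome = 6000, h2x = 0.2,
                                        theta = 0.2, mode = "asymptotic",
                                        seed = 5))
  inst <- select_instruments(sim$exposure, sim$ld)
  h1 <- harmonize(inst, sim$outcome)
  # rebuild an outcome table already expressed on the exposure orientation
  idx <- match(h1$rsid, sim$exposure$rsid)
  aligned_out <- sumstats(data.frame(
    rsid = h1$rsid,
    effect_allele = sim$exposure$effect_allele[idx],
    other_allele = sim$exposure$other_allele[idx],
    beta = h1$by, se = h1$sy,
    pvalue = 2 * pnorm(-abs(h1$by / h1$sy)),
    eaf = sim$exposure$eaf[idx]
  ), trait_id = "outcome")
  inst2 <- subset_instruments(inst, keep = h1$rsid)
  h2 <- harmonize(inst2, aligned_out)
  expect_equal(h2$by, h1$by)
  expect_equal(h2$bx, h1$bx)
  # no transformation applied; palindromes stay flagged but unchanged
  expect_true(all(h2$status %in% c("aligned", "palindromic_kept")))
})

test_that("sign consistency: relabelling both outcome alleles and negating by is a no-op", {
  sim <- simulate_two_sample(sim_config(m = 40, n_exposure = 6000,
                                        n_outcome = 6000, h2x = 0.2,
                                        theta = 0.2, mode = "asymptotic",
                                        seed = 6))
  inst <- select_instruments(sim$exposure, sim$ld)
  out <- as.data.frame(sim$outcome)
  relabelled <- sumstats(transform(out,
    effect_allele = other_allele, other_allele = effect_allele,
    beta = -beta, eaf = 1 - eaf
  ), trait_id = "outcome")
  h1 <- harmonize(inst, sim$outcome)
  h2 <- harmonize(inst, relabelled)
  expect_equal(h2$rsid, h1$rsid)
  expect_equal(h2$by, h1$by)
})

test_that("the Wald ratio is invariant to the declared effect allele", {
  sim <- simulate_two_sample(sim_config(m = 30, n_exposure = 6000,
                                        n_outcome = 6000, h2x = 0.2,
                                        theta = 0.3, mode = "asymptotic",
                                        seed = 8))
  inst <- select_instruments(sim$exposure, sim$ld)
  h1 <- harmonize(inst, sim$outcome)
  # flip the exposure's declared effect allele instead
  ex <- as.data.frame(sim$exposure)
  flipped <- sumstats(transform(ex,
    effect_allele = other_allele, other_allele = effect_allele,
    beta = -beta, eaf = 1 - eaf
  ), trait_id = "exposure")
  inst2 <- select_instruments(flipped, sim$ld)
  h2 <- harmonize(inst2, sim$outcome)
  common <- intersect(h1$rsid, h2$rsid)
  expect_gt(length(common), 0)
  r1 <- with(h1[match(common, h1$rsid), ], by / bx)
  r2 <- with(h2[match(common, h2$rsid), ], by / bx)
  expect_equal(r1, r2)
})

test_that("retained + dropped counts add up to instruments present", {
  sim <- simulate_two_sample(sim_config(m = 60, n_exposure = 5000,
                                        n_outcome = 5000, h2x = 0.25,
                                        theta = 0.1, mode = "asymptotic",
                                        seed = 12, palindrome_frac = 0.4))
  inst <- select_instruments(sim$exposure, sim$ld)
  h <- harmonize(inst, sim$outcome)
  expect_equal(nrow(h) + nrow(attr(h, "drop_log")), nrow(inst))
})
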