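test_that("fixed-W refit reproduces the free fit on the same data", {
  gt <- tiny_gt(p = 8, s = 3, T_cycle = 50, k = 3, noise_sd = 0.05, seed = 1)
  E <- synthesize_emg(gt)
  free <- nmf_extract(E, 3, n_restarts = 5, seed = 1)
  cf <- fit_C_fixed_W(E, free$W, seed = 2)
  expect_equal(cf$VAF_total, free$VAF_total, tolerance = 1e-3)
  expect_true(all(cf$refit >= 0))
})

test_that("fixed-W refit with the true basis recovers the true coefficients", {
  gt <- tiny_gt(p = 8, s = 3, T_cycle = 50, k = 3, seed = 2)
  E <- synthesize_emg(gt)
  W_eff <- effective_truth_W(gt, E)
  cf <- fit_C_fixed_W(E, W_eff, seed = 3)
  expect_gte(cf$VAF_total, 0.999)
  for (j in 1:3)
    expect_gte(abs(cosine(cf$C[j, ], gt$C_true[j, ])), 0.999)
  # mismatched muscles (permuted rows of W) reconstruct strictly worse
  W_perm <- W_eff[c(5, 3, 8, 1, 7, 2, 6, 4), ]
  cf_bad <- fit_C_fixed_W(E, W_perm, seed = 3)
  expect_lt(cf_bad$VAF_total, cf$VAF_total)
})

test_that("fixed-C refit mirrors fixed-W and degrades under time shifts", {
  gt <- tiny_gt(p = 8, s = 3, T_cycle = 50, k = 3, noise_sd = 0.05, seed = 3)
  E <- synthesize_emg(gt)
  free <- nmf_extract(E, 3, n_restarts = 5, seed = 4)
  cf <- fit_W_fixed_C(E, free$C, seed = 5)
  expect_equal(cf$VAF_total, free$VAF_total, tolerance = 1e-3)

  gt0 <- tiny_gt(p = 8, s = 3, T_cycle = 48, k = 3, seed = 4)
  E0 <- synthesize_emg(gt0)
  cf_true <- fit_W_fixed_C(E0, gt0$C_true, seed = 6)
  expect_gte(cf_true$VAF_total, 0.999)
  for (j in 1:3) {
    W_eff <- effective_truth_W(gt0, E0)
    expect_gte(abs(cosine(cf_true$W[, j], W_eff[, j])), 0.999)
  }
  # quarter-cycle shifted coefficients reconstruct strictly worse
  C_shift <- emgsynergy:::circshift_cycles(gt0$C_true, 12, 48, 3)
  cf_shift <- fit_W_fixed_C(E0, C_shift, seed = 6)
  expect_lt(cf_shift$VAF_total, cf_true$VAF_total)
})

test_that("fixed-part refits never beat the free fit", {
  gt <- tiny_gt(p = 6, s = 2, T_cycle = 40, k = 3, noise_sd = 0.1, seed = 5)
  cohA <- synthesize_cohort(2, gt, per_subject_shift = c(0, 5),
                            per_subject_W_perturbation = 0.1, seed = 5)
  freeB <- nmf_extract(cohA[[2]], 2, n_restarts = 5, seed = 7)
  freeA <- nmf_extract(cohA[[1]], 2, n_restarts = 5, seed = 8)
  cfW <- fit_C_fixed_W(cohA[[2]], freeA$W, seed = 9)
  cfC <- fit_W_fixed_C(cohA[[2]], freeA$C, seed = 9)
  expect_lte(cfW$VAF_total, freeB$VAF_total + 1e-3)
  expect_lte(cfC$VAF_total, freeB$VAF_total + 1e-3)
})

test_that("within-subject cross-validation is self-consistent and robust across noise realisations", {
  gt <- tiny_gt(p = 8, s = 2, T_cycle = 50, k = 3, noise_sd = 0.05, seed = 6)
  setA <- synthesize_emg(gt, seed = 100)
  setB <- synthesize_emg(gt, seed = 200)
  self <- within_subject_crossval(setA, setA, 2, n_restarts = 5, seed = 10)
  expect_equal(self$cross_fit$VAF_total, self$free_A$VAF_total,
               tolerance = 1e-3)
  cross <- within_subject_crossval(setA, setB, 2, n_restarts = 5, seed = 11)
  expect_gt(cross$cross_fit$VAF_total, cross$free_B$VAF_total - 0.05)
  expect_true(all(cross$W_similarity > 0.9))

  # sets generated from different synergy bases cross-validate much worse
  gt2 <- tiny_gt(p = 8, s = 2, T_cycle = 50, k = 3, noise_sd = 0.05,
                 seed = 60)
  setC <- synthesize_emg(gt2, seed = 300)
  other <- within_subject_crossval(setA, setC, 2, n_restarts = 5, seed = 12)
  expect_lt(other$cross_fit$VAF_total, cross$cross_fit$VAF_total - 0.10)
})

test_that("cohort cross-validation enumerates all ordered pairs", {
  gt <- tiny_gt(p = 6, s = 2, T_cycle = 30, k = 2, noise_sd = 0.05, seed = 7)
  coh <- synthesize_cohort(3, gt, per_subject_shift = c(0, 3, 6), seed = 7)
  cv <- cohort_crossval(coh, 2, mode = "fix_W", n_restarts = 3, seed = 13)
  expect_equal(nrow(cv$pairs), 6L)
  expect_true(all(cv$pairs$control != cv$pairs$compared))
  expect_equal(dim(cv$VAF_muscle), c(6L, 6L))
  expect_equal(cv$mean_VAF, mean(cv$pairs$VAF_total))
  expect_error(cohort_crossval(coh[1], 2), "at least 2")
})

test_that("identical subjects cross-validate at the self-fit VAF", {
  gt <- tiny_gt(p = 6, s = 2, T_cycle = 30, k = 2, seed = 8)
  coh <- synthesize_cohort(2, gt, per_subject_shift = c(0, 0), seed = 8)
  cv <- cohort_crossval(coh, 2, mode = "fix_W", n_restarts = 3, seed = 14)
  self_vaf <- cv$free_fits[[1]]$VAF_total
  expect_equal(unname(cv$pairs$VAF_total), rep(self_vaf, 2), tolerance = 1e-3)
})

test_that("low-VAF muscles are flagged at the 75% adequacy threshold", {
  expect_equal(flag_low_vaf_muscles(c(0.9, 0.74, 0.75, 0.2)),
               c(FALSE, TRUE, FALSE, TRUE))
})
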