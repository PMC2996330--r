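test_that("risk_category_cutpoints invert the percentile-risk relation", {
  K <- 0.05
  z <- risk_category_cutpoints(K, 0.1, 0.2)
  # push the cutpoint back through the risk equation
  R_back <- pnorm((liability_threshold(K) - z) / sqrt(1 - 0.1),
                  lower.tail = FALSE)
  expect_equal(R_back, 0.2, tolerance = 1e-10)
  # V = 0: finite cutpoint, risk at z equals r
  z0 <- risk_category_cutpoints(K, 0, K)
  expect_equal(z0, liability_threshold(K) + qnorm(K), tolerance = 1e-12)
  th <- c(0.01, 0.06, 0.2, 0.5)
  expect_true(all(diff(risk_category_cutpoints(0.1, 0.15, th)) > 0))
  expect_error(risk_category_cutpoints(0.1, 0.15, c(0.2, 0.06)),
               "increasing")
  expect_error(risk_category_cutpoints(0.1, 1, 0.2))
})

test_that("joint_conditional_moments: identical models, marginals, MC oracle", {
  # identical models: perfect conditional correlation
  nm <- nested_models(0.1, 0.1, 0.1, cov_old_new = 0.1)
  jm <- joint_conditional_moments(nm)
  expect_equal(jm$case$cor, 1, tolerance = 1e-9)
  expect_equal(jm$case$mean[1], jm$case$mean[2], tolerance = 1e-12)

  # marginal case moments equal the univariate PA moments for each model
  nm <- nested_models(0.05, 0.05, 0.1)
  jm <- joint_conditional_moments(nm)
  mm_new <- conditional_moments(disease_model(0.05, 0.1))
  mm_old <- conditional_moments(disease_model(0.05, 0.05))
  expect_equal(jm$case$mean[2], mm_new$mean_meas_case, tolerance = 1e-12)
  expect_equal(jm$case$cov[2, 2], mm_new$var_meas_case, tolerance = 1e-12)
  expect_equal(jm$control$mean[1], mm_old$mean_meas_control,
               tolerance = 1e-12)
  expect_equal(jm$control$cov[1, 1], mm_old$var_meas_control,
               tolerance = 1e-12)

  # Monte-Carlo oracle: 1e7 liability triples partitioned by case status
  sim <- mc_liability_triples(0.05, 0.05, 0.1, 1e7, seed = 13)
  for (grp in c("case", "control")) {
    sel <- if (grp == "case") sim$case else !sim$case
    g <- jm[[grp]]
    expect_lt(abs(g$mean[1] - mean(sim$z_old[sel])), 2e-3)
    expect_lt(abs(g$mean[2] - mean(sim$z_new[sel])), 2e-3)
    expect_lt(abs(g$cov[1, 1] - var(sim$z_old[sel])), 2e-3)
    expect_lt(abs(g$cov[2, 2] - var(sim$z_new[sel])), 2e-3)
    expect_lt(abs(g$cov[1, 2] - cov(sim$z_old[sel], sim$z_new[sel])), 2e-3)
  }
  expect_error(nested_models(0.05, 0.3, 0.4, cov_old_new = -0.3),
               "positive semidefinite")
})

test_that("reclassification_table reproduces printed NRIs", {
  expect_lt(abs(reclassification_table(nested_models(0.05, 0.05, 0.1),
                                       c(0.06, 0.2))$nri - 0.099), 2e-3)
  expect_lt(abs(reclassification_table(nested_models(0.1, 0.05, 0.15),
                                       c(0.06, 0.2))$nri - 0.306), 5e-3)
  # identical models: all mass on the diagonal
  rt0 <- reclassification_table(nested_models(0.1, 0.1, 0.1, 0.1),
                                c(0.06, 0.2))
  expect_lt(sum(rt0$case_matrix[upper.tri(rt0$case_matrix)]) +
              sum(rt0$case_matrix[lower.tri(rt0$case_matrix)]), 1e-8)
  expect_lt(abs(rt0$nri), 1e-8)
  expect_error(reclassification_table(nested_models(0.1, 0.05, 0.1),
                                      c(0.06, 1.2)))
})

test_that("reclassification matrices are normalised, marginalise, and mix", {
  K <- 0.08
  nm <- nested_models(K, 0.06, 0.14)
  th <- c(0.04, 0.1, 0.25)
  rt <- reclassification_table(nm, th)
  expect_equal(sum(rt$case_matrix), 1, tolerance = 1e-6)
  expect_equal(sum(rt$control_matrix), 1, tolerance = 1e-6)
  expect_true(abs(rt$nri) <= 2)

  # row sums reproduce single-model category occupancy within each group
  mm_old <- conditional_moments(disease_model(K, 0.06))
  z_old <- c(-Inf, risk_category_cutpoints(K, 0.06, th), Inf)
  occ_case <- diff(pnorm(z_old, mm_old$mean_meas_case,
                         sqrt(mm_old$var_meas_case)))
  expect_equal(rowSums(rt$case_matrix), occ_case, tolerance = 1e-6)
  occ_ctrl <- diff(pnorm(z_old, mm_old$mean_meas_control,
                         sqrt(mm_old$var_meas_control)))
  expect_equal(rowSums(rt$control_matrix), occ_ctrl, tolerance = 1e-6)

  # mixture: K * cases + (1-K) * controls recovers the unconditional
  # transition matrix. The conditional laws are Pearson-Aitken normal
  # approximations (the exact conditionals of a truncated trivariate
  # normal are skewed), so the identity holds to the approximation scale
  # (~1e-3), not to machine precision.
  z_new <- c(-Inf, risk_category_cutpoints(K, 0.14, th), Inf)
  sig <- nm$sigma[2:3, 2:3]
  sd_u <- sqrt(diag(sig))
  rho_u <- sig[1, 2] / prod(sd_u)
  uncond <- matrix(0, 4, 4)
  for (i in 1:4) {
    for (j in 1:4) {
      uncond[i, j] <- liabilityMetrics:::.bvn_rect(
        z_old[i], z_old[i + 1], z_new[j], z_new[j + 1],
        c(0, 0), sd_u, rho_u)
    }
  }
  expect_lt(max(abs(K * rt$case_matrix + (1 - K) * rt$control_matrix -
                      uncond)), 1e-3)
})

test_that("NRI vanishes as Vnew -> Vold and grows with the added variance", {
  th <- c(0.06, 0.2)
  nris <- sapply(c(0.1001, 0.105, 0.12, 0.15, 0.2), function(vn) {
    reclassification_table(nested_models(0.1, 0.1, vn), th)$nri
  })
  expect_lt(abs(nris[1]), 5e-3)
  expect_true(all(diff(nris) > 0))
})

test_that("weighted_nri reduces, isolates components, and shift-scores", {
  nm <- nested_models(0.1, 0.05, 0.25)
  rt <- reclassification_table(nm, c(0.06, 0.2))
  expect_equal(weighted_nri(rt), rt$nri, tolerance = 1e-12)
  expect_equal(weighted_nri(rt, c(1, 1, 0, 0)),
               rt$p_up_case - rt$p_down_case, tolerance = 1e-12)
  # oracle by direct cell enumeration
  a <- rt$case_matrix
  b <- rt$control_matrix
  enum <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      s <- abs(i - j)
      enum <- enum + sign(j - i) * s * (a[i, j] - b[i, j])
    }
  }
  shifted <- weighted_nri(rt, category_shift_scores = TRUE)
  expect_equal(shifted, enum, tolerance = 1e-12)
  # a 2-step move exists, so shift scoring changes the magnitude upward
  expect_gt(a[1, 3] + a[3, 1], 1e-8)
  expect_gt(abs(shifted), abs(rt$nri))
})

test_that("idi reproduces printed values and is consistent with Table 3", {
  expect_lt(abs(idi(nested_models(0.1, 0.1, 0.2)) - 0.043), 1e-3)
  expect_identical(idi(nested_models(0.1, 0.15, 0.15)), 0)
  # cross-table consistency: slope difference 0.0577 - 0.0255 = 0.0322
  expect_lt(abs(idi(nested_models(0.05, 0.1, 0.2)) - 0.0322), 1e-3)
})
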