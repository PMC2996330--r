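test_that("risk densities normalise, average to K, and mix correctly", {
  for (i in seq_len(nrow(grid_models()))) {
    g <- grid_models()[i, ]
    m <- disease_model(g$K, g$Vm)
    d <- risk_density(m)
    expect_lt(abs(integrate(d$pdf, 1e-14, 1 - 1e-14, rel.tol = 1e-9,
                            subdivisions = 500L)$value - 1), 1e-6)
    expect_lt(abs(integrate(function(r) r * d$pdf(r), 1e-14, 1 - 1e-14,
                            rel.tol = 1e-9, subdivisions = 500L)$value -
                    g$K), 1e-6)
  }
  # pointwise mixture identity on a fine grid
  m <- disease_model(0.05, 0.1)
  dp <- risk_density(m, "population")
  dc <- risk_density(m, "cases")
  dn <- risk_density(m, "noncases")
  r <- seq(1e-4, 0.6, length.out = 1000)
  expect_lt(max(abs(0.05 * dc$pdf(r) + 0.95 * dn$pdf(r) - dp$pdf(r))),
            1e-9)
  # conditional cdfs are proper and ordered (cases stochastically larger)
  rs <- c(0.01, 0.05, 0.1, 0.3)
  expect_true(all(dc$cdf(rs) <= dn$cdf(rs) + 1e-9))
  expect_equal(dc$cdf(0.999), 1, tolerance = 1e-4)
  expect_error(risk_density(disease_model(0.1, 0)), "point mass")
})

test_that("population risk histogram matches the closed-form density", {
  # mirrors the simulated-vs-theoretical density comparison at K = 0.005
  # with Vm = 0.0442
  K <- 0.005
  Vm <- 0.0442
  m <- disease_model(K, Vm)
  set.seed(404)
  n <- 1e6
  # independent generative route: draw measurable liability, transform by
  # the conditional tail probability (not via the package's percentile map)
  zm <- rnorm(n, 0, sqrt(Vm))
  risks <- pnorm((qnorm(1 - K) - zm) / sqrt(1 - Vm), lower.tail = FALSE)
  d <- risk_density(m)
  brk <- quantile(risks, probs = seq(0, 1, length.out = 51))
  brk[1] <- 0
  brk[51] <- 1
  counts <- table(cut(risks, brk, include.lowest = TRUE))
  p_obs <- as.numeric(counts) / n
  p_exp <- diff(d$cdf(pmin(pmax(brk, 1e-12), 1 - 1e-12)))
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(max(abs(p_obs - p_exp) / se), 3 + 1e-9)
})

test_that("predictiveness_curve is Eq-consistent, flat at Vm = 0, fans out", {
  m <- disease_model(0.1, 0.1)
  pc <- predictiveness_curve(m, grid = 1001)
  expect_true(all(diff(pc$R) > 0))
  expect_equal(pc$R[501], risk_at_percentile(m, pc$p[501]), tolerance = 1e-12)
  expect_equal(pc$p[501], 0.5, tolerance = 1e-9)
  pc0 <- predictiveness_curve(disease_model(0.1, 0), grid = 101)
  expect_true(all(pc0$R == 0.1))
  # curves for increasing Vm cross near the prevalence and fan out
  curves <- lapply(c(0.05, 0.1, 0.2), function(v) {
    predictiveness_curve(disease_model(0.1, v), grid = 999)
  })
  at <- function(cv, p) cv$R[which.min(abs(cv$p - p))]
  expect_true(at(curves[[1]], 0.05) > at(curves[[2]], 0.05))
  expect_true(at(curves[[2]], 0.05) > at(curves[[3]], 0.05))
  expect_true(at(curves[[1]], 0.95) < at(curves[[2]], 0.95))
  expect_true(at(curves[[2]], 0.95) < at(curves[[3]], 0.95))
})

test_that("proportion_cases_explained reproduces printed values", {
  expect_lt(abs(proportion_cases_explained(disease_model(0.005, 0.05),
                                           0.5) - 0.746), 1e-3)
  expect_lt(abs(proportion_cases_explained(disease_model(0.01, 0.1),
                                           0.2) - 0.500), 1e-3)
  m <- disease_model(0.05, 0.1)
  expect_equal(proportion_cases_explained(m, 1), 1, tolerance = 1e-9)
  expect_equal(proportion_cases_explained(m, 0), 0)
  # concavity bound: always at least the population fraction
  x <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(proportion_cases_explained(m, x) >= x))
  expect_equal(proportion_cases_explained(disease_model(0.05, 0), x), x,
               tolerance = 1e-9)
})

test_that("cases-explained area is near but not equal to AUC, gap grows in K", {
  expect_equal(cases_explained_curve(disease_model(0.1, 0), 500)$area, 0.5,
               tolerance = 1e-6)
  gaps <- sapply(c(0.005, 0.05, 0.1, 0.3365), function(K) {
    m <- disease_model(K, 0.123)
    auc_exact(m) - cases_explained_curve(m, 3000)$area
  })
  expect_lt(abs(gaps[1]), 0.01)   # rare disease: nearly equal
  expect_gt(abs(gaps[1]), 1e-4)   # ... but not identical
  expect_true(all(diff(gaps) > 0))  # gap widens with prevalence
  # area identity: trapezoid area equals (1/K) * int TP(c) dc
  m <- disease_model(0.05, 0.1)
  area_int <- integrate(function(cv) {
    vapply(cv, function(cc) liabilityMetrics:::tp_integral(m, cc), 0)
  }, 0, 1, rel.tol = 1e-8)$value / 0.05
  expect_equal(cases_explained_curve(m, 3000)$area, area_int,
               tolerance = 1e-5)
})

test_that("risk_summary reproduces the printed dispersion column", {
  rs <- risk_summary(disease_model(0.05, 0.2))
  expect_lt(abs(rs$mean_risk_cases - 0.1049), 1e-4)
  expect_lt(abs(rs$mean_risk_noncases - 0.0472), 1e-4)
  expect_lt(abs(rs$discrimination_slope - 0.0577), 1e-4)
  expect_lt(abs(rs$var_ratio - 0.0578), 1e-4)
  expect_lt(abs(rs$rr_between - 17.56), 1e-2)
  expect_lt(abs(risk_summary(disease_model(0.005, 0.2))$rr_between - 58.42),
            1e-2)
  rs0 <- risk_summary(disease_model(0.3, 0))
  expect_identical(rs0$var_risk, 0)
  expect_identical(rs0$discrimination_slope, 0)
  expect_identical(rs0$rr_between, 1)
})

test_that("variance ratio equals discrimination slope exactly", {
  for (i in seq_len(nrow(grid_models()))) {
    g <- grid_models()[i, ]
    rs <- risk_summary(disease_model(g$K, g$Vm))
    expect_lt(abs(rs$var_ratio - rs$discrimination_slope), 1e-6)
    expect_lt(rs$var_risk, g$K * (1 - g$K))
  }
})
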