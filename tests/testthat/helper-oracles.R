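# Shared fixtures and independent Monte-Carlo / quadrature oracles.

# (K, Vm) grid used by several property tests
grid_models <- function() {
  expand.grid(K = c(0.005, 0.01, 0.05, 0.1, 0.3365),
              Vm = c(0.02, 0.05, 0.1, 0.2))
}

# Liability pairs (measurable, overall), partitioned at the threshold.
# Independent of the package: draws the generative model directly.
mc_liability <- function(K, Vm, n, seed) {
  set.seed(seed)
  zm <- stats::rnorm(n, 0, sqrt(Vm))
  L <- zm + stats::rnorm(n, 0, sqrt(1 - Vm))
  list(zm = zm, L = L, case = L > stats::qnorm(1 - K))
}

# Liability triples (old measurable, new measurable, overall) under an
# independently added factor
mc_liability_triples <- function(K, Vold, Vnew, n, seed) {
  set.seed(seed)
  z_old <- stats::rnorm(n, 0, sqrt(Vold))
  z_new <- z_old + stats::rnorm(n, 0, sqrt(Vnew - Vold))
  L <- z_new + stats::rnorm(n, 0, sqrt(1 - Vnew))
  list(z_old = z_old, z_new = z_new, case = L > stats::qnorm(1 - K))
}

# 1-D quadrature oracle for the bivariate normal cdf:
# P(X <= h, Y <= k) = int phi(x) Phi((k - rho x)/sqrt(1-rho^2)) dx over x < h
bvn_cdf_quadrature <- function(h, k, rho) {
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((k - rho * x) / sqrt(1 - rho^2))
  }, lower = -Inf, upper = h, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# Standard-normal quantile by bisection on the survival function only
qnorm_bisect <- function(p_upper, tol = 1e-10) {
  lo <- -10
  hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid, lower.tail = FALSE) > p_upper) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_panel <- function() {
  load_panel(system.file("extdata", "synthetic-30-locus-panel.tsv",
                         package = "liabilityMetrics"))
}

# Approximate standard error of a Mann-Whitney AUC (Hanley & McNeil 1982)
auc_se <- function(auc, n1, n0) {
  n1 <- as.numeric(n1)
  n0 <- as.numeric(n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
}
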