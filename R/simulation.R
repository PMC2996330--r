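#' Calibrate the logistic intercept to a target disease probability
#'
#' Finds the intercept `beta0` of the multiplicative-odds cohort model
#' `logit(P) = beta0 + sum_i beta_i g_i` (with `beta_i = log OR_i` and
#' genotypes `g_i ~ Binomial(2, raf_i)` independent across loci) such that
#' the population mean of `P` equals `K`. The expectation is computed
#' deterministically: the distribution of the genetic score
#' `S = sum beta_i g_i` is built by exact convolution of the per-locus
#' three-point distributions onto a fine grid (step `1e-4` on the log-odds
#' scale), and `E[plogis(beta0 + S)]` is root-found over `beta0`.
#'
#' @param panel a `"variant_panel"` (may have zero rows).
#' @param K target overall disease probability.
#' @return The calibrated intercept; exactly `qlogis(K)` for an empty or
#'   null (all OR = 1) panel.
#' @export
calibrate_intercept <- function(panel, K) {
  stopifnot(inherits(panel, "variant_panel"), K > 0, K < 1)
  if (nrow(panel) == 0 ||
      all(panel$or_het == 1) && all(panel$or_hom == 1)) {
    return(stats::qlogis(K))
  }
  dist <- score_distribution(panel)
  f <- function(b0) sum(dist$prob * stats::plogis(b0 + dist$value)) - K
  lo <- stats::qlogis(K) - max(abs(dist$value)) - 1
  hi <- stats::qlogis(K) + 1
  out <- tryCatch(
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-12),
    error = function(e) stop("intercept calibration failed to bracket a ",
                             "root on [", format(lo), ", ", format(hi),
                             "]: ", conditionMessage(e))
  )
  out$root
}

# Exact distribution of S = sum_i log(OR) * g_i over independent loci,
# discretised onto a grid of step `h` on the log-odds scale. Grid
# round-off perturbs each locus value by at most h/2, which moves E[P] by
# far less than the 1e-4 calibration contract.
score_distribution <- function(panel, h = 1e-4) {
  b_het <- log(panel$or_het)
  b_hom <- log(panel$or_hom)
  lo <- sum(pmin(0, b_het, b_hom))
  hi <- sum(pmax(0, b_het, b_hom))
  n_bins <- as.integer(round((hi - lo) / h)) + 1L
  prob <- numeric(n_bins)
  prob[as.integer(round(-lo / h)) + 1L] <- 1  # point mass at S = 0
  for (i in seq_len(nrow(panel))) {
    off <- as.integer(round(c(0, b_het[i], b_hom[i]) / h))
    w <- c(panel$f0[i], panel$f1[i], panel$f2[i])
    nz <- which(prob > 0)
    newp <- numeric(n_bins)
    for (g in 1:3) {
      idx <- nz + off[g]
      keep <- idx >= 1L & idx <= n_bins
      newp[idx[keep]] <- newp[idx[keep]] + prob[nz[keep]] * w[g]
    }
    prob <- newp
  }
  nz <- which(prob > 0)
  list(value = lo + (nz - 1L) * h, prob = prob[nz])
}

#' Simulate a cohort under the multiplicative odds-ratio model
#'
#' Draws `N` individuals: genotypes independently `Binomial(2, raf)` per
#' locus, true risk from the logistic model with intercept `beta0` and
#' per-allele log-odds coefficients, and binary outcome by comparing a
#' uniform draw to the true risk. Fully reproducible given `seed`.
#'
#' @param panel a `"variant_panel"`.
#' @param beta0 logistic intercept (see [calibrate_intercept()]).
#' @param N cohort size.
#' @param seed integer seed (required).
#' @return A list of class `"simulated_cohort"` with `genotypes` (N x L
#'   integer matrix), `true_risk`, `outcome` (0/1), `beta0`, `betas`
#'   (per-allele log ORs), `panel` and `seed`.
#' @export
simulate_cohort <- function(panel, beta0, N, seed) {
  stopifnot(inherits(panel, "variant_panel"), N >= 1, is.numeric(seed))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  L <- nrow(panel)
  G <- matrix(0L, nrow = N, ncol = L,
              dimnames = list(NULL, panel$id))
  for (j in seq_len(L)) {
    G[, j] <- stats::rbinom(N, 2L, panel$raf[j])
  }
  betas <- log(panel$or_het)
  # heterozygote effect is per-allele; a non-multiplicative or_hom adds a
  # genotype-specific deviation
  eta <- beta0 + G %*% betas
  dev <- log(panel$or_hom) - 2 * log(panel$or_het)
  if (any(abs(dev) > 1e-12)) {
    eta <- eta + (G == 2L) %*% dev
  }
  risk <- stats::plogis(as.numeric(eta))
  outcome <- as.integer(stats::runif(N) < risk)
  structure(list(genotypes = G, true_risk = risk, outcome = outcome,
                 beta0 = beta0, betas = betas, panel = panel,
                 seed = as.integer(seed)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: N = %d, %d loci, prevalence %.4f (seed %d)\n",
              length(x$outcome), ncol(x$genotypes), mean(x$outcome), x$seed))
  invisible(x)
}

#' Empirical prediction metrics from a simulated cohort
#'
#' Rank-based (Mann-Whitney) AUC of the true risk score against the
#' outcome, with ties counted half; discrimination slope as the mean risk
#' difference between cases and non-cases; proportion of cases captured in
#' the top risk fractions (by sorting); and empirical risk percentiles.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param top_fractions fractions of the population at highest risk for
#'   the cases-explained summaries (default 0.1, 0.2, 0.5).
#' @param percentiles percentiles of the risk distribution to report
#'   (default 0.1 and 0.9).
#' @return A list with `auc`, `discrimination_slope`, `prevalence`,
#'   `prop_cases_explained` (named by fraction), `risk_at_p` (named by
#'   percentile), `rr_between` and `range_between`.
#' @export
empirical_metrics <- function(cohort, top_fractions = c(0.1, 0.2, 0.5),
                              percentiles = c(0.1, 0.9)) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  y <- cohort$outcome
  r <- cohort$true_risk
  n1 <- as.numeric(sum(y == 1L))  # numeric: n1*n0 overflows int at N ~ 1e6
  n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present to compute empirical metrics")
  }
  rk <- rank(r)  # midranks handle ties as 1/2
  auc <- (sum(rk[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(r, decreasing = TRUE)
  cum_cases <- cumsum(y[ord]) / n1
  idx <- pmax(1L, floor(top_fractions * length(y)))
  pce <- stats::setNames(cum_cases[idx], paste0("top", top_fractions))
  qs <- stats::quantile(r, probs = percentiles, names = FALSE, type = 7)
  list(auc = auc,
       discrimination_slope = mean(r[y == 1L]) - mean(r[y == 0L]),
       prevalence = mean(y),
       prop_cases_explained = pce,
       risk_at_p = stats::setNames(qs, paste0("p", percentiles)),
       rr_between = qs[length(qs)] / qs[1],
       range_between = qs[length(qs)] - qs[1])
}

#' Empirical reclassification between nested fitted models
#'
#' Mirrors the two-model protocol used to validate the analytic NRI: an
#' "old" logistic model is refitted on the first `old_loci_count` loci and
#' a "new" model on all loci; individuals are cross-tabulated by the risk
#' categories of their fitted risks, separately in cases and non-cases,
#' and the empirical NRI is returned in the same structure as
#' [reclassification_table()].
#'
#' @param cohort a [simulate_cohort()] result.
#' @param old_loci_count number of leading loci forming the old model
#'   (must be less than the total).
#' @param thresholds strictly increasing risk thresholds in (0, 1).
#' @return An object of class `"reclassification_result"` (with
#'   `models = NULL` and an extra element `fits` holding the two glm
#'   coefficient vectors).
#' @export
empirical_reclassification <- function(cohort, old_loci_count, thresholds) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  L <- ncol(cohort$genotypes)
  if (old_loci_count >= L) {
    stop("'old_loci_count' must be less than the number of loci (", L, ")")
  }
  if (any(thresholds <= 0 | thresholds >= 1) ||
      is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly increasing in (0, 1)")
  }
  y <- cohort$outcome
  fit <- function(cols) {
    df <- as.data.frame(cohort$genotypes[, cols, drop = FALSE])
    m <- stats::glm(y ~ ., data = df, family = stats::binomial())
    if (!m$converged) stop("logistic fit did not converge")
    m
  }
  m_old <- fit(seq_len(old_loci_count))
  m_new <- fit(seq_len(L))
  r_old <- stats::fitted(m_old)
  r_new <- stats::fitted(m_new)
  brk <- c(0, thresholds, 1)
  # half-open [lower, upper): a risk at a threshold joins the upper bin
  bin <- function(r) findInterval(r, brk, rightmost.closed = TRUE,
                                  left.open = FALSE)
  ncat <- length(thresholds) + 1L
  tab <- function(sel) {
    m <- table(factor(bin(r_old)[sel], levels = seq_len(ncat)),
               factor(bin(r_new)[sel], levels = seq_len(ncat)))
    m <- unclass(m)
    m / sum(m)
  }
  a <- tab(y == 1L)
  b <- tab(y == 0L)
  up <- upper.tri(a)
  dn <- lower.tri(a)
  res <- list(thresholds = thresholds, case_matrix = a, control_matrix = b,
              p_up_case = sum(a[up]), p_down_case = sum(a[dn]),
              p_up_control = sum(b[up]), p_down_control = sum(b[dn]),
              models = NULL,
              fits = list(old = stats::coef(m_old), new = stats::coef(m_new)))
  res$nri <- (res$p_up_case - res$p_down_case) -
    (res$p_up_control - res$p_down_control)
  structure(res, class = "reclassification_result")
}

#' Export a simulated cohort to delimited text
#'
#' Writes one row per individual with the genotype vector, true risk and
#' outcome, suitable for external analysis.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  df <- data.frame(id = seq_along(cohort$outcome), cohort$genotypes,
                   true_risk = cohort$true_risk, outcome = cohort$outcome)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
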