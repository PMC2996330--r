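#' Distribution of predicted risks
#'
#' Closed-form distribution of the predicted absolute risk `R` in the
#' population, in cases, or in non-cases. The population cdf is
#' `F(R) = pnorm((T + sqrt(1 - Vm) * qnorm(R)) / sqrt(Vm))` and the density
#' `g(R)` follows by the chain rule. Bayes' rule gives the conditional
#' densities: `R * g(R) / K` in cases and `(1 - R) * g(R) / (1 - K)` in
#' non-cases.
#'
#' @param model a [disease_model()] with `Vm > 0` (at `Vm = 0` the risk
#'   distribution is a point mass at `K` and no density exists).
#' @param group one of `"population"`, `"cases"`, `"noncases"`.
#' @return A list of class `"risk_density"` with vectorised functions
#'   `pdf(R)` and `cdf(R)` on the open support (0, 1), plus `group` and the
#'   originating `model`.
#' @examples
#' d <- risk_density(disease_model(0.005, 0.0442))
#' integrate(d$pdf, 0, 1)$value   # 1
#' @export
risk_density <- function(model,
                         group = c("population", "cases", "noncases")) {
  stopifnot(inherits(model, "disease_model"))
  group <- match.arg(group)
  if (model$constant_risk) {
    stop("risk distribution is a point mass at K when Vm = 0; no density")
  }
  K <- model$K
  Tt <- model$T
  Vm <- model$Vm
  sv <- sqrt(Vm)
  sr <- sqrt(1 - Vm)
  u <- function(R) (Tt + sr * stats::qnorm(R)) / sv
  g_pop <- function(R) {
    stats::dnorm(u(R)) * sr / (sv * stats::dnorm(stats::qnorm(R)))
  }
  pdf <- switch(group,
    population = g_pop,
    cases = function(R) R * g_pop(R) / K,
    noncases = function(R) (1 - R) * g_pop(R) / (1 - K)
  )
  cdf <- switch(group,
    population = function(R) stats::pnorm(u(R)),
    # F_case(r) = P(R <= r | D = 1) = (K - TP(p(r))) / K, with p(r) the
    # population percentile of r; integrals in p-space stay smooth
    cases = function(R) {
      vapply(R, function(r) {
        pr <- percentile_at_risk(model, r)
        (K - tp_integral(model, pr)) / K
      }, numeric(1))
    },
    noncases = function(R) {
      vapply(R, function(r) {
        pr <- percentile_at_risk(model, r)
        (pr - (K - tp_integral(model, pr))) / (1 - K)
      }, numeric(1))
    }
  )
  structure(list(group = group, pdf = pdf, cdf = cdf, model = model),
            class = "risk_density")
}

#' Predictiveness curve
#'
#' Predicted absolute risk plotted against the percentile of measurable
#' liability (equivalently, of risk). The curve is horizontal at `K` when
#' `Vm = 0` and fans out with increasing variance explained, pivoting near
#' the prevalence.
#'
#' @param model a [disease_model()].
#' @param grid number of evenly spaced interior percentiles (default 5000).
#' @return A data frame with columns `p` (percentile), `z` (liability
#'   score `sqrt(Vm) * qnorm(p)`) and `R` (predicted risk).
#' @export
predictiveness_curve <- function(model, grid = 5000L) {
  stopifnot(inherits(model, "disease_model"), grid >= 2)
  p <- seq_len(grid) / (grid + 1)
  data.frame(p = p, z = sqrt(model$Vm) * stats::qnorm(p),
             R = risk_at_percentile(model, p))
}

#' Proportion of cases occurring in the top risk fraction
#'
#' Fraction of all cases found among the `topFraction` of the population at
#' highest predicted risk: `(1/K) * integral of R(p) dp over the top
#' percentiles`. Equals the shaded-area ratio under the predictiveness
#' curve.
#'
#' @param model a [disease_model()].
#' @param topFraction fraction of the population at highest risk, in
#'   `[0, 1]`. Vectorised.
#' @return Proportion(s) of cases explained, in `[0, 1]`.
#' @examples
#' proportion_cases_explained(disease_model(0.005, 0.05), 0.5)  # 0.746
#' @export
proportion_cases_explained <- function(model, topFraction) {
  stopifnot(inherits(model, "disease_model"), is.numeric(topFraction))
  if (any(topFraction < 0 | topFraction > 1)) {
    stop("'topFraction' must lie in [0, 1]")
  }
  vapply(topFraction, function(x) {
    if (x == 0) return(0)
    tp_integral(model, 1 - x) / model$K
  }, numeric(1))
}

#' Cases-explained (Lorenz-type) curve and its area
#'
#' Cumulative proportion of cases captured against the cumulative
#' proportion of the population ranked in descending order of predicted
#' risk. Its area, `(1/K) * integral of TP(c) dc`, is often mistaken for
#' the AUC; the two agree closely only for rare outcomes (compare with
#' [auc_exact()]).
#'
#' @param model a [disease_model()].
#' @param grid number of interior grid points (default 5000).
#' @return A list of class `"cases_explained_curve"` with a data frame
#'   `points` (columns `top_fraction`, `cases_explained`, including the
#'   endpoints (0,0) and (1,1)) and the trapezoidal `area`.
#' @export
cases_explained_curve <- function(model, grid = 5000L) {
  stopifnot(inherits(model, "disease_model"), grid >= 2)
  x <- c(0, seq_len(grid) / (grid + 1), 1)
  y <- c(0, proportion_cases_explained(model, x[-c(1, length(x))]), 1)
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(
    list(points = data.frame(top_fraction = x, cases_explained = y),
         area = area),
    class = "cases_explained_curve"
  )
}

#' @export
print.cases_explained_curve <- function(x, ...) {
  cat(sprintf("Cases-explained curve: %d points, area = %.4f\n",
              nrow(x$points), x$area))
  invisible(x)
}

#' Summary indices of the predicted-risk distribution
#'
#' Dispersion and percentile summaries of the predicted risks. All
#' expectations are computed as integrals over the percentile `p`
#' (`E[h(R)] = integral of h(R(p)) dp`), which keeps the integrand smooth
#' where the risk density `g(R)` is unbounded. Reported are the variance of
#' risks, its ratio to the maximum achievable variance `K(1-K)` (a ratio
#' that equals the discrimination slope exactly), the mean risks in cases
#' (`E[R^2]/K`) and non-cases, the discrimination slope (their difference),
#' the risks at two reference percentiles, and their ratio and range.
#'
#' @param model a [disease_model()].
#' @param p_low,p_high reference percentiles (defaults 0.1 and 0.9).
#' @return A list of class `"risk_summary"` with elements `var_risk`,
#'   `var_ratio`, `mean_risk_cases`, `mean_risk_noncases`,
#'   `discrimination_slope`, `risk_at_p` (named vector at the two
#'   percentiles), `rr_between` and `range_between`.
#' @examples
#' risk_summary(disease_model(0.05, 0.2))
#' @export
risk_summary <- function(model, p_low = 0.1, p_high = 0.9) {
  stopifnot(inherits(model, "disease_model"))
  if (!(p_low > 0 && p_low < p_high && p_high < 1)) {
    stop("need 0 < p_low < p_high < 1")
  }
  K <- model$K
  if (model$constant_risk) {
    out <- list(var_risk = 0, var_ratio = 0, mean_risk_cases = K,
                mean_risk_noncases = K, discrimination_slope = 0,
                risk_at_p = stats::setNames(c(K, K),
                                            paste0("p", c(p_low, p_high))),
                rr_between = 1, range_between = 0)
    return(structure(out, class = "risk_summary"))
  }
  ER2 <- stats::integrate(function(p) risk_at_percentile(model, p)^2,
                          0, 1, rel.tol = 1e-10, abs.tol = 1e-12,
                          subdivisions = 400L)$value
  var_risk <- ER2 - K^2
  mean_cases <- ER2 / K
  mean_noncases <- (K - ER2) / (1 - K)
  r_lo <- risk_at_percentile(model, p_low)
  r_hi <- risk_at_percentile(model, p_high)
  structure(
    list(var_risk = var_risk,
         var_ratio = var_risk / (K * (1 - K)),
         mean_risk_cases = mean_cases,
         mean_risk_noncases = mean_noncases,
         discrimination_slope = mean_cases - mean_noncases,
         risk_at_p = stats::setNames(c(r_lo, r_hi),
                                     paste0("p", c(p_low, p_high))),
         rr_between = r_hi / r_lo,
         range_between = r_hi - r_lo),
    class = "risk_summary"
  )
}

#' @export
print.risk_summary <- function(x, ...) {
  cat("Predicted-risk summary\n")
  cat(sprintf("  var(R)            %.4g\n", x$var_risk))
  cat(sprintf("  var(R)/K(1-K)     %.4f\n", x$var_ratio))
  cat(sprintf("  mean risk cases   %.4f\n", x$mean_risk_cases))
  cat(sprintf("  mean risk noncases %.4f\n", x$mean_risk_noncases))
  cat(sprintf("  discrimination slope %.4f\n", x$discrimination_slope))
  cat(sprintf("  risk at %s  %.4f ; at %s  %.4f\n",
              names(x$risk_at_p)[1], x$risk_at_p[1],
              names(x$risk_at_p)[2], x$risk_at_p[2]))
  cat(sprintf("  RR between        %.2f ; range %.4f\n",
              x$rr_between, x$range_between))
  invisible(x)
}
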