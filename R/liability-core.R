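#' Disease model under the liability threshold framework
#'
#' Constructs the basic object of the framework: a disease with overall
#' probability `K` (lifetime or period risk) and a measurable (known-factor)
#' liability component explaining a proportion `Vm` of the unit total
#' liability variance. Total liability is standard normal; disease occurs
#' when it exceeds the threshold `T = qnorm(1 - K)`. Conditional on a
#' measurable liability score `z`, total liability is `N(z, 1 - Vm)`.
#'
#' `Vm` below `1e-12` is treated as exactly zero (constant-risk model): every
#' individual's predicted risk is `K` and dispersion-based indices degenerate.
#'
#' @param K overall probability of disease, in (0, 1).
#' @param Vm proportion of liability variance explained by measured factors,
#'   in `[0, 1)`. Interpretable as the heritability captured by the known
#'   variants when the measured factors are genetic.
#' @return An object of class `"disease_model"`: a list with elements `K`,
#'   `Vm`, `T` (liability threshold) and `constant_risk` (logical flag for
#'   the degenerate `Vm = 0` case).
#' @examples
#' m <- disease_model(K = 0.005, Vm = 0.05)
#' m$T                      # liability threshold, about 2.576
#' risk_at_percentile(m, 0.9)
#' @export
disease_model <- function(K, Vm) {
  stopifnot(is.numeric(K), length(K) == 1L, is.finite(K))
  stopifnot(is.numeric(Vm), length(Vm) == 1L, is.finite(Vm))
  if (K <= 0 || K >= 1) {
    stop("'K' must lie strictly in (0, 1), got ", format(K))
  }
  if (Vm < 0 || Vm >= 1) {
    stop("'Vm' must lie in [0, 1), got ", format(Vm))
  }
  constant <- Vm < 1e-12
  structure(
    list(K = K, Vm = if (constant) 0 else Vm,
         T = liability_threshold(K), constant_risk = constant),
    class = "disease_model"
  )
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Liability threshold disease model\n")
  cat(sprintf("  K (disease probability): %g\n", x$K))
  cat(sprintf("  Vm (variance explained): %g%s\n", x$Vm,
              if (x$constant_risk) "  [constant-risk model]" else ""))
  cat(sprintf("  T (liability threshold): %.6f\n", x$T))
  invisible(x)
}

#' Liability threshold for a given disease probability
#'
#' The threshold `T` on the standard-normal liability scale above which
#' disease occurs, so that the upper-tail mass beyond `T` equals `K`.
#'
#' @param K overall probability of disease, in (0, 1).
#' @return The threshold `T = qnorm(1 - K)`, computed with the upper-tail
#'   form so that rare diseases (`K < 1e-3`) lose no precision.
#' @export
liability_threshold <- function(K) {
  stopifnot(is.numeric(K), all(is.finite(K)))
  if (any(K <= 0 | K >= 1)) {
    stop("'K' must lie strictly in (0, 1)")
  }
  stats::qnorm(K, lower.tail = FALSE)
}

#' Conditional moments of liability in cases and controls
#'
#' Moments of the overall and measurable liability after selecting on
#' disease status. Selecting cases truncates the overall liability below
#' `T`, giving mean `a = dnorm(T)/K` and variance `b = 1 + T*a - a^2`;
#' controls are truncated above `T` with mean `dnorm(T)/(K - 1)` and the
#' analogous variance. The Pearson-Aitken selection formula then shrinks
#' these onto the measurable component: within cases the measurable
#' liability has mean `a*Vm` and variance `Vm * (1 - (1 - b) * Vm)`, and
#' similarly within controls.
#'
#' @param model a [disease_model()].
#' @return A list of class `"conditional_moments"` with elements
#'   `mean_overall_case` (a), `var_overall_case` (b), `mean_overall_control`,
#'   `var_overall_control`, `mean_meas_case`, `var_meas_case`,
#'   `mean_meas_control`, `var_meas_control`.
#' @export
conditional_moments <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  K <- model$K
  Tt <- model$T
  Vm <- model$Vm
  a <- stats::dnorm(Tt) / K           # truncated-normal mean, cases
  b <- 1 + Tt * a - a^2               # truncated-normal variance, cases
  c0 <- -stats::dnorm(Tt) / (1 - K)   # truncated-normal mean, controls
  d <- 1 + Tt * c0 - c0^2             # truncated-normal variance, controls
  structure(
    list(
      mean_overall_case = a,
      var_overall_case = b,
      mean_overall_control = c0,
      var_overall_control = d,
      mean_meas_case = a * Vm,
      var_meas_case = Vm * (1 - (1 - b) * Vm),
      mean_meas_control = c0 * Vm,
      var_meas_control = Vm * (1 - (1 - d) * Vm)
    ),
    class = "conditional_moments"
  )
}

#' Predicted absolute risk at a percentile of measurable liability
#'
#' For an individual at lower-tail percentile `p` of the measurable
#' liability, the liability score is `z = sqrt(Vm) * qnorm(p)` and the
#' predicted absolute risk is the chance that the overall liability,
#' `N(z, 1 - Vm)`, exceeds the threshold:
#' `R(p) = pnorm((T - sqrt(Vm) * qnorm(p)) / sqrt(1 - Vm), lower.tail = FALSE)`.
#'
#' @param model a [disease_model()].
#' @param p percentile(s) of measurable liability, strictly in (0, 1).
#'   Vectorised.
#' @return Predicted absolute risk(s), strictly increasing in `p` when
#'   `Vm > 0`; identically `K` when `Vm = 0`.
#' @export
risk_at_percentile <- function(model, p) {
  stopifnot(inherits(model, "disease_model"), is.numeric(p))
  if (any(p <= 0 | p >= 1)) {
    stop("'p' must lie strictly in (0, 1)")
  }
  if (model$constant_risk) {
    return(rep(model$K, length(p)))
  }
  z <- sqrt(model$Vm) * stats::qnorm(p)
  stats::pnorm((model$T - z) / sqrt(1 - model$Vm), lower.tail = FALSE)
}

#' Percentile of measurable liability at a given predicted risk
#'
#' Exact inverse of [risk_at_percentile()]:
#' `p = pnorm((T + sqrt(1 - Vm) * qnorm(R)) / sqrt(Vm))`.
#'
#' @param model a [disease_model()] with `Vm > 0`.
#' @param R predicted absolute risk(s), strictly in (0, 1). Vectorised.
#' @return Percentile(s) in (0, 1).
#' @export
percentile_at_risk <- function(model, R) {
  stopifnot(inherits(model, "disease_model"), is.numeric(R))
  if (model$constant_risk) {
    stop("percentile_at_risk() is undefined when Vm = 0: risk is constant at K")
  }
  if (any(R <= 0 | R >= 1)) {
    stop("'R' must lie strictly in (0, 1)")
  }
  stats::pnorm((model$T + sqrt(1 - model$Vm) * stats::qnorm(R)) /
                 sqrt(model$Vm))
}
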