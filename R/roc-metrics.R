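#' True-positive mass above a percentile cutoff
#'
#' `TP(c) = integral of R(p) dp over (c, 1)`: the joint probability of
#' testing positive (measurable-liability percentile above `c`) and being
#' affected. Computed by adaptive quadrature in percentile space, where the
#' integrand is smooth even for rare diseases.
#'
#' @param model a [disease_model()].
#' @param cutoff percentile cutoff in `[0, 1)`.
#' @return The probability mass `TP(cutoff)`.
#' @keywords internal
tp_integral <- function(model, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (model$constant_risk) {
    return(model$K * (1 - cutoff))
  }
  if (cutoff > 1 - 1e-12) {
    return(0)
  }
  stats::integrate(function(p) risk_at_percentile(model, p),
                   lower = cutoff, upper = 1,
                   rel.tol = 1e-8, abs.tol = 1e-9,
                   subdivisions = 400L)$value
}

#' Classification table at a percentile cutoff
#'
#' Population 2x2 table for the test "measurable-liability percentile
#' exceeds `c`". The TP cell is the integral of the predicted risk over
#' percentiles above `c`; the remaining cells follow from the margins
#' (row sums `1 - c` and `c`, column sums `K` and `1 - K`).
#'
#' @param model a [disease_model()].
#' @param cutoff percentile cutoff `c`, strictly in (0, 1).
#' @return A list of class `"classification_table"` with cells `TP`, `FP`,
#'   `FN`, `TN` (population fractions), the `cutoff`, and the derived
#'   `sensitivity`, `specificity`, `PPV`, `NPV`.
#' @examples
#' m <- disease_model(0.1, 0.2)
#' classification_table(m, 0.8)
#' @export
classification_table <- function(model, cutoff) {
  stopifnot(inherits(model, "disease_model"))
  if (cutoff <= 0 || cutoff >= 1) {
    stop("'cutoff' must lie strictly in (0, 1)")
  }
  K <- model$K
  TP <- tp_integral(model, cutoff)
  FN <- K - TP
  FP <- (1 - cutoff) - TP
  TN <- cutoff - FN
  structure(
    list(TP = TP, FP = FP, FN = FN, TN = TN, cutoff = cutoff,
         sensitivity = TP / K, specificity = TN / (1 - K),
         PPV = TP / (1 - cutoff), NPV = TN / cutoff),
    class = "classification_table"
  )
}

#' @export
print.classification_table <- function(x, ...) {
  cat(sprintf("Classification table at percentile cutoff c = %g\n", x$cutoff))
  m <- matrix(c(x$TP, x$FP, x$FN, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("Test +", "Test -"),
                              c("Disease +", "Disease -")))
  print(round(m, 6))
  cat(sprintf("sensitivity %.4f  specificity %.4f  PPV %.4f  NPV %.4f\n",
              x$sensitivity, x$specificity, x$PPV, x$NPV))
  invisible(x)
}

#' ROC curve from the liability model
#'
#' Sensitivity and 1 - specificity evaluated over an equally spaced grid of
#' interior percentile cutoffs, with the endpoints (0,0) and (1,1) appended,
#' and the area obtained by trapezoidal integration.
#'
#' @param model a [disease_model()].
#' @param n_cutoffs number of interior percentile cutoffs (default 5000).
#' @return A list of class `"roc_curve"` with a data frame `points`
#'   (columns `FPR`, `TPR`, ordered along the curve) and the scalar `auc`.
#' @examples
#' roc_curve(disease_model(0.005, 0.05))$auc   # about 0.678
#' @export
roc_curve <- function(model, n_cutoffs = 5000L) {
  stopifnot(inherits(model, "disease_model"), n_cutoffs >= 2)
  K <- model$K
  cuts <- seq_len(n_cutoffs) / (n_cutoffs + 1)
  if (model$constant_risk) {
    TPc <- K * (1 - cuts)
  } else {
    TPc <- vapply(cuts, function(cc) tp_integral(model, cc), numeric(1))
  }
  TPR <- TPc / K
  FPR <- ((1 - cuts) - TPc) / (1 - K)
  FPR <- c(1, FPR, 0)
  TPR <- c(1, TPR, 0)
  ord <- order(FPR, TPR)
  FPR <- FPR[ord]
  TPR <- TPR[ord]
  auc <- sum(diff(FPR) * (utils::head(TPR, -1) + utils::tail(TPR, -1)) / 2)
  structure(list(points = data.frame(FPR = FPR, TPR = TPR), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Exact AUC by the closed-form integral
#'
#' The area under the ROC curve equals
#' `1/(K(1-K)) * integral over c in (0,1) of TP(c) * (1 - R(c)) dc`,
#' which follows from integrating sensitivity against the differential of
#' 1 - specificity in cutoff space. Evaluated by nested adaptive quadrature.
#'
#' @param model a [disease_model()].
#' @return The exact AUC; 0.5 when `Vm = 0`.
#' @export
auc_exact <- function(model) {
  stopifnot(inherits(model, "disease_model"))
  if (model$constant_risk) {
    return(0.5)
  }
  K <- model$K
  f <- function(cv) {
    vapply(cv, function(cc) {
      tp_integral(model, cc) * (1 - risk_at_percentile(model, cc))
    }, numeric(1))
  }
  val <- stats::integrate(f, 0, 1, rel.tol = 1e-9, abs.tol = 1e-10,
                          subdivisions = 400L)$value
  val / (K * (1 - K))
}

#' Binormal approximation to the AUC
#'
#' Approximates the AUC by assuming the measurable liability is normal
#' within cases and controls, with moments from the Pearson-Aitken formula
#' ([conditional_moments()]). With `equal_variance = FALSE` the standard
#' binormal result
#' `pnorm((mu_case - mu_control) / sqrt(sd_case^2 + sd_control^2))` is used.
#' With `equal_variance = TRUE` the two conditional variances are replaced
#' by their common unselected value `Vm`, giving the spreadsheet-friendly
#' form `pnorm((mu_case - mu_control) / sqrt(2 * Vm))`; the conditional
#' variances shrink only mildly under selection, so this is adequate
#' especially for common diseases.
#'
#' @param model a [disease_model()].
#' @param equal_variance assume equal case/control variances (default FALSE).
#' @return Approximate AUC; 0.5 when `Vm = 0`.
#' @export
auc_binormal <- function(model, equal_variance = FALSE) {
  stopifnot(inherits(model, "disease_model"))
  if (model$constant_risk) {
    return(0.5)
  }
  mm <- conditional_moments(model)
  num <- mm$mean_meas_case - mm$mean_meas_control
  den <- if (equal_variance) {
    sqrt(2 * model$Vm)
  } else {
    sqrt(mm$var_meas_case + mm$var_meas_control)
  }
  stats::pnorm(num / den)
}

#' Approximate TPR and FPR at an absolute-risk threshold
#'
#' Converts an absolute risk threshold `Rstar` to the corresponding
#' measurable-liability value `z* = T + sqrt(1 - Vm) * qnorm(Rstar)` and
#' reads off the upper-tail mass beyond `z*` within the binormal case and
#' control distributions.
#'
#' @param model a [disease_model()] with `Vm > 0`.
#' @param Rstar absolute risk threshold, strictly in (0, 1).
#' @return A named numeric vector `c(TPR = , FPR = )`.
#' @export
rates_at_risk_threshold <- function(model, Rstar) {
  stopifnot(inherits(model, "disease_model"))
  if (model$constant_risk) {
    stop("rates_at_risk_threshold() requires Vm > 0")
  }
  if (Rstar <= 0 || Rstar >= 1) {
    stop("'Rstar' must lie strictly in (0, 1)")
  }
  zs <- model$T + sqrt(1 - model$Vm) * stats::qnorm(Rstar)
  mm <- conditional_moments(model)
  c(TPR = stats::pnorm((zs - mm$mean_meas_case) / sqrt(mm$var_meas_case),
                       lower.tail = FALSE),
    FPR = stats::pnorm((zs - mm$mean_meas_control) / sqrt(mm$var_meas_control),
                       lower.tail = FALSE))
}
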