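#' Nested risk-model pair
#'
#' Describes two nested prediction models for the same disease: an "old"
#' model explaining `Vold` of the liability variance and a "new" model
#' explaining `Vnew`. Under the default of an independently added risk
#' factor, the covariance between the two measurable liabilities equals
#' `Vold` (the old factors are a subset of the new). A correlated addition
#' can be expressed by supplying `cov_old_new` directly; the implied 3x3
#' covariance matrix of (overall, old, new) liability must be positive
#' semidefinite.
#'
#' @param K overall disease probability, in (0, 1).
#' @param Vold,Vnew variance explained under the old and new models, each
#'   in `[0, 1)`.
#' @param cov_old_new covariance between old and new measurable liabilities
#'   (default `Vold`, the independent-addition case).
#' @return An object of class `"nested_models"`.
#' @export
nested_models <- function(K, Vold, Vnew, cov_old_new = Vold) {
  stopifnot(K > 0, K < 1, Vold >= 0, Vold < 1, Vnew >= 0, Vnew < 1)
  sigma <- matrix(c(1, Vold, Vnew,
                    Vold, Vold, cov_old_new,
                    Vnew, cov_old_new, Vnew), 3, 3)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop("covariance matrix of (overall, old, new) liability is not ",
         "positive semidefinite; check Vold=", Vold, ", Vnew=", Vnew,
         ", cov_old_new=", cov_old_new)
  }
  structure(list(K = K, Vold = Vold, Vnew = Vnew,
                 cov_old_new = cov_old_new, sigma = sigma,
                 T = liability_threshold(K)),
            class = "nested_models")
}

#' Measurable-liability cutpoints for risk-category thresholds
#'
#' Inverts the percentile-risk relation for a model with variance explained
#' `V`: the measurable-liability value whose predicted risk equals `r` is
#' `z = T + sqrt(1 - V) * qnorm(r)`.
#'
#' @param K disease probability.
#' @param V variance explained, in `[0, 1)`.
#' @param thresholds strictly increasing risk thresholds in (0, 1).
#' @return Numeric vector of liability cutpoints, strictly increasing.
#' @export
risk_category_cutpoints <- function(K, V, thresholds) {
  stopifnot(V >= 0, V < 1, all(thresholds > 0), all(thresholds < 1))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly increasing")
  }
  liability_threshold(K) + sqrt(1 - V) * stats::qnorm(thresholds)
}

#' Joint case/control moments of the old and new measurable liabilities
#'
#' Pearson-Aitken conditioning of the bivariate measurable-liability vector
#' (old model, new model) on disease status. Selecting cases truncates the
#' overall liability below `T` (mean `a`, variance `b`); the measurable
#' vector then has mean `a * v` and covariance `Sigma_m - (1 - b) * v v'`,
#' where `v = (Vold, Vnew)'` is the covariance of the measurable vector
#' with the overall liability and `Sigma_m` its unconditional covariance.
#' Controls are handled with the upper-truncation moments.
#'
#' @param models a [nested_models()] object.
#' @return A list with components `case` and `control`, each holding
#'   `mean` (length 2), `cov` (2x2), `sd` and `cor`.
#' @export
joint_conditional_moments <- function(models) {
  stopifnot(inherits(models, "nested_models"))
  mm <- conditional_moments(disease_model(models$K, 0))
  v <- c(models$Vold, models$Vnew)
  sigma_m <- models$sigma[2:3, 2:3]
  shrink <- function(mean_overall, var_overall) {
    mu <- mean_overall * v
    cv <- sigma_m - (1 - var_overall) * tcrossprod(v)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      stop("conditional covariance not positive semidefinite for Vold=",
           models$Vold, ", Vnew=", models$Vnew,
           ", cov_old_new=", models$cov_old_new)
    }
    sd <- sqrt(pmax(diag(cv), 0))
    rho <- if (all(sd > 0)) cv[1, 2] / prod(sd) else 1
    list(mean = mu, cov = cv, sd = sd, cor = max(-1, min(1, rho)))
  }
  list(case = shrink(mm$mean_overall_case, mm$var_overall_case),
       control = shrink(mm$mean_overall_control, mm$var_overall_control))
}

#' Analytic reclassification table and net reclassification improvement
#'
#' Cross-tabulates, separately within cases and non-cases, the risk
#' category occupied under the old and new models, using bivariate-normal
#' rectangle probabilities over the liability cutpoints of
#' [risk_category_cutpoints()]. Categories are half-open `[lower, upper)`:
#' a risk exactly at a threshold belongs to the upper category (a
#' measure-zero convention in the continuous model). The net
#' reclassification improvement is
#' `NRI = (P(up|case) - P(down|case)) - (P(up|control) - P(down|control))`.
#'
#' @param models a [nested_models()] object.
#' @param thresholds strictly increasing risk thresholds in (0, 1) defining
#'   the categories (e.g. `c(0.06, 0.2)` for the ATP-III style 0-6%,
#'   6-20%, >20% bins).
#' @return An object of class `"reclassification_result"`: list with
#'   `thresholds`, `case_matrix`, `control_matrix` (rows = old category,
#'   columns = new category, each normalised within its group),
#'   `p_up_case`, `p_down_case`, `p_up_control`, `p_down_control`, `nri`,
#'   and the originating `models`.
#' @examples
#' nm <- nested_models(0.05, 0.05, 0.1)
#' reclassification_table(nm, c(0.06, 0.2))$nri   # about 0.099
#' @export
reclassification_table <- function(models, thresholds) {
  stopifnot(inherits(models, "nested_models"), length(thresholds) >= 1)
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("'thresholds' must lie strictly in (0, 1)")
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("'thresholds' must be strictly increasing")
  }
  z_old <- c(-Inf, risk_category_cutpoints(models$K, models$Vold, thresholds),
             Inf)
  z_new <- c(-Inf, risk_category_cutpoints(models$K, models$Vnew, thresholds),
             Inf)
  jm <- joint_conditional_moments(models)
  ncat <- length(thresholds) + 1L
  cell_matrix <- function(g) {
    m <- matrix(0, ncat, ncat)
    for (i in seq_len(ncat)) {
      for (j in seq_len(ncat)) {
        m[i, j] <- .bvn_rect(z_old[i], z_old[i + 1L],
                             z_new[j], z_new[j + 1L],
                             g$mean, g$sd, g$cor)
      }
    }
    m / sum(m)
  }
  a <- cell_matrix(jm$case)
  b <- cell_matrix(jm$control)
  up <- upper.tri(a)
  dn <- lower.tri(a)
  res <- list(thresholds = thresholds,
              case_matrix = a, control_matrix = b,
              p_up_case = sum(a[up]), p_down_case = sum(a[dn]),
              p_up_control = sum(b[up]), p_down_control = sum(b[dn]),
              models = models)
  res$nri <- (res$p_up_case - res$p_down_case) -
    (res$p_up_control - res$p_down_control)
  structure(res, class = "reclassification_result")
}

#' @export
print.reclassification_result <- function(x, ...) {
  cat(sprintf("Reclassification at thresholds %s\n",
              paste(x$thresholds, collapse = ", ")))
  cat("Cases (rows old, cols new):\n")
  print(round(x$case_matrix, 4))
  cat("Non-cases:\n")
  print(round(x$control_matrix, 4))
  cat(sprintf("up|case %.4f  down|case %.4f  up|ctrl %.4f  down|ctrl %.4f\n",
              x$p_up_case, x$p_down_case, x$p_up_control, x$p_down_control))
  cat(sprintf("NRI = %.4f\n", x$nri))
  invisible(x)
}

#' Weighted or shift-scored net reclassification improvement
#'
#' Generalises the NRI by weighting its four components (loss functions
#' for moving cases down may differ from moving controls up), and
#' optionally scoring each transition by the number of categories moved
#' rather than by direction alone.
#'
#' @param result a [reclassification_table()] result.
#' @param weights length-4 numeric: weights for up-in-cases, down-in-cases,
#'   up-in-controls, down-in-controls (all 1 reduces to the plain NRI).
#' @param category_shift_scores if `TRUE`, each transition contributes its
#'   absolute category distance `|i - j|` instead of 1.
#' @return The weighted NRI value.
#' @export
weighted_nri <- function(result, weights = c(1, 1, 1, 1),
                         category_shift_scores = FALSE) {
  stopifnot(inherits(result, "reclassification_result"),
            length(weights) == 4, is.numeric(weights))
  a <- result$case_matrix
  b <- result$control_matrix
  n <- nrow(a)
  score <- if (category_shift_scores) {
    abs(outer(seq_len(n), seq_len(n), "-"))
  } else {
    matrix(1, n, n)
  }
  up <- upper.tri(a)
  dn <- lower.tri(a)
  (weights[1] * sum((a * score)[up]) - weights[2] * sum((a * score)[dn])) -
    (weights[3] * sum((b * score)[up]) - weights[4] * sum((b * score)[dn]))
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slope (mean predicted risk in cases minus
#' non-cases) between the new and old models, computed from the analytic
#' risk distribution of each.
#'
#' @param models a [nested_models()] object.
#' @return The IDI value.
#' @export
idi <- function(models) {
  stopifnot(inherits(models, "nested_models"))
  s_new <- risk_summary(disease_model(models$K, models$Vnew))
  s_old <- risk_summary(disease_model(models$K, models$Vold))
  s_new$discrimination_slope - s_old$discrimination_slope
}
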