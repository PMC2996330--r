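#' Read a variant panel from a delimited text file
#'
#' A panel is a table of independent susceptibility variants with columns
#' `id`, `raf` (risk-allele frequency) and `or` (per-allele odds ratio);
#' an optional `or_hom` column overrides the default multiplicative
#' homozygote odds ratio `or^2`. The dialect (TSV or CSV) is detected from
#' the file extension (`.csv` means comma; anything else tab). Genotype
#' frequencies are filled in under Hardy-Weinberg equilibrium.
#'
#' @param path path to the panel file.
#' @return A data frame of class `"variant_panel"` with columns `id`,
#'   `raf`, `or_het`, `or_hom`, `f0`, `f1`, `f2` (HWE genotype
#'   frequencies for 0, 1, 2 copies of the risk allele).
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0) stop("no variants in panel file: ", path)
  need <- c("id", "raf", "or")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("panel file missing column(s): ", paste(missing, collapse = ", "))
  }
  variant_panel(id = as.character(df$id), raf = df$raf, or_het = df$or,
                or_hom = if ("or_hom" %in% names(df)) df$or_hom else NULL)
}

#' Construct a variant panel from vectors
#'
#' @param id variant identifiers.
#' @param raf risk-allele frequencies, each strictly in (0, 1).
#' @param or_het heterozygote odds ratios (per-allele), positive.
#' @param or_hom homozygote odds ratios; default `or_het^2`
#'   (multiplicative model, additive on the log-odds scale).
#' @return A data frame of class `"variant_panel"`.
#' @export
variant_panel <- function(id, raf, or_het, or_hom = NULL) {
  if (is.null(or_hom)) or_hom <- or_het^2
  n <- length(id)
  stopifnot(length(raf) == n, length(or_het) == n, length(or_hom) == n)
  bad <- which(!is.finite(raf) | raf <= 0 | raf >= 1)
  if (length(bad)) {
    stop("invalid raf (must be in (0,1)) at row(s): ",
         paste(bad, collapse = ", "), " [id: ",
         paste(id[bad], collapse = ", "), "]")
  }
  bad <- which(!is.finite(or_het) | or_het <= 0 |
                 !is.finite(or_hom) | or_hom <= 0)
  if (length(bad)) {
    stop("invalid odds ratio (must be > 0) at row(s): ",
         paste(bad, collapse = ", "))
  }
  q <- raf
  structure(
    data.frame(id = as.character(id), raf = q, or_het = or_het,
               or_hom = or_hom, f0 = (1 - q)^2, f1 = 2 * q * (1 - q),
               f2 = q^2, stringsAsFactors = FALSE),
    class = c("variant_panel", "data.frame")
  )
}

#' Genotype-specific absolute risks from an odds ratio
#'
#' Converts the per-genotype odds ratios of one variant into absolute
#' risks consistent with the overall disease probability `K`: the baseline
#' (non-carrier) risk `P0` is found by root-finding so that the
#' HWE-weighted mean of the three genotype risks equals `K`, where each
#' genotype risk comes from multiplying the baseline odds by the genotype
#' odds ratio. This is the cohort-study odds-ratio-to-risk-ratio
#' correction generalised to three genotype classes; the resulting risk
#' ratios converge to the odds ratios as `K` tends to 0.
#'
#' @param variant a single-row `"variant_panel"` (or a list with fields
#'   `raf`, `or_het`, `or_hom`, `f0`, `f1`, `f2`).
#' @param K overall disease probability.
#' @return A list of class `"genotype_risks"` with `baseline_risk`,
#'   `absolute_risks` (length 3), `relative_risks` (reference genotype 1)
#'   and `genotype_freqs`.
#' @export
or_to_genotype_risks <- function(variant, K) {
  stopifnot(K > 0, K < 1)
  v <- as.list(variant)
  ors <- c(1, v$or_het, v$or_hom)
  f <- c(v$f0, v$f1, v$f2)
  mean_risk <- function(p0) {
    sum(f * stats::plogis(stats::qlogis(p0) + log(ors))) - K
  }
  eps <- .Machine$double.eps
  root <- tryCatch(
    stats::uniroot(mean_risk, lower = eps, upper = 1 - 1e-12,
                   tol = 1e-14)$root,
    error = function(e) stop("no baseline risk in (0,1) satisfies the ",
                             "mean-risk constraint: ", conditionMessage(e))
  )
  abs_risks <- stats::plogis(stats::qlogis(root) + log(ors))
  structure(
    list(baseline_risk = root, absolute_risks = abs_risks,
         relative_risks = abs_risks / abs_risks[1], genotype_freqs = f),
    class = "genotype_risks"
  )
}

#' Liability variance explained by a variant panel
#'
#' For each variant the genotype absolute risks (from
#' [or_to_genotype_risks()]) are mapped to genotype liability means against
#' the population threshold, `mu_g = T - qnorm(1 - risk_g)`, assuming unit
#' residual variance; the per-locus contribution is the variance of
#' `mu_g` under the HWE genotype frequencies. Contributions add over
#' independent loci. This single-locus threshold-shift construction is an
#' approximation that is accurate for the small per-locus effects typical
#' of GWAS hits; see the methods vignette for its limits.
#'
#' @param panel a `"variant_panel"`.
#' @param K overall disease probability.
#' @return Total variance explained `Vm` in `[0, 1)`.
#' @examples
#' p <- variant_panel("rs1", raf = 0.3, or_het = 1.5)
#' variance_explained(p, K = 0.005)
#' @export
variance_explained <- function(panel, K) {
  stopifnot(inherits(panel, "variant_panel"))
  Tt <- liability_threshold(K)
  vm <- 0
  for (i in seq_len(nrow(panel))) {
    gr <- or_to_genotype_risks(panel[i, ], K)
    mu <- Tt - stats::qnorm(gr$absolute_risks, lower.tail = FALSE)
    f <- gr$genotype_freqs
    vm <- vm + sum(f * mu^2) - sum(f * mu)^2
  }
  if (vm >= 1) {
    stop("panel explains variance >= 1 on the liability scale; ",
         "the additive small-effect approximation has broken down")
  }
  vm
}

#' Generate a random synthetic variant panel
#'
#' Seeded fixture generator emulating a GWAS-era susceptibility panel:
#' risk-allele frequencies uniform on a plausible range and per-allele
#' odds ratios log-uniform on a modest-effect range, multiplicative over
#' genotypes. Intended for tests and simulation studies; it emulates the
#' shape of real panels (many loci, small effects), not any specific
#' disease.
#'
#' @param n_loci number of variants.
#' @param seed integer seed (required, for reproducibility).
#' @param raf_range range of allele frequencies (default 0.05-0.95).
#' @param or_range range of per-allele odds ratios (default 1.05-1.6).
#' @return A `"variant_panel"`.
#' @export
random_panel <- function(n_loci, seed, raf_range = c(0.05, 0.95),
                         or_range = c(1.05, 1.6)) {
  stopifnot(n_loci >= 1, is.numeric(seed))
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))
  raf <- stats::runif(n_loci, raf_range[1], raf_range[2])
  or_het <- exp(stats::runif(n_loci, log(or_range[1]), log(or_range[2])))
  variant_panel(id = sprintf("locus%02d", seq_len(n_loci)),
                raf = raf, or_het = or_het)
}
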