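#' Construct a limiting-dilution assay
#'
#' @param doses Cells per well at each dilution (e.g. `c(1, 5, 10)`).
#' @param n_wells Total wells per dose.
#' @param n_positive Wells with spheres per dose.
#' @return Data frame of class `dilution_assay`.
#' @export
dilution_assay <- function(doses, n_wells, n_positive) {
  if (any(doses <= 0)) stop("doses must be > 0")
  if (any(n_wells < 0) || any(n_positive < 0) || any(n_positive > n_wells))
    stop("need 0 <= n_positive <= n_wells")
  d <- data.frame(dose = as.numeric(doses), n_wells = as.integer(n_wells),
                  n_positive = as.integer(n_positive))
  class(d) <- c("dilution_assay", "data.frame")
  d
}

# Log-likelihood of the single-hit Poisson model at frequency lambda:
# P(positive well | dose d) = 1 - exp(-lambda * d).
elda_loglik <- function(lambda, assay) {
  d <- assay$dose; pos <- assay$n_positive; neg <- assay$n_wells - pos
  if (lambda <= 0) return(if (sum(pos) == 0) 0 else -Inf)
  if (!is.finite(lambda)) return(if (sum(neg) == 0) 0 else -Inf)
  # log(1 - exp(-lambda d)) computed stably via expm1
  sum(pos * log(-expm1(-lambda * d))) - lambda * sum(neg * d)
}

#' Fit the single-hit Poisson limiting-dilution model
#'
#' Maximum-likelihood estimate of the sphere-forming frequency
#' `lambda` under `P(positive | dose d) = 1 - exp(-lambda d)`, with a 95%
#' profile-likelihood confidence interval (chi-square_1 cutoff 3.841 on
#' log lambda).  Results are reported in the conventional "1/N" display
#' where `N = 1/lambda` is cells per sphere-forming cell, so the lower
#' confidence limit is the larger N.  Boundary cases: all wells negative
#' gives `lambda = 0` ("1/Inf") with a finite upper-N bound; all wells
#' positive gives `lambda = Inf` with a finite lower-N bound.
#'
#' @param assay A `dilution_assay` (or data frame with columns `dose`,
#'   `n_wells`, `n_positive`).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `elda_fit` with `lambda_hat`, `N_hat`,
#'   `ci_lower_N`, `ci_upper_N` (N-scale, `ci_upper_N <= N_hat <=
#'   ci_lower_N` when finite), `loglik`, `assay`, `conf_level`.
#' @export
elda_fit <- function(assay, conf_level = 0.95) {
  assay <- assay[assay$n_wells > 0, , drop = FALSE]
  if (!nrow(assay)) stop("no dose with n_wells > 0")
  if (any(assay$dose <= 0)) stop("doses must be > 0")
  total_pos <- sum(assay$n_positive)
  total_neg <- sum(assay$n_wells - assay$n_positive)
  cut <- stats::qchisq(conf_level, df = 1) / 2

  ll <- function(x) elda_loglik(exp(x), assay)

  if (total_pos == 0L) {
    # all negative: MLE at the lambda = 0 boundary, loglik sup = 0
    lambda_hat <- 0; llmax <- 0
    # upper bound solves -lambda * sum(n d) = -cut exactly
    lam_up <- cut / sum(assay$n_wells * assay$dose)
    lam_lo <- 0
  } else if (total_neg == 0L) {
    # all positive: MLE at the lambda = Inf boundary, loglik sup = 0
    lambda_hat <- Inf; llmax <- 0
    lam_up <- Inf
    f <- function(x) ll(x) + cut
    lo <- 0; while (f(lo) > 0) lo <- lo - 5
    lam_lo <- exp(stats::uniroot(f, c(lo, lo + 5), tol = 1e-10)$root)
  } else {
    opt <- stats::optimize(ll, interval = c(-25, 10), maximum = TRUE,
                           tol = 1e-10)
    lambda_hat <- exp(opt$maximum); llmax <- opt$objective
    f <- function(x) ll(x) - (llmax - cut)
    lo <- opt$maximum; while (f(lo) > 0) lo <- lo - 2
    lam_lo <- exp(stats::uniroot(f, c(lo, opt$maximum), tol = 1e-10)$root)
    hi <- opt$maximum; while (f(hi) > 0 && hi < 50) hi <- hi + 2
    lam_up <- if (f(hi) > 0) Inf else
      exp(stats::uniroot(f, c(opt$maximum, hi), tol = 1e-10)$root)
  }

  structure(list(lambda_hat = lambda_hat,
                 N_hat = 1 / lambda_hat,
                 ci_lower_N = 1 / lam_lo,   # larger N (lower frequency)
                 ci_upper_N = 1 / lam_up,   # smaller N (higher frequency)
                 lambda_ci = c(lower = lam_lo, upper = lam_up),
                 loglik = llmax, assay = assay, conf_level = conf_level),
            class = "elda_fit")
}

fmt_over <- function(x) {
  if (!is.finite(x)) {
    if (is.nan(x)) "NaN" else if (x > 0) "Inf" else "-Inf"
  } else format(round(x, 2), nsmall = 2, trim = TRUE)
}

#' @export
print.elda_fit <- function(x, ...) {
  cat(sprintf("Sphere-forming frequency: 1/%s (lower %s, upper %s)\n",
              fmt_over(x$N_hat), fmt_over(x$ci_lower_N),
              fmt_over(x$ci_upper_N)))
  cat(sprintf("lambda = %s per cell, %d%% profile-likelihood CI\n",
              format(signif(x$lambda_hat, 4)),
              round(100 * x$conf_level)))
  invisible(x)
}

#' @export
coef.elda_fit <- function(object, ...) c(lambda = object$lambda_hat)

#' @export
logLik.elda_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' @export
confint.elda_fit <- function(object, parm = "lambda", level = NULL, ...) {
  matrix(object$lambda_ci, 1L,
         dimnames = list("lambda", c("lower", "upper")))
}

#' Likelihood-ratio comparison of two limiting-dilution assays
#'
#' Tests equal sphere-forming frequency in two assays: twice the
#' log-likelihood gain of separate-lambda fits over the pooled
#' shared-lambda fit, referred to the chi-square_1 upper tail.  When both
#' assays have no positive well the frequencies are indistinguishable at
#' the boundary and the test is reported as absent (`NA`).
#'
#' @param a,b `dilution_assay` objects.
#' @return List with `lrt_stat`, `p`, and the three fits.
#' @export
elda_compare <- function(a, b) {
  if (sum(a$n_positive) == 0L && sum(b$n_positive) == 0L)
    return(list(lrt_stat = NA_real_, p = NA_real_,
                fit_a = NULL, fit_b = NULL, fit_pooled = NULL))
  fa <- elda_fit(a); fb <- elda_fit(b)
  pooled <- rbind(as.data.frame(a), as.data.frame(b))
  fp <- elda_fit(pooled)
  stat <- max(0, 2 * (fa$loglik + fb$loglik - fp$loglik))
  list(lrt_stat = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       fit_a = fa, fit_b = fb, fit_pooled = fp)
}

#' Delta-delta-Ct fold change
#'
#' Relative quantification against an endogenous reference gene (TBP by
#' default): per sample `dCt = mean(Ct_target) - mean(Ct_reference)`, then
#' `fold = 2^-(dCt_sample - dCt_control)`.
#'
#' @param q Data frame with columns `target`, `sample`, `ct` (one row per
#'   well).
#' @param sample,control_sample Sample labels to compare.
#' @param target Target gene id.
#' @param reference Reference gene id (default `"TBP"`).
#' @return Fold change (numeric scalar).
#' @export
ddct_fold_change <- function(q, sample, control_sample, target,
                             reference = "TBP") {
  mean_ct <- function(smp, gene) {
    v <- q$ct[q$sample == smp & q$target == gene]
    if (!length(v)) stop("no Ct wells for ", gene, " in sample ", smp)
    if (any(v <= 0)) stop("non-positive Ct value")
    mean(v)
  }
  d_s <- mean_ct(sample, target) - mean_ct(sample, reference)
  d_c <- mean_ct(control_sample, target) - mean_ct(control_sample, reference)
  2^(-(d_s - d_c))
}

#' ChIP-qPCR percent of input
#'
#' Adjusts the input Ct for the input dilution (`ct_input -
#' log2(1/input_fraction)`) and expresses the immunoprecipitated signal as
#' a percentage of input: `100 * 2^(adjusted_input - ct_ip)`.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the diluted input sample.
#' @param input_fraction Fraction of chromatin used as input, in `(0, 1]`
#'   (default 0.01, i.e. a 1% input).
#' @return Percent input (vectorized).
#' @export
chip_percent_input <- function(ct_ip, ct_input, input_fraction = 0.01) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Fold enrichment over a negative-control region
#'
#' Ratio of percent-input at a region of interest over percent-input at a
#' negative control (e.g. the TBP promoter).
#'
#' @param percent_region Percent input at the region of interest.
#' @param percent_control Percent input at the negative-control region.
#' @return Fold enrichment (vectorized).
#' @export
chip_fold_over_control <- function(percent_region, percent_control) {
  if (any(percent_control == 0)) stop("zero percent-input in the control")
  percent_region / percent_control
}

#' Densitometry ratio over a loading control
#'
#' @param signal Band intensity of the protein of interest.
#' @param loading_control Band intensity of the loading control (e.g.
#'   total H3); must be positive.
#' @return Elementwise `signal / loading_control`.
#' @export
densitometry_ratio <- function(signal, loading_control) {
  if (any(loading_control <= 0)) stop("loading control must be positive")
  signal / loading_control
}
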