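# Per-study effect sizes and sampling variances.

.check_groups <- function(mean_p, sd_p, n_p, mean_c, sd_c, n_c, need_mean = TRUE,
                          label = NULL) {
  bad_n <- n_p < 2 | n_c < 2
  if (any(bad_n))
    stop("group size below 2 makes the bias term 1/(2(n-1)) undefined",
         if (!is.null(label)) paste0(" (", paste(label[bad_n], collapse = ", "), ")"),
         call. = FALSE)
  if (any(sd_p <= 0 | sd_c <= 0))
    stop("non-positive SD", call. = FALSE)
  if (need_mean && any(mean_p <= 0 | mean_c <= 0)) {
    bad <- mean_p <= 0 | mean_c <= 0
    stop("non-positive mean; log-CV measures are undefined",
         if (!is.null(label)) paste0(" (", paste(label[bad], collapse = ", "), ")"),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Log coefficient of variation ratio (lnCVR)
#'
#' Relative variability of patients versus controls on the coefficient of
#' variation scale, which adjusts the SD ratio for group differences in mean
#' level (in many natural systems the SD scales with the mean):
#' \deqn{\mathrm{lnCVR} = \ln\!\frac{S_p/\bar x_p}{S_c/\bar x_c}
#'       + \frac{1}{2(n_p-1)} - \frac{1}{2(n_c-1)},}
#' where \eqn{S}, \eqn{\bar x} and \eqn{n} are the reported SD, mean and
#' sample size of the patient (p) and control (c) groups; the last two terms
#' correct the small-sample bias of the log SD estimates.  Values above 0
#' indicate relatively greater variability in patients.
#'
#' The sampling variance uses the standard independent-groups approximation
#' \deqn{v = \frac{S_p^2}{n_p \bar x_p^2} + \frac{1}{2(n_p-1)} +
#'           \frac{S_c^2}{n_c \bar x_c^2} + \frac{1}{2(n_c-1)},}
#' with no mean-SD correlation term (this choice is echoed in the output
#' metadata of the pipeline, since variance formulas for CV ratios are an
#' assumption rather than part of the estimator's definition).
#'
#' @param mean_p,sd_p,n_p Patient mean, SD and sample size (vectorised).
#' @param mean_c,sd_c,n_c Control mean, SD and (possibly fractional,
#'   shared-control-adjusted) sample size.
#' @return Data frame with columns `yi` (estimate) and `vi` (variance).
#' @seealso [ln_vr()], [hedges_g()], [effect_sizes()]
#' @examples
#' ln_cvr(10, 2, 16, 10, 1, 16)  # ln 2, bias terms cancel
#' @export
ln_cvr <- function(mean_p, sd_p, n_p, mean_c, sd_c, n_c) {
  .check_groups(mean_p, sd_p, n_p, mean_c, sd_c, n_c, need_mean = TRUE)
  yi <- log((sd_p / mean_p) / (sd_c / mean_c)) +
    1 / (2 * (n_p - 1)) - 1 / (2 * (n_c - 1))
  vi <- sd_p^2 / (n_p * mean_p^2) + 1 / (2 * (n_p - 1)) +
        sd_c^2 / (n_c * mean_c^2) + 1 / (2 * (n_c - 1))
  data.frame(yi = yi, vi = vi)
}

#' Log variability ratio (lnVR)
#'
#' The mean-unadjusted analogue of [ln_cvr()]:
#' \eqn{\ln(S_p/S_c) + 1/(2(n_p-1)) - 1/(2(n_c-1))}, with sampling variance
#' \eqn{1/(2(n_p-1)) + 1/(2(n_c-1))}.  Equals lnCVR exactly when the group
#' means are equal.
#'
#' @inheritParams ln_cvr
#' @return Data frame with `yi` and `vi`.
#' @export
ln_vr <- function(mean_p, sd_p, n_p, mean_c, sd_c, n_c) {
  .check_groups(mean_p, sd_p, n_p, mean_c, sd_c, n_c, need_mean = FALSE)
  yi <- log(sd_p / sd_c) + 1 / (2 * (n_p - 1)) - 1 / (2 * (n_c - 1))
  vi <- 1 / (2 * (n_p - 1)) + 1 / (2 * (n_c - 1))
  data.frame(yi = yi, vi = vi)
}

#' Hedges' g standardised mean difference
#'
#' Cohen's d (patient minus control mean over the pooled SD) shrunk by the
#' small-sample correction factor \eqn{J = 1 - 3/(4\,df - 1)} with
#' \eqn{df = n_p + n_c - 2}.  Negative values indicate lower metabolite
#' levels in patients.
#'
#' @inheritParams ln_cvr
#' @param variance `"LS"` (default) for the usual large-sample variance
#'   \eqn{J^2\,[(n_p+n_c)/(n_p n_c) + d^2/(2(n_p+n_c))]}; `"UB"` for the
#'   exact-df unbiased-variance alternative.
#' @return Data frame with `yi`, `vi` and `df`.
#' @examples
#' hedges_g(12, 2, 20, 10, 2, 20)  # d = 1, g = 1 - 3/151
#' @export
hedges_g <- function(mean_p, sd_p, n_p, mean_c, sd_c, n_c,
                     variance = c("LS", "UB")) {
  variance <- match.arg(variance)
  .check_groups(mean_p, sd_p, n_p, mean_c, sd_c, n_c, need_mean = FALSE)
  df <- n_p + n_c - 2
  sp2 <- ((n_p - 1) * sd_p^2 + (n_c - 1) * sd_c^2) / df
  if (any(sp2 <= 0)) stop("pooled SD is zero", call. = FALSE)
  d <- (mean_p - mean_c) / sqrt(sp2)
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  N <- n_p + n_c
  vi <- if (variance == "LS") {
    J^2 * (N / (n_p * n_c) + d^2 / (2 * N))
  } else {
    1 / n_p + 1 / n_c + (1 - (df - 2) / (df * J^2)) * g^2
  }
  data.frame(yi = g, vi = vi, df = df)
}

#' Effect-size table for validated study records
#'
#' Applies [ln_cvr()], [ln_vr()] or [hedges_g()] row-wise to a validated
#' record table, carrying through the identifying columns, in the style of a
#' per-study effect-size calculator.
#'
#' @param records Data frame of validated records (or a `study_table`).
#' @param measure One of `"lnCVR"`, `"lnVR"`, `"SMD"`.
#' @param g_variance Variance flavour for `measure = "SMD"`.
#' @return Data frame with identifying columns, `measure`, `yi`, `vi`.
#' @export
effect_sizes <- function(records, measure = c("lnCVR", "lnVR", "SMD"),
                         g_variance = c("LS", "UB")) {
  measure <- match.arg(measure)
  g_variance <- match.arg(g_variance)
  if (inherits(records, "study_table")) records <- records$records
  es <- switch(measure,
    lnCVR = ln_cvr(records$mean_p, records$sd_p, records$n_p,
                   records$mean_c, records$sd_c, records$n_c),
    lnVR  = ln_vr(records$mean_p, records$sd_p, records$n_p,
                  records$mean_c, records$sd_c, records$n_c),
    SMD   = hedges_g(records$mean_p, records$sd_p, records$n_p,
                     records$mean_c, records$sd_c, records$n_c,
                     variance = g_variance))
  carry <- intersect(c("study_id", "cohort_id", "region", "metabolite",
                       "medication_status", .moderator_cols),
                     names(records))
  cbind(records[carry], measure = measure, es)
}

#' Weighted Pearson correlation
#'
#' Correlation between two vectors under non-negative observation weights
#' (normalised to sum to one): the weighted covariance over the product of
#' weighted SDs, as used to check that metabolite SDs scale with their means
#' across studies.
#'
#' @param x,y Numeric vectors.
#' @param w Non-negative weights, at least one positive.
#' @return Correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(w), length(x) >= 3,
            all(w >= 0), sum(w) > 0, all(is.finite(c(x, y, w))))
  cw <- stats::cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE, method = "ML")
  r <- cw$cor[1, 2]
  if (!is.finite(r)) stop("zero weighted variance", call. = FALSE)
  r
}
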