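# Random-effects meta-analysis engine: REML tau^2, inverse-variance pooling,
# moderator meta-regression, and the S3 methods around the fitted object.

# Fisher scoring safeguarded by a score-sign bracket.  The restricted
# likelihood is unimodal in tau^2 with a score that is positive below the
# optimum and negative above it, so every evaluation tightens a bracket
# [lo, hi]; Fisher-scoring steps are accepted only inside the open bracket
# and every third iteration bisects it outright, which guarantees geometric
# convergence even where the expected information badly over- or
# under-estimates the curvature (both happen for extreme weight patterns).
.fit_reml <- function(yi, vi, X, tol = 1e-10, maxit = 200L) {
  k <- length(yi); p <- ncol(X)
  w0 <- 1 / vi
  b0 <- solve(crossprod(X, X * w0), crossprod(X, w0 * yi))
  Q <- sum(w0 * (yi - X %*% b0)^2)
  C <- sum(w0) - sum(w0^2) / sum(w0)
  tau2 <- max(0, (Q - (k - p)) / C)
  lo <- 0; hi <- Inf
  trace <- numeric(0)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    w <- 1 / (vi + tau2)
    WX <- X * w
    XtWXi <- solve(crossprod(X, WX))
    # P = W - W X (X'WX)^-1 X' W  (k is small; form it explicitly)
    P <- diag(w, k) - WX %*% XtWXi %*% t(WX)
    Py <- drop(P %*% yi)
    score <- 0.5 * (sum(Py^2) - sum(diag(P)))
    info <- 0.5 * sum(P * P)
    if (!is.finite(info) || info <= 0) break
    if (tau2 == 0 && score <= 0) { conv <- TRUE; break }  # boundary optimum
    if (score > 0) lo <- max(lo, tau2) else hi <- min(hi, tau2)
    if (is.finite(hi) && hi - lo < tol) {
      tau2 <- (lo + hi) / 2; conv <- TRUE; break
    }
    if (!is.finite(hi)) {
      # no upper bracket yet: take the Fisher step but at least double
      cand <- max(tau2 + score / info, 2 * max(tau2, 1e-4))
    } else {
      cand <- tau2 + score / info
      if (it %% 3 == 0 || !is.finite(cand) || cand <= lo || cand >= hi)
        cand <- (lo + hi) / 2
    }
    trace <- c(trace, cand)
    if (abs(cand - tau2) < tol) { tau2 <- cand; conv <- TRUE; break }
    tau2 <- cand
  }
  if (!conv)
    stop("REML estimation of tau^2 did not converge in ", maxit,
         " iterations; trace tail: ",
         paste(signif(utils::tail(trace, 5), 6), collapse = ", "),
         call. = FALSE)
  list(tau2 = tau2, iterations = length(trace))
}

.fit_dl <- function(yi, vi, X) {
  if (ncol(X) > 1)
    stop("DerSimonian-Laird is available for intercept-only pooling; ",
         "use method = 'REML' for meta-regression", call. = FALSE)
  k <- length(yi)
  w0 <- 1 / vi
  mu <- sum(w0 * yi) / sum(w0)
  Q <- sum(w0 * (yi - mu)^2)
  C <- sum(w0) - sum(w0^2) / sum(w0)
  list(tau2 = max(0, (Q - (k - 1)) / C), iterations = 1L)
}

#' Random-effects meta-analysis and meta-regression
#'
#' Fits the normal-normal random-effects model
#' \eqn{y_i \sim N(x_i'\beta,\; v_i + \tau^2)} to per-study effect sizes
#' `yi` with known sampling variances `vi`.  The between-study variance
#' \eqn{\tau^2} is estimated by restricted maximum likelihood (Fisher scoring
#' safeguarded by score-sign bracketing with bisection, projection to zero at
#' the boundary, convergence tolerance `1e-10` on \eqn{\tau^2}, at most 200
#' iterations), with
#' DerSimonian-Laird and fixed-effect alternatives available for sensitivity
#' analyses.  Coefficients are the weighted least-squares solution with
#' weights \eqn{1/(v_i + \hat\tau^2)}; tests and confidence intervals use
#' plain Wald normal quantiles (no Knapp-Hartung adjustment), matching the
#' usual z/p reporting style.
#'
#' For an intercept-only fit the object is the pooled estimate; with a
#' one-sided `mods` formula it is a moderator meta-regression, in which the
#' reported slope is per unit of the moderator.  Rows with missing moderator
#' values are dropped from the regression (never from pooling).
#'
#' Heterogeneity is summarised by \eqn{\tau^2} and, for intercept-only fits,
#' by \eqn{I^2 = 100\,\hat\tau^2/(\hat\tau^2 + s^2)} with the typical
#' within-study variance
#' \eqn{s^2 = (k-1)\sum w_i /\big[(\sum w_i)^2 - \sum w_i^2\big]},
#' \eqn{w_i = 1/v_i}.
#'
#' @param yi Effect sizes.
#' @param vi Sampling variances (> 0).
#' @param mods Optional one-sided formula of moderators, evaluated in `data`.
#' @param data Optional data frame holding `yi`, `vi`, moderators and
#'   (optionally) `study_id` used for provenance.
#' @param method `"REML"` (default), `"DL"`, or `"FE"`.
#' @param level Confidence level (default 0.95).
#' @param min_k Minimum number of studies: 2 to pool, 5 (default) for a
#'   meta-regression; lowering it below 5 triggers a warning.
#' @return An object of class `remeta` with components `b`, `se`, `zval`,
#'   `pval`, `ci.lb`, `ci.ub`, `tau2`, `i2`, `k`, and the inputs.
#' @seealso [compare_subgroups()], [bh_fdr()], [effect_sizes()]
#' @examples
#' es <- ln_cvr(c(11, 10, 12), c(2.2, 1.9, 2.5), c(20, 25, 30),
#'              c(10, 10, 11), c(1.8, 2.0, 2.1), c(20, 25, 30))
#' fit <- remeta(es$yi, es$vi)
#' summary(fit)
#' @export
remeta <- function(yi, vi, mods = NULL, data = NULL,
                   method = c("REML", "DL", "FE"), level = 0.95,
                   min_k = if (is.null(mods)) 2L else 5L) {
  method <- match.arg(method)
  cl <- match.call()
  if (!is.null(data)) {
    yi <- eval(substitute(yi), data, parent.frame())
    vi <- eval(substitute(vi), data, parent.frame())
  }
  stopifnot(is.numeric(yi), is.numeric(vi), length(yi) == length(vi))
  if (any(!is.finite(yi)) || any(!is.finite(vi)) || any(vi <= 0))
    stop("effect sizes must be finite with positive sampling variances",
         call. = FALSE)
  study_ids <- if (!is.null(data) && !is.null(data$study_id))
    as.character(data$study_id) else NULL

  X <- matrix(1, length(yi), 1, dimnames = list(NULL, "intercept"))
  keep <- rep(TRUE, length(yi))
  if (!is.null(mods)) {
    stopifnot(inherits(mods, "formula"))
    mf <- stats::model.frame(mods, data = data, na.action = stats::na.pass)
    Xm <- stats::model.matrix(mods, mf)
    keep <- stats::complete.cases(Xm)
    X <- Xm[keep, , drop = FALSE]
    yi <- yi[keep]; vi <- vi[keep]
    if (!is.null(study_ids)) study_ids <- study_ids[keep]
    nonconst <- apply(X[, -1, drop = FALSE], 2, function(col) length(unique(col)) > 1)
    if (!all(nonconst))
      stop("constant moderator(s): ",
           paste(colnames(X)[-1][!nonconst], collapse = ", "), call. = FALSE)
  }
  k <- length(yi)
  if (!is.null(mods) && min_k < 5L)
    warning("meta-regression with min_k below 5 is fragile", call. = FALSE)
  if (k < max(min_k, ncol(X) + 1L))
    stop("too few studies (k = ", k, ") for this fit", call. = FALSE)

  ft <- switch(method,
    REML = .fit_reml(yi, vi, X),
    DL = .fit_dl(yi, vi, X),
    FE = list(tau2 = 0, iterations = 0L))
  tau2 <- ft$tau2

  w <- 1 / (vi + tau2)
  XtWX <- crossprod(X, X * w)
  Vb <- solve(XtWX)
  b <- drop(Vb %*% crossprod(X, w * yi))
  se <- sqrt(diag(Vb))
  zval <- b / se
  pval <- 2 * stats::pnorm(-abs(zval))
  zc <- stats::qnorm(1 - (1 - level) / 2)
  i2 <- NA_real_
  if (ncol(X) == 1) {
    w0 <- 1 / vi
    s2 <- (k - 1) * sum(w0) / (sum(w0)^2 - sum(w0^2))
    i2 <- 100 * tau2 / (tau2 + s2)
  }

  out <- list(b = b, se = se, zval = zval, pval = pval,
              ci.lb = b - zc * se, ci.ub = b + zc * se,
              vb = Vb, tau2 = tau2, i2 = i2, k = k, p = ncol(X),
              yi = yi, vi = vi, X = X, method = method, level = level,
              iterations = ft$iterations, study_ids = study_ids, call = cl)
  class(out) <- "remeta"
  out
}

#' REML estimate of the between-study variance
#'
#' Convenience wrapper returning only \eqn{\hat\tau^2} from an
#' intercept-only [remeta()] fit.
#'
#' @inheritParams remeta
#' @return Non-negative scalar \eqn{\hat\tau^2}.
#' @export
reml_tau2 <- function(yi, vi) remeta(yi, vi, method = "REML")$tau2

#' @export
print.remeta <- function(x, digits = 4, ...) {
  type <- if (x$p == 1) "Random-effects pooling" else "Mixed-effects meta-regression"
  cat(type, " (k = ", x$k, ", ", x$method, ")\n", sep = "")
  cat("tau^2 = ", format(x$tau2, digits = digits),
      if (!is.na(x$i2)) paste0(", I^2 = ", format(x$i2, digits = 3), "%"),
      "\n", sep = "")
  tab <- data.frame(estimate = x$b, se = x$se, z = x$zval, p = x$pval,
                    ci.lb = x$ci.lb, ci.ub = x$ci.ub,
                    row.names = colnames(x$X))
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.remeta <- function(object, ...) {
  object$qe <- {
    w0 <- 1 / object$vi
    b0 <- solve(crossprod(object$X, object$X * w0),
                crossprod(object$X, w0 * object$yi))
    sum(w0 * (object$yi - object$X %*% b0)^2)
  }
  object$qe_df <- object$k - object$p
  object$qe_p <- stats::pchisq(object$qe, object$qe_df, lower.tail = FALSE)
  class(object) <- c("summary.remeta", "remeta")
  object
}

#' @export
print.summary.remeta <- function(x, digits = 4, ...) {
  print.remeta(x, digits = digits, ...)
  cat("Q(df = ", x$qe_df, ") = ", format(x$qe, digits = digits),
      ", p = ", format(x$qe_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.remeta <- function(object, ...) setNames(object$b, colnames(object$X))

#' @export
vcov.remeta <- function(object, ...) object$vb

#' @export
confint.remeta <- function(object, parm, level = NULL, ...) {
  zc <- stats::qnorm(1 - (1 - (level %||% object$level)) / 2)
  out <- cbind(object$b - zc * object$se, object$b + zc * object$se)
  dimnames(out) <- list(colnames(object$X), c("ci.lb", "ci.ub"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.remeta <- function(object, ...) drop(object$X %*% object$b)

#' @export
residuals.remeta <- function(object, ...) object$yi - fitted(object)

#' @export
predict.remeta <- function(object, newmods = NULL, ...) {
  X <- if (is.null(newmods)) object$X else {
    nm <- as.matrix(newmods)
    cbind(1, nm)
  }
  est <- drop(X %*% object$b)
  se <- sqrt(rowSums((X %*% object$vb) * X))
  zc <- stats::qnorm(1 - (1 - object$level) / 2)
  data.frame(pred = est, se = se, ci.lb = est - zc * se, ci.ub = est + zc * se)
}

#' @export
simulate.remeta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  sdv <- sqrt(object$vi + object$tau2)
  out <- replicate(nsim, stats::rnorm(object$k, mu, sdv))
  as.data.frame(out)
}

#' Forest-style plot of a pooled fit
#'
#' Base-graphics forest plot: per-study estimates with 95% intervals from
#' the sampling variances, and the pooled estimate with its interval at the
#' bottom.  For meta-regressions, plots effects against the first moderator.
#'
#' @param x A `remeta` object.
#' @param labels Optional study labels.
#' @param xlab X-axis label.
#' @param ... Passed to plotting primitives.
#' @export
plot.remeta <- function(x, labels = NULL, xlab = "effect size", ...) {
  if (x$p > 1) {
    mod <- x$X[, 2]
    graphics::plot(mod, x$yi, cex = 0.6 + 1.4 * (1 / x$vi) / max(1 / x$vi),
                   xlab = colnames(x$X)[2], ylab = xlab, pch = 16, ...)
    ab <- x$b[1:2]
    graphics::abline(ab[1], ab[2], lwd = 2)
    return(invisible(x))
  }
  k <- x$k
  labs <- labels %||% x$study_ids %||% paste("study", seq_len(k))
  lo <- x$yi - .norm_z * sqrt(x$vi); hi <- x$yi + .norm_z * sqrt(x$vi)
  ylim <- c(0, k + 2)
  graphics::plot(NA, xlim = range(c(lo, hi, x$ci.lb, x$ci.ub)), ylim = ylim,
                 yaxt = "n", ylab = "", xlab = xlab, ...)
  graphics::segments(lo, k:1, hi, k:1)
  graphics::points(x$yi, k:1, pch = 15, cex = 0.8)
  graphics::axis(2, at = k:1, labels = labs, las = 1, cex.axis = 0.7)
  graphics::abline(v = 0, lty = 3)
  graphics::segments(x$ci.lb, 0, x$ci.ub, 0, lwd = 3)
  graphics::points(x$b, 0, pch = 18, cex = 1.4)
  invisible(x)
}
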