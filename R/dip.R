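# Hartigan's dip test of unimodality with Monte-Carlo calibration.

# run code under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Hartigan's dip statistic
#'
#' The dip is the sup-norm distance from the empirical CDF of a sample to
#' the nearest unimodal CDF, computed exactly by the iterative greatest
#' convex minorant / least concave majorant algorithm on the sorted sample
#' (tied samples, where the nearest unimodal distribution may carry an atom
#' at the mode, are handled by an exact feasibility search over
#' convex-then-concave fits).  The statistic is invariant to affine
#' transformations of the data and satisfies \eqn{1/(2n) \le D \le 1/4};
#' constant samples return the lower bound \eqn{1/(2n)}.
#'
#' @param x Numeric vector, at least two finite values.
#' @return The dip statistic \eqn{D}.
#' @examples
#' dip_stat(c(0, 1))                     # 0.25, the maximum
#' dip_stat(seq(0, 1, length.out = 50))  # 0.01, the 1/(2n) floor
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least two observations", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in sample", call. = FALSE)
  dip_stat_cpp(x)
}

#' Monte-Carlo p-value for the dip statistic
#'
#' Calibrates an observed dip against `n_sim` samples of the same size drawn
#' from Uniform(0, 1) -- the least favourable unimodal null, the same null
#' from which the classical dip tables were built -- with the add-one
#' correction \eqn{p = (1 + \#\{D^{null} \ge D\})/(n_{sim} + 1)}.
#'
#' @param dip Observed dip statistic.
#' @param n Sample size the dip was computed from.
#' @param n_sim Number of null replicates (at least 500; default 2000).
#' @param seed Integer seed governing the null draws (required, so results
#'   are reproducible; the caller's RNG state is preserved).
#' @return P-value in (0, 1\].
#' @export
dip_pvalue <- function(dip, n, n_sim = 2000, seed) {
  stopifnot(is.numeric(dip), length(dip) == 1, n >= 2, n_sim >= 500)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the Monte-Carlo calibration", call. = FALSE)
  nulls <- .with_seed(seed, dip_null_cpp(as.integer(n), as.integer(n_sim)))
  (1 + sum(nulls >= dip)) / (n_sim + 1)
}

#' Dip test of unimodality
#'
#' Computes [dip_stat()] and its Monte-Carlo [dip_pvalue()], returning a
#' verdict at \eqn{\alpha = 0.05} (the dip is one-sided by construction:
#' large values indicate departure from unimodality).
#'
#' @inheritParams dip_pvalue
#' @param x Numeric sample.
#' @return Object of class `dip_test`: list with `statistic`, `p.value`,
#'   `n`, `n_sim`, `seed`, `verdict` (`"unimodal_compatible"` or
#'   `"bimodal_evidence"`).
#' @export
dip_test <- function(x, n_sim = 2000, seed) {
  D <- dip_stat(x)
  p <- dip_pvalue(D, length(x), n_sim = n_sim, seed = seed)
  out <- list(statistic = D, p.value = p, n = length(x), n_sim = n_sim,
              seed = seed,
              verdict = if (p < 0.05) "bimodal_evidence" else "unimodal_compatible")
  class(out) <- "dip_test"
  out
}

#' @export
print.dip_test <- function(x, digits = 4, ...) {
  cat("Hartigan's dip test (Monte-Carlo, n_sim = ", x$n_sim, ")\n", sep = "")
  cat("D = ", format(x$statistic, digits = digits),
      ", n = ", x$n, ", p = ", format(x$p.value, digits = 3),
      "  [", x$verdict, "]\n", sep = "")
  invisible(x)
}

#' Pool normalised per-study samples and test unimodality
#'
#' Each study's sample is normalised (`divide_by_mean`, the default
#' mean-scaling, or `subtract_mean` for mean-centring), the normalised
#' values are concatenated across studies, and the pooled sample is dip
#' tested; per-study dip tests are returned alongside.
#'
#' @param samples List of numeric vectors (one per study, each n >= 2), or a
#'   long-format data frame with columns `study_id` and `value`.
#' @param scheme Normalisation scheme.
#' @param n_sim,seed Monte-Carlo settings; per-study tests use seeds derived
#'   deterministically from `seed`.
#' @return Object of class `dip_pooled`: list with `pooled` (a `dip_test`),
#'   `per_study` (named list of `dip_test`), `scheme`.
#' @export
pool_and_test <- function(samples, scheme = c("divide_by_mean", "subtract_mean"),
                          n_sim = 2000, seed) {
  scheme <- match.arg(scheme)
  if (is.data.frame(samples)) {
    stopifnot(all(c("study_id", "value") %in% names(samples)))
    samples <- split(samples$value, samples$study_id)
  }
  stopifnot(length(samples) >= 1, all(vapply(samples, length, 1L) >= 2))
  if (is.null(names(samples)))
    names(samples) <- paste0("study_", seq_along(samples))
  norm1 <- function(v) {
    if (scheme == "divide_by_mean") {
      m <- mean(v)
      if (abs(m) < .Machine$double.eps^0.5)
        stop("study mean is zero; cannot divide by mean", call. = FALSE)
      v / m
    } else v - mean(v)
  }
  normed <- lapply(samples, norm1)
  pooled <- dip_test(unlist(normed, use.names = FALSE), n_sim = n_sim, seed = seed)
  per_study <- lapply(seq_along(normed), function(i)
    dip_test(normed[[i]], n_sim = n_sim,
             seed = (seed + 48271 * i) %% 2147483647))
  names(per_study) <- names(samples)
  out <- list(pooled = pooled, per_study = per_study, scheme = scheme)
  class(out) <- "dip_pooled"
  out
}

#' @export
print.dip_pooled <- function(x, ...) {
  cat("Pooled dip test over", length(x$per_study), "studies (",
      x$scheme, "):\n")
  print(x$pooled)
  uni <- sum(vapply(x$per_study, function(d) d$verdict == "unimodal_compatible", TRUE))
  cat("Per-study verdicts:", uni, "unimodal-compatible,",
      length(x$per_study) - uni, "with bimodality evidence\n")
  invisible(x)
}
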