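# Subgroup comparison and multiplicity control.

#' Wald comparison of two independent pooled estimates
#'
#' Compares two subgroup estimates (e.g. antipsychotic-naive vs medicated
#' patients) fitted on disjoint study sets:
#' \eqn{z = (a - b)/\sqrt{se_a^2 + se_b^2}} with a two-sided normal p-value.
#'
#' @param a,b Either `remeta` objects or named vectors
#'   `c(estimate = , se = )`.  When both are `remeta` objects carrying study
#'   ids, overlapping study sets raise an error.
#' @return Object of class `wald_test` with `estimate_a`, `estimate_b`,
#'   `z`, `p`.
#' @examples
#' compare_subgroups(c(estimate = 0.3, se = 0.1), c(estimate = 0, se = 0.1))
#' @export
compare_subgroups <- function(a, b) {
  grab <- function(x) {
    if (inherits(x, "remeta")) {
      stopifnot(x$p == 1)
      list(est = x$b[[1]], se = x$se[[1]], ids = x$study_ids)
    } else {
      stopifnot(is.numeric(x), all(c("estimate", "se") %in% names(x)))
      list(est = unname(x["estimate"]), se = unname(x["se"]), ids = NULL)
    }
  }
  ga <- grab(a); gb <- grab(b)
  if (!is.null(ga$ids) && !is.null(gb$ids) && length(intersect(ga$ids, gb$ids)))
    stop("subgroups share studies: ",
         paste(intersect(ga$ids, gb$ids), collapse = ", "), call. = FALSE)
  z <- (ga$est - gb$est) / sqrt(ga$se^2 + gb$se^2)
  out <- list(estimate_a = ga$est, se_a = ga$se,
              estimate_b = gb$est, se_b = gb$se,
              z = z, p = 2 * stats::pnorm(-abs(z)))
  class(out) <- "wald_test"
  out
}

#' @export
print.wald_test <- function(x, digits = 4, ...) {
  cat("Wald subgroup comparison: a =", format(x$estimate_a, digits = digits),
      "vs b =", format(x$estimate_b, digits = digits), "\n")
  cat("z =", format(x$z, digits = digits), ", p =", format(x$p, digits = 3), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate flags
#'
#' Step-up FDR control at rate `q` (default 10%, as used across the six
#' brain-region families): reject all \eqn{p_{(i)}} with
#' \eqn{i \le \max\{i : p_{(i)} \le i\,q/m\}}.  Input order is preserved.
#'
#' @param p P-values in \[0, 1\].
#' @param q Target false discovery rate.
#' @return List with `reject` (logical, original order) and `p_adjusted`
#'   (Benjamini-Hochberg adjusted p-values via [stats::p.adjust()]).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05, 0.2), q = 0.1)$reject
#' @export
bh_fdr <- function(p, q = 0.10) {
  if (!length(p)) return(list(reject = logical(0), p_adjusted = numeric(0)))
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1, na.rm = TRUE),
            q > 0, q < 1)
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = !is.na(adj) & adj <= q, p_adjusted = adj)
}
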