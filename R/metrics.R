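# Frequentist and Bayesian disproportionality metrics on a 2x2 table.
#
# All four metrics return a `metric_result`: a point estimate with interval
# bounds at a stated level plus auxiliary statistics. Zero cells make ROR /
# PRR undefined; by default an undefined-result marker (all-NA estimate) is
# returned rather than silently applying the Haldane-Anscombe +0.5
# correction, because the n11 >= 3 signal rule makes such tables
# non-signals in any case. Set `continuity = TRUE` to apply the correction.

metric_result <- function(name, estimate, lower, upper, level, aux = list(),
                          undefined = FALSE, reason = NULL) {
  structure(list(name = name, estimate = estimate, lower = lower,
                 upper = upper, level = level, aux = aux,
                 undefined = undefined, reason = reason),
            class = "metric_result")
}

undefined_metric <- function(name, level, reason, aux = list()) {
  metric_result(name, NA_real_, NA_real_, NA_real_, level, aux,
                undefined = TRUE, reason = reason)
}

#' @export
print.metric_result <- function(x, digits = 3, ...) {
  if (x$undefined) {
    cat(sprintf("%s: undefined (%s)\n", x$name, x$reason))
  } else {
    cat(sprintf("%s = %.*f  [%.*f, %.*f]  (%.0f%% interval)\n",
                x$name, digits, x$estimate, digits, x$lower,
                digits, x$upper, 100 * x$level))
    for (a in names(x$aux)) {
      cat(sprintf("  %s = %s\n", a, format(x$aux[[a]], digits = digits)))
    }
  }
  invisible(x)
}

as_ct <- function(tab) {
  if (inherits(tab, "contingency2x2")) return(tab)
  if (is.matrix(tab) && all(dim(tab) == 2)) {
    return(contingency(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
  }
  if (is.numeric(tab) && length(tab) == 4) {
    return(contingency(tab[1], tab[2], tab[3], tab[4]))
  }
  stop("not a 2x2 table", call. = FALSE)
}

#' Reporting odds ratio
#'
#' The ROR is the odds of the target event among reports (pairs) with the
#' drug versus without: `(n11 * n22) / (n12 * n21)`. Its confidence
#' interval is the Wald interval on the log scale,
#' `exp(log(ROR) +/- z * sqrt(1/n11 + 1/n12 + 1/n21 + 1/n22))`, which makes
#' the point estimate the geometric mean of the bounds. A two-sided Fisher
#' exact p-value accompanies the estimate.
#'
#' @param tab a `contingency2x2`, 2x2 matrix, or length-4 vector
#'   (n11, n12, n21, n22).
#' @param level interval level (default 0.95).
#' @param continuity apply the Haldane-Anscombe +0.5 correction to all
#'   cells when any cell is zero (default `FALSE`: return an undefined
#'   marker instead).
#' @return a `metric_result` with `aux$p_value`.
#' @export
ror <- function(tab, level = 0.95, continuity = FALSE) {
  tab <- as_ct(tab)
  n <- c(tab$n11, tab$n12, tab$n21, tab$n22)
  p <- fisher_exact(tab)
  if (any(n == 0)) {
    if (!continuity) {
      return(undefined_metric("ROR", level, "zero cell",
                              aux = list(p_value = p)))
    }
    n <- n + 0.5
  }
  est <- (n[1] * n[4]) / (n[2] * n[3])
  se <- sqrt(sum(1 / n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  metric_result("ROR", est, exp(log(est) - z * se), exp(log(est) + z * se),
                level, aux = list(p_value = p))
}

#' Fisher's exact test p-value for a 2x2 table
#'
#' Two-sided exact p-value with fixed margins (the sum of hypergeometric
#' probabilities of tables at most as probable as the observed one).
#'
#' @inheritParams ror
#' @return the two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as_ct(tab)
  stats::fisher.test(ct_matrix(tab))$p.value
}

#' Proportional reporting ratio
#'
#' The PRR compares the proportion of target events among the drug's pairs
#' against the same proportion among all other drugs' pairs:
#' `[n11/(n11+n12)] / [n21/(n21+n22)]`, with the log-scale Wald interval
#' `exp(log(PRR) +/- z * sqrt(1/n11 - 1/(n11+n12) + 1/n21 - 1/(n21+n22)))`.
#' The accompanying chi-square statistic is the 2x2 test with Yates
#' continuity correction (the MHRA convention); disable the correction
#' with `yates = FALSE`.
#'
#' @inheritParams ror
#' @param yates use the Yates-corrected chi-square (default `TRUE`).
#' @return a `metric_result` with `aux$chi_square`.
#' @export
prr <- function(tab, level = 0.95, continuity = FALSE, yates = TRUE) {
  tab <- as_ct(tab)
  n <- c(tab$n11, tab$n12, tab$n21, tab$n22)
  if (n[1] + n[2] == 0 || n[3] + n[4] == 0) {
    stop("PRR requires both drug rows to be non-empty", call. = FALSE)
  }
  chi2 <- tryCatch(
    suppressWarnings(unname(
      stats::chisq.test(ct_matrix(tab), correct = yates)$statistic)),
    error = function(e) NA_real_)
  if (n[1] == 0 || n[3] == 0) {
    if (!continuity) {
      return(undefined_metric("PRR", level, "zero target cell",
                              aux = list(chi_square = chi2)))
    }
    n <- n + 0.5
  }
  est <- (n[1] / (n[1] + n[2])) / (n[3] / (n[3] + n[4]))
  se <- sqrt(1 / n[1] - 1 / (n[1] + n[2]) + 1 / n[3] - 1 / (n[3] + n[4]))
  z <- stats::qnorm(1 - (1 - level) / 2)
  metric_result("PRR", est, exp(log(est) - z * se), exp(log(est) + z * se),
                level, aux = list(chi_square = chi2))
}

#' Bayesian confidence propagation neural network information component
#'
#' The information component is the shrunken log2 ratio of observed to
#' expected co-reporting: with expected count `E = n1+ * n+1 / n++`,
#' `IC = log2((n11 + 0.5) / (E + 0.5))`. The credibility interval comes
#' from the gamma posterior of the reporting-rate ratio lambda,
#' `lambda ~ Gamma(shape = n11 + 0.5, rate = E + 0.5)`, on the log2 scale.
#' `variant = "approx"` instead uses the moment-style closed-form lower
#' bound `IC - 3.3 * (n11 + 0.5)^(-1/2) - 2.0 * (n11 + 0.5)^(-3/2)` (and
#' its mirror for the upper bound), a common large-database approximation.
#'
#' @inheritParams ror
#' @param variant `"gamma"` (exact posterior quantiles, default) or
#'   `"approx"`.
#' @return a `metric_result` with `aux$expected` (the expected count E).
#' @export
bcpnn_ic <- function(tab, level = 0.95, variant = c("gamma", "approx")) {
  variant <- match.arg(variant)
  tab <- as_ct(tab)
  m <- ct_margins(tab)
  E <- m$n1p * m$np1 / m$npp
  if (E == 0) stop("degenerate margins: expected count is zero",
                   call. = FALSE)
  ic <- log2((tab$n11 + 0.5) / (E + 0.5))
  if (variant == "gamma") {
    a <- (1 - level) / 2
    lo <- log2(stats::qgamma(a, shape = tab$n11 + 0.5, rate = E + 0.5))
    hi <- log2(stats::qgamma(1 - a, shape = tab$n11 + 0.5, rate = E + 0.5))
  } else {
    s <- tab$n11 + 0.5
    lo <- ic - 3.3 * s^(-0.5) - 2.0 * s^(-1.5)
    hi <- ic + 2.4 * s^(-0.5) + 0.5 * s^(-1.5)
  }
  metric_result("IC", ic, lo, hi, level, aux = list(expected = E))
}

#' Signal rules for the four disproportionality metrics
#'
#' Applies the fixed per-metric thresholds used in SRS screening:
#' \itemize{
#'   \item ROR signal: `n11 >= 3` and the lower 95% bound `ROR025 > 1`;
#'   \item PRR signal: `n11 >= 3`, `PRR025 > 2` (strict), and
#'     chi-square `> 4`;
#'   \item IC signal: `IC025 > 0`;
#'   \item EBGM signal: `EBGM05 >= 2.0` (inclusive).
#' }
#' A metric that is missing or undefined yields a `FALSE` flag. No
#' multiplicity correction is applied; these are fixed screening
#' thresholds.
#'
#' @param metrics named list with any of elements `ror`, `prr`, `ic`,
#'   `ebgm`, each a `metric_result`.
#' @param n11 the observed target cell count.
#' @return an object of class `signal_flags`: logical `ror_signal`,
#'   `prr_signal`, `ic_signal`, `ebgm_signal` plus `n11`.
#' @export
apply_signal_rules <- function(metrics, n11) {
  ok <- function(m) !is.null(m) && inherits(m, "metric_result") &&
    !isTRUE(m$undefined) && !is.na(m$lower)
  m <- metrics
  flags <- list(
    ror_signal = ok(m$ror) && n11 >= 3 && m$ror$lower > 1,
    prr_signal = ok(m$prr) && n11 >= 3 && m$prr$lower > 2 &&
      !is.na(m$prr$aux$chi_square) && m$prr$aux$chi_square > 4,
    ic_signal = ok(m$ic) && m$ic$lower > 0,
    ebgm_signal = ok(m$ebgm) && m$ebgm$lower >= 2.0,
    n11 = n11
  )
  structure(flags, class = "signal_flags")
}

#' @export
print.signal_flags <- function(x, ...) {
  mark <- function(b) if (isTRUE(b)) "yes" else "no"
  cat(sprintf("signals (n11 = %d): ROR %s | PRR %s | IC %s | EBGM %s\n",
              x$n11, mark(x$ror_signal), mark(x$prr_signal),
              mark(x$ic_signal), mark(x$ebgm_signal)))
  invisible(x)
}
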