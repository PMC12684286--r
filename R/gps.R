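# Gamma-Poisson Shrinker (empirical Bayes) for observed/expected reporting
# ratios. The prior on the rate ratio lambda is the DuMouchel two-component
# gamma mixture  lambda ~ w * Gamma(a1, b1) + (1 - w) * Gamma(a2, b2)
# (shape/rate); counts are Poisson(lambda * E) given lambda, so marginally
# each count is a two-component negative-binomial mixture. Hyperparameters
# are fitted by maximizing the marginal likelihood over the whole
# (drug, event) cell universe; per-cell posteriors then shrink the
# observed/expected ratio.

#' Observed and expected counts for the (drug, event) cell universe
#'
#' Computes, for every (drug, event) combination in the pair universe, the
#' observed pair count `n` and the expected count under row/column
#' independence. With strata, expected counts are computed within each
#' stratum (`E_de = sum_s n_d+(s) * n_+e(s) / n_++(s)`) and pooled, which
#' adjusts the baseline for reporting differences across strata; pairs
#' whose stratum label is `NA` are excluded.
#'
#' @param pairs data.frame from [expand_pairs()].
#' @param strata optional character vector, one stratum label per row of
#'   `pairs` (e.g. sex crossed with age group).
#' @return data.frame with columns `drug`, `event`, `n`, `E` covering the
#'   full drug x event grid.
#' @export
gps_expected_counts <- function(pairs, strata = NULL) {
  if (is.null(strata)) strata <- rep("all", nrow(pairs))
  stopifnot(length(strata) == nrow(pairs))
  keep <- !is.na(strata)
  pairs <- pairs[keep, , drop = FALSE]
  strata <- strata[keep]
  if (nrow(pairs) == 0) stop("no pairs with resolvable strata", call. = FALSE)
  dlev <- sort(unique(pairs$drug))
  elev <- sort(unique(pairs$pt_code))
  d <- factor(pairs$drug, levels = dlev)
  e <- factor(pairs$pt_code, levels = elev)
  n_mat <- matrix(0, length(dlev), length(elev),
                  dimnames = list(dlev, elev))
  E_mat <- matrix(0, length(dlev), length(elev),
                  dimnames = list(dlev, elev))
  for (s in unique(strata)) {
    i <- strata == s
    t_s <- table(d[i], e[i])
    n_mat <- n_mat + t_s
    tot <- sum(t_s)
    if (tot > 0) E_mat <- E_mat + outer(rowSums(t_s), colSums(t_s)) / tot
  }
  data.frame(drug = rep(dlev, times = length(elev)),
             event = rep(elev, each = length(dlev)),
             n = as.vector(n_mat), E = as.vector(E_mat),
             stringsAsFactors = FALSE)
}

# log marginal likelihood of counts under the mixture prior;
# theta = (logit w, log a1, log b1, log a2, log b2)
gps_loglik <- function(theta, n, E) {
  w <- stats::plogis(theta[1])
  a1 <- exp(theta[2]); b1 <- exp(theta[3])
  a2 <- exp(theta[4]); b2 <- exp(theta[5])
  l1 <- stats::dnbinom(n, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(n, size = a2, prob = b2 / (b2 + E), log = TRUE)
  hi <- pmax(l1 + log(w), l2 + log1p(-w))
  lo <- pmin(l1 + log(w), l2 + log1p(-w))
  sum(hi + log1p(exp(lo - hi)))
}

#' Fit the Gamma-Poisson Shrinker prior
#'
#' Maximizes the marginal log-likelihood of the observed cell counts given
#' their expected counts under the two-component gamma mixture prior.
#' Optimization is over the unconstrained parameters
#' `(logit w, log a1, log b1, log a2, log b2)` starting from the classical
#' initialization `(w, a1, b1, a2, b2) = (1/3, 0.2, 0.1, 2, 4)`, plus a
#' small number of seeded random restarts; the best optimum is kept.
#'
#' @param n integer vector of observed cell counts.
#' @param E numeric vector of expected counts (same length, `E > 0` cells
#'   are used; zero-expectation cells are dropped).
#' @param init numeric length-5 starting value `(w, a1, b1, a2, b2)`.
#' @param restarts number of random restarts around `init`.
#' @param seed integer seed for the restart jitter.
#' @return an object of class `gps_fit` with elements `w, a1, b1, a2, b2`,
#'   `loglik`, `n_cells`, `convergence`.
#' @export
gps_fit <- function(n, E, init = c(1 / 3, 0.2, 0.1, 2, 4), restarts = 4,
                    seed = 1L) {
  stopifnot(length(n) == length(E))
  keep <- E > 0 & !is.na(n) & !is.na(E)
  n <- n[keep]; E <- E[keep]
  if (length(n) < 2) stop("need at least 2 cells with E > 0", call. = FALSE)
  if (length(n) < 10) {
    warning("fewer than 10 cells: hyperparameter estimates will be unstable")
  }
  theta0 <- c(stats::qlogis(init[1]), log(init[-1]))
  starts <- list(theta0)
  if (restarts > 0) {
    jit <- local({
      set.seed(seed)
      lapply(seq_len(restarts), function(i) theta0 + stats::rnorm(5, 0, 0.7))
    })
    starts <- c(starts, jit)
  }
  best <- NULL
  conv <- 1L
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, gps_loglik, n = n, E = E, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = 4000,
                                  reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value > best$value) {
      best <- res
      conv <- res$convergence
    }
  }
  if (is.null(best)) stop("GPS hyperparameter optimization failed",
                          call. = FALSE)
  th <- best$par
  structure(list(w = stats::plogis(th[1]),
                 a1 = exp(th[2]), b1 = exp(th[3]),
                 a2 = exp(th[4]), b2 = exp(th[5]),
                 loglik = best$value, n_cells = length(n),
                 convergence = conv),
            class = "gps_fit")
}

#' @export
print.gps_fit <- function(x, digits = 4, ...) {
  cat("Gamma-Poisson Shrinker prior (two-component gamma mixture)\n")
  cat(sprintf("  w = %.*f | Gamma(a1 = %.*f, b1 = %.*f)", digits, x$w,
              digits, x$a1, digits, x$b1))
  cat(sprintf(" + Gamma(a2 = %.*f, b2 = %.*f)\n", digits, x$a2, digits, x$b2))
  cat(sprintf("  fitted on %d cells, log-likelihood %.3f\n",
              x$n_cells, x$loglik))
  invisible(x)
}

#' @export
coef.gps_fit <- function(object, ...) {
  c(w = object$w, a1 = object$a1, b1 = object$b1,
    a2 = object$a2, b2 = object$b2)
}

#' @export
logLik.gps_fit <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n_cells, class = "logLik")
}

# posterior mixture for one cell: component Gamma(a_k + n, b_k + E) with
# weights proportional to prior weight x marginal component likelihood
gps_posterior_mix <- function(n11, E, hyper) {
  l1 <- stats::dnbinom(n11, size = hyper$a1,
                       prob = hyper$b1 / (hyper$b1 + E), log = TRUE) +
    log(hyper$w)
  l2 <- stats::dnbinom(n11, size = hyper$a2,
                       prob = hyper$b2 / (hyper$b2 + E), log = TRUE) +
    log1p(-hyper$w)
  m <- max(l1, l2)
  q1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  list(q = c(q1, 1 - q1),
       shape = c(hyper$a1 + n11, hyper$a2 + n11),
       rate = c(hyper$b1 + E, hyper$b2 + E))
}

gps_mix_cdf <- function(x, mix) {
  mix$q[1] * stats::pgamma(x, mix$shape[1], mix$rate[1]) +
    mix$q[2] * stats::pgamma(x, mix$shape[2], mix$rate[2])
}

gps_mix_quantile <- function(p, mix) {
  qs <- stats::qgamma(p, mix$shape, mix$rate)
  lower <- min(qs) * 0.5
  upper <- max(qs) * 2 + 1e-12
  stats::uniroot(function(x) gps_mix_cdf(x, mix) - p, c(lower, upper),
                 extendInt = "yes", tol = 1e-10)$root
}

#' Empirical Bayes geometric mean for one cell
#'
#' Given the fitted prior and a cell's observed count `n11` and expected
#' count `E`, the posterior for the rate ratio lambda is a two-component
#' gamma mixture. The EBGM point estimate is the posterior geometric mean
#' `2^(E[log2 lambda])` (computed via the digamma function); with
#' `estimate = "mean"` the posterior arithmetic mean is used instead.
#' Interval bounds are posterior percentiles of lambda obtained by
#' root-finding on the mixture CDF; the default level is 90%, so the
#' bounds are EBGM05 and EBGM95.
#'
#' @param n11 observed count for the cell.
#' @param E expected count (must be positive).
#' @param hyper a `gps_fit` object.
#' @param level interval level (default 0.90).
#' @param estimate `"geometric"` (default) or `"mean"`.
#' @return a `metric_result` named `"EBGM"` with `aux$expected = E`.
#' @export
gps_posterior <- function(n11, E, hyper, level = 0.90,
                          estimate = c("geometric", "mean")) {
  estimate <- match.arg(estimate)
  stopifnot(E > 0)
  mix <- gps_posterior_mix(n11, E, hyper)
  if (estimate == "geometric") {
    elog <- sum(mix$q * (digamma(mix$shape) - log(mix$rate)))
    est <- exp(elog)
  } else {
    est <- sum(mix$q * mix$shape / mix$rate)
  }
  a <- (1 - level) / 2
  lo <- gps_mix_quantile(a, mix)
  hi <- gps_mix_quantile(1 - a, mix)
  metric_result("EBGM", est, lo, hi, level, aux = list(expected = E))
}
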