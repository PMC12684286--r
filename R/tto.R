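# Time-to-onset (TTO) analysis: days from therapy start to event onset
# (+1 day so same-day onsets count as 1), Weibull maximum likelihood with
# bootstrap percentile intervals, and hazard-pattern classification from
# the shape parameter.

#' Collect time-to-onset records for one drug
#'
#' Joins, per case, the drug's therapy-start dates with the onsets of the
#' target events and computes `days = (onset - start) + 1` (the +1 avoids
#' zero-day values when the event occurs on the start date, so `log(t)` is
#' always defined). Only complete, valid calendar dates qualify; records
#' are excluded when the start is incomplete, the onset is incomplete, or
#' the onset precedes the start. Exclusion counts by reason are attached
#' as attribute `exclusions`. When a case lists the drug more than once,
#' or has several qualifying events, each (drug occurrence, event
#' occurrence) combination contributes a record; `multiple = "earliest"`
#' keeps only the earliest onset per case instead.
#'
#' @param cases an `srs_cases` object.
#' @param drug canonical drug identifier.
#' @param pt_set character vector of target PT codes.
#' @param multiple `"all"` (default) or `"earliest"`.
#' @return data.frame with columns `case_id`, `drug`, `pt_code`, `start`,
#'   `onset` (Dates) and `days` (integer >= 1); attribute `exclusions` is
#'   a named integer vector.
#' @export
collect_tto <- function(cases, drug, pt_set, multiple = c("all", "earliest")) {
  multiple <- match.arg(multiple)
  d <- cases$drugs[!is.na(cases$drugs$canonical) &
                     cases$drugs$canonical == drug, , drop = FALSE]
  e <- cases$events[cases$events$pt_code %in% pt_set, , drop = FALSE]
  dd <- data.frame(case_id = d$case_id, start_raw = d$therapy_start,
                   stringsAsFactors = FALSE)
  ee <- data.frame(case_id = e$case_id, pt_code = e$pt_code,
                   onset_raw = e$onset, stringsAsFactors = FALSE)
  j <- merge(dd, ee, by = "case_id", sort = FALSE)
  excl <- c(incomplete_start = 0L, incomplete_onset = 0L,
            negative_interval = 0L)
  if (nrow(j)) {
    start <- pd_as_date(j$start_raw)
    onset <- pd_as_date(j$onset_raw)
    inc_s <- is.na(start)
    inc_o <- !inc_s & is.na(onset)
    neg <- !inc_s & !inc_o & onset < start
    excl <- c(incomplete_start = sum(inc_s), incomplete_onset = sum(inc_o),
              negative_interval = sum(neg))
    keep <- !inc_s & !inc_o & !neg
    j <- j[keep, , drop = FALSE]
    start <- start[keep]; onset <- onset[keep]
    out <- data.frame(case_id = j$case_id,
                      drug = rep(drug, nrow(j)),
                      pt_code = j$pt_code, start = start, onset = onset,
                      days = as.integer(onset - start) + 1L,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(case_id = character(0), drug = character(0),
                      pt_code = character(0),
                      start = as.Date(character(0)),
                      onset = as.Date(character(0)), days = integer(0),
                      stringsAsFactors = FALSE)
  }
  if (multiple == "earliest" && nrow(out)) {
    o <- order(out$case_id, out$days)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$case_id), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}

#' Descriptive statistics for time-to-onset values
#'
#' Median, first and third quartile (linear interpolation between order
#' statistics, quantile type 7), minimum and maximum.
#'
#' @param days numeric vector of TTO values (must be non-empty).
#' @return named numeric vector `median, q1, q3, min, max`.
#' @export
tto_descriptives <- function(days) {
  if (length(days) == 0) stop("no TTO records", call. = FALSE)
  q <- stats::quantile(days, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3], min = min(days), max = max(days))
}

# profile score for the Weibull shape: the MLE beta solves g(beta) = 0 with
#   g(beta) = sum(t^b log t)/sum(t^b) - 1/b - mean(log t).
# Scale-invariant in t, so t is rescaled by its max to avoid overflow.
weibull_profile_g <- function(beta, logt) {
  lt_max <- max(logt)
  w <- exp(beta * (logt - lt_max))
  sum(w * logt) / sum(w) - 1 / beta - mean(logt)
}

#' Weibull maximum likelihood fit
#'
#' Fits shape `beta` and scale `alpha` by maximum likelihood. The shape
#' solves the one-dimensional profile equation
#' `sum(t^b log t)/sum(t^b) - 1/b = mean(log t)` (root-found; the left
#' side is strictly increasing in `b`), after which
#' `alpha = mean(t^b)^(1/b)`. All-identical samples have a degenerate
#' likelihood and raise an error.
#'
#' @param days positive numeric vector, `n >= 2`, not all equal.
#' @return list with `alpha`, `beta`, `loglik`, `n`.
#' @export
weibull_mle <- function(days) {
  t <- as.numeric(days)
  if (length(t) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(t <= 0)) stop("TTO values must be positive", call. = FALSE)
  if (stats::var(t) == 0) {
    stop("degenerate likelihood: all values identical", call. = FALSE)
  }
  logt <- log(t)
  lo <- 1e-3; hi <- 1
  while (weibull_profile_g(hi, logt) < 0 && hi < 1e4) hi <- hi * 2
  beta <- stats::uniroot(weibull_profile_g, c(lo, hi), logt = logt,
                         tol = 1e-12)$root
  # alpha via scaled power mean to avoid overflow
  m <- max(t)
  alpha <- m * mean((t / m)^beta)^(1 / beta)
  ll <- weibull_loglik(alpha, beta, t)
  list(alpha = alpha, beta = beta, loglik = ll, n = length(t))
}

weibull_loglik <- function(alpha, beta, t) {
  sum(stats::dweibull(t, shape = beta, scale = alpha, log = TRUE))
}

# Vectorized Newton solver for the profile shape equation over the columns
# of a matrix of resamples (used by the bootstrap; one uniroot per column
# would dominate the run time). Returns NA for columns that fail.
weibull_shape_matrix <- function(tm, tol = 1e-10, maxit = 60) {
  logt <- log(tm)
  mlt <- colMeans(logt)
  sdl <- sqrt(pmax(colMeans(logt^2) - mlt^2, 0))
  beta <- pmin(pmax(1 / (sdl * sqrt(6) / pi), 0.05), 50)
  beta[sdl == 0] <- NA
  lt_max <- apply(logt, 2, max)
  ltc <- sweep(logt, 2, lt_max)   # logt - max, columnwise
  for (it in seq_len(maxit)) {
    act <- which(!is.na(beta))
    if (!length(act)) break
    w <- exp(sweep(ltc[, act, drop = FALSE], 2, beta[act], `*`))
    sw <- colSums(w)
    a1 <- colSums(w * logt[, act, drop = FALSE]) / sw
    a2 <- colSums(w * logt[, act, drop = FALSE]^2) / sw
    g <- a1 - 1 / beta[act] - mlt[act]
    gp <- (a2 - a1^2) + 1 / beta[act]^2
    step <- g / gp
    step <- pmin(pmax(step, -beta[act] / 2), beta[act] * 2)
    newb <- beta[act] - step
    done <- abs(step) < tol * pmax(1, newb)
    beta[act] <- newb
    if (all(done)) break
  }
  beta[!is.finite(beta) | beta <= 0] <- NA
  beta
}

#' Bootstrap confidence intervals for a Weibull fit
#'
#' Nonparametric bootstrap: `B` resamples with replacement of size `n`,
#' each refitted by maximum likelihood. With `type = "percentile"`
#' (default) the 2.5th/97.5th percentiles of the resampled `alpha`,
#' `beta` and sample median give the 95% intervals. The shape estimator
#' is biased upward and skewed at small `n`, which makes the percentile
#' interval undercover there (about 84% observed coverage for the shape
#' at `n = 17`); `type = "bca"` applies the bias-corrected and
#' accelerated adjustment (jackknife acceleration), restoring
#' near-nominal coverage. Resamples where the fit fails (e.g. all values
#' identical) are redrawn; the redraw count is attached as attribute
#' `redraws`, and more than 10% failures is an error.
#'
#' @param days positive numeric vector.
#' @param B number of bootstrap resamples (default 2000).
#' @param seed integer seed (the resampling is reproducible given the
#'   seed).
#' @param level interval level (default 0.95).
#' @param type `"percentile"` or `"bca"`.
#' @return list with `alpha_ci`, `beta_ci`, `median_ci` (length-2
#'   vectors), `B`, `seed`, `type`.
#' @export
bootstrap_weibull <- function(days, B = 2000, seed = 1L, level = 0.95,
                              type = c("percentile", "bca")) {
  type <- match.arg(type)
  t <- as.numeric(days)
  n <- length(t)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  tm <- matrix(t[idx], nrow = n)
  beta <- weibull_shape_matrix(tm)
  redraws <- 0L
  while (anyNA(beta)) {
    bad <- which(is.na(beta))
    redraws <- redraws + length(bad)
    if (redraws > 0.1 * B) {
      stop("more than 10% of bootstrap resamples failed to fit",
           call. = FALSE)
    }
    idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), nrow = n)
    tm[, bad] <- matrix(t[idx2], nrow = n)
    beta[bad] <- weibull_shape_matrix(tm[, bad, drop = FALSE])
  }
  # alpha per column from the fitted shapes (scaled like weibull_mle)
  m <- apply(tm, 2, max)
  alpha <- m * colMeans(sweep(tm, 2, m, `/`) ^
                          rep(beta, each = n))^(1 / beta)
  med <- apply(tm, 2, stats::median)
  a <- (1 - level) / 2
  if (type == "percentile") {
    qs <- function(stat, ...) {
      unname(stats::quantile(stat, c(a, 1 - a), type = 7))
    }
  } else {
    # BCa: bias correction from the bootstrap distribution, acceleration
    # from the jackknife of the original sample
    jk_idx <- matrix(rep(seq_len(n), n), n)[-seq(1, n * n, by = n + 1)]
    jk_mat <- matrix(t[matrix(jk_idx, n - 1)], n - 1)
    jk_beta <- weibull_shape_matrix(jk_mat)
    jk_m <- apply(jk_mat, 2, max)
    jk_alpha <- jk_m * colMeans(sweep(jk_mat, 2, jk_m, `/`) ^
                                  rep(jk_beta, each = n - 1))^(1 / jk_beta)
    jk_med <- apply(jk_mat, 2, stats::median)
    fit0 <- weibull_mle(t)
    jk <- list(alpha = jk_alpha, beta = jk_beta, median = jk_med)
    hat <- list(alpha = fit0$alpha, beta = fit0$beta,
                median = stats::median(t))
    qs <- function(stat, what) {
      th <- hat[[what]]
      z0 <- stats::qnorm(mean(stat < th))
      jx <- jk[[what]]
      dj <- mean(jx, na.rm = TRUE) - jx
      accel <- sum(dj^3, na.rm = TRUE) /
        (6 * sum(dj^2, na.rm = TRUE)^1.5)
      if (!is.finite(z0) || !is.finite(accel)) {
        return(unname(stats::quantile(stat, c(a, 1 - a), type = 7)))
      }
      z <- stats::qnorm(c(a, 1 - a))
      adj <- stats::pnorm(z0 + (z0 + z) / (1 - accel * (z0 + z)))
      unname(stats::quantile(stat, adj, type = 7))
    }
  }
  out <- list(alpha_ci = qs(alpha, "alpha"), beta_ci = qs(beta, "beta"),
              median_ci = qs(med, "median"), B = B, seed = seed,
              level = level, type = type)
  attr(out, "redraws") <- redraws
  out
}

#' Classify the hazard pattern from the shape parameter interval
#'
#' The Weibull shape describes how the reporting hazard evolves with
#' treatment duration: `wear_out` (increasing hazard) when the lower CI
#' bound exceeds 1, `early_failure` (decreasing) when the upper bound is
#' below 1, and `random` (constant-hazard compatible) when the interval
#' includes 1.
#'
#' @param beta_ci length-2 numeric vector, lower and upper 95% bounds for
#'   beta.
#' @return one of `"wear_out"`, `"early_failure"`, `"random"`.
#' @export
classify_failure <- function(beta_ci) {
  stopifnot(length(beta_ci) == 2, beta_ci[1] <= beta_ci[2])
  if (beta_ci[1] > 1) "wear_out"
  else if (beta_ci[2] < 1) "early_failure"
  else "random"
}

#' Weibull time-to-onset model
#'
#' Fits the Weibull law to a vector of time-to-onset values by maximum
#' likelihood ([weibull_mle()]), attaches bootstrap percentile confidence
#' intervals ([bootstrap_weibull()]), classifies the hazard pattern
#' ([classify_failure()]) and records the descriptive statistics.
#'
#' @param days positive numeric vector of TTO values (or a data.frame
#'   from [collect_tto()], whose `days` column is used).
#' @param B bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param boot compute bootstrap intervals (default `TRUE`; requires
#'   `n >= 5`).
#' @param boot_type interval type, see [bootstrap_weibull()].
#' @return an object of class `tto_weibull` with components `alpha`,
#'   `beta`, `alpha_ci`, `beta_ci`, `median_ci`, `loglik`, `n`, `days`,
#'   `descriptives`, `classification`, `B`, `seed`.
#' @examples
#' set.seed(7)
#' fit <- tto_weibull(rweibull(40, shape = 1.6, scale = 470), B = 200)
#' fit
#' coef(fit)
#' @export
tto_weibull <- function(days, B = 2000, seed = 1L, boot = TRUE,
                        boot_type = "percentile") {
  if (is.data.frame(days)) days <- days$days
  fit <- weibull_mle(days)
  desc <- tto_descriptives(days)
  ci <- NULL
  classification <- NA_character_
  if (isTRUE(boot)) {
    if (length(days) < 5) {
      warning("n < 5: bootstrap intervals skipped")
    } else {
      ci <- bootstrap_weibull(days, B = B, seed = seed, type = boot_type)
      classification <- classify_failure(ci$beta_ci)
    }
  }
  structure(list(alpha = fit$alpha, beta = fit$beta,
                 alpha_ci = ci$alpha_ci, beta_ci = ci$beta_ci,
                 median_ci = ci$median_ci, loglik = fit$loglik,
                 n = fit$n, days = as.numeric(days),
                 descriptives = desc, classification = classification,
                 B = if (is.null(ci)) NA_integer_ else ci$B,
                 seed = if (is.null(ci)) NA_integer_ else ci$seed),
            class = "tto_weibull")
}

#' @export
print.tto_weibull <- function(x, digits = 2, ...) {
  cat(sprintf("Weibull time-to-onset model (n = %d)\n", x$n))
  fmt_ci <- function(ci) if (is.null(ci)) "" else
    sprintf(" [%.*f-%.*f]", digits, ci[1], digits, ci[2])
  cat(sprintf("  shape beta  = %.*f%s\n", digits, x$beta,
              fmt_ci(x$beta_ci)))
  cat(sprintf("  scale alpha = %.*f days%s\n", digits, x$alpha,
              fmt_ci(x$alpha_ci)))
  d <- x$descriptives
  cat(sprintf("  median TTO  = %.1f days%s (IQR %.1f-%.1f, range %g-%g)\n",
              d["median"], fmt_ci(x$median_ci), d["q1"], d["q3"],
              d["min"], d["max"]))
  if (!is.na(x$classification)) {
    cat(sprintf("  hazard pattern: %s\n", x$classification))
  }
  invisible(x)
}

#' @export
coef.tto_weibull <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' @export
logLik.tto_weibull <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = object$n, class = "logLik")
}

#' @export
summary.tto_weibull <- function(object, ...) {
  print(object, digits = 3)
  invisible(object)
}

#' @export
simulate.tto_weibull <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            stats::rweibull(object$n, shape = object$beta,
                            scale = object$alpha),
            simplify = FALSE)
}

#' Plot-data for a fitted time-to-onset model
#'
#' Returns the tabular ingredients of the usual TTO figure: histogram bin
#' counts of the observed values, the fitted Weibull density curve, and
#' the fitted hazard (failure-rate) curve.
#'
#' @param fit a `tto_weibull` object.
#' @param n_grid number of grid points for the curves.
#' @return list of data.frames `histogram` (`mid`, `lower`, `upper`,
#'   `count`), `density` (`t`, `density`) and `hazard` (`t`, `hazard`).
#' @export
weibull_plot_data <- function(fit, n_grid = 200) {
  h <- graphics::hist(fit$days, plot = FALSE)
  tmax <- max(fit$days) * 1.2
  t <- seq(tmax / n_grid, tmax, length.out = n_grid)
  dens <- stats::dweibull(t, shape = fit$beta, scale = fit$alpha)
  surv <- stats::pweibull(t, shape = fit$beta, scale = fit$alpha,
                          lower.tail = FALSE)
  list(
    histogram = data.frame(mid = h$mids,
                           lower = utils::head(h$breaks, -1),
                           upper = h$breaks[-1], count = h$counts),
    density = data.frame(t = t, density = dens),
    hazard = data.frame(t = t, hazard = dens / surv)
  )
}

#' @export
plot.tto_weibull <- function(x, which = c("density", "hazard"), ...) {
  which <- match.arg(which)
  pd <- weibull_plot_data(x)
  if (which == "density") {
    graphics::hist(x$days, freq = FALSE, col = "grey85", border = "white",
                   main = "Time to onset", xlab = "days")
    graphics::lines(pd$density$t, pd$density$density, lwd = 2)
  } else {
    graphics::plot(pd$hazard$t, pd$hazard$hazard, type = "l", lwd = 2,
                   xlab = "days", ylab = "hazard",
                   main = "Fitted Weibull hazard")
  }
  invisible(pd)
}
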