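# Time-to-onset collection, descriptives, Weibull MLE and bootstrap.

test_that("TTO collection applies the +1 rule and excludes bad dates by
           reason", {
  cases <- manual_cases(
    manual_demo(c("A", "B", "C", "D", "E")),
    drugs = manual_drug(c("A", "B", "C", "D", "E"),
                        rep("PEMAFIBRATE", 5),
                        start = c("20210101", "20210101", "202101",
                                  "20210101", "20210301")),
    events = manual_event(c("A", "B", "C", "D", "E"), rep("e1", 5),
                          onset = c("20210101", "20210131", "20210110",
                                    "202102", "20210101")))
  rec <- collect_tto(cases, "pemafibrate", "e1")
  # A: same day -> 1; B: 30 days apart -> 31
  expect_equal(rec$days[rec$case_id == "A"], 1L)
  expect_equal(rec$days[rec$case_id == "B"], 31L)
  expect_false("C" %in% rec$case_id)  # month-only start
  expect_false("D" %in% rec$case_id)  # month-only onset
  expect_false("E" %in% rec$case_id)  # onset before start
  excl <- attr(rec, "exclusions")
  expect_equal(unname(excl["incomplete_start"]), 1L)
  expect_equal(unname(excl["incomplete_onset"]), 1L)
  expect_equal(unname(excl["negative_interval"]), 1L)
  expect_true(all(rec$days >= 1))
})

test_that("each qualifying event contributes a record unless collapsed to
           the earliest", {
  cases <- manual_cases(
    manual_demo("A"),
    drugs = manual_drug("A", "PEMAFIBRATE", start = "20210101"),
    events = manual_event(c("A", "A"), c("e1", "e2"),
                          onset = c("20210301", "20210201")))
  expect_equal(nrow(collect_tto(cases, "pemafibrate", c("e1", "e2"))), 2)
  one <- collect_tto(cases, "pemafibrate", c("e1", "e2"),
                     multiple = "earliest")
  expect_equal(one$pt_code, "e2")
})

test_that("descriptive statistics match the sort-based oracle", {
  expect_equal(tto_descriptives(c(1, 2, 3, 4, 5)),
               c(median = 3, q1 = 2, q3 = 4, min = 1, max = 5))
  expect_equal(unname(tto_descriptives(7)), rep(7, 5))
  set.seed(61)
  for (i in 1:10) {
    x <- sample(1:1000, sample(3:40, 1), replace = TRUE)
    d <- tto_descriptives(x)
    expect_equal(unname(d),
                 unname(c(quantile(x, 0.5), quantile(x, 0.25),
                          quantile(x, 0.75), min(x), max(x))))
  }
  expect_error(tto_descriptives(numeric(0)), "no TTO")
})

test_that("the Weibull MLE solves the profile score and matches a grid
           oracle", {
  t5 <- c(100, 200, 300, 400, 500)
  f <- weibull_mle(t5)
  g <- weibull_grid_oracle(t5)
  expect_equal(f$beta, unname(g["beta"]), tolerance = 5e-3)
  expect_equal(f$alpha, unname(g["alpha"]), tolerance = 5e-3)
  expect_gte(f$loglik, unname(g["ll"]))
  # stationarity of the profile score at the solution
  expect_lt(abs(srsignal:::weibull_profile_g(f$beta, log(t5))), 1e-8)
  # degenerate and undersized inputs
  expect_error(weibull_mle(c(5, 5, 5)), "identical")
  expect_error(weibull_mle(7), "at least 2")
})

test_that("exponential data reduce to the exponential fit", {
  set.seed(62)
  t <- rexp(20000, rate = 1 / 300)
  f <- weibull_mle(t)
  expect_equal(f$beta, 1, tolerance = 0.03)
  # with the shape pinned at 1 the scale estimator is the sample mean
  m <- max(t)
  expect_equal(m * mean(t / m), mean(t))
})

test_that("the profile-equation MLE agrees with an independent
           general-purpose fitter", {
  set.seed(67)
  t <- rweibull(500, 1.4, 380)
  f <- weibull_mle(t)
  ref <- fitdistrplus::fitdist(t, "weibull")
  # agreement limited by the reference optimizer's convergence tolerance
  expect_equal(f$beta, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(f$alpha, unname(ref$estimate["scale"]), tolerance = 1e-3)
  expect_gte(f$loglik, ref$loglik - 1e-8)
})

test_that("the fit is scale-equivariant", {
  set.seed(63)
  t <- rweibull(200, 1.7, 450)
  f1 <- weibull_mle(t)
  f2 <- weibull_mle(t * 3.5)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha * 3.5, tolerance = 1e-6)
})

test_that("the sample median converges to alpha * log(2)^(1/beta)", {
  set.seed(64)
  t <- rweibull(1e5, 1.59, 469.66)
  expect_equal(median(t), 469.66 * log(2)^(1 / 1.59), tolerance = 0.02)
})

test_that("bootstrap intervals are reproducible and contain the point
           estimates", {
  set.seed(65)
  t <- rweibull(17, 1.59, 469.66)
  b1 <- bootstrap_weibull(t, B = 500, seed = 9)
  b2 <- bootstrap_weibull(t, B = 500, seed = 9)
  expect_identical(b1, b2)
  f <- weibull_mle(t)
  expect_gt(f$beta, b1$beta_ci[1])
  expect_lt(f$beta, b1$beta_ci[2])
  expect_gt(f$alpha, b1$alpha_ci[1])
  expect_lt(f$alpha, b1$alpha_ci[2])
  expect_true(all(is.finite(c(b1$beta_ci, b1$alpha_ci, b1$median_ci))))
})

test_that("hazard patterns classify by the shape interval against 1", {
  expect_equal(classify_failure(c(1.17, 2.56)), "wear_out")
  expect_equal(classify_failure(c(0.87, 2.94)), "random")
  expect_equal(classify_failure(c(0.3, 0.9)), "early_failure")
})

test_that("the tto_weibull object carries fit, intervals, classification
           and plot data", {
  set.seed(66)
  t <- rweibull(40, 1.6, 400)
  fit <- tto_weibull(t, B = 300, seed = 2)
  expect_s3_class(fit, "tto_weibull")
  expect_equal(unname(coef(fit)), c(fit$alpha, fit$beta))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_true(fit$classification %in% c("wear_out", "random",
                                        "early_failure"))
  pd <- weibull_plot_data(fit)
  expect_named(pd, c("histogram", "density", "hazard"))
  expect_true(all(diff(pd$hazard$hazard) > 0) == (fit$beta > 1))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_length(sims[[1]], fit$n)
})
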