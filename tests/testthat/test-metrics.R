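# Contingency construction and the frequentist metrics.

test_that("contingency cells classify pairs exhaustively", {
  pairs <- data.frame(
    case_id = as.character(1:6),
    drug = c("d", "d", "d", "x", "x", "x"),
    pt_code = c("e", "f", "f", "e", "g", "g"),
    stringsAsFactors = FALSE)
  tab <- build_contingency(pairs, "d", "e")
  expect_equal(unclass(tab)[c("n11", "n12", "n21", "n22")],
               list(n11 = 1L, n12 = 2L, n21 = 1L, n22 = 2L))
  # empty drug set
  tab0 <- build_contingency(pairs, character(0), "e")
  expect_equal(tab0$n11 + tab0$n12, 0)
  # all pairs qualify
  tab1 <- build_contingency(pairs, c("d", "x"), c("e", "f", "g"))
  expect_equal(c(tab1$n12, tab1$n21, tab1$n22), c(0, 0, 0))
  expect_error(build_contingency(pairs[0, ], "d", "e"), "empty")
})

test_that("cells always sum to the pair universe, also per stratum", {
  cases <- tiny_cases(n = 700, seed = 3)
  pairs <- expand_pairs(cases)
  tab <- build_contingency(pairs, "pemafibrate", "10008629")
  expect_equal(tab$n11 + tab$n12 + tab$n21 + tab$n22, nrow(pairs))
  lab <- case_stratum(cases, "sex")
  per_case <- lab[match(pairs$case_id, cases$demo$case_id)]
  tot <- 0
  for (lv in c("male", "female")) {
    sub <- pairs[!is.na(per_case) & per_case == lv, ]
    t_s <- build_contingency(sub, "pemafibrate", "10008629")
    tot <- tot + t_s$n11 + t_s$n12 + t_s$n21 + t_s$n22
  }
  expect_equal(tot, sum(!is.na(per_case)))
})

test_that("ROR matches direct arithmetic and its Wald interval", {
  m <- ror(c(5, 95, 10, 890))
  expect_equal(m$estimate, 4450 / 950)
  se <- sqrt(1 / 5 + 1 / 95 + 1 / 10 + 1 / 890)
  expect_equal(m$lower, exp(log(4450 / 950) - qnorm(0.975) * se))
  expect_equal(m$upper, exp(log(4450 / 950) + qnorm(0.975) * se))
  expect_equal(ror(c(10, 10, 10, 10))$estimate, 1.0)
})

test_that("PRR matches direct arithmetic; equal proportions give PRR 1 and
           zero chi-square", {
  m <- prr(c(5, 95, 10, 890))
  expect_equal(m$estimate, (5 / 100) / (10 / 900))
  se <- sqrt(1 / 5 - 1 / 100 + 1 / 10 - 1 / 900)
  expect_equal(m$lower, exp(log(4.5) - qnorm(0.975) * se))
  m0 <- prr(c(10, 90, 100, 900))
  expect_equal(m0$estimate, 1.0)
  expect_equal(m0$aux$chi_square, 0)
  # Yates correction matches base chisq.test and can be disabled
  tab <- matrix(c(12, 88, 30, 870), 2, byrow = TRUE)
  expect_equal(
    prr(c(12, 88, 30, 870))$aux$chi_square,
    unname(suppressWarnings(chisq.test(tab,
                                       correct = TRUE))$statistic))
  expect_equal(
    prr(c(12, 88, 30, 870), yates = FALSE)$aux$chi_square,
    unname(suppressWarnings(chisq.test(tab,
                                       correct = FALSE))$statistic))
})

test_that("zero cells yield undefined markers unless continuity is on", {
  m <- ror(c(0, 10, 10, 10))
  expect_true(m$undefined)
  expect_true(is.na(m$estimate))
  mc <- ror(c(0, 10, 10, 10), continuity = TRUE)
  expect_false(mc$undefined)
  expect_equal(mc$estimate, (0.5 * 10.5) / (10.5 * 10.5))
  mp <- prr(c(0, 10, 10, 10))
  expect_true(mp$undefined)
  expect_false(prr(c(0, 10, 10, 10), continuity = TRUE)$undefined)
})

test_that("the CI geometric-mean identity holds to machine precision", {
  set.seed(21)
  tabs <- random_tables(300)
  for (i in seq_len(nrow(tabs))) {
    r <- ror(tabs[i, ])
    p <- prr(tabs[i, ])
    expect_equal(sqrt(r$lower * r$upper), r$estimate, tolerance = 1e-12)
    expect_equal(sqrt(p$lower * p$upper), p$estimate, tolerance = 1e-12)
  }
})

test_that("ROR and PRR agree in sign relative to 1, and ROR is the more
           extreme of the two", {
  set.seed(22)
  tabs <- random_tables(10000)
  r <- (tabs[, 1] * tabs[, 4]) / (tabs[, 2] * tabs[, 3])
  p <- (tabs[, 1] / (tabs[, 1] + tabs[, 2])) /
    (tabs[, 3] / (tabs[, 3] + tabs[, 4]))
  expect_true(all(sign(r - p) == sign(p - 1) | p == 1))
  prop <- tabs[, 1] * tabs[, 4] == tabs[, 2] * tabs[, 3]
  expect_true(all((abs(r - 1) < 1e-12 & abs(p - 1) < 1e-12) == prop))
  # spot-check the closed forms against the metric functions
  i <- sample(nrow(tabs), 25)
  for (k in i) {
    expect_equal(ror(tabs[k, ])$estimate, r[k])
    expect_equal(prr(tabs[k, ])$estimate, p[k])
  }
})

test_that("Fisher exact p matches full hypergeometric enumeration", {
  expect_equal(fisher_exact(c(1, 9, 11, 3)),
               fisher_enum_oracle(1, 9, 11, 3), tolerance = 1e-7)
  expect_equal(round(fisher_exact(c(1, 9, 11, 3)), 6), 0.002759)
  expect_equal(fisher_exact(c(2, 2, 2, 2)), 1.0)
  # symmetric complement gives the identical p
  expect_equal(fisher_exact(c(0, 5, 5, 0)), fisher_exact(c(5, 0, 0, 5)))
})

test_that("IC satisfies its algebraic identity and shrinks to zero at
           independence", {
  # n11 = E exactly
  m <- bcpnn_ic(c(10, 90, 90, 810))
  expect_equal(m$aux$expected, 10)
  expect_equal(m$estimate, 0)
  set.seed(23)
  tabs <- random_tables(200)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    m <- bcpnn_ic(t)
    E <- (t[1] + t[2]) * (t[1] + t[3]) / sum(t)
    expect_equal(2^m$estimate * (E + 0.5), t[1] + 0.5, tolerance = 1e-12)
    expect_lt(m$lower, m$estimate + 1e-12)
    expect_gt(m$upper, m$estimate - 1e-12)
  }
})

test_that("IC credibility bounds match Monte-Carlo posterior quantiles", {
  t <- c(20, 980, 100, 8900)
  m <- bcpnn_ic(t)
  E <- m$aux$expected
  set.seed(24)
  draws <- log2(rgamma(1e6, shape = 20 + 0.5, rate = E + 0.5))
  q <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(m$lower - q[1]), 0.01)
  expect_lt(abs(m$upper - q[2]), 0.01)
})

test_that("signal rules honor their strict and inclusive boundaries", {
  mk <- function(name, lower, aux = list()) {
    srsignal:::metric_result(name, lower + 1, lower, lower + 2, 0.95, aux)
  }
  # n11 >= 3 gate for ROR
  f <- apply_signal_rules(list(ror = mk("ROR", 5)), n11 = 2)
  expect_false(f$ror_signal)
  expect_true(apply_signal_rules(list(ror = mk("ROR", 1.001)),
                                 n11 = 3)$ror_signal)
  expect_false(apply_signal_rules(list(ror = mk("ROR", 1.0)),
                                  n11 = 3)$ror_signal)
  # PRR: strict > 2 and chi-square > 4
  prr_m <- function(lo, chi) mk("PRR", lo, aux = list(chi_square = chi))
  expect_false(apply_signal_rules(list(prr = prr_m(2.0, 10)),
                                 n11 = 5)$prr_signal)
  expect_true(apply_signal_rules(list(prr = prr_m(2.001, 10)),
                                n11 = 5)$prr_signal)
  expect_false(apply_signal_rules(list(prr = prr_m(3, 4.0)),
                                 n11 = 5)$prr_signal)
  # IC: strict > 0
  expect_false(apply_signal_rules(list(ic = mk("IC", 0)), 5)$ic_signal)
  expect_true(apply_signal_rules(list(ic = mk("IC", 1e-6)), 5)$ic_signal)
  # EBGM: inclusive >= 2.0
  expect_true(apply_signal_rules(list(ebgm = mk("EBGM", 2.0)),
                                 5)$ebgm_signal)
  expect_false(apply_signal_rules(list(ebgm = mk("EBGM", 1.999)),
                                  5)$ebgm_signal)
  # undefined metrics never signal
  und <- srsignal:::undefined_metric("ROR", 0.95, "zero cell")
  expect_false(apply_signal_rules(list(ror = und), 10)$ror_signal)
})
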