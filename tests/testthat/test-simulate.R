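# Synthetic SRS generator: validation, reproducibility, calibration, and
# the ground-truth estimand.

test_that("invalid configurations report every violation at once", {
  cfg <- default_sim_config(n_reports = 100)
  cfg$sex_ratio_male <- 1.5
  cfg$date_missing_prob <- -0.1
  cfg$age_band_probs <- c("20s" = 0.5, "30s" = 0.4)  # sums to 0.9
  err <- tryCatch(validate_sim_config(cfg), error = function(e)
    conditionMessage(e))
  expect_match(err, "sex_ratio_male")
  expect_match(err, "date_missing_prob")
  expect_match(err, "age_band_probs")
})

test_that("identical configurations produce identical datasets and files", {
  cfg <- tiny_sim_config(n = 400, seed = 77)
  s1 <- simulate_srs(cfg)
  s2 <- simulate_srs(cfg)
  expect_identical(s1$jader, s2$jader)
  expect_identical(s1$faers, s2$faers)
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  p1 <- write_srs(s1, t1); p2 <- write_srs(s2, t2)
  md5 <- function(p) unname(tools::md5sum(unlist(p)))
  expect_equal(md5(p1), md5(p2))
})

test_that("FAERS duplication is undone exactly by version dedup", {
  cfg <- default_sim_config(n_reports = 1000, seed = 78,
                            duplicate_prob = 0.5)
  sim <- simulate_srs(cfg)
  expect_gt(nrow(sim$faers$demo), 1000)
  dd <- dedup_faers(sim$faers$demo)
  expect_equal(nrow(dd), 1000)
  expect_true(all(dd$caseversion >= "1"))
  # retained rows are the max version per case
  dup_cases <- names(which(table(sim$faers$demo$caseid) == 2))
  expect_true(all(dd$caseversion[dd$caseid %in% dup_cases] == "2"))
})

test_that("demographic marginals are calibrated to the configuration", {
  n <- 20000
  cfg <- default_sim_config(n_reports = n, seed = 79)
  sim <- simulate_srs(cfg)
  cases <- merge_case_level(sim$jader, "jader")
  # binomial 99% bounds
  bound <- function(p) 2.58 * sqrt(p * (1 - p) / n)
  p_male <- mean(cases$demo$sex == "male")
  expect_lt(abs(p_male - cfg$sex_ratio_male),
            bound(cfg$sex_ratio_male))
  for (b in names(cfg$age_band_probs)) {
    ph <- mean(cases$demo$age_band == b)
    expect_lt(abs(ph - cfg$age_band_probs[[b]]),
              bound(cfg$age_band_probs[[b]]))
  }
})

test_that("a null association yields an empirical ROR near 1", {
  cfg <- default_sim_config(n_reports = 20000, theta = 1, seed = 80)
  sim <- simulate_srs(cfg)
  cases <- merge_case_level(sim$jader, "jader")
  m <- disprop(expand_pairs(cases), "pemafibrate", "10008629",
               unit = "icsr")$metrics$ror
  expect_gt(m$upper, 1)
  expect_lt(m$lower, 1)
})

test_that("the estimated log-ROR is centered on log(theta) across
           replicates", {
  theta <- 4
  est <- vapply(1:12, function(s) {
    cfg <- default_sim_config(n_reports = 20000, theta = theta,
                              seed = 300 + s)
    cases <- merge_case_level(simulate_srs(cfg)$jader, "jader")
    log(disprop(expand_pairs(cases), "pemafibrate", "10008629",
                unit = "icsr")$metrics$ror$estimate)
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - log(theta)), 3 * se)
})

test_that("true_ror returns theta, defaults to 1, and guards confounded
           queries", {
  cfg <- default_sim_config(theta = 3.74)
  expect_equal(true_ror(cfg, "pemafibrate", "10008629"), 3.74)
  expect_equal(true_ror(cfg, "bezafibrate", "10008612"), 1.0)
  cfg$association_theta <- rbind(
    cfg$association_theta,
    data.frame(drug = "fenofibrate", event = "10008629", theta = 2))
  expect_error(true_ror(cfg, "pemafibrate", "10008629"), "confounded")
})

test_that("simulated time-to-onset follows the configured Weibull law", {
  cfg <- default_sim_config(n_reports = 30000, theta = 4, seed = 81,
                            date_missing_prob = 0)
  sim <- simulate_srs(cfg)
  cases <- merge_case_level(sim$jader, "jader")
  rec <- collect_tto(cases, "pemafibrate",
                     c("10008629", "10008612", "10008614"))
  expect_gt(nrow(rec), 60)
  f <- weibull_mle(rec$days)
  expect_equal(f$beta, 1.59, tolerance = 0.15)
  expect_equal(f$alpha, 469.66, tolerance = 0.1 * 469.66)
})

test_that("date missingness removes records from TTO at the configured
           rate", {
  cfg <- default_sim_config(n_reports = 20000, theta = 4, seed = 82,
                            date_missing_prob = 0.4)
  sim <- simulate_srs(cfg)
  cases <- merge_case_level(sim$jader, "jader")
  rec <- collect_tto(cases, "pemafibrate",
                     c("10008629", "10008612", "10008614"))
  excl <- attr(rec, "exclusions")
  tot <- nrow(rec) + sum(excl)
  # completeness requires both dates intact: (1 - 0.4)^2 = 0.36,
  # checked within 3 binomial standard errors of the joined-record count
  p_hat <- unname(nrow(rec) + excl["negative_interval"]) / tot
  expect_lt(abs(p_hat - 0.36), 3 * sqrt(0.36 * 0.64 / tot))
})
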