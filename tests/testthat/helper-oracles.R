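# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Two-sided Fisher exact p by full hypergeometric enumeration: sum the
# probabilities of all tables with the observed margins whose point
# probability is <= that of the observed table (within relative tolerance).
fisher_enum_oracle <- function(n11, n12, n21, n22, rel_tol = 1e-7) {
  m <- n11 + n12          # row 1 total
  np1 <- n11 + n21        # col 1 total
  npp <- n11 + n12 + n21 + n22
  lo <- max(0, np1 - (npp - m))
  hi <- min(m, np1)
  support <- lo:hi
  probs <- dhyper(support, m, npp - m, np1)
  p_obs <- dhyper(n11, m, npp - m, np1)
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

# Dense grid search maximizer of the Weibull log-likelihood.
weibull_grid_oracle <- function(t, beta_grid = seq(0.2, 6, by = 0.002),
                                alpha_grid = NULL) {
  if (is.null(alpha_grid)) {
    alpha_grid <- seq(min(t) / 2, max(t) * 2, length.out = 2500)
  }
  best <- c(alpha = NA, beta = NA, ll = -Inf)
  for (b in beta_grid) {
    # profile alpha in closed form for each beta: alpha = mean(t^b)^(1/b)
    a <- mean(t^b)^(1 / b)
    ll <- sum(dweibull(t, shape = b, scale = a, log = TRUE))
    if (ll > best["ll"]) best <- c(alpha = a, beta = b, ll = ll)
  }
  best
}

# Random 2x2 tables with all cells >= min_cell.
random_tables <- function(n_tables, max_cell = 50, min_cell = 1) {
  matrix(sample(min_cell:max_cell, 4 * n_tables, replace = TRUE),
         ncol = 4)
}

# A compact simulated dataset for pipeline tests (small but non-trivial).
tiny_sim_config <- function(n = 3000, theta = 6, seed = 99, ...) {
  default_sim_config(n_reports = n, theta = theta, seed = seed, ...)
}

tiny_cases <- function(n = 3000, theta = 6, seed = 99,
                       dialect = "jader", ...) {
  sim <- simulate_srs(tiny_sim_config(n, theta, seed, ...))
  if (dialect == "jader") {
    merge_case_level(sim$jader, "jader")
  } else {
    tabs <- sim$faers
    tabs$demo <- dedup_faers(tabs$demo)
    suppressMessages(merge_case_level(tabs, "faers"))
  }
}

# Hand-built srs_cases object for unit tests needing exact content.
manual_cases <- function(demo, drugs = NULL, events = NULL,
                         dialect = "jader") {
  if (is.null(drugs)) drugs <- srsignal:::empty_drugs()
  if (is.null(events)) events <- srsignal:::empty_events()
  structure(list(demo = demo, drugs = drugs, events = events,
                 dialect = dialect), class = "srs_cases")
}

manual_demo <- function(case_id, sex = "male", age_band = "60s",
                        height_low = NA_integer_,
                        weight_low = NA_integer_) {
  data.frame(case_id = case_id, sex = sex, age_band = age_band,
             height_low = height_low,
             height_high = height_low + 10L,
             weight_low = weight_low,
             weight_high = weight_low + 10L,
             reporter = "healthcare_professional",
             report_year = 2020L, stringsAsFactors = FALSE)
}

manual_drug <- function(case_id, name, role = "suspect_unspecified",
                        start = NA_character_, end = NA_character_) {
  data.frame(case_id = case_id,
             drug_seq = as.character(seq_along(case_id)),
             raw_name = name, canonical = match_drug(name),
             role = role, therapy_start = start, therapy_end = end,
             stringsAsFactors = FALSE)
}

manual_event <- function(case_id, pt_code, onset = NA_character_) {
  data.frame(case_id = case_id, pt_code = pt_code, pt_name = pt_code,
             onset = onset, stringsAsFactors = FALSE)
}
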