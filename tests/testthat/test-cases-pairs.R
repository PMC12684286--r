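# Case-level merge semantics, lexicon matching, and pair expansion.

test_that("merge is a left join on DEMO: every case appears once", {
  demo <- data.frame("識別番号" = c("A", "B"),
                     "性別" = c("男性", "女性"),
                     check.names = FALSE)
  drug <- data.frame("識別番号" = c("A", "A", "A"),
                     "医薬品一般名" = c("ペマフィブラート",
                                               "X", "Y"),
                     check.names = FALSE)
  cases <- merge_case_level(list(demo = demo, drug = drug), "jader")
  expect_equal(nrow(cases$demo), 2)
  expect_equal(sum(cases$drugs$case_id == "A"), 3)
  expect_equal(sum(cases$drugs$case_id == "B"), 0)
  expect_equal(cases$demo$sex, c("male", "female"))
})

test_that("orphan event rows are dropped with a message", {
  demo <- data.frame("識別番号" = "A", check.names = FALSE)
  reac <- data.frame("識別番号" = c("A", "ZZZ"),
                     "有害事象" = c("e1", "e2"),
                     check.names = FALSE)
  expect_message(
    cases <- merge_case_level(list(demo = demo, reac = reac), "jader"),
    "orphan")
  expect_equal(cases$events$case_id, "A")
})

test_that("FAERS therapy start dates attach via dsg_drug_seq", {
  tabs <- list(
    demo = data.frame(primaryid = "11", caseid = "A", caseversion = "1",
                      event_dt = "20210301", stringsAsFactors = FALSE),
    drug = data.frame(primaryid = c("11", "11"), caseid = c("A", "A"),
                      drug_seq = c("1", "2"), role_cod = c("PS", "C"),
                      drugname = c("PEMAFIBRATE", "ASPIRIN"),
                      stringsAsFactors = FALSE),
    ther = data.frame(primaryid = "11", caseid = "A", dsg_drug_seq = "1",
                      start_dt = "20200115", end_dt = "",
                      stringsAsFactors = FALSE),
    reac = data.frame(primaryid = "11", caseid = "A",
                      pt = "Cholelithiasis", stringsAsFactors = FALSE))
  cases <- merge_case_level(tabs, "faers")
  expect_equal(cases$drugs$therapy_start, c("20200115", NA))
  # event onset comes from DEMO event_dt
  expect_equal(cases$events$onset, "20210301")
})

test_that("drug names match the lexicon exactly after normalization", {
  expect_equal(match_drug("  fenofibric acid "), "fenofibrate")
  expect_equal(match_drug("CHOLINE  FENOFIBRATE"), "fenofibrate")
  expect_equal(match_drug("PEMAFIBRATE"), "pemafibrate")
  expect_equal(match_drug("ペマフィブラート"), "pemafibrate")
  expect_true(is.na(match_drug("ASPIRIN")))
})

test_that("pair expansion is the drug x event product within each case", {
  cases <- manual_cases(
    manual_demo(c("A", "B", "C")),
    drugs = manual_drug(c("A", "A", "B", "C"),
                        c("PEMAFIBRATE", "ASPIRIN", "BEZAFIBRATE", "X")),
    events = manual_event(c("A", "A", "A", "C"),
                          c("e1", "e2", "e3", "e1")))
  pairs <- expand_pairs(cases)
  # A: 2 drugs x 3 events = 6; B: 0 events -> 0; C: 1 x 1 = 1
  expect_equal(nrow(pairs), 7)
  expect_equal(sum(pairs$case_id == "A"), 6)
  expect_equal(sum(pairs$case_id == "B"), 0)
})

test_that("pair count identity holds on simulated data", {
  cases <- tiny_cases(n = 800, seed = 5)
  pairs <- expand_pairs(cases)
  nd <- table(factor(cases$drugs$case_id,
                     levels = cases$demo$case_id))
  ne <- table(factor(cases$events$case_id,
                     levels = cases$demo$case_id))
  expect_equal(nrow(pairs), sum(as.numeric(nd) * as.numeric(ne)))
})

test_that("primary-suspect filtering keeps only suspect roles", {
  pairs <- data.frame(case_id = "A", drug = "d", pt_code = "e",
                      role = c("primary_suspect", "secondary_suspect",
                               "concomitant", "interacting",
                               "suspect_unspecified"),
                      stringsAsFactors = FALSE)
  expect_equal(filter_primary_suspect(pairs)$role,
               c("primary_suspect", "suspect_unspecified"))
  expect_equal(
    filter_primary_suspect(pairs, include_unspecified_suspect = FALSE)$role,
    "primary_suspect")
  expect_equal(nrow(filter_primary_suspect(pairs[pairs$role ==
                                                   "concomitant", ])), 0)
  expect_equal(nrow(filter_primary_suspect(pairs[0, ])), 0)
})

test_that("unique-ICSR counting deduplicates cases across pairs", {
  pairs <- data.frame(
    case_id = c("A", "A", "B", "B", "C"),
    drug = c("pemafibrate", "fenofibrate", "pemafibrate", "pemafibrate",
             "other"),
    pt_code = c("e1", "e1", "e1", "e2", "e1"),
    stringsAsFactors = FALSE)
  fib <- c("pemafibrate", "fenofibrate")
  # A has two qualifying pairs via two fibrates -> one ICSR
  expect_equal(count_unique_icsrs(pairs, fib, "e1"), 2)
  expect_equal(count_unique_icsrs(pairs, fib, c("e1", "e2")), 2)
  expect_equal(count_unique_icsrs(pairs, "nope", "e1"), 0)
})

test_that("unique-ICSR count is bounded by qualifying pairs, with equality
           iff no case repeats", {
  set.seed(31)
  for (i in 1:20) {
    pairs <- data.frame(
      case_id = sample(LETTERS[1:6], 30, replace = TRUE),
      drug = sample(c("d1", "d2"), 30, replace = TRUE),
      pt_code = sample(c("e1", "e2"), 30, replace = TRUE),
      stringsAsFactors = FALSE)
    q <- pairs$drug == "d1" & pairs$pt_code == "e1"
    cnt <- count_unique_icsrs(pairs, "d1", "e1")
    # brute-force set count
    expect_equal(cnt, length(unique(pairs$case_id[q])))
    expect_lte(cnt, sum(q))
    if (sum(q) > 0 && !any(duplicated(pairs$case_id[q]))) {
      expect_equal(cnt, sum(q))
    }
  }
})

test_that("writing and re-reading a dataset reproduces the case records", {
  cfg <- default_sim_config(n_reports = 150, theta = 2, seed = 17,
                            date_missing_prob = 0)
  sim <- simulate_srs(cfg)
  td <- withr::local_tempdir()
  paths <- write_srs(sim, td)
  jtabs <- read_jader_tables(as.list(paths$jader))
  direct <- merge_case_level(sim$jader, "jader")
  reread <- merge_case_level(jtabs, "jader")
  expect_equal(reread, direct)
  ftabs <- read_faers_tables(as.list(paths$faers))
  fdirect <- suppressMessages(merge_case_level(
    within(sim$faers, demo <- dedup_faers(demo)), "faers"))
  freread <- suppressMessages(merge_case_level(
    within(ftabs, demo <- dedup_faers(demo)), "faers"))
  expect_equal(freread, fdirect)
})
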