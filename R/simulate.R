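# Synthetic SRS generator. Emits the same raw tables as a JADER or FAERS
# download, but from a fully specified generative model with a known
# association strength, so every downstream stage (readers, dedup, merge,
# pair expansion, metrics, TTO) can be validated against ground truth.
#
# Generative model per report: demographics are sampled from the
# configured marginals; each drug is present independently with its
# exposure probability; each event occurs with odds
#   baseline_odds * prod(theta(d, e) over exposed drugs d),
# converted to a probability p = odds / (1 + odds). The multiplicative
# action on the *odds* scale makes the report-level reporting odds ratio
# of a single associated drug equal theta exactly, which is what makes
# parameter recovery a clean test.

#' Construct a synthetic-SRS configuration
#'
#' See [default_sim_config()] for the ready-made default scenario. All
#' arguments are validated together; invalid configurations raise one
#' error listing every violation.
#'
#' @param n_reports number of reports (cases) to generate.
#' @param drugs list of drug specs: each a list with `name` (canonical
#'   identifier), `exposure_prob`, `role_distribution` (named numeric over
#'   the role codes, summing to 1), and display names `jader_name`,
#'   `faers_name`.
#' @param events list of event specs: each a list with `pt_code`,
#'   `pt_name`, `baseline_odds`.
#' @param association_theta data.frame with columns `drug`, `event`,
#'   `theta` (odds multipliers; absent pairs have theta = 1).
#' @param sex_ratio_male probability a report is male.
#' @param age_band_probs,height_band_probs,weight_band_probs named
#'   probability vectors over decade age bands (`"20s"` ...) and 10-cm /
#'   10-kg band lower bounds (`"150"` ...); each must sum to 1.
#' @param reporter_hcp_prob probability the reporter is a healthcare
#'   professional (otherwise consumer).
#' @param tto_law data.frame with columns `drug`, `event`, `alpha`,
#'   `beta`: Weibull time-to-onset law (days) for realized (drug, event)
#'   combinations.
#' @param date_missing_prob probability that a date loses its day
#'   component (independently per recorded date).
#' @param duplicate_prob probability a FAERS case is emitted twice with
#'   incremented case version (exact copy otherwise).
#' @param report_years integer vector of calendar years reports are drawn
#'   from.
#' @param seed integer seed; the same configuration (including seed)
#'   yields identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_reports, drugs, events,
                       association_theta = NULL, sex_ratio_male = 0.5,
                       age_band_probs, height_band_probs,
                       weight_band_probs, reporter_hcp_prob = 0.95,
                       tto_law = NULL, date_missing_prob = 0,
                       duplicate_prob = 0, report_years = 2015:2024,
                       seed = 1L) {
  if (is.null(association_theta)) {
    association_theta <- data.frame(drug = character(0),
                                    event = character(0),
                                    theta = numeric(0))
  }
  if (is.null(tto_law)) {
    tto_law <- data.frame(drug = character(0), event = character(0),
                          alpha = numeric(0), beta = numeric(0))
  }
  cfg <- structure(list(
    n_reports = n_reports, drugs = drugs, events = events,
    association_theta = association_theta,
    sex_ratio_male = sex_ratio_male,
    age_band_probs = age_band_probs,
    height_band_probs = height_band_probs,
    weight_band_probs = weight_band_probs,
    reporter_hcp_prob = reporter_hcp_prob,
    tto_law = tto_law, date_missing_prob = date_missing_prob,
    duplicate_prob = duplicate_prob, report_years = report_years,
    seed = as.integer(seed)), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a synthetic-SRS configuration
#'
#' Checks every constraint and reports all violations in a single error.
#'
#' @param config a `sim_config` object (or plain list with the same
#'   fields).
#' @return the config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)
  prob_ok <- function(p) is.numeric(p) && length(p) == 1 && !is.na(p) &&
    p >= 0 && p <= 1
  if (!is.numeric(config$n_reports) || config$n_reports < 1) {
    push("n_reports must be a positive integer")
  }
  for (d in config$drugs) {
    if (!prob_ok(d$exposure_prob)) {
      push(sprintf("drug %s: exposure_prob not in [0,1]", d$name))
    }
    rd <- d$role_distribution
    if (!is.numeric(rd) || any(rd < 0) || abs(sum(rd) - 1) > 1e-8 ||
        !all(names(rd) %in% drug_roles())) {
      push(sprintf(paste("drug %s: role_distribution must be a named",
                         "probability vector over role codes summing to 1"),
                   d$name))
    }
  }
  for (e in config$events) {
    if (!is.numeric(e$baseline_odds) || e$baseline_odds < 0) {
      push(sprintf("event %s: baseline_odds must be >= 0", e$pt_code))
    }
  }
  if (any(config$association_theta$theta <= 0)) {
    push("association_theta: theta must be > 0")
  }
  if (!prob_ok(config$sex_ratio_male)) push("sex_ratio_male not in [0,1]")
  for (nm in c("age_band_probs", "height_band_probs",
               "weight_band_probs")) {
    p <- config[[nm]]
    if (!is.numeric(p) || is.null(names(p)) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      push(sprintf("%s must be a named probability vector summing to 1",
                   nm))
    }
  }
  if (!prob_ok(config$reporter_hcp_prob)) {
    push("reporter_hcp_prob not in [0,1]")
  }
  if (nrow(config$tto_law) &&
      (any(config$tto_law$alpha <= 0) || any(config$tto_law$beta <= 0))) {
    push("tto_law: alpha and beta must be > 0")
  }
  if (!prob_ok(config$date_missing_prob)) {
    push("date_missing_prob not in [0,1]")
  }
  if (!prob_ok(config$duplicate_prob)) push("duplicate_prob not in [0,1]")
  if (length(errs)) {
    stop("invalid sim_config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(config)
}

sim_drug <- function(name, exposure_prob,
                     role_distribution = c(primary_suspect = 0.25,
                                           secondary_suspect = 0.10,
                                           concomitant = 0.55,
                                           interacting = 0.10),
                     jader_name = name, faers_name = toupper(name)) {
  list(name = name, exposure_prob = exposure_prob,
       role_distribution = role_distribution,
       jader_name = jader_name, faers_name = faers_name)
}

sim_event <- function(pt_code, pt_name, baseline_odds) {
  list(pt_code = pt_code, pt_name = pt_name, baseline_odds = baseline_odds)
}

#' Default synthetic-SRS scenario
#'
#' The default configuration mirrors the structure of the fibrate /
#' biliary-event analysis: the three fibrates plus ten background drugs;
#' the fourteen target biliary PTs plus eight common background events; a
#' single ground-truth association (pemafibrate vs cholelithiasis, odds
#' multiplier `theta`, default 4); a Weibull time-to-onset law for
#' pemafibrate and the biliary PTs with scale 469.66 days and shape 1.59;
#' demographics matching the reported fibrate case profile (67.9% male,
#' 67.9% aged >= 60); day components missing from 39.3% of dates (the
#' reported completeness of onset data is 60.7%); and a 10% FAERS
#' duplicate-version rate. Report volume defaults to 50,000 so the target
#' cells are well populated.
#'
#' @param n_reports number of reports.
#' @param theta ground-truth odds multiplier for the
#'   pemafibrate-cholelithiasis pair.
#' @param seed integer seed.
#' @param date_missing_prob,duplicate_prob see [sim_config()].
#' @return a `sim_config` object.
#' @export
default_sim_config <- function(n_reports = 50000, theta = 4, seed = 1L,
                               date_missing_prob = 0.393,
                               duplicate_prob = 0.10) {
  fib_roles <- c(primary_suspect = 0.55, secondary_suspect = 0.10,
                 concomitant = 0.30, interacting = 0.05)
  drugs <- c(
    list(
      sim_drug("pemafibrate", 0.05, fib_roles,
               jader_name = "ペマフィブラート",
               faers_name = "PEMAFIBRATE"),
      sim_drug("fenofibrate", 0.04, fib_roles,
               jader_name = "フェノフィブラート",
               faers_name = "FENOFIBRIC ACID"),
      sim_drug("bezafibrate", 0.03, fib_roles,
               jader_name = "ベザフィブラート",
               faers_name = "BEZAFIBRATE")
    ),
    lapply(1:10, function(i) {
      sim_drug(sprintf("background_drug_%02d", i), 0.12,
               jader_name = sprintf("背景薬%02d", i),
               faers_name = sprintf("BACKGROUND DRUG %02d", i))
    })
  )
  pts <- default_event_pts()
  events <- c(
    lapply(1:3, function(i) {
      sim_event(pts$pt_code[i], pts$pt_name[i], baseline_odds = 0.010)
    }),
    lapply(4:14, function(i) {
      sim_event(pts$pt_code[i], pts$pt_name[i], baseline_odds = 0.003)
    }),
    lapply(1:8, function(i) {
      sim_event(sprintf("8000%04d", i), sprintf("Background event %d", i),
                baseline_odds = 0.12)
    })
  )
  biliary <- pts$pt_code[1:3]
  sim_config(
    n_reports = n_reports, drugs = drugs, events = events,
    association_theta = data.frame(drug = "pemafibrate",
                                   event = "10008629", theta = theta),
    sex_ratio_male = 0.679,
    age_band_probs = c("20s" = 0.04, "30s" = 0.07, "40s" = 0.09,
                       "50s" = 0.121, "60s" = 0.28, "70s" = 0.25,
                       "80s" = 0.149),
    height_band_probs = c("140" = 0.10, "150" = 0.30, "160" = 0.35,
                          "170" = 0.20, "180" = 0.05),
    weight_band_probs = c("40" = 0.15, "50" = 0.30, "60" = 0.30,
                          "70" = 0.15, "80" = 0.10),
    reporter_hcp_prob = 0.97,
    tto_law = data.frame(drug = "pemafibrate", event = biliary,
                         alpha = 469.66, beta = 1.59),
    date_missing_prob = date_missing_prob,
    duplicate_prob = duplicate_prob,
    report_years = 2015:2024, seed = seed
  )
}

#' Ground-truth reporting odds ratio of the generative model
#'
#' Returns the population report-level reporting odds ratio implied by the
#' configuration for one (drug, event) pair: exactly `theta(drug, event)`,
#' because the association acts multiplicatively on the odds scale. The
#' estimand is only clean when no *other* drug carries a non-unit theta
#' for the same event; in that case the marginal odds ratio is not
#' collapsible over the co-exposure and an error is raised.
#'
#' @param config a `sim_config`.
#' @param drug,event identifiers of the queried pair.
#' @return the positive real theta (1 if unset).
#' @export
true_ror <- function(config, drug, event) {
  at <- config$association_theta
  others <- at[at$event == event & at$drug != drug & at$theta != 1, ,
               drop = FALSE]
  if (nrow(others)) {
    stop("estimand confounded: other drug(s) with theta != 1 for event ",
         event, ": ", paste(others$drug, collapse = ", "), call. = FALSE)
  }
  hit <- at$drug == drug & at$event == event
  if (any(hit)) at$theta[which(hit)[1]] else 1
}

round_half_up <- function(x) floor(x + 0.5)

blank_day <- function(dates_int, blank) {
  # dates_int: Date vector; returns compact partial strings with the day
  # component removed where blank is TRUE
  out <- format(dates_int, "%Y%m%d")
  out[blank] <- format(dates_int[blank], "%Y%m")
  out[is.na(dates_int)] <- ""
  out
}

#' Simulate a synthetic SRS dataset in both dialects
#'
#' Draws one dataset from the generative model of a [sim_config()] and
#' renders it as raw JADER-dialect tables (`demo`, `drug`, `reac`, an
#' empty `hist`) and FAERS-dialect tables (`demo`, `drug`, `reac`,
#' `ther`), exactly as [read_jader_tables()] / [read_faers_tables()]
#' would return them. FAERS cases are duplicated with incremented case
#' versions with the configured probability, so [dedup_faers()] has real
#' work to do. The same configuration yields identical tables.
#'
#' @param config a `sim_config` object.
#' @return an object of class `srs_sim`: list with `jader`, `faers`
#'   (named lists of character data.frames) and the `config`.
#' @export
simulate_srs <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_reports)
  D <- length(config$drugs)
  Ev <- length(config$events)
  dnames <- vapply(config$drugs, `[[`, "", "name")
  ecodes <- vapply(config$events, `[[`, "", "pt_code")
  enames <- vapply(config$events, `[[`, "", "pt_name")

  # demographics ------------------------------------------------------
  sex <- ifelse(stats::runif(n) < config$sex_ratio_male, "male", "female")
  age_band <- sample(names(config$age_band_probs), n, replace = TRUE,
                     prob = config$age_band_probs)
  hband <- sample(names(config$height_band_probs), n, replace = TRUE,
                  prob = config$height_band_probs)
  wband <- sample(names(config$weight_band_probs), n, replace = TRUE,
                  prob = config$weight_band_probs)
  reporter <- ifelse(stats::runif(n) < config$reporter_hcp_prob,
                     "hcp", "consumer")
  year <- sample(config$report_years, n, replace = TRUE)

  # exposures and drug entries ----------------------------------------
  expo <- matrix(0L, n, D)
  for (j in seq_len(D)) {
    expo[, j] <- stats::rbinom(n, 1L, config$drugs[[j]]$exposure_prob)
  }
  ent <- which(expo == 1L, arr.ind = TRUE)
  ent <- ent[order(ent[, 1], ent[, 2]), , drop = FALSE]
  ecase <- ent[, 1]; edrug <- ent[, 2]
  roles <- character(nrow(ent))
  for (j in seq_len(D)) {
    k <- edrug == j
    rd <- config$drugs[[j]]$role_distribution
    if (any(k)) {
      roles[k] <- sample(names(rd), sum(k), replace = TRUE, prob = rd)
    }
  }
  start_pool <- seq(as.Date("2015-01-01"), as.Date("2023-12-31"), by = 1)
  tstart <- sample(start_pool, nrow(ent), replace = TRUE)
  tend <- tstart + round_half_up(stats::rexp(nrow(ent), rate = 1 / 400))

  # events -------------------------------------------------------------
  odds <- matrix(rep(vapply(config$events, `[[`, 0, "baseline_odds"),
                     each = n), n, Ev)
  at <- config$association_theta
  for (r in seq_len(nrow(at))) {
    j <- match(at$drug[r], dnames)
    k <- match(at$event[r], ecodes)
    if (is.na(j) || is.na(k)) next
    odds[expo[, j] == 1L, k] <- odds[expo[, j] == 1L, k] * at$theta[r]
  }
  evmat <- matrix(stats::rbinom(n * Ev, 1L, odds / (1 + odds)), n, Ev)
  eent <- which(evmat == 1L, arr.ind = TRUE)
  eent <- eent[order(eent[, 1], eent[, 2]), , drop = FALSE]
  vcase <- eent[, 1]; vevent <- eent[, 2]

  # onsets: default a random date in the report year; (drug, event)
  # combinations with a TTO law get onset = therapy start + rounded
  # Weibull draw (floored at 0 days), first law wins
  onset <- as.Date(sprintf("%d-01-01", year[vcase])) +
    sample.int(365, length(vcase), replace = TRUE) - 1L
  law <- config$tto_law
  assigned <- rep(FALSE, length(vcase))
  entkey <- paste(ecase, edrug)
  for (r in seq_len(nrow(law))) {
    j <- match(law$drug[r], dnames)
    k <- match(law$event[r], ecodes)
    if (is.na(j) || is.na(k)) next
    sel <- which(!assigned & vevent == k & expo[cbind(vcase, j)] == 1L)
    if (!length(sel)) next
    st <- tstart[match(paste(vcase[sel], j), entkey)]
    lag <- pmax(0, round_half_up(
      stats::rweibull(length(sel), shape = law$beta[r],
                      scale = law$alpha[r])))
    onset[sel] <- st + lag
    assigned[sel] <- TRUE
  }

  # date missingness: blank the day component independently per date
  miss_start <- stats::runif(nrow(ent)) < config$date_missing_prob
  miss_onset <- stats::runif(length(vcase)) < config$date_missing_prob
  start_str <- blank_day(tstart, miss_start)
  end_str <- blank_day(tend, rep(FALSE, nrow(ent)))
  onset_str <- blank_day(onset, miss_onset)

  # JADER rendering ----------------------------------------------------
  cid <- sprintf("SIM%07d", seq_len(n))
  jnames <- vapply(config$drugs, `[[`, "", "jader_name")
  jrole <- c(primary_suspect = "被疑薬",
             secondary_suspect = "被疑薬",
             suspect_unspecified = "被疑薬",
             concomitant = "併用薬",
             interacting = "相互作用")[roles]
  drug_seq <- stats::ave(seq_along(ecase), ecase, FUN = seq_along)
  jader <- list(
    demo = data.frame(
      "識別番号" = cid,
      "性別" = ifelse(sex == "male", "男性", "女性"),
      "年齢" = paste0(sub("s$", "", age_band), "歳代"),
      "身長" = paste0(hband, "cm台"),
      "体重" = paste0(wband, "kg台"),
      "報告者" = ifelse(reporter == "hcp", "医療従事者",
                              "消費者"),
      "報告年" = as.character(year),
      check.names = FALSE, stringsAsFactors = FALSE),
    drug = data.frame(
      "識別番号" = cid[ecase],
      "医薬品連番" = as.character(drug_seq),
      "医薬品一般名" = jnames[edrug],
      "医薬品の関与" = jrole,
      "投与開始日" = start_str,
      "投与終了日" = end_str,
      check.names = FALSE, stringsAsFactors = FALSE),
    reac = data.frame(
      "識別番号" = cid[vcase],
      "有害事象コード" = ecodes[vevent],
      "有害事象" = enames[vevent],
      "発現日" = onset_str,
      check.names = FALSE, stringsAsFactors = FALSE),
    hist = data.frame(
      "識別番号" = character(0),
      "有害事象コード" = character(0),
      "有害事象" = character(0),
      "発現日" = character(0),
      check.names = FALSE, stringsAsFactors = FALSE)
  )

  # FAERS rendering ----------------------------------------------------
  dup <- stats::runif(n) < config$duplicate_prob
  caseid <- as.character(6000000L + seq_len(n))
  # each case emits versions 1..(1+dup); content identical across versions
  nver <- 1L + dup
  rows <- rep(seq_len(n), nver)
  ver <- sequence(nver)
  primaryid <- paste0(caseid[rows], ver)
  fnames <- vapply(config$drugs, `[[`, "", "faers_name")
  frole <- c(primary_suspect = "PS", secondary_suspect = "SS",
             suspect_unspecified = "SS", concomitant = "C",
             interacting = "I")[roles]
  # earliest onset per case for DEMO event_dt (partial strings sort
  # correctly in compact form)
  ev_first <- tapply(onset_str, vcase, function(s) sort(s)[1])
  event_dt <- rep("", n)
  event_dt[as.integer(names(ev_first))] <- unname(ev_first)
  # map per-case drug/event rows to every emitted version
  dmap <- split(seq_along(ecase), ecase)
  emap <- split(seq_along(vcase), vcase)
  exp_rows <- function(map, case_rows) {
    idx <- map[as.character(case_rows)]
    list(i = unlist(idx, use.names = FALSE),
         rep = rep(seq_along(case_rows), lengths(idx)))
  }
  dx <- exp_rows(dmap, rows)
  ex <- exp_rows(emap, rows)
  age_years <- as.character(as.integer(sub("s$", "", age_band)) + 5L)
  faers <- list(
    demo = data.frame(
      primaryid = primaryid, caseid = caseid[rows],
      caseversion = as.character(ver),
      sex = c(male = "M", female = "F")[sex[rows]],
      age = age_years[rows], age_cod = "YR",
      occp_cod = ifelse(reporter[rows] == "hcp", "MD", "CN"),
      event_dt = event_dt[rows],
      stringsAsFactors = FALSE),
    drug = data.frame(
      primaryid = primaryid[dx$rep], caseid = caseid[rows][dx$rep],
      drug_seq = as.character(drug_seq[dx$i]),
      role_cod = frole[dx$i], drugname = fnames[edrug[dx$i]],
      stringsAsFactors = FALSE),
    reac = data.frame(
      primaryid = primaryid[ex$rep], caseid = caseid[rows][ex$rep],
      pt = enames[vevent[ex$i]],
      stringsAsFactors = FALSE),
    ther = data.frame(
      primaryid = primaryid[dx$rep], caseid = caseid[rows][dx$rep],
      dsg_drug_seq = as.character(drug_seq[dx$i]),
      start_dt = start_str[dx$i], end_dt = end_str[dx$i],
      stringsAsFactors = FALSE)
  )
  structure(list(jader = jader, faers = faers, config = config),
            class = "srs_sim")
}

#' @export
print.srs_sim <- function(x, ...) {
  cat(sprintf(
    "<srs_sim> %d reports | JADER: %d drug rows, %d event rows | FAERS: %d demo rows\n",
    x$config$n_reports, nrow(x$jader$drug), nrow(x$jader$reac),
    nrow(x$faers$demo)))
  invisible(x)
}

#' Write a simulated dataset to disk in both dialects
#'
#' JADER tables go to `dir/jader/<table>.csv` in the legacy CP932
#' encoding; FAERS tables go to `dir/faers/<TABLE>.txt` as "$"-delimited
#' ASCII. Output is byte-identical for identical simulations.
#'
#' @param sim an `srs_sim` object.
#' @param dir output directory (created if needed).
#' @param encoding encoding for the JADER CSV files.
#' @return named list of written file paths, invisibly.
#' @export
write_srs <- function(sim, dir, encoding = "CP932") {
  jd <- file.path(dir, "jader"); fd <- file.path(dir, "faers")
  dir.create(jd, recursive = TRUE, showWarnings = FALSE)
  dir.create(fd, recursive = TRUE, showWarnings = FALSE)
  paths <- list(jader = character(0), faers = character(0))
  for (tab in names(sim$jader)) {
    p <- file.path(jd, paste0(tab, ".csv"))
    df <- sim$jader[[tab]]
    lines <- c(paste(names(df), collapse = ","),
               if (nrow(df)) do.call(paste, c(unname(df), sep = ",")))
    writeLines(iconv(lines, "UTF-8", encoding), p, useBytes = TRUE)
    paths$jader[tab] <- p
  }
  for (tab in names(sim$faers)) {
    p <- file.path(fd, paste0(toupper(tab), ".txt"))
    df <- sim$faers[[tab]]
    lines <- c(paste(names(df), collapse = "$"),
               if (nrow(df)) do.call(paste, c(unname(df), sep = "$")))
    writeLines(lines, p)
    paths$faers[tab] <- p
  }
  invisible(paths)
}
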