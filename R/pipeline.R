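# Pipeline orchestration: ingest -> primary / sensitivity / stratified /
# TTO analyses, with tabular outputs and seeded reproducibility.

#' Read a pipeline run configuration from YAML
#'
#' The YAML file may carry `input` (dialect and table paths), `simulate`
#' (synthetic-data settings), `drugs`, `events` (target PT codes),
#' `analysis` options and a `tto` block; missing entries fall back to the
#' package defaults at the point of use. Used by the command-line wrapper
#' in `inst/cli/`.
#'
#' @param path YAML file path.
#' @return the configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  yaml::read_yaml(path)
}

#' Ingest raw SRS files into case records
#'
#' Reads the tables of the given dialect, de-duplicates FAERS case
#' versions, and merges to case level.
#'
#' @param paths named list of table file paths (see
#'   [read_jader_tables()] / [read_faers_tables()]).
#' @param dialect `"jader"` or `"faers"`.
#' @param lexicon drug lexicon.
#' @param event_source JADER event table, `"reac"` or `"hist"`.
#' @param encoding JADER file encoding.
#' @return an `srs_cases` object.
#' @export
ingest_srs <- function(paths, dialect = c("jader", "faers"),
                       lexicon = default_lexicon(),
                       event_source = c("reac", "hist"),
                       encoding = "CP932") {
  dialect <- match.arg(dialect)
  if (dialect == "jader") {
    tabs <- read_jader_tables(paths, encoding = encoding)
  } else {
    tabs <- read_faers_tables(paths)
    tabs$demo <- dedup_faers(tabs$demo)
  }
  merge_case_level(tabs, dialect, lexicon = lexicon,
                   event_source = match.arg(event_source))
}

# pair-level stratum labels (sex x age) used for stratified GPS expected
# counts; NA where either component is unresolved
gps_pair_strata <- function(cases, pairs) {
  sx <- case_stratum(cases, "sex")
  ag <- case_stratum(cases, "age")
  lab <- ifelse(is.na(sx) | is.na(ag), NA_character_, paste(sx, ag))
  lab[match(pairs$case_id, cases$demo$case_id)]
}

run_rows <- function(pairs, cases, drugs, event_set, unit, continuity,
                     gps, gps_seed, overall_label = "all_fibrates") {
  strata <- if (gps) gps_pair_strata(cases, pairs) else NULL
  one <- function(drug_set, label) {
    fit <- tryCatch(
      disprop(pairs, drug_set, event_set, unit = unit,
              continuity = continuity, gps = gps, gps_strata = strata,
              gps_seed = gps_seed),
      error = function(e) NULL)
    if (is.null(fit)) {
      row <- disprop_row(disprop(contingency(0, 1, 1, 1)),
                         drug_label = label)
      row[, !(names(row) %in% c("drug"))] <- NA
      row$n_pairs <- sum(pairs$drug %in% drug_set &
                           pairs$pt_code %in% event_set)
      row$n11 <- row$n_pairs
      row$n_icsr <- count_unique_icsrs(pairs, drug_set, event_set)
      row[c("ror_signal", "prr_signal", "ic_signal",
            "ebgm_signal")] <- FALSE
      return(row)
    }
    disprop_row(fit, drug_label = label)
  }
  rows <- lapply(drugs, function(d) one(d, d))
  rows <- c(rows, list(one(drugs, overall_label)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Primary disproportionality analysis table
#'
#' One row per target drug plus an overall row combining all target
#' drugs. Per-drug `n_pairs` counts drug-event pairs (not mutually
#' exclusive across drugs when one report lists several target drugs);
#' `n_icsr` counts unique case reports, which is the headline N for the
#' overall row. EBGM defaults to on for JADER (with sex x age stratified
#' expected counts) and off for FAERS; forcing it on for FAERS computes
#' an unstratified EBGM with a warning.
#'
#' @param cases an `srs_cases` object.
#' @param drugs character vector of target drug identifiers.
#' @param event_set character vector of target PT codes.
#' @param unit counting unit of the 2x2 table.
#' @param continuity Haldane-Anscombe correction for zero cells.
#' @param gps compute EBGM (`NULL` = only for the JADER dialect).
#' @param gps_seed seed for GPS optimization restarts.
#' @return data.frame, one row per drug plus the overall row, with
#'   counts, all estimates/intervals and signal flags.
#' @export
run_primary <- function(cases, drugs = names(default_lexicon()),
                        event_set = default_event_pts()$pt_code,
                        unit = "pair", continuity = FALSE, gps = NULL,
                        gps_seed = 1L) {
  if (is.null(gps)) gps <- identical(cases$dialect, "jader")
  if (gps && !identical(cases$dialect, "jader")) {
    warning("computing unstratified EBGM for a non-JADER dialect")
  }
  pairs <- expand_pairs(cases)
  run_rows(pairs, cases, drugs, event_set, unit, continuity, gps,
           gps_seed)
}

#' Sensitivity analysis restricted to primary suspect drugs
#'
#' Repeats the primary analysis on the pair universe restricted to
#' primary-suspect roles (JADER's undifferentiated suspect role counts as
#' primary suspect). A drug with no primary-suspect pairs yields a row of
#' `NA` estimates (`n_pairs = 0`): signal estimation is not applicable.
#'
#' @inheritParams run_primary
#' @param include_unspecified_suspect see [filter_primary_suspect()].
#' @return data.frame as in [run_primary()].
#' @export
run_sensitivity <- function(cases, drugs = names(default_lexicon()),
                            event_set = default_event_pts()$pt_code,
                            unit = "pair", continuity = FALSE,
                            gps = NULL, gps_seed = 1L,
                            include_unspecified_suspect = TRUE) {
  if (is.null(gps)) gps <- identical(cases$dialect, "jader")
  pairs <- filter_primary_suspect(expand_pairs(cases),
                                  include_unspecified_suspect)
  run_rows(pairs, cases, drugs, event_set, unit, continuity, gps,
           gps_seed)
}

#' Stratified disproportionality tables
#'
#' Runs [stratified_analysis()] for each requested variable and each
#' target drug, flattening the per-stratum fits into one table.
#'
#' @inheritParams run_primary
#' @param variables stratification variables to run.
#' @return data.frame with columns `variable`, `stratum` plus the
#'   [run_primary()] columns (one row per drug x stratum).
#' @export
run_stratified <- function(cases, drugs = names(default_lexicon()),
                           event_set = default_event_pts()$pt_code,
                           variables = c("sex", "age", "bmi"),
                           unit = "pair", continuity = FALSE) {
  out <- list()
  for (v in variables) {
    for (d in drugs) {
      fits <- suppressWarnings(
        stratified_analysis(cases, d, event_set, variable = v,
                            unit = unit, continuity = continuity))
      for (lv in names(fits)) {
        row <- if (is.null(fits[[lv]])) {
          r <- disprop_row(disprop(contingency(0, 1, 1, 1)),
                           drug_label = d)
          r[, !(names(r) %in% "drug")] <- NA
          r
        } else {
          disprop_row(fits[[lv]], drug_label = d)
        }
        out[[length(out) + 1L]] <- cbind(
          data.frame(variable = v, stratum = lv,
                     stringsAsFactors = FALSE), row)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Time-to-onset analysis bundle
#'
#' Collects complete-date time-to-onset records for one drug and fits the
#' Weibull model overall and per event group.
#'
#' @param cases an `srs_cases` object.
#' @param drug canonical drug identifier (default pemafibrate).
#' @param pt_groups named list of PT-code groups to fit separately; the
#'   `Overall` group (union of all codes) is always added.
#' @param B,seed bootstrap settings, see [bootstrap_weibull()].
#' @param multiple per-case multiplicity handling, see [collect_tto()].
#' @return list with `records` (the TTO records and exclusion counts as
#'   attribute) and `fits` (named list of `tto_weibull`, `NULL` for
#'   groups with fewer than 5 records).
#' @export
run_tto <- function(cases, drug = "pemafibrate",
                    pt_groups = list(
                      Cholelithiasis = "10008629",
                      Cholecystitis = c("10008612", "10008614")),
                    B = 2000, seed = 1L, multiple = "all") {
  all_pts <- unique(unlist(pt_groups))
  records <- collect_tto(cases, drug, all_pts, multiple = multiple)
  groups <- c(pt_groups, list(Overall = all_pts))
  fits <- lapply(groups, function(pts) {
    d <- records$days[records$pt_code %in% pts]
    if (length(d) < 5 || stats::var(d) == 0) return(NULL)
    tto_weibull(d, B = B, seed = seed)
  })
  excl <- attr(records, "exclusions")
  message(sprintf(
    "TTO exclusions: %d incomplete start, %d incomplete onset, %d negative interval",
    excl["incomplete_start"], excl["incomplete_onset"],
    excl["negative_interval"]))
  list(records = records, fits = fits)
}

tto_fit_json <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(n = fit$n, alpha = fit$alpha, beta = fit$beta,
       alpha_ci = fit$alpha_ci, beta_ci = fit$beta_ci,
       median = unname(fit$descriptives["median"]),
       median_ci = fit$median_ci, q1 = unname(fit$descriptives["q1"]),
       q3 = unname(fit$descriptives["q3"]),
       min = unname(fit$descriptives["min"]),
       max = unname(fit$descriptives["max"]),
       classification = fit$classification, loglik = fit$loglik,
       B = fit$B, seed = fit$seed)
}

round_df <- function(df, digits = 2) {
  num <- vapply(df, is.numeric, TRUE) &
    !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full analysis pipeline and write its outputs
#'
#' Orchestrates the selected analyses on one ingested dataset and writes,
#' under `out_dir`: `primary.csv` / `sensitivity.csv` /
#' `stratified.csv` (2-decimal human tables) with full-precision JSON
#' mirrors, `tto.json` + `tto_records.csv` + `tto_plotdata.csv`, and a
#' `run_info.json` carrying the seed and an MD5 hash of the effective
#' configuration. Outputs are deterministic given the inputs and seed.
#'
#' @param cases an `srs_cases` object.
#' @param out_dir output directory (created if needed).
#' @param analyses subset of `"primary"`, `"sensitivity"`,
#'   `"stratified"`, `"tto"`.
#' @param drugs,event_set,unit,continuity see [run_primary()].
#' @param tto_drug,pt_groups,B see [run_tto()].
#' @param seed integer seed used for every stochastic step (GPS restarts,
#'   bootstrap).
#' @return (invisibly) a named list with the computed tables/fits.
#' @export
run_all <- function(cases, out_dir,
                    analyses = c("primary", "sensitivity", "stratified",
                                 "tto"),
                    drugs = names(default_lexicon()),
                    event_set = default_event_pts()$pt_code,
                    unit = "pair", continuity = FALSE,
                    tto_drug = "pemafibrate",
                    pt_groups = list(
                      Cholelithiasis = "10008629",
                      Cholecystitis = c("10008612", "10008614")),
                    B = 2000, seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(analyses = analyses, drugs = drugs, event_set = event_set,
              unit = unit, continuity = continuity, tto_drug = tto_drug,
              pt_groups = pt_groups, B = B, seed = seed,
              dialect = cases$dialect)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  info <- list(config_hash = cfg_hash, seed = seed,
               n_cases = nrow(cases$demo))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list()
  emit <- function(df, name) {
    utils::write.csv(round_df(df), file.path(out_dir,
                                             paste0(name, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(df, file.path(out_dir, paste0(name, ".json")),
                         digits = NA, na = "null")
  }
  if ("primary" %in% analyses) {
    out$primary <- run_primary(cases, drugs, event_set, unit, continuity,
                               gps_seed = seed)
    emit(out$primary, "primary")
  }
  if ("sensitivity" %in% analyses) {
    out$sensitivity <- run_sensitivity(cases, drugs, event_set, unit,
                                       continuity, gps_seed = seed)
    emit(out$sensitivity, "sensitivity")
  }
  if ("stratified" %in% analyses) {
    out$stratified <- run_stratified(cases, drugs, event_set,
                                     unit = unit,
                                     continuity = continuity)
    emit(out$stratified, "stratified")
  }
  if ("tto" %in% analyses) {
    out$tto <- run_tto(cases, tto_drug, pt_groups, B = B, seed = seed)
    utils::write.csv(out$tto$records,
                     file.path(out_dir, "tto_records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      Filter(Negate(is.null), lapply(out$tto$fits, tto_fit_json)),
      file.path(out_dir, "tto.json"), auto_unbox = TRUE, digits = NA)
    ov <- out$tto$fits$Overall
    if (!is.null(ov)) {
      pd <- weibull_plot_data(ov)
      pd_flat <- rbind(
        data.frame(series = "histogram", x = pd$histogram$mid,
                   y = pd$histogram$count),
        data.frame(series = "density", x = pd$density$t,
                   y = pd$density$density),
        data.frame(series = "hazard", x = pd$hazard$t,
                   y = pd$hazard$hazard))
      utils::write.csv(pd_flat, file.path(out_dir, "tto_plotdata.csv"),
                       row.names = FALSE)
    }
  }
  invisible(out)
}
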