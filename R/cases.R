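# Case-level data model: standardize raw dialect tables into one
# demographics table plus per-case drug and event tables, then expand
# drug-event pairs for disproportionality counting.

jader_columns <- function() {
  list(
    case_id = "識別番号",
    sex = "性別",
    age = "年齢",
    height = "身長",
    weight = "体重",
    reporter = "報告者",
    report_year = "報告年",
    drug_seq = "医薬品連番",
    drug_name = "医薬品一般名",
    drug_role = "医薬品の関与",
    therapy_start = "投与開始日",
    therapy_end = "投与終了日",
    pt_code = "有害事象コード",
    pt_name = "有害事象",
    onset = "発現日"
  )
}

jader_role_map <- function() {
  c("被疑薬" = "suspect_unspecified",
    "併用薬" = "concomitant",
    "相互作用" = "interacting")
}

faers_role_map <- function() {
  c(PS = "primary_suspect", SS = "secondary_suspect",
    C = "concomitant", I = "interacting")
}

drug_roles <- function() {
  c("primary_suspect", "secondary_suspect", "suspect_unspecified",
    "concomitant", "interacting")
}

col_or_na <- function(df, col) {
  if (col %in% names(df)) as.character(df[[col]]) else
    rep(NA_character_, nrow(df))
}

# "60歳代" -> "60s"; "10歳未満" -> "0s"; "100歳以上" -> "100s"
jader_age_band <- function(x) {
  out <- rep(NA_character_, length(x))
  has <- grepl("^[0-9]+歳代$", x)
  out[has] <- paste0(sub("歳代$", "", x[has]), "s")
  out[grepl("歳未満$", x)] <- "0s"
  out[grepl("^100.*歳以上$", x)] <- "100s"
  out
}

# 10-unit anthropometry bands, "160cm台" -> [160, 170)
jader_band_bounds <- function(x) {
  low <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  low[!grepl("^[0-9]+(cm|kg)台$", x)] <- NA_integer_
  data.frame(low = low, high = low + 10L)
}

map_or <- function(x, map, default) {
  out <- unname(map[as.character(x)])
  out[is.na(out)] <- default
  out
}

empty_drugs <- function() {
  data.frame(case_id = character(0), drug_seq = character(0),
              raw_name = character(0), canonical = character(0),
              role = character(0), therapy_start = character(0),
              therapy_end = character(0), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(case_id = character(0), pt_code = character(0),
              pt_name = character(0), onset = character(0),
              stringsAsFactors = FALSE)
}

#' Merge raw SRS tables into case-level records
#'
#' Left-merges the drug and event tables onto the demographics table by the
#' case key: every DEMO row yields exactly one case, with zero or more drug
#' and event entries attached. Orphan drug/event rows (no DEMO parent) are
#' dropped with a message giving the count. Drug names are matched against
#' the lexicon; therapy dates and event onsets are kept as partial-date
#' strings.
#'
#' For the FAERS dialect, run [dedup_faers()] on the DEMO table first;
#' rows belonging to superseded case versions then drop out here as
#' orphans. FAERS event onsets come from the DEMO `event_dt` field (one
#' onset per case, attached to each of its events); therapy starts come
#' from the THER table, keyed by report id and drug sequence.
#'
#' @param tables named list of character data.frames from
#'   [read_jader_tables()] or [read_faers_tables()].
#' @param dialect `"jader"` or `"faers"`.
#' @param lexicon drug lexicon, see [default_lexicon()].
#' @param event_source for JADER, which table supplies events: `"reac"`
#'   (default) or `"hist"`.
#' @param columns for JADER, the column-name map; override entries of
#'   `srsignal:::jader_columns()` if your extract uses different headers.
#' @return an object of class `srs_cases`: a list with standardized
#'   data.frames `demo` (one row per case: `case_id`, `sex`, `age_band`,
#'   `height_low/high`, `weight_low/high`, `reporter`, `report_year`),
#'   `drugs` (`case_id`, `drug_seq`, `raw_name`, `canonical`, `role`,
#'   `therapy_start`, `therapy_end`) and `events` (`case_id`, `pt_code`,
#'   `pt_name`, `onset`), plus the `dialect`.
#' @export
merge_case_level <- function(tables, dialect = c("jader", "faers"),
                             lexicon = default_lexicon(),
                             event_source = c("reac", "hist"),
                             columns = jader_columns()) {
  dialect <- match.arg(dialect)
  event_source <- match.arg(event_source)
  names(tables) <- tolower(names(tables))
  if (is.null(tables$demo)) stop("'demo' table is required", call. = FALSE)

  if (dialect == "jader") {
    cm <- columns
    d <- tables$demo
    hb <- jader_band_bounds(col_or_na(d, cm$height))
    wb <- jader_band_bounds(col_or_na(d, cm$weight))
    demo <- data.frame(
      case_id = as.character(d[[cm$case_id]]),
      sex = map_or(col_or_na(d, cm$sex),
                   c("男性" = "male", "女性" = "female"),
                   "unknown"),
      age_band = jader_age_band(col_or_na(d, cm$age)),
      height_low = hb$low, height_high = hb$high,
      weight_low = wb$low, weight_high = wb$high,
      reporter = map_or(col_or_na(d, cm$reporter),
                        c("医療従事者" = "healthcare_professional",
                          "消費者" = "consumer"),
                        "unknown"),
      report_year = suppressWarnings(as.integer(col_or_na(d, cm$report_year))),
      stringsAsFactors = FALSE
    )
    key <- demo$case_id

    dr <- tables$drug
    if (is.null(dr) || nrow(dr) == 0) {
      drugs <- empty_drugs()
    } else {
      drugs <- data.frame(
        case_id = as.character(dr[[cm$case_id]]),
        drug_seq = col_or_na(dr, cm$drug_seq),
        raw_name = col_or_na(dr, cm$drug_name),
        stringsAsFactors = FALSE
      )
      drugs$canonical <- match_drug(drugs$raw_name, lexicon)
      drugs$role <- map_or(col_or_na(dr, cm$drug_role), jader_role_map(),
                           "suspect_unspecified")
      drugs$therapy_start <- col_or_na(dr, cm$therapy_start)
      drugs$therapy_end <- col_or_na(dr, cm$therapy_end)
    }

    ev <- tables[[event_source]]
    if (is.null(ev) || nrow(ev) == 0) {
      events <- empty_events()
    } else {
      events <- data.frame(
        case_id = as.character(ev[[cm$case_id]]),
        pt_code = col_or_na(ev, cm$pt_code),
        pt_name = col_or_na(ev, cm$pt_name),
        onset = col_or_na(ev, cm$onset),
        stringsAsFactors = FALSE
      )
      # pt_code may be absent in some extracts; fall back to the PT name
      miss <- is.na(events$pt_code) | !nzchar(events$pt_code)
      events$pt_code[miss] <- events$pt_name[miss]
    }
  } else {
    d <- tables$demo
    demo <- data.frame(
      case_id = as.character(d$caseid),
      sex = map_or(col_or_na(d, "sex"), c(M = "male", F = "female"),
                   "unknown"),
      age_band = faers_age_band(col_or_na(d, "age"), col_or_na(d, "age_cod")),
      height_low = NA_integer_, height_high = NA_integer_,
      weight_low = NA_integer_, weight_high = NA_integer_,
      reporter = map_or(col_or_na(d, "occp_cod"),
                        c(MD = "healthcare_professional",
                          PH = "healthcare_professional",
                          HP = "healthcare_professional",
                          OT = "healthcare_professional",
                          CN = "consumer", LW = "consumer"),
                        "unknown"),
      report_year = suppressWarnings(as.integer(substr(
        col_or_na(d, "event_dt"), 1, 4))),
      stringsAsFactors = FALSE
    )
    pid <- as.character(d$primaryid)
    key <- pid
    case_of_pid <- stats::setNames(demo$case_id, pid)
    onset_of_pid <- stats::setNames(col_or_na(d, "event_dt"), pid)

    dr <- tables$drug
    if (is.null(dr) || nrow(dr) == 0) {
      drugs <- empty_drugs()
      drugs$primaryid <- character(0)
    } else {
      drugs <- data.frame(
        case_id = unname(case_of_pid[as.character(dr$primaryid)]),
        primaryid = as.character(dr$primaryid),
        drug_seq = col_or_na(dr, "drug_seq"),
        raw_name = col_or_na(dr, "drugname"),
        stringsAsFactors = FALSE
      )
      drugs$canonical <- match_drug(drugs$raw_name, lexicon)
      drugs$role <- map_or(col_or_na(dr, "role_cod"), faers_role_map(),
                           "suspect_unspecified")
      th <- tables$ther
      if (!is.null(th) && nrow(th) > 0) {
        thkey <- paste(as.character(th$primaryid),
                       col_or_na(th, "dsg_drug_seq"), sep = "\r")
        start_map <- stats::setNames(col_or_na(th, "start_dt"), thkey)
        end_map <- stats::setNames(col_or_na(th, "end_dt"), thkey)
        dkey <- paste(drugs$primaryid, drugs$drug_seq, sep = "\r")
        drugs$therapy_start <- unname(start_map[dkey])
        drugs$therapy_end <- unname(end_map[dkey])
      } else {
        drugs$therapy_start <- NA_character_
        drugs$therapy_end <- NA_character_
      }
    }

    re <- tables$reac
    if (is.null(re) || nrow(re) == 0) {
      events <- empty_events()
      events$primaryid <- character(0)
    } else {
      repid <- as.character(re$primaryid)
      events <- data.frame(
        case_id = unname(case_of_pid[repid]),
        primaryid = repid,
        pt_code = col_or_na(re, "pt"),
        pt_name = col_or_na(re, "pt"),
        onset = unname(onset_of_pid[repid]),
        stringsAsFactors = FALSE
      )
    }
    # orphan detection keys on primaryid for FAERS
    drugs <- drop_orphans(drugs, drugs$primaryid, key, "drug")
    events <- drop_orphans(events, events$primaryid, key, "event")
    drugs$primaryid <- NULL
    events$primaryid <- NULL
  }

  if (dialect == "jader") {
    drugs <- drop_orphans(drugs, drugs$case_id, key, "drug")
    events <- drop_orphans(events, events$case_id, key, "event")
  }
  rownames(demo) <- rownames(drugs) <- rownames(events) <- NULL
  structure(list(demo = demo, drugs = drugs, events = events,
                 dialect = dialect),
            class = "srs_cases")
}

drop_orphans <- function(df, df_key, parent_keys, what) {
  if (nrow(df) == 0) return(df)
  orphan <- !(df_key %in% parent_keys) | is.na(df_key)
  if (any(orphan)) {
    message(sum(orphan), " orphan ", what,
            " row(s) without a DEMO parent dropped")
    df <- df[!orphan, , drop = FALSE]
  }
  df
}

faers_age_band <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  a[!is.na(age_cod) & !(toupper(age_cod) %in% c("YR", ""))] <- NA
  band <- ifelse(is.na(a) | a < 0, NA_character_,
                 paste0(pmin(floor(a / 10) * 10, 100), "s"))
  band
}

#' @export
print.srs_cases <- function(x, ...) {
  cat(sprintf("<srs_cases> %s dialect: %d cases, %d drug rows, %d event rows\n",
              x$dialect, nrow(x$demo), nrow(x$drugs), nrow(x$events)))
  invisible(x)
}

#' Expand case records into drug-event pairs
#'
#' The counting unit of disproportionality analysis is the drug-event pair:
#' one pair per (case, drug occurrence, event occurrence) combination, so a
#' case with two drugs and three events contributes six pairs. Drug
#' identity is the canonical lexicon identifier where the name matched, and
#' the normalized raw name otherwise; the drug role is retained for
#' sensitivity filtering.
#'
#' @param cases an `srs_cases` object from [merge_case_level()].
#' @return data.frame with columns `case_id`, `drug`, `canonical` (NA if
#'   unmatched), `role`, `drug_seq`, `pt_code`, `event_seq`.
#' @export
expand_pairs <- function(cases) {
  stopifnot(inherits(cases, "srs_cases"))
  drugs <- cases$drugs
  events <- cases$events
  d <- data.frame(case_id = drugs$case_id,
                  drug = ifelse(is.na(drugs$canonical),
                                normalize_drug_name(drugs$raw_name),
                                drugs$canonical),
                  canonical = drugs$canonical,
                  role = drugs$role,
                  drug_seq = drugs$drug_seq,
                  stringsAsFactors = FALSE)
  e <- data.frame(case_id = events$case_id,
                  pt_code = events$pt_code,
                  event_seq = stats::ave(seq_len(nrow(events)),
                                         events$case_id, FUN = seq_along),
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0 || nrow(e) == 0) {
    out <- data.frame(case_id = character(0), drug = character(0),
                      canonical = character(0), role = character(0),
                      drug_seq = character(0), pt_code = character(0),
                      event_seq = integer(0), stringsAsFactors = FALSE)
    return(out)
  }
  out <- merge(d, e, by = "case_id", all = FALSE, sort = FALSE)
  rownames(out) <- NULL
  out
}

#' Restrict pairs to primary suspect drugs
#'
#' Sensitivity analyses restrict the pair universe to drugs reported as
#' primary suspect. FAERS distinguishes primary (PS) from secondary (SS)
#' suspects; JADER has a single suspect role, which is treated as primary
#' suspect here (`include_unspecified_suspect = TRUE`) since it is the
#' closest semantic match.
#'
#' @param pairs data.frame from [expand_pairs()].
#' @param include_unspecified_suspect also keep the undifferentiated
#'   suspect role used by JADER.
#' @return the qualifying rows of `pairs`.
#' @export
filter_primary_suspect <- function(pairs, include_unspecified_suspect = TRUE) {
  keep <- c("primary_suspect",
            if (include_unspecified_suspect) "suspect_unspecified")
  pairs[pairs$role %in% keep, , drop = FALSE]
}

#' Count unique case reports for a drug set and event set
#'
#' Agent-level pair counts are not mutually exclusive (one report can list
#' several target drugs); the overall total is therefore reported as the
#' number of unique case reports having at least one qualifying pair.
#'
#' @param pairs data.frame from [expand_pairs()].
#' @param drug_set,event_set character vectors of drug identifiers / PT
#'   codes.
#' @return integer count of distinct `case_id`s.
#' @export
count_unique_icsrs <- function(pairs, drug_set, event_set) {
  hit <- pairs$drug %in% drug_set & pairs$pt_code %in% event_set
  length(unique(pairs$case_id[hit]))
}
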