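# Stratified disproportionality: sex, age group, and BMI strata derived
# from the banded demographics SRS databases record.

#' Body mass index from banded height and weight
#'
#' JADER records height and weight in 10-cm and 10-kg bands; BMI is
#' computed from the band midpoints: `mid([low, high)) = (low + high) / 2`
#' and `BMI = weight_mid / (height_mid / 100)^2`. Reports missing either
#' band get `NA` (they are excluded from BMI strata, not imputed).
#'
#' @param height_low,height_high band bounds in cm (half-open
#'   `[low, high)`).
#' @param weight_low,weight_high band bounds in kg.
#' @return numeric BMI vector.
#' @examples
#' bmi_from_bands(160, 170, 60, 70)   # 65 / 1.65^2 = 23.9
#' @export
bmi_from_bands <- function(height_low, height_high, weight_low,
                           weight_high) {
  hmid <- (height_low + height_high) / 2
  wmid <- (weight_low + weight_high) / 2
  wmid / (hmid / 100)^2
}

# decade integer from an age band label "60s" -> 60, NA otherwise
band_decade <- function(band) {
  suppressWarnings(as.integer(sub("^([0-9]+)s$", "\\1", band)))
}

#' Stratum label per case
#'
#' Resolves one of the three stratification variables to a per-case label:
#' \itemize{
#'   \item `sex`: `"male"` / `"female"`; unknown sex is `NA`.
#'   \item `age`: `"ge60"` for bands 60s and above, `"20to50"` for bands
#'     20s-50s; other bands (children, unknown) are `NA`. Bands are
#'     resolved on their literal decade label.
#'   \item `bmi`: `"ge25"` / `"lt25"` from [bmi_from_bands()]; `NA` when
#'     either band is missing.
#' }
#'
#' @param cases an `srs_cases` object.
#' @param variable `"sex"`, `"age"` or `"bmi"`.
#' @return character vector of labels, one per row of `cases$demo`, `NA`
#'   where the stratum is unresolvable (such cases are excluded from the
#'   stratified analysis).
#' @export
case_stratum <- function(cases, variable = c("sex", "age", "bmi")) {
  variable <- match.arg(variable)
  demo <- cases$demo
  if (variable == "sex") {
    out <- ifelse(demo$sex %in% c("male", "female"), demo$sex,
                  NA_character_)
  } else if (variable == "age") {
    dec <- band_decade(demo$age_band)
    out <- ifelse(is.na(dec), NA_character_,
                  ifelse(dec >= 60, "ge60",
                         ifelse(dec >= 20 & dec <= 50, "20to50",
                                NA_character_)))
  } else {
    bmi <- bmi_from_bands(demo$height_low, demo$height_high,
                          demo$weight_low, demo$weight_high)
    out <- ifelse(is.na(bmi), NA_character_,
                  ifelse(bmi >= 25, "ge25", "lt25"))
  }
  out
}

#' Subset case records to a set of case ids
#'
#' @param cases an `srs_cases` object.
#' @param case_ids character vector of case ids to keep.
#' @return an `srs_cases` object restricted to those cases.
#' @export
subset_cases <- function(cases, case_ids) {
  structure(list(
    demo = cases$demo[cases$demo$case_id %in% case_ids, , drop = FALSE],
    drugs = cases$drugs[cases$drugs$case_id %in% case_ids, , drop = FALSE],
    events = cases$events[cases$events$case_id %in% case_ids, ,
                          drop = FALSE],
    dialect = cases$dialect), class = "srs_cases")
}

#' Stratified disproportionality analysis
#'
#' Re-derives the drug-event pair universe within each level of a
#' stratification variable and recomputes all metrics and signal flags per
#' stratum. Cases whose stratum is unresolvable (unknown sex, unresolvable
#' age band, missing height/weight band) are excluded from every stratum.
#' A stratum in which the target cell is empty yields undefined metric
#' markers and all-false flags rather than an error.
#'
#' @param cases an `srs_cases` object.
#' @param drug_set,event_set target drug identifiers / PT codes.
#' @param variable stratification variable, see [case_stratum()].
#' @param ... further arguments passed to [disprop()] (e.g. `unit`,
#'   `gps`).
#' @return named list of `disprop` fits, one per stratum level, with class
#'   `stratified_disprop`.
#' @export
stratified_analysis <- function(cases, drug_set, event_set,
                                variable = c("sex", "age", "bmi"), ...) {
  variable <- match.arg(variable)
  lab <- case_stratum(cases, variable)
  levels_present <- switch(variable,
                           sex = c("male", "female"),
                           age = c("ge60", "20to50"),
                           bmi = c("ge25", "lt25"))
  out <- list()
  for (lv in levels_present) {
    ids <- cases$demo$case_id[!is.na(lab) & lab == lv]
    sub <- subset_cases(cases, ids)
    pairs <- expand_pairs(sub)
    fit <- tryCatch(
      disprop(pairs, drug_set, event_set, ...),
      error = function(e) {
        warning(sprintf("stratum %s=%s: %s", variable, lv,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    out[[lv]] <- fit
  }
  structure(out, variable = variable, class = "stratified_disprop")
}

#' @export
print.stratified_disprop <- function(x, ...) {
  cat(sprintf("Stratified disproportionality by %s\n",
              attr(x, "variable")))
  for (lv in names(x)) {
    cat(sprintf("-- stratum: %s --\n", lv))
    if (is.null(x[[lv]])) cat("  (no analysable data)\n") else
      print(x[[lv]], ...)
  }
  invisible(x)
}
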