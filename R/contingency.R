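#' 2x2 contingency tables for disproportionality analysis
#'
#' `contingency()` constructs the 2x2 table of a disproportionality
#' analysis from its four cells: `n11` target-drug/target-event pairs,
#' `n12` target-drug/other-event, `n21` other-drug/target-event, `n22`
#' neither. Marginals are derived, never stored.
#'
#' @param n11,n12,n21,n22 nonnegative integer cell counts.
#' @return an object of class `contingency2x2`.
#' @export
contingency <- function(n11, n12, n21, n22) {
  cells <- c(n11 = n11, n12 = n12, n21 = n21, n22 = n22)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(cells) < 1) stop("table total must be >= 1", call. = FALSE)
  structure(as.list(cells), class = "contingency2x2")
}

#' @export
print.contingency2x2 <- function(x, ...) {
  m <- ct_matrix(x)
  dimnames(m) <- list(c("drug", "other drugs"),
                      c("event", "other events"))
  cat("2x2 contingency table (drug-event pairs):\n")
  print(stats::addmargins(as.table(m)))
  invisible(x)
}

ct_matrix <- function(tab) {
  matrix(c(tab$n11, tab$n12, tab$n21, tab$n22), nrow = 2, byrow = TRUE)
}

ct_margins <- function(tab) {
  list(n1p = tab$n11 + tab$n12, n2p = tab$n21 + tab$n22,
       np1 = tab$n11 + tab$n21, np2 = tab$n12 + tab$n22,
       npp = tab$n11 + tab$n12 + tab$n21 + tab$n22)
}

#' Build a contingency table from drug-event pairs
#'
#' Classifies every pair by whether its drug is in `drug_set` and its event
#' in `event_set`. With `unit = "pair"` (the counting convention of the
#' standard 2x2 table) cells count pairs and sum to the number of pairs.
#' With `unit = "icsr"` cells count unique case reports, classified by
#' whether the case has any target-drug pair and any target-event pair;
#' this is the report-level table for which a multiplicative odds
#' association in the generative model is recovered exactly.
#'
#' @param pairs data.frame from [expand_pairs()].
#' @param drug_set,event_set character vectors of drug identifiers and PT
#'   codes defining the target cell.
#' @param unit counting unit, `"pair"` or `"icsr"`.
#' @return a `contingency2x2` object.
#' @export
build_contingency <- function(pairs, drug_set, event_set,
                              unit = c("pair", "icsr")) {
  unit <- match.arg(unit)
  if (nrow(pairs) == 0) stop("empty pair universe", call. = FALSE)
  if (unit == "pair") {
    d <- pairs$drug %in% drug_set
    e <- pairs$pt_code %in% event_set
    contingency(sum(d & e), sum(d & !e), sum(!d & e), sum(!d & !e))
  } else {
    d <- tapply(pairs$drug %in% drug_set, pairs$case_id, any)
    e <- tapply(pairs$pt_code %in% event_set, pairs$case_id, any)
    contingency(sum(d & e), sum(d & !e), sum(!d & e), sum(!d & !e))
  }
}
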