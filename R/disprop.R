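#' Disproportionality analysis of a drug set against an event set
#'
#' The central fitting function of the package: builds the 2x2 table for
#' the chosen drug and event sets, computes the reporting odds ratio,
#' proportional reporting ratio, information component and (optionally)
#' the Gamma-Poisson Shrinker EBGM, and applies the standard signal rules.
#'
#' `x` is either a pair universe (data.frame from [expand_pairs()], with
#' `drug_set`/`event_set` given) or a ready-made `contingency2x2`. EBGM
#' needs the whole cell universe to fit its prior, so it is only computed
#' when `x` is a pair universe and `gps = TRUE`: the prior is fitted on
#' the full drug x event grid (optionally with stratified expected
#' counts), and the posterior is evaluated at the aggregated target cell
#' using its stratified expected count.
#'
#' @param x pair data.frame or `contingency2x2`.
#' @param drug_set,event_set target drug identifiers / PT codes (pair
#'   input only).
#' @param unit counting unit for the 2x2 table, see [build_contingency()].
#' @param level confidence/credibility level for ROR, PRR and IC (EBGM
#'   uses `ebgm_level`).
#' @param ebgm_level interval level for EBGM (default 0.90).
#' @param continuity Haldane-Anscombe correction for zero cells in
#'   ROR/PRR.
#' @param gps compute EBGM (pair input only).
#' @param gps_strata optional per-pair stratum labels for stratified
#'   expected counts (rows with `NA` are excluded from the GPS universe).
#' @param gps_seed seed for the GPS restart jitter.
#' @param ... passed on to [ror()], [prr()] and [bcpnn_ic()] are not
#'   accepted; reserved.
#' @return an object of class `disprop`: the table, a named list
#'   `metrics` (`ror`, `prr`, `ic`, and `ebgm` when computed), the
#'   `signal_flags`, counts (`n11`, `n_pairs`, `n_icsr` when available)
#'   and, when fitted, the `gps_fit`.
#' @examples
#' tab <- contingency(20, 980, 100, 8900)
#' fit <- disprop(tab)
#' fit
#' coef(fit)
#' @export
disprop <- function(x, drug_set = NULL, event_set = NULL,
                    unit = c("pair", "icsr"), level = 0.95,
                    ebgm_level = 0.90, continuity = FALSE, gps = FALSE,
                    gps_strata = NULL, gps_seed = 1L, ...) {
  unit <- match.arg(unit)
  n_icsr <- NA_integer_
  n_pairs <- NA_integer_
  gfit <- NULL
  if (inherits(x, "contingency2x2")) {
    tab <- x
    if (isTRUE(gps)) {
      stop("EBGM needs the pair universe; pass pairs, not a 2x2 table",
           call. = FALSE)
    }
  } else {
    stopifnot(is.data.frame(x), !is.null(drug_set), !is.null(event_set))
    tab <- build_contingency(x, drug_set, event_set, unit = unit)
    n_pairs <- sum(x$drug %in% drug_set & x$pt_code %in% event_set)
    n_icsr <- count_unique_icsrs(x, drug_set, event_set)
  }

  metrics <- list(
    ror = ror(tab, level = level, continuity = continuity),
    prr = prr(tab, level = level, continuity = continuity),
    ic = bcpnn_ic(tab, level = level)
  )
  if (isTRUE(gps)) {
    universe <- gps_expected_counts(x, strata = gps_strata)
    gfit <- gps_fit(universe$n, universe$E, seed = gps_seed)
    # aggregated target cell: pooled pair-level observed and expected
    # counts (EBGM is defined on the pair universe whatever `unit` the
    # 2x2 table uses)
    in_cell <- universe$drug %in% drug_set & universe$event %in% event_set
    cell_n <- sum(universe$n[in_cell])
    cell_E <- sum(universe$E[in_cell])
    if (cell_E > 0) {
      metrics$ebgm <- gps_posterior(cell_n, cell_E, gfit,
                                    level = ebgm_level)
    } else {
      metrics$ebgm <- undefined_metric("EBGM", ebgm_level,
                                       "zero expected count")
    }
  }
  flags <- apply_signal_rules(metrics, tab$n11)
  structure(list(table = tab, metrics = metrics, flags = flags,
                 n11 = tab$n11, n_pairs = n_pairs, n_icsr = n_icsr,
                 unit = unit, level = level, ebgm_level = ebgm_level,
                 drug_set = drug_set, event_set = event_set,
                 gps_fit = gfit),
            class = "disprop")
}

#' @export
print.disprop <- function(x, digits = 2, ...) {
  cat("Disproportionality analysis")
  if (!is.null(x$drug_set)) {
    cat(sprintf(" [%s vs %d target PT(s)]",
                paste(x$drug_set, collapse = "+"), length(x$event_set)))
  }
  cat(sprintf("  (unit: %s)\n", x$unit))
  cat(sprintf("n11 = %d", x$n11))
  if (!is.na(x$n_icsr)) cat(sprintf(" | unique ICSRs = %d", x$n_icsr))
  cat("\n")
  for (m in x$metrics) print(m, digits = digits)
  print(x$flags)
  invisible(x)
}

#' @export
summary.disprop <- function(object, ...) {
  df <- disprop_row(object)
  cat("Disproportionality summary\n")
  print(df, row.names = FALSE, digits = 4)
  invisible(df)
}

#' @export
coef.disprop <- function(object, ...) {
  out <- vapply(object$metrics, function(m) m$estimate, numeric(1))
  names(out) <- toupper(names(out))
  out
}

# one flat result row (used by summary and by the pipeline tables)
disprop_row <- function(fit, drug_label = NULL) {
  g <- function(m, f) if (is.null(fit$metrics[[m]])) NA_real_ else
    fit$metrics[[m]][[f]]
  ga <- function(m, f) {
    v <- if (is.null(fit$metrics[[m]])) NULL else fit$metrics[[m]]$aux[[f]]
    if (is.null(v)) NA_real_ else v
  }
  data.frame(
    drug = if (is.null(drug_label))
      paste(fit$drug_set, collapse = "+") else drug_label,
    n_pairs = fit$n_pairs, n_icsr = fit$n_icsr, n11 = fit$n11,
    ror = g("ror", "estimate"), ror_lower = g("ror", "lower"),
    ror_upper = g("ror", "upper"), p_value = ga("ror", "p_value"),
    prr = g("prr", "estimate"), prr_lower = g("prr", "lower"),
    prr_upper = g("prr", "upper"), chi_square = ga("prr", "chi_square"),
    ic = g("ic", "estimate"), ic_lower = g("ic", "lower"),
    ic_upper = g("ic", "upper"),
    ebgm = g("ebgm", "estimate"), ebgm_lower = g("ebgm", "lower"),
    ebgm_upper = g("ebgm", "upper"),
    ror_signal = fit$flags$ror_signal, prr_signal = fit$flags$prr_signal,
    ic_signal = fit$flags$ic_signal, ebgm_signal = fit$flags$ebgm_signal,
    stringsAsFactors = FALSE
  )
}
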