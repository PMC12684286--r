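# Readers for the two SRS table dialects.
#
# JADER: comma-separated CSV in a Shift-JIS-family legacy encoding (CP932 by
# default; the PMDA distributes its tables that way). FAERS: "$"-delimited
# ASCII with a header line, one file per table per quarter.

# Read a text file in `encoding`, returning UTF-8 lines; any byte sequence
# that does not decode is a hard error naming file and line (silently
# substituting characters would corrupt drug names).
read_lines_encoded <- function(path, encoding) {
  raw_lines <- readLines(path, warn = FALSE, encoding = "bytes")
  out <- iconv(raw_lines, from = encoding, to = "UTF-8")
  bad <- which(is.na(out) & !is.na(raw_lines))
  if (length(bad)) {
    stop(sprintf("undecodable %s bytes in '%s' at line %d",
                 encoding, path, bad[1]), call. = FALSE)
  }
  out
}

check_tables <- function(paths, required) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("'paths' must be a named list/vector of table files", call. = FALSE)
  }
  names(paths) <- tolower(names(paths))
  missing_tab <- setdiff(required, names(paths))
  if (length(missing_tab)) {
    stop("missing required table(s): ", paste(missing_tab, collapse = ", "),
         call. = FALSE)
  }
  for (tab in names(paths)) {
    if (!file.exists(paths[[tab]])) {
      stop(sprintf("file for table '%s' not found: %s", tab, paths[[tab]]),
           call. = FALSE)
    }
  }
  paths
}

#' Read JADER-dialect tables
#'
#' Reads the relational CSV tables of the JADER dialect (DEMO, DRUG, REAC,
#' HIST) as character data.frames: all fields are kept as text and parsed
#' lazily downstream, so no information is lost to type coercion. Files are
#' decoded from a legacy Japanese encoding (CP932 by default).
#'
#' @param paths named list or vector of file paths; names are table names
#'   (case-insensitive). `demo` is required; other tables are optional.
#' @param encoding source encoding of the files.
#' @return named list of character data.frames, one per supplied table.
#' @seealso [read_faers_tables()], [merge_case_level()]
#' @export
read_jader_tables <- function(paths, encoding = "CP932") {
  paths <- check_tables(paths, required = "demo")
  out <- lapply(paths, function(p) {
    lines <- read_lines_encoded(p, encoding)
    if (length(lines) == 0 ||
        (length(lines) == 1 && !nzchar(lines[1]))) {
      return(data.frame())
    }
    utils::read.csv(text = lines, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  })
  out
}

# Split "$"-delimited lines without dropping empty trailing fields
# (strsplit() alone would drop them).
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "\x1f"), "$", fixed = TRUE)
  lapply(parts, function(p) {
    p[length(p)] <- sub("\x1f$", "", p[length(p)])
    p
  })
}

#' Read FAERS-dialect tables
#'
#' Reads the quarterly "$"-delimited ASCII tables of the FAERS dialect
#' (DEMO, DRUG, REAC, THER, OUTC). The first line is the header; every data
#' row must have the same number of fields, and empty trailing fields are
#' preserved as empty text.
#'
#' @param paths named list or vector of file paths; names are table names
#'   (case-insensitive). `demo` is required.
#' @return named list of character data.frames.
#' @seealso [read_jader_tables()], [dedup_faers()]
#' @export
read_faers_tables <- function(paths) {
  paths <- check_tables(paths, required = "demo")
  out <- lapply(names(paths), function(tab) {
    p <- paths[[tab]]
    lines <- readLines(p, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(data.frame())
    fields <- split_dollar(lines)
    header <- fields[[1]]
    ncols <- length(header)
    arity <- lengths(fields)
    bad <- which(arity[-1] != ncols)
    if (length(bad)) {
      stop(sprintf(
        "table '%s' (%s): row at line %d has %d fields, header has %d",
        tab, p, bad[1] + 1L, arity[bad[1] + 1L], ncols), call. = FALSE)
    }
    if (length(fields) == 1) {
      df <- as.data.frame(matrix(character(0), ncol = ncols))
    } else {
      m <- matrix(unlist(fields[-1], use.names = FALSE),
                  ncol = ncols, byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
    }
    names(df) <- tolower(header)
    df
  })
  names(out) <- tolower(names(paths))
  out
}

#' De-duplicate FAERS DEMO rows by case version
#'
#' FAERS carries successive versions of the same case; duplicate reports
#' are removed by keeping, for each `caseid`, the row with the highest
#' `caseversion`. A missing case version counts as version 0, and ties on
#' version are broken by keeping the row with the larger report identifier
#' (`primaryid`). The rule is idempotent.
#'
#' @param demo data.frame with columns `caseid`, `caseversion`, and
#'   (for tie-breaking) `primaryid`.
#' @return data.frame with exactly one row per `caseid`, in order of first
#'   appearance of each case.
#' @export
dedup_faers <- function(demo) {
  stopifnot(is.data.frame(demo), "caseid" %in% names(demo))
  if (nrow(demo) == 0) return(demo)
  ver <- suppressWarnings(as.numeric(demo$caseversion))
  ver[is.na(ver)] <- 0
  pid <- suppressWarnings(as.numeric(demo$primaryid))
  if (anyNA(pid)) pid <- xtfrm(as.character(demo$primaryid))
  o <- order(match(demo$caseid, unique(demo$caseid)), -ver, -pid)
  keep <- o[!duplicated(demo$caseid[o])]
  demo[sort(keep), , drop = FALSE]
}
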