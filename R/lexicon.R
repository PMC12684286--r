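#' Normalize a drug name for lexicon matching
#'
#' Uppercases, trims, and collapses internal whitespace. Matching against
#' the lexicon is exact on this normalized form; no fuzzy matching is
#' attempted because the target drugs are identified by explicit search
#' strings.
#'
#' @param x character vector of raw drug names.
#' @return normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  toupper(trimws(gsub("[[:space:]]+", " ", as.character(x))))
}

#' Default fibrate lexicon
#'
#' Maps canonical drug identifiers to their verbatim name variants as they
#' appear in FAERS (English) and JADER (Japanese generic names). Fenofibric
#' acid and choline fenofibrate are spelling/salt variants of fenofibrate
#' and map to it.
#'
#' @return named list: canonical identifier -> character vector of synonyms.
#' @export
default_lexicon <- function() {
  list(
    pemafibrate = c("PEMAFIBRATE", "ペマフィブラート"),
    fenofibrate = c("FENOFIBRATE", "FENOFIBRIC ACID", "CHOLINE FENOFIBRATE",
                    "フェノフィブラート"),
    bezafibrate = c("BEZAFIBRATE", "ベザフィブラート")
  )
}

#' Match raw drug names against a lexicon
#'
#' @param raw_name character vector of raw drug names as reported.
#' @param lexicon named list as returned by [default_lexicon()].
#' @return character vector of canonical identifiers; `NA` where the
#'   normalized name is not in the lexicon.
#' @examples
#' match_drug(c("  fenofibric acid ", "PEMAFIBRATE", "ASPIRIN"))
#' @export
match_drug <- function(raw_name, lexicon = default_lexicon()) {
  syn <- unlist(lexicon, use.names = FALSE)
  canon <- rep(names(lexicon), lengths(lexicon))
  map <- stats::setNames(canon, normalize_drug_name(syn))
  out <- unname(map[normalize_drug_name(raw_name)])
  out
}

#' Default target event set: preferred terms for cholecystitis and
#' cholelithiasis
#'
#' The target adverse events are the preferred terms (PTs) grouped under
#' the MedDRA high-level term "Cholecystitis and cholelithiasis"
#' (HLT code 10008616). MedDRA content is licensed and its hierarchy is not
#' parsed here, so PT membership is plain configuration: this default ships
#' the three PTs named in published case material (cholelithiasis,
#' cholecystitis, acute cholecystitis) under their MedDRA codes, padded to
#' the HLT's fourteen PTs with clearly synthetic placeholder entries
#' (codes `9000xxxx`). Replace with the licensed PT list before analysing
#' real data.
#'
#' @return data.frame with columns `pt_code`, `pt_name`; attribute `hlt`
#'   carries the HLT code.
#' @export
default_event_pts <- function() {
  out <- data.frame(
    pt_code = c("10008629", "10008612", "10008614",
                sprintf("9000%04d", 1:11)),
    pt_name = c("Cholelithiasis", "Cholecystitis", "Cholecystitis acute",
                paste0("Biliary placeholder PT ", 1:11)),
    stringsAsFactors = FALSE
  )
  attr(out, "hlt") <- "10008616"
  out
}
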