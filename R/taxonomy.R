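## Rule-based multimorbidity taxonomy: ICD-10 / ATC prefix patterns mapped to
## disease categories with per-category look-back windows and prescription
## thresholds.  The shipped fixture covers every category with representative
## ICD prefixes plus the full ATC lists; a complete classification file can be
## dropped in without code changes.

VALID_WINDOWS <- c("ever", "last_1y", "last_2y", "last_3y", "last_5y")
WINDOW_DAYS <- c(ever = Inf, last_1y = 365, last_2y = 730,
                 last_3y = 1095, last_5y = 1825)

## reserved targets in the classification file
RESERVED_TARGETS <- c("UNSPECIFIC", "EXCLUDE", "PSYCH")

UNSPECIFIC_2Y <- "Unspecific symptoms, two years back"
UNSPECIFIC_EVER <- "Unspecific symptoms, ever"
OTHER_CATEGORY <- "Other"

#' Load a disease-category taxonomy from a classification file
#'
#' Reads a tab-separated classification file with columns `pattern`, `kind`
#' (`icd` or `atc`), `target` (a disease-category name, or one of the
#' reserved targets `UNSPECIFIC`, `EXCLUDE`, `PSYCH`), `window` (one of
#' `ever`, `last_1y`, `last_2y`, `last_3y`, `last_5y`; ignored for reserved
#' targets) and `min_rx` (minimum prescriptions per rolling year for drug
#' qualification: 0 when drug codes are unused, otherwise typically 2, or 4
#' for the painful-condition category).  An optional `cluster` column carries
#' the organ-system cluster label.
#'
#' Two unspecific-symptom categories (two-year and ever windows) are derived
#' from the `UNSPECIFIC` patterns, and a residual `Other` category (three-year
#' window) absorbs every ICD code that matches no pattern; both are part of
#' the testable category set, which therefore has `nrow(x$categories)` =
#' number of named categories + 3.
#'
#' @param path path to the classification TSV.
#' @return an object of class `taxonomy` with elements `patterns`
#'   (pattern-matching table), `categories` (one row per testable category:
#'   `category`, `cluster`, `window`, `min_rx`) and `source` (the file path).
#' @seealso [classify_code()], [default_taxonomy()]
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("taxonomy file not found: %s", path)
  raw <- utils::read.delim(path, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("pattern", "kind", "target", "window", "min_rx")
  if (!all(need %in% names(raw)))
    stopf("taxonomy file must have columns: %s", paste(need, collapse = ", "))
  if (!"cluster" %in% names(raw)) raw$cluster <- rep("-", nrow(raw))
  if (nrow(raw) == 0) return(new_taxonomy(raw))

  raw$pattern <- normalise_code(raw$pattern)
  if (any(!nzchar(raw$pattern))) stopf("empty pattern in taxonomy file")
  if (!all(raw$kind %in% c("icd", "atc")))
    stopf("taxonomy kind must be 'icd' or 'atc'")
  raw$min_rx <- suppressWarnings(as.integer(raw$min_rx))
  if (anyNA(raw$min_rx) || any(!raw$min_rx %in% c(0L, 2L, 4L)))
    stopf("min_rx must be one of 0, 2, 4")

  named <- raw$target[!raw$target %in% RESERVED_TARGETS]
  bad_win <- raw$window[!raw$target %in% RESERVED_TARGETS &
                          !raw$window %in% VALID_WINDOWS]
  if (length(bad_win))
    stopf("unknown window token(s): %s", paste(unique(bad_win), collapse = ", "))

  # a pattern may serve only one target within a kind
  key <- paste(raw$kind, raw$pattern)
  dup <- key[duplicated(key)]
  if (length(dup)) {
    tgt <- vapply(unique(dup), function(k)
      length(unique(raw$target[key == k])), integer(1))
    if (any(tgt > 1) || length(dup))
      stopf("duplicate or conflicting pattern(s): %s",
            paste(unique(dup), collapse = ", "))
  }

  # window / min_rx / cluster must be constant within a category
  for (cat in unique(named)) {
    sel <- raw$target == cat
    if (length(unique(raw$window[sel])) > 1 ||
        length(unique(raw$min_rx[sel])) > 1)
      stopf("category '%s' has inconsistent window or min_rx", cat)
  }
  new_taxonomy(raw, source = path)
}

new_taxonomy <- function(raw, source = NA_character_) {
  pat <- data.table::data.table(
    pattern = raw$pattern, kind = raw$kind, target = raw$target,
    nchar = nchar(raw$pattern))
  named <- raw[!raw$target %in% RESERVED_TARGETS, , drop = FALSE]
  cats <- unique(data.table::data.table(
    category = named$target, cluster = named$cluster,
    window = named$window, min_rx = named$min_rx))
  has_unspec <- any(raw$target == "UNSPECIFIC")
  extra <- data.table::data.table(
    category = c(if (has_unspec) c(UNSPECIFIC_2Y, UNSPECIFIC_EVER),
                 OTHER_CATEGORY),
    cluster = c(if (has_unspec) rep("Unspecific symptoms", 2), "Other diagnoses"),
    window = c(if (has_unspec) c("last_2y", "ever"), "last_3y"),
    min_rx = 0L)
  cats <- rbind(cats, extra)
  structure(list(patterns = pat, categories = cats, source = source),
            class = "taxonomy")
}

#' Default shipped taxonomy
#'
#' @return the `taxonomy` built from the classification file shipped with the
#'   package (representative ICD-10 prefixes per category plus the full ATC
#'   drug-code lists).
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy.tsv", package = "regpseudo",
                            mustWork = TRUE))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d patterns, %d testable categories\n",
              nrow(x$patterns), nrow(x$categories)))
  invisible(x)
}

## uppercase, strip dots and whitespace (ICD-10 'I20.0' -> 'I200')
normalise_code <- function(x) {
  gsub("[. ]", "", toupper(trimws(x)))
}

#' Classify diagnosis or prescription codes
#'
#' Longest-prefix match against the taxonomy patterns; when several patterns
#' of equal length match (possible only with a malformed file), precedence is
#' `EXCLUDED` > `PSYCH` > named category > `UNSPECIFIC`.  Unmatched ICD codes
#' fall through to the residual `OTHER`; unmatched ATC codes are ignored
#' (`NA`), since prescriptions only ever qualify through an explicit rule.
#'
#' @param taxonomy a [load_taxonomy()] object.
#' @param code character vector of ICD-10 or ATC codes (dots tolerated).
#' @param kind `"icd"` or `"atc"`.
#' @return character vector: a category name, `"UNSPECIFIC"`, `"OTHER"`,
#'   `"EXCLUDED"`, `"PSYCH"`, or `NA` for unmatched ATC codes.
#' @export
classify_code <- function(taxonomy, code, kind = c("icd", "atc")) {
  kind <- match.arg(kind)
  stopifnot(inherits(taxonomy, "taxonomy"))
  code <- normalise_code(code)
  if (any(!nzchar(code))) stopf("empty code")
  out <- rep(NA_character_, length(code))
  matched_len <- rep(-1L, length(code))
  pat <- taxonomy$patterns[taxonomy$patterns$kind == kind, ]
  prec <- function(target) {
    # higher wins at equal prefix length
    ifelse(target == "EXCLUDE", 4L,
           ifelse(target == "PSYCH", 3L, ifelse(target == "UNSPECIFIC", 1L, 2L)))
  }
  matched_prec <- rep(-1L, length(code))
  if (nrow(pat)) {
    for (L in sort(unique(pat$nchar))) {
      pL <- pat[pat$nchar == L, ]
      hit <- match(substr(code, 1L, L), pL$pattern)
      ok <- !is.na(hit)
      if (!any(ok)) next
      tgt <- pL$target[hit[ok]]
      pr <- prec(tgt)
      take <- (L > matched_len[ok]) | (L == matched_len[ok] & pr > matched_prec[ok])
      idx <- which(ok)[take]
      out[idx] <- tgt[take]
      matched_len[idx] <- L
      matched_prec[idx] <- pr[take]
    }
  }
  out[out == "EXCLUDE"] <- "EXCLUDED"
  if (kind == "icd") out[is.na(out)] <- "OTHER"
  out
}
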