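#' Define a study period
#'
#' A study period fixes the date range from which publications are analysed
#' and anchors the research time distance at the outbreak starting point.
#'
#' @param start_date,end_date First and last publication date retained
#'   (inclusive), as `Date` or ISO-8601 strings.
#' @param outbreak_start Date the outbreak is taken to begin; must not be
#'   after `start_date`. Research time distance is measured in days from
#'   this anchor.
#'
#' @return An object of class `study_period`: a list with elements
#'   `start_date`, `end_date`, `outbreak_start` (all `Date`).
#' @examples
#' study_period("2020-01-24", "2020-09-03", "2019-12-12")
#' @export
study_period <- function(start_date, end_date, outbreak_start) {
  start_date <- parse_iso_date(start_date)
  end_date <- parse_iso_date(end_date)
  outbreak_start <- parse_iso_date(outbreak_start)
  if (anyNA(c(start_date, end_date, outbreak_start))) {
    stop("study_period dates must be parseable day-level ISO-8601 dates",
         call. = FALSE)
  }
  if (start_date > end_date) {
    stop("start_date must not be after end_date", call. = FALSE)
  }
  if (outbreak_start > start_date) {
    stop("outbreak_start must not be after start_date", call. = FALSE)
  }
  structure(
    list(start_date = start_date, end_date = end_date,
         outbreak_start = outbreak_start),
    class = "study_period"
  )
}

#' @exportS3Method base::print
print.study_period <- function(x, ...) {
  cat("<study_period> ", format(x$start_date), " .. ", format(x$end_date),
      " (outbreak anchor ", format(x$outbreak_start), ")\n", sep = "")
  invisible(x)
}

# Strict day-level ISO parser: "2020", "2020-05" and malformed dates -> NA.
# Day-level windows need day-level dates, so year-only values are rejected.
parse_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  parsed <- as.Date(rep(NA_character_, length(x)))
  parsed[ok] <- as.Date(x[ok], format = "%Y-%m-%d", optional = TRUE)
  # as.Date() with format is lenient about impossible dates on some platforms;
  # round-trip to catch e.g. "2020-13-45"
  rt <- !is.na(parsed) & format(parsed, "%Y-%m-%d") == x
  out[rt] <- parsed[rt]
  out
}

#' Read publication metadata
#'
#' Reads a table of publication records, one row per paper, from either a
#' CORD-19-style metadata CSV (columns `abstract` and `publish_time`
#' required; `cord_uid`/`sha` and `title` used when present) or a JSONL
#' dialect with keys `doc_id`, `abstract`, `pub_date` and optionally
#' `title`, `language_tag`. Rows whose publication date does not parse to a
#' day-level ISO-8601 date are dropped and counted in the load report.
#'
#' @param path Path to the metadata file.
#' @param dialect `"cord19_csv"` or `"jsonl"`.
#'
#' @return A tibble with columns `doc_id`, `title`, `abstract`, `pub_date`
#'   (`Date`), `language_tag`. The load report (counts of rows read and
#'   dropped) is attached as attribute `"load_report"`; see
#'   [load_report()].
#' @seealso [filter_records()]
#' @export
read_metadata <- function(path, dialect = c("cord19_csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("metadata file not found: ", path, call. = FALSE)
  }
  raw <- switch(dialect,
    cord19_csv = read_cord19_csv(path),
    jsonl = read_jsonl_records(path)
  )
  n_read <- nrow(raw)
  raw$pub_date <- parse_iso_date(raw$pub_date_raw)
  bad <- is.na(raw$pub_date)
  out <- raw[!bad, c("doc_id", "title", "abstract", "pub_date", "language_tag")]
  out <- tibble::as_tibble(out)
  attr(out, "load_report") <- list(
    path = path, dialect = dialect, n_read = n_read,
    n_kept = nrow(out), dropped_bad_date = sum(bad)
  )
  out
}

read_cord19_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("abstract", "publish_time")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cord19_csv input is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  id <- if ("cord_uid" %in% names(df)) df$cord_uid
        else if ("sha" %in% names(df)) df$sha
        else sprintf("row%06d", seq_len(nrow(df)))
  data.frame(
    doc_id = id,
    title = if ("title" %in% names(df)) df$title else NA_character_,
    abstract = df$abstract,
    pub_date_raw = df$publish_time,
    language_tag = if ("language" %in% names(df)) df$language
                   else NA_character_,
    stringsAsFactors = FALSE
  )
}

read_jsonl_records <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  need <- c("doc_id", "abstract", "pub_date")
  for (key in need) {
    if (!all(vapply(recs, function(r) key %in% names(r), logical(1)))) {
      stop("jsonl input is missing required key: ", key, call. = FALSE)
    }
  }
  grab <- function(key) {
    vapply(recs, function(r) {
      v <- r[[key]]
      if (is.null(v) || length(v) == 0) NA_character_ else as.character(v[[1]])
    }, character(1))
  }
  data.frame(
    doc_id = grab("doc_id"), title = grab("title"), abstract = grab("abstract"),
    pub_date_raw = grab("pub_date"), language_tag = grab("language_tag"),
    stringsAsFactors = FALSE
  )
}

#' Retrieve the load/filter report attached to a record table
#'
#' @param records A tibble returned by [read_metadata()] or
#'   [filter_records()].
#' @return A named list of counts, or `NULL` if none is attached.
#' @export
load_report <- function(records) {
  attr(records, "load_report", exact = TRUE)
}

#' Filter publication records to valid, in-period, English abstracts
#'
#' Drops records with empty abstracts, records classified as non-English,
#' and records whose publication date falls outside the study period.
#' Records outside the period are dropped, not clipped. Order is preserved
#' and the operation is idempotent.
#'
#' When `language_tag` is present it is trusted (`"en"` or missing passes);
#' otherwise a lightweight heuristic is used: the abstract must be at least
#' 60% ASCII-letter characters (among letters) and contain at least one
#' common English function word. The heuristic is deliberately permissive —
#' it exists to drop clearly non-English records, not to adjudicate edge
#' cases.
#'
#' @param records Tibble with columns `doc_id`, `abstract`, `pub_date` and
#'   optionally `language_tag`.
#' @param period A [study_period()].
#' @return Filtered tibble, with a report attribute (`"load_report"`)
#'   recording how many records each rule removed.
#' @export
filter_records <- function(records, period) {
  stopifnot(inherits(period, "study_period"))
  abstract <- if (is.null(records$abstract)) character(nrow(records))
              else records$abstract
  empty <- is.na(abstract) | !nzchar(trimws(abstract))

  tag <- if ("language_tag" %in% names(records)) records$language_tag
         else rep(NA_character_, nrow(records))
  english <- ifelse(
    !is.na(tag) & nzchar(tag),
    tolower(tag) %in% c("en", "eng", "en-us", "en-gb"),
    vapply(abstract, looks_english, logical(1), USE.NAMES = FALSE)
  )

  in_period <- !is.na(records$pub_date) &
    records$pub_date >= period$start_date &
    records$pub_date <= period$end_date

  keep <- !empty & english & in_period
  out <- records[keep, , drop = FALSE]
  attr(out, "load_report") <- list(
    n_in = nrow(records), n_kept = sum(keep),
    dropped_empty_abstract = sum(empty),
    dropped_non_english = sum(!empty & !english),
    dropped_out_of_period = sum(!empty & english & !in_period),
    empty_result = sum(keep) == 0
  )
  out
}

# English heuristic: letter composition + at least one high-frequency
# English function word. Empty/NA abstracts are handled upstream.
looks_english <- function(text) {
  if (is.na(text) || !nzchar(text)) return(FALSE)
  letters_all <- gregexpr("[[:alpha:]]", text)[[1]]
  n_alpha <- if (letters_all[1] == -1) 0L else length(letters_all)
  ascii <- gregexpr("[A-Za-z]", text)[[1]]
  n_ascii <- if (ascii[1] == -1) 0L else length(ascii)
  if (n_alpha == 0) return(FALSE)
  if (n_ascii / n_alpha < 0.6) return(FALSE)
  words <- c("the", "of", "and", "in", "to", "a", "is", "was", "for", "with",
             "we", "that", "are", "on", "this")
  toks <- strsplit(tolower(text), "[^a-z]+")[[1]]
  any(toks %in% words)
}
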