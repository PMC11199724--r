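#' @importFrom rlang .data
#' @importFrom Rcpp sourceCpp
#' @useDynLib phytometrics, .registration = TRUE
"_PACKAGE"

# Canonical record fields, in serialization order.  Field names are part of
# the on-disk JSON-lines contract and must not change.
biblio_fields <- function() {
  c(
    "record_id", "doi", "title", "abstract", "year", "doc_type", "language",
    "authors", "institutions", "countries", "author_keywords",
    "index_keywords", "citation_count"
  )
}

biblio_list_fields <- function() {
  c("authors", "institutions", "countries", "author_keywords", "index_keywords")
}

doc_types <- function() c("article", "review", "other")

#' Construct a bibliographic corpus
#'
#' A `biblio_corpus` is a tibble with one row per publication and list-columns
#' for the multi-valued entity fields (authors, institutions, countries,
#' keywords), plus a `provenance` attribute recording where the records came
#' from and what cleaning was applied.
#'
#' @param records a data frame with the canonical fields (see Details).
#' @param provenance a list; typically holds `source` and a `cleaning` log.
#' @return an object of class `biblio_corpus`.
#' @details Required columns: `record_id`, `doi`, `title`, `abstract`,
#'   `year`, `doc_type`, `language`, `authors`, `institutions`, `countries`,
#'   `author_keywords`, `index_keywords`, `citation_count`.  Invariants
#'   enforced: unique `record_id`, integer `year`, non-negative
#'   `citation_count`, `doc_type` one of article/review/other, and no
#'   duplicate entries within any entity list.
#' @export
biblio_corpus <- function(records, provenance = list()) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(biblio_fields(), names(records))
  if (length(missing) > 0) {
    abort_arg("corpus is missing required field(s): ", paste(missing, collapse = ", "))
  }
  records <- records[biblio_fields()]
  records$year <- as.integer(records$year)
  records$citation_count <- as.integer(records$citation_count)
  for (f in biblio_list_fields()) {
    records[[f]] <- lapply(records[[f]], function(x) {
      x <- as.character(x)
      unique(x[!is.na(x) & nzchar(x)])
    })
  }
  out <- structure(records,
    class = c("biblio_corpus", class(tibble::tibble())),
    provenance = provenance
  )
  validate_biblio_corpus(out)
  out
}

validate_biblio_corpus <- function(corpus) {
  if (anyDuplicated(corpus$record_id) > 0) {
    abort_arg("record_id values must be unique within a corpus")
  }
  if (any(is.na(corpus$year))) {
    abort_arg("all records must carry a parseable integer year")
  }
  if (any(is.na(corpus$citation_count) | corpus$citation_count < 0)) {
    abort_arg("citation_count must be a non-negative integer")
  }
  bad_type <- setdiff(unique(corpus$doc_type), doc_types())
  if (length(bad_type) > 0) {
    abort_arg("doc_type must be one of article/review/other; found: ",
              paste(bad_type, collapse = ", "))
  }
  doi <- corpus$doi[!is.na(corpus$doi) & nzchar(corpus$doi)]
  if (anyDuplicated(tolower(doi)) > 0) {
    # permitted pre-dedup; recorded so deduplicate() can act on it
    attr(corpus, "has_duplicate_dois") <- TRUE
  }
  invisible(corpus)
}

#' @export
print.biblio_corpus <- function(x, ...) {
  prov <- corpus_provenance(x)
  cat(sprintf("<biblio_corpus> %d records", nrow(x)))
  if (nrow(x) > 0) cat(sprintf(", years %d-%d", min(x$year), max(x$year)))
  if (!is.null(prov$source)) cat(sprintf(", source: %s", prov$source))
  cat("\n")
  NextMethod()
  invisible(x)
}

#' Provenance of a corpus
#'
#' @param corpus a `biblio_corpus`.
#' @return the provenance list (source path, cleaning report, rejects).
#' @export
corpus_provenance <- function(corpus) {
  attr(corpus, "provenance") %||% list()
}

set_provenance <- function(corpus, provenance) {
  attr(corpus, "provenance") <- provenance
  corpus
}

# dplyr-style subsetting helpers keep the class and provenance.
corpus_slice <- function(corpus, idx) {
  out <- corpus[idx, , drop = FALSE]
  structure(out,
    class = class(corpus),
    provenance = corpus_provenance(corpus)
  )
}

#' Restrict a corpus to a publication period
#'
#' Keeps records with `start <= year <= end` (both boundaries inclusive), so
#' that consecutive periods such as 2002-2012 and 2013-2022 partition a
#' 2002-2022 corpus exactly.
#'
#' @param corpus a `biblio_corpus`.
#' @param start,end integer calendar years, `start <= end`.
#' @return the filtered `biblio_corpus`.
#' @export
filter_by_period <- function(corpus, start, end) {
  stopifnot(is_biblio_corpus(corpus))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) abort_arg("start and end must be integer years")
  if (start > end) abort_arg("start year (", start, ") exceeds end year (", end, ")")
  corpus_slice(corpus, corpus$year >= start & corpus$year <= end)
}

#' @export
#' @rdname biblio_corpus
is_biblio_corpus <- function(x) inherits(x, "biblio_corpus")
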