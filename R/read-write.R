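#' Default Scopus-style column mapping
#'
#' Maps canonical record fields to the column headers of a Scopus CSV export.
#' Any entry can be overridden; set an entry to `NA` to declare the column
#' absent.  `record_id` falls back to a synthesized sequential id when its
#' column is missing, and `countries` falls back to extraction from the
#' affiliation strings.
#'
#' @return named list: canonical field -> CSV column name.
#' @export
scopus_column_map <- function() {
  list(
    record_id       = "EID",
    doi             = "DOI",
    title           = "Title",
    abstract        = "Abstract",
    year            = "Year",
    doc_type        = "Document Type",
    language        = "Language of Original Document",
    authors         = "Authors",
    institutions    = "Affiliations",
    countries       = "Countries",
    author_keywords = "Author Keywords",
    index_keywords  = "Index Keywords",
    citation_count  = "Cited by"
  )
}

split_multi <- function(x, delim) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  parts <- trimws(strsplit(x, delim, fixed = TRUE)[[1]])
  unique(parts[nzchar(parts)])
}

join_multi <- function(x, delim) paste(x, collapse = delim)

normalize_doc_type <- function(x) {
  x <- tolower(trimws(x %||% ""))
  x[is.na(x)] <- ""
  out <- rep("other", length(x))
  out[x == "article"] <- "article"
  out[x %in% c("review", "review article")] <- "review"
  out
}

# Scopus affiliations end with the country name; take the last
# comma-separated token of each affiliation and keep gazetteer matches.
countries_from_affiliations <- function(affils, gazetteer = country_gazetteer()) {
  if (length(affils) == 0) return(character(0))
  last <- vapply(strsplit(affils, ",", fixed = TRUE), function(p) {
    trimws(p[[length(p)]])
  }, character(1))
  hit <- gazetteer[match(tolower(last), tolower(gazetteer))]
  unique(hit[!is.na(hit)])
}

#' Read a Scopus-style bibliographic CSV export
#'
#' Parses one publication per row into a [biblio_corpus()].  Multi-valued
#' fields (authors, affiliations, keywords) are split on `delim`.  Rows whose
#' year cannot be parsed as an integer are not silently dropped: they are
#' routed to a rejects table in the corpus provenance.
#'
#' @param path path to a CSV file.
#' @param column_map named list mapping canonical fields to CSV headers; see
#'   [scopus_column_map()].  Required resolvable columns: title, year,
#'   authors.
#' @param delim delimiter for multi-valued cells (Scopus convention `"; "`).
#' @return a `biblio_corpus`; `corpus_provenance()` carries the source path
#'   and a `rejects` tibble (row number, reason).
#' @export
read_bibliographic_csv <- function(path, column_map = scopus_column_map(),
                                   delim = "; ") {
  if (!file.exists(path)) abort_arg("file not found: ", path)
  cmap <- utils::modifyList(scopus_column_map(), column_map)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, na = character())
  if (nrow(raw) == 0) abort_arg("empty corpus: ", path, " contains no records")

  required <- c("title", "year", "authors")
  for (f in required) {
    col <- cmap[[f]]
    if (is.null(col) || is.na(col) || !(col %in% names(raw))) {
      abort_arg("required column for field '", f, "' (mapped to '",
                cmap[[f]] %||% "<unset>", "') not found in ", path)
    }
  }
  get_col <- function(field) {
    col <- cmap[[field]]
    if (is.null(col) || is.na(col) || !(col %in% names(raw))) return(rep(NA_character_, nrow(raw)))
    x <- raw[[col]]
    x[!nzchar(x)] <- NA_character_
    x
  }

  year_raw <- get_col("year")
  year <- suppressWarnings(as.integer(year_raw))
  ok <- !is.na(year)
  rejects <- tibble::tibble(
    row = which(!ok),
    title = get_col("title")[!ok],
    reason = sprintf("unparseable year '%s'", year_raw[!ok])
  )

  n <- nrow(raw)
  rid <- get_col("record_id")
  if (all(is.na(rid))) rid <- sprintf("rec%05d", seq_len(n))
  cites <- suppressWarnings(as.integer(get_col("citation_count")))
  cites[is.na(cites)] <- 0L

  authors <- lapply(get_col("authors"), split_multi, delim = delim)
  institutions <- lapply(get_col("institutions"), split_multi, delim = delim)
  countries_col <- get_col("countries")
  countries <- lapply(seq_len(n), function(i) {
    if (!is.na(countries_col[i])) split_multi(countries_col[i], delim)
    else countries_from_affiliations(institutions[[i]])
  })

  records <- tibble::tibble(
    record_id = rid,
    doi = get_col("doi"),
    title = dplyr::coalesce(get_col("title"), ""),
    abstract = dplyr::coalesce(get_col("abstract"), ""),
    year = year,
    doc_type = normalize_doc_type(get_col("doc_type")),
    language = dplyr::coalesce(get_col("language"), "English"),
    authors = authors,
    institutions = institutions,
    countries = countries,
    author_keywords = lapply(get_col("author_keywords"), split_multi, delim = delim),
    index_keywords = lapply(get_col("index_keywords"), split_multi, delim = delim),
    citation_count = cites
  )
  kept <- records[ok, , drop = FALSE]
  biblio_corpus(kept, provenance = list(
    source = path,
    rejects = rejects,
    cleaning = list(rows_read = n, rows_kept = sum(ok), rows_rejected = sum(!ok))
  ))
}

#' Write a corpus as a Scopus-style CSV
#'
#' Inverse of [read_bibliographic_csv()] under the default column map:
#' writing then reading reproduces the corpus field-for-field.
#'
#' @param corpus a `biblio_corpus`.
#' @param path output path.
#' @param delim delimiter for multi-valued cells.
#' @return `path`, invisibly.
#' @export
write_bibliographic_csv <- function(corpus, path, delim = "; ") {
  stopifnot(is_biblio_corpus(corpus))
  cmap <- scopus_column_map()
  out <- tibble::tibble(
    !!cmap$record_id := corpus$record_id,
    !!cmap$doi := dplyr::coalesce(corpus$doi, ""),
    !!cmap$title := corpus$title,
    !!cmap$abstract := corpus$abstract,
    !!cmap$year := as.character(corpus$year),
    !!cmap$doc_type := corpus$doc_type,
    !!cmap$language := corpus$language,
    !!cmap$authors := vapply(corpus$authors, join_multi, character(1), delim = delim),
    !!cmap$institutions := vapply(corpus$institutions, join_multi, character(1), delim = delim),
    !!cmap$countries := vapply(corpus$countries, join_multi, character(1), delim = delim),
    !!cmap$author_keywords := vapply(corpus$author_keywords, join_multi, character(1), delim = delim),
    !!cmap$index_keywords := vapply(corpus$index_keywords, join_multi, character(1), delim = delim),
    !!cmap$citation_count := as.character(corpus$citation_count)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read / write the canonical JSON-lines corpus format
#'
#' One JSON object per line with the canonical field names; the stable
#' interchange format between pipeline stages.
#'
#' @param corpus a `biblio_corpus`.
#' @param path file path.
#' @return `write_corpus_jsonl()` returns `path` invisibly;
#'   `read_corpus_jsonl()` returns a `biblio_corpus`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(is_biblio_corpus(corpus))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    rec <- lapply(biblio_fields(), function(f) {
      v <- corpus[[f]][[i]]
      if (f %in% biblio_list_fields()) as.list(v) else v
    })
    names(rec) <- biblio_fields()
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  if (!file.exists(path)) abort_arg("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_arg("empty corpus: ", path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  records <- tibble::tibble(
    record_id = vapply(recs, function(r) as.character(r$record_id), character(1)),
    doi = vapply(recs, function(r) if (is.null(r$doi)) NA_character_ else as.character(r$doi), character(1)),
    title = vapply(recs, function(r) as.character(r$title), character(1)),
    abstract = vapply(recs, function(r) as.character(r$abstract %||% ""), character(1)),
    year = vapply(recs, function(r) as.integer(r$year), integer(1)),
    doc_type = vapply(recs, function(r) as.character(r$doc_type), character(1)),
    language = vapply(recs, function(r) as.character(r$language), character(1)),
    authors = lapply(recs, function(r) as.character(unlist(r$authors))),
    institutions = lapply(recs, function(r) as.character(unlist(r$institutions))),
    countries = lapply(recs, function(r) as.character(unlist(r$countries))),
    author_keywords = lapply(recs, function(r) as.character(unlist(r$author_keywords))),
    index_keywords = lapply(recs, function(r) as.character(unlist(r$index_keywords))),
    citation_count = vapply(recs, function(r) as.integer(r$citation_count), integer(1))
  )
  biblio_corpus(records, provenance = list(source = path))
}

#' Write the cleaning report of a corpus as JSON
#'
#' @param corpus a `biblio_corpus` whose provenance holds a cleaning log.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(corpus, path) {
  prov <- corpus_provenance(corpus)
  jsonlite::write_json(prov[setdiff(names(prov), "source")], path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
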