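#' Alias map for entity-name normalization
#'
#' Bibliographic exports spell the same institution, author, country, or
#' keyword in several ways.  An alias map sends each variant to a canonical
#' string.  Maps must be idempotent: every canonical value that appears as a
#' key must map to itself, so applying the map twice equals applying it once.
#'
#' @param entity_level one of `"author"`, `"institution"`, `"country"`,
#'   `"keyword"`.
#' @param mapping named character vector, `names = variant`, value = canonical.
#' @return an `alias_map` object.
#' @export
#' @examples
#' alias_map("institution", c("Univ. Fed. Amazonas" = "UFAM", "UFAM" = "UFAM"))
alias_map <- function(entity_level, mapping) {
  entity_level <- match.arg(entity_level, c("author", "institution", "country", "keyword"))
  mapping <- unlist(mapping)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  canon_as_key <- intersect(unname(mapping), names(mapping))
  bad <- canon_as_key[mapping[canon_as_key] != canon_as_key]
  # values not present as keys are implicitly fixed points, which is fine;
  # a canonical string that maps elsewhere would make the map non-idempotent
  if (length(bad) > 0) {
    abort_arg("alias map is not idempotent; canonical value(s) remapped: ",
              paste(bad, collapse = ", "))
  }
  structure(list(entity_level = entity_level, mapping = mapping),
            class = "alias_map")
}

alias_field_for <- function(level) {
  switch(level,
    author = "authors",
    institution = "institutions",
    country = "countries",
    keyword = c("author_keywords", "index_keywords")
  )
}

#' Apply alias maps to a corpus
#'
#' Replaces every entity string by its canonical form; entities made
#' identical within a record collapse to one occurrence.  Strings with no
#' alias pass through unchanged and are collected in the provenance report
#' (`unmapped`), so dirty names remain visible rather than silently kept.
#'
#' @param corpus a `biblio_corpus`.
#' @param aliases an `alias_map` or a list of them (one per entity level).
#' @return the normalized `biblio_corpus`; provenance gains
#'   `cleaning$aliases_applied` counts and an `unmapped` list.
#' @export
normalize_entities <- function(corpus, aliases) {
  stopifnot(is_biblio_corpus(corpus))
  if (inherits(aliases, "alias_map")) aliases <- list(aliases)
  stopifnot(all(vapply(aliases, inherits, logical(1), "alias_map")))

  prov <- corpus_provenance(corpus)
  applied <- list()
  unmapped <- list()
  for (am in aliases) {
    fields <- alias_field_for(am$entity_level)
    n_applied <- 0L
    seen_unmapped <- character(0)
    for (f in fields) {
      corpus[[f]] <- lapply(corpus[[f]], function(x) {
        hit <- match(x, names(am$mapping))
        n_applied <<- n_applied + sum(!is.na(hit) & am$mapping[hit] != x, na.rm = TRUE)
        seen_unmapped <<- union(seen_unmapped, x[is.na(hit)])
        out <- ifelse(is.na(hit), x, unname(am$mapping[hit]))
        unique(out)
      })
    }
    applied[[am$entity_level]] <- n_applied
    unmapped[[am$entity_level]] <- sort(seen_unmapped)
  }
  prov$cleaning$aliases_applied <- applied
  prov$unmapped <- unmapped
  set_provenance(corpus, prov)
}

# Title key for DOI-less deduplication: lowercase, punctuation stripped,
# whitespace collapsed.
normalize_title_key <- function(title) {
  x <- tolower(title)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Remove duplicate records
#'
#' Duplicate detection uses the DOI when present (case-insensitive); DOI-less
#' records fall back to the normalized title plus year.  Within a duplicate
#' group the record with the largest citation count is kept (first occurrence
#' on ties), so citation analyses lose nothing.  The number removed is logged
#' in the provenance cleaning report; `input = kept + removed` always holds.
#'
#' @param corpus a `biblio_corpus`.
#' @return the deduplicated `biblio_corpus`.  Idempotent.
#' @export
deduplicate <- function(corpus) {
  stopifnot(is_biblio_corpus(corpus))
  has_doi <- !is.na(corpus$doi) & nzchar(corpus$doi)
  key <- ifelse(has_doi,
    paste0("doi:", tolower(corpus$doi)),
    paste0("title:", normalize_title_key(corpus$title), "|", corpus$year)
  )
  ord <- order(match(key, unique(key)), -corpus$citation_count,
               seq_len(nrow(corpus)))
  keep_first <- !duplicated(key[ord])
  keep_idx <- sort(ord[keep_first])

  prov <- corpus_provenance(corpus)
  prov$cleaning$duplicates_removed <-
    (prov$cleaning$duplicates_removed %||% 0L) + (nrow(corpus) - length(keep_idx))
  prov$cleaning$records_in <- nrow(corpus)
  prov$cleaning$records_kept <- length(keep_idx)
  set_provenance(corpus_slice(corpus, keep_idx), prov)
}
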