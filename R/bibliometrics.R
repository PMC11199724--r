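entity_levels <- function() {
  c("country", "institution", "author", "doc_type", "language")
}

level_field <- function(level) {
  switch(level,
    country = "countries",
    institution = "institutions",
    author = "authors",
    doc_type = "doc_type",
    language = "language",
    keyword = NULL
  )
}

# One row per (record, entity) under whole counting: a record credits each
# distinct entity it lists with one full publication.
entity_long <- function(corpus, level) {
  field <- level_field(level)
  if (is.null(field)) abort_arg("unknown entity level: ", level)
  if (field %in% biblio_list_fields()) {
    tibble::tibble(
      record_id = rep(corpus$record_id, lengths(corpus[[field]])),
      year = rep(corpus$year, lengths(corpus[[field]])),
      citation_count = rep(corpus$citation_count, lengths(corpus[[field]])),
      entity = unlist(corpus[[field]], use.names = FALSE) %||% character(0)
    )
  } else {
    tibble::tibble(
      record_id = corpus$record_id,
      year = corpus$year,
      citation_count = corpus$citation_count,
      entity = corpus[[field]]
    )
  }
}

#' Annual publication counts
#'
#' Overall series, or per-entity series for the `top_k` most productive
#' entities at a level.  The series covers every year from the first to the
#' last year present, with zeros filled in, and its total equals the corpus
#' size (overall) or each entity's whole-counted publication total.
#'
#' @param corpus a non-empty `biblio_corpus`.
#' @param level `"overall"` or an entity level
#'   (country/institution/author/doc_type/language).
#' @param top_k for entity levels, how many top entities to include.
#' @return a tibble with columns `year`, `entity` (absent for overall), `n`.
#' @export
annual_counts <- function(corpus, level = "overall", top_k = 5) {
  stopifnot(is_biblio_corpus(corpus))
  if (nrow(corpus) == 0) abort_arg("annual_counts: empty corpus has no series")
  years <- seq(min(corpus$year), max(corpus$year))
  if (identical(level, "overall")) {
    counts <- table(factor(corpus$year, levels = years))
    return(tibble::tibble(year = years, n = as.integer(counts)))
  }
  long <- entity_long(corpus, level)
  top <- entity_counts(corpus, level, min_docs = 1)
  top <- utils::head(top$entity, top_k)
  long <- long[long$entity %in% top, , drop = FALSE]
  grid <- tidyr::expand_grid(entity = top, year = years)
  tallied <- dplyr::count(long, .data$entity, .data$year)
  out <- dplyr::left_join(grid, tallied, by = c("entity", "year"))
  out$n <- as.integer(dplyr::coalesce(out$n, 0L))
  out
}

#' Ranked entity table
#'
#' Publication counts, citation totals and citation ratios per entity under
#' whole counting, sorted by publication count (descending) with
#' alphabetical tie order, restricted to entities with at least `min_docs`
#' publications.
#'
#' @param corpus a `biblio_corpus`.
#' @param level entity level: country, institution, author, doc_type, or
#'   language.
#' @param min_docs minimum publication count to retain a row.
#' @return a tibble: `entity`, `publication_count`, `citation_total`,
#'   `citation_ratio` (exact, unrounded; round with [round_half_up()] for
#'   reporting).
#' @export
entity_counts <- function(corpus, level, min_docs = 1) {
  stopifnot(is_biblio_corpus(corpus))
  level <- match.arg(level, entity_levels())
  long <- entity_long(corpus, level)
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$entity),
    publication_count = dplyr::n(),
    citation_total = sum(.data$citation_count),
    .groups = "drop"
  )
  out <- out[out$publication_count >= min_docs, , drop = FALSE]
  out$citation_ratio <- out$citation_total / out$publication_count
  dplyr::arrange(out, dplyr::desc(.data$publication_count), .data$entity)
}

#' Citation ratio
#'
#' Average number of citations per published record for an entity.
#'
#' @param citation_total non-negative numeric.
#' @param publication_count positive numeric.
#' @param digits optional; when given, the ratio is rounded half-up to this
#'   many decimals (reporting convention: 1 decimal).
#' @return the ratio.  A zero `publication_count` is an error, never a
#'   silent zero.
#' @export
#' @examples
#' citation_ratio(23041, 1219, digits = 1) # 18.9
citation_ratio <- function(citation_total, publication_count, digits = NULL) {
  stopifnot(is.numeric(citation_total), is.numeric(citation_total))
  if (any(citation_total < 0)) abort_arg("citation_total must be non-negative")
  if (any(publication_count <= 0)) {
    abort_arg("citation ratio undefined for publication_count = 0")
  }
  r <- citation_total / publication_count
  if (!is.null(digits)) r <- round_half_up(r, digits)
  r
}

#' Percentage share
#'
#' `100 * count / total`, rounded half-up to `decimals` places -- the
#' convention used for all printed shares.
#'
#' @param count integer(ish) in `[0, total]`.
#' @param total positive integer.
#' @param decimals decimal places (default 1).
#' @return the percentage.
#' @export
#' @examples
#' share(1638, 1850) # 88.5
share <- function(count, total, decimals = 1) {
  if (any(total <= 0)) abort_arg("share: total must be positive")
  if (any(count < 0 | count > total)) abort_arg("share: count must lie in [0, total]")
  round_half_up(100 * count / total, decimals)
}
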