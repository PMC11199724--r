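#' The five grouped Technology Readiness Level categories
#'
#' The nine-level TRL scale collapsed to five categories: patent-stage TRL5
#' is rarely visible in publications on its own (grouped with TRL4), and
#' clinical-phase levels 6-9 cannot be separated from abstracts (grouped).
#' Order matters: ties in classification break toward the lower (more
#' conservative) category.
#'
#' @return character vector `c("TRL1","TRL2","TRL3","TRL4_5","TRL6_9")`.
#' @export
trl_categories <- function() c("TRL1", "TRL2", "TRL3", "TRL4_5", "TRL6_9")

#' @rdname trl_categories
#' @export
trl_category_descriptions <- function() {
  c(
    TRL1 = "basic research: identification of extracts and fundamental principles",
    TRL2 = "isolation of substances, fractionation, chemical characterization",
    TRL3 = "in vitro and in silico testing",
    TRL4_5 = "in vivo animal testing, formulation research, patenting",
    TRL6_9 = "clinical trials (phases I-IV) and population-response studies"
  )
}

#' Validate a TRL anchor-keyword set
#'
#' @param x named list: category -> character vector of lowercase anchor
#'   terms (uni- or bi-grams).  Must cover exactly the five categories with
#'   non-empty, pairwise non-identical sets.
#' @return the validated list (terms lowercased), class `trl_keyword_set`.
#' @export
trl_keyword_set <- function(x) {
  if (!setequal(names(x), trl_categories())) {
    abort_arg("keyword set must define exactly the categories ",
              paste(trl_categories(), collapse = ", "))
  }
  x <- lapply(x[trl_categories()], function(v) unique(tolower(trimws(as.character(v)))))
  if (any(lengths(x) == 0)) abort_arg("every TRL category needs at least one anchor term")
  for (i in 1:4) for (j in (i + 1):5) {
    if (setequal(x[[i]], x[[j]])) {
      abort_arg("categories ", names(x)[i], " and ", names(x)[j],
                " have identical anchor sets")
    }
  }
  structure(x, class = "trl_keyword_set")
}

#' Load the shipped (or a custom) anchor-keyword YAML
#'
#' @param path YAML file mapping each category to a term list; default is
#'   the set shipped with the package, built from the grouped-level
#'   descriptions.
#' @return a `trl_keyword_set`.
#' @export
default_trl_keywords <- function(path = system.file("extdata", "trl_keywords.yaml",
                                                    package = "phytometrics")) {
  trl_keyword_set(yaml::read_yaml(path))
}

#' Represent a document for distance computation
#'
#' Two representations bridge the topic model and the distance measures:
#' `token_set` (for Jaccard) is the preprocessed token set, optionally
#' expanded with the `top_m` words of every topic whose document weight
#' reaches `theta_min`; `topic_distribution` (for the probabilistic
#' measures) is the document's topic distribution.
#'
#' @param tokens character vector of preprocessed tokens (non-empty).
#' @param model an `lda_model`, required when `top_m > 0` or for
#'   `topic_distribution` mode.
#' @param mode `"token_set"` or `"topic_distribution"`.
#' @param top_m topic words added per active topic (0 = raw token set).
#' @param theta_min minimum topic weight for a topic to contribute words.
#' @param theta optional precomputed topic distribution for the document;
#'   inferred from `model` when missing.
#' @return a character set or a numeric distribution.
#' @export
document_representation <- function(tokens, model = NULL,
                                    mode = c("token_set", "topic_distribution"),
                                    top_m = 5, theta_min = 0.2, theta = NULL) {
  mode <- match.arg(mode)
  if (length(tokens) == 0) {
    abort_arg("cannot represent a document with no usable tokens")
  }
  need_theta <- mode == "topic_distribution" || top_m > 0
  if (need_theta && is.null(theta)) {
    if (is.null(model)) abort_arg("a fitted topic model is required here")
    theta <- infer_theta(model, tokens)
  }
  if (mode == "topic_distribution") return(theta)
  out <- unique(tokens)
  if (top_m > 0) {
    for (k in which(theta >= theta_min)) {
      out <- union(out, top_words(model, k, top_m))
    }
  }
  out
}

#' Represent the TRL categories for distance computation
#'
#' In set mode each category is its preprocessed anchor-token set; in
#' distribution mode the anchors are concatenated into a pseudo-document and
#' its topic distribution inferred with the fitted model.
#'
#' @param keywords a `trl_keyword_set`.
#' @param model an `lda_model` (distribution mode only).
#' @param mode `"token_set"` or `"topic_distribution"`.
#' @return named list over the five categories.
#' @export
category_representation <- function(keywords, model = NULL,
                                    mode = c("token_set", "topic_distribution")) {
  mode <- match.arg(mode)
  stopifnot(inherits(keywords, "trl_keyword_set"))
  sets <- lapply(keywords, function(terms) {
    unique(unlist(lapply(terms, preprocess), use.names = FALSE))
  })
  if (mode == "token_set") return(sets)
  if (is.null(model)) abort_arg("distribution mode requires a fitted topic model")
  out <- vector("list", length(sets))
  names(out) <- names(sets)
  for (cat in names(sets)) {
    in_vocab <- intersect(sets[[cat]], model$vocab)
    if (length(in_vocab) == 0) {
      abort_arg("anchor terms of category ", cat,
                " are entirely out of the model vocabulary")
    }
    out[[cat]] <- infer_theta(model, sets[[cat]])
  }
  out
}

#' Classify a corpus into TRL categories
#'
#' Each record's abstract is represented (token set or topic distribution,
#' matching the measure), distances to the five category representations are
#' computed, and the record is assigned the argmin category; exact ties break
#' toward the lower category, the conservative maturity claim.  Records with
#' empty token lists are unclassifiable: they are excluded (never guessed)
#' and counted.
#'
#' @param corpus a `biblio_corpus`.
#' @param keywords a `trl_keyword_set`.
#' @param model an `lda_model` fitted on the corpus (required for the
#'   distribution measures and for token-set expansion with `top_m > 0`).
#' @param measure one of [trl_measures()].
#' @param top_m,theta_min token-set expansion parameters (Jaccard only); see
#'   [document_representation()].
#' @return a tibble (class `trl_classification`): `record_id`, `predicted`,
#'   and the five distance columns `d_TRL1 .. d_TRL6_9`; attributes
#'   `measure`, `unclassifiable` (record ids).
#' @export
classify_corpus <- function(corpus, keywords, model = NULL,
                            measure = "jaccard", top_m = 5, theta_min = 0.2) {
  stopifnot(is_biblio_corpus(corpus))
  measure <- match.arg(measure, trl_measures())
  use_sets <- measure == "jaccard"
  mode <- if (use_sets) "token_set" else "topic_distribution"
  if (!use_sets && is.null(model)) {
    abort_arg("measure '", measure, "' operates on topic distributions and ",
              "requires a fitted model")
  }
  cat_repr <- category_representation(keywords, model, mode)
  cats <- trl_categories()

  tokens <- lapply(corpus$abstract, preprocess)
  ok <- lengths(tokens) > 0
  ids <- corpus$record_id

  theta_for <- function(i) {
    if (!is.null(model) && ids[i] %in% rownames(model$theta)) {
      model$theta[ids[i], ]
    } else if (!is.null(model)) {
      infer_theta(model, tokens[[i]])
    } else NULL
  }

  dmat <- matrix(NA_real_, nrow = nrow(corpus), ncol = length(cats),
                 dimnames = list(NULL, paste0("d_", cats)))
  for (i in which(ok)) {
    th <- if (!use_sets || top_m > 0) theta_for(i) else NULL
    repr <- document_representation(tokens[[i]], model, mode,
                                    top_m = if (use_sets) top_m else 0,
                                    theta_min = theta_min, theta = th)
    dmat[i, ] <- vapply(cats, function(cc) {
      trl_distance(repr, cat_repr[[cc]], measure)
    }, numeric(1))
  }
  predicted <- rep(NA_character_, nrow(corpus))
  predicted[ok] <- cats[apply(dmat[ok, , drop = FALSE], 1, which.min)]

  out <- tibble::tibble(record_id = ids, predicted = predicted)
  out <- dplyr::bind_cols(out, tibble::as_tibble(dmat))
  out <- out[ok, , drop = FALSE]
  structure(out,
    class = c("trl_classification", class(tibble::tibble())),
    measure = measure,
    unclassifiable = ids[!ok]
  )
}

#' Evaluate a classification against a labeled benchmark
#'
#' @param result a `trl_classification` (from [classify_corpus()]).
#' @param benchmark a data frame `record_id`, `category` (true labels); all
#'   ids must have been classified.
#' @return list: `error_rate` (misclassified / benchmark size), `confusion`
#'   (5x5 matrix, rows = true, columns = predicted), `n`.  The confusion
#'   trace over `n` equals `1 - error_rate` identically.
#' @export
evaluate <- function(result, benchmark) {
  if (nrow(benchmark) == 0) abort_arg("benchmark is empty")
  bad <- setdiff(benchmark$record_id, result$record_id)
  if (length(bad) > 0) {
    abort_arg("benchmark ids missing from classification: ",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  cats <- trl_categories()
  pred <- result$predicted[match(benchmark$record_id, result$record_id)]
  truth <- as.character(benchmark$category)
  if (!all(truth %in% cats)) abort_arg("benchmark labels must be TRL categories")
  confusion <- table(factor(truth, levels = cats), factor(pred, levels = cats))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  n <- nrow(benchmark)
  list(
    error_rate = 1 - sum(diag(confusion)) / n,
    confusion = confusion,
    n = n
  )
}

#' Select the best distance measure on a benchmark
#'
#' Classifies the benchmarked records under each candidate measure and
#' returns the one with minimum benchmark error; ties break by the fixed
#' preference order jaccard, jensen_shannon, hellinger, kullback_leibler.
#'
#' @param corpus a `biblio_corpus`.
#' @param keywords a `trl_keyword_set`.
#' @param model an `lda_model`.
#' @param benchmark labeled subset (`record_id`, `category`).
#' @param measures candidate measures (default all four).
#' @param ... passed to [classify_corpus()] (e.g. `top_m`).
#' @return list: `measure` (chosen), `errors` (tibble measure x error_rate).
#' @export
select_measure <- function(corpus, keywords, model, benchmark,
                           measures = trl_measures(), ...) {
  if (length(measures) == 0) abort_arg("need at least one candidate measure")
  measures <- measures[order(match(measures, trl_measures()))]
  sub <- corpus_slice(corpus, corpus$record_id %in% benchmark$record_id)
  errs <- vapply(measures, function(m) {
    res <- classify_corpus(sub, keywords, model, measure = m, ...)
    evaluate(res, benchmark)$error_rate
  }, numeric(1))
  list(
    measure = measures[which.min(errs)],
    errors = tibble::tibble(measure = measures, error_rate = unname(errs))
  )
}

#' TRL distribution of a classification
#'
#' @param result a `trl_classification`.
#' @param decimals decimal places for the shares (default 1).
#' @return tibble: `category`, `n`, `share` (percent of classified records;
#'   shares use half-up rounding).
#' @export
trl_distribution <- function(result, decimals = 1) {
  if (nrow(result) == 0) abort_arg("no classified records")
  cats <- trl_categories()
  n <- as.integer(table(factor(result$predicted, levels = cats)))
  tibble::tibble(
    category = cats,
    n = n,
    share = share(n, sum(n), decimals)
  )
}

#' Per-country TRL profile
#'
#' Cross-tabulates predicted categories against countries (whole counting: a
#' record credits each country it lists).
#'
#' @param result a `trl_classification`.
#' @param corpus the classified `biblio_corpus`.
#' @param top_k keep the `top_k` most productive countries.
#' @return tibble: `country`, one count column per category, `total`.
#' @export
trl_by_country <- function(result, corpus, top_k = 5) {
  cats <- trl_categories()
  idx <- match(result$record_id, corpus$record_id)
  long <- tibble::tibble(
    country = unlist(corpus$countries[idx], use.names = FALSE),
    category = rep(result$predicted, lengths(corpus$countries[idx]))
  )
  tab <- dplyr::count(long, .data$country, .data$category)
  wide <- tidyr::pivot_wider(tab, names_from = "category", values_from = "n",
                             values_fill = 0L)
  for (cc in setdiff(cats, names(wide))) wide[[cc]] <- 0L
  wide <- wide[c("country", cats)]
  wide$total <- as.integer(rowSums(wide[cats]))
  dplyr::arrange(wide, dplyr::desc(.data$total), .data$country) |>
    utils::head(top_k)
}
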