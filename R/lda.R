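#' Preprocess an abstract into tokens
#'
#' Lowercases, strips punctuation and digits-only tokens are kept (alnum),
#' removes English stopwords, and drops tokens shorter than 2 characters.
#' Deterministic; an empty or whitespace-only input yields an empty token
#' vector (callers treat such records as unclassifiable).
#'
#' @param text a character scalar (abstract).
#' @param stopwords character vector of words to remove.
#' @return character vector of tokens (order preserved, duplicates kept).
#' @export
#' @examples
#' preprocess("In vitro tests of the extract.")
preprocess <- function(text, stopwords = trl_stopwords()) {
  if (length(text) != 1 || is.na(text)) text <- ""
  x <- tolower(text)
  x <- gsub("[^[:alnum:]]+", " ", x)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens <- tokens[nchar(tokens) >= 2]
  tokens[!(tokens %in% stopwords)]
}

#' Fit a latent Dirichlet allocation topic model
#'
#' Collapsed Gibbs sampling over the token streams of the corpus abstracts.
#' The returned per-document topic distributions (`theta`) and per-topic word
#' distributions (`phi`) are read off the final chain state smoothed by the
#' symmetric Dirichlet priors, so every row sums to one.
#'
#' @param corpus a `biblio_corpus`, or a list of token vectors.
#' @param K number of topics; needs at least `K` documents with non-empty
#'   token lists.
#' @param seed RNG seed (controls initialization and sampling).
#' @param iterations Gibbs sweeps (default 500).
#' @param alpha,beta symmetric Dirichlet hyperparameters (defaults `1/K` and
#'   0.01).
#' @return an object of class `lda_model`: `K`, `vocab`, `theta` (docs x K,
#'   rownames = record ids where available), `phi` (K x vocab),
#'   hyperparameters, `iterations`, `seed`, and `empty_docs` (ids of
#'   documents with no usable tokens; their theta rows are uniform).
#' @export
fit_topic_model <- function(corpus, K, seed = 1L, iterations = 500L,
                            alpha = 1 / K, beta = 0.01) {
  if (is_biblio_corpus(corpus)) {
    tokens <- lapply(corpus$abstract, preprocess)
    ids <- corpus$record_id
  } else {
    tokens <- lapply(corpus, as.character)
    ids <- names(corpus) %||% sprintf("doc%04d", seq_along(corpus))
  }
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  if (length(vocab) == 0) abort_arg("vocabulary is empty after preprocessing")
  nonempty <- lengths(tokens) > 0
  if (sum(nonempty) < K) {
    abort_arg("need at least K = ", K, " documents with non-empty token lists; have ",
              sum(nonempty))
  }
  doc_idx <- rep(seq_along(tokens), lengths(tokens))
  word_idx <- match(unlist(tokens, use.names = FALSE), vocab)

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  fit <- lda_gibbs_fit(doc_idx - 1L, word_idx - 1L,
                       n_docs = length(tokens), n_vocab = length(vocab),
                       K = as.integer(K), alpha = alpha, beta = beta,
                       iterations = as.integer(iterations))
  theta <- fit$theta
  rownames(theta) <- ids
  phi <- fit$phi
  colnames(phi) <- vocab
  structure(list(
    K = as.integer(K), vocab = vocab, theta = theta, phi = phi,
    alpha = alpha, beta = beta, iterations = as.integer(iterations),
    seed = as.integer(seed), empty_docs = ids[!nonempty]
  ), class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d, vocabulary %d terms, %d documents, %d iterations (seed %d)\n",
              x$K, length(x$vocab), nrow(x$theta), x$iterations, x$seed))
  invisible(x)
}

#' Infer a topic distribution for a new token list
#'
#' Fold-in Gibbs sampling with the fitted topic-word distributions held
#' fixed; used to embed category anchor sets as pseudo-documents.
#' Out-of-vocabulary tokens are ignored.
#'
#' @param model an `lda_model`.
#' @param tokens character vector of tokens.
#' @param seed RNG seed.
#' @param iterations fold-in sweeps.
#' @return numeric vector of length `K` summing to one.
#' @export
infer_theta <- function(model, tokens, seed = 1L, iterations = 100L) {
  stopifnot(inherits(model, "lda_model"))
  idx <- match(tokens, model$vocab)
  idx <- idx[!is.na(idx)]
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  as.numeric(lda_gibbs_infer(idx - 1L, model$phi, model$alpha,
                             as.integer(iterations)))
}

#' Top words of a topic
#'
#' @param model an `lda_model`.
#' @param topic topic index in `1..K`.
#' @param m number of words.
#' @return character vector of the `m` highest-probability words.
#' @export
top_words <- function(model, topic, m = 10) {
  stopifnot(inherits(model, "lda_model"), topic >= 1, topic <= model$K)
  if (m <= 0) return(character(0))
  p <- model$phi[topic, ]
  names(sort(p, decreasing = TRUE))[seq_len(min(m, length(p)))]
}
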