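#' Parameters for the synthetic-corpus generator
#'
#' Defaults emulate the statistical structure of the study corpus: a
#' 2002-2022 window with a post-2010 volume surge, one dominant country at
#' 66% of the mixture, block-structured author collaboration, a five-category
#' TRL mixture matching the observed classification shares, abstracts drawn
#' from per-category vocabularies diluted by a shared background vocabulary
#' (`overlap`), and heavy-tailed negative-binomial citation counts.
#'
#' @param n_records number of unique records.
#' @param year_range inclusive calendar-year window.
#' @param year_weights per-year sampling weights (default: flat to 2010,
#'   then linearly increasing).
#' @param country_mixture named probabilities for the primary country; the
#'   reserved name `OTHER` spreads its mass uniformly over the remaining
#'   gazetteer countries.
#' @param p_second_country probability a record lists a second country.
#' @param n_authors,n_blocks author pool size and number of collaboration
#'   blocks.
#' @param p_in,p_out within-block and cross-block co-author selection
#'   weights (`p_in >= p_out`; `p_out = 0` makes blocks disconnected).
#' @param authors_per_record integer range to draw the author count from.
#' @param trl_distribution named probabilities over [trl_categories()].
#' @param vocab_size per-category vocabulary size (anchor terms of the
#'   shipped keyword sets plus synthetic filler terms).
#' @param background_size shared background vocabulary size.
#' @param overlap fraction of abstract tokens drawn from the background
#'   vocabulary instead of the record's category vocabulary (0 = fully
#'   separable).
#' @param abstract_length_mean mean abstract length in tokens (Poisson,
#'   floor 30).
#' @param citation_mean,citation_dispersion negative-binomial citation
#'   parameters.
#' @param n_duplicates injected duplicate rows (half exact-DOI copies, half
#'   DOI-less title-case variants).
#' @param n_name_variants institutions that additionally appear under a
#'   variant spelling.
#' @param seed RNG seed; the same parameters and seed reproduce the corpus
#'   exactly.
#' @return a validated `synth_params` list.
#' @export
synth_params <- function(n_records = 500,
                         year_range = c(2002, 2022),
                         year_weights = NULL,
                         country_mixture = c(
                           Brazil = 0.66, `United States` = 0.13,
                           Peru = 0.07, Spain = 0.055, France = 0.05,
                           OTHER = 0.035
                         ),
                         p_second_country = 0.2,
                         n_authors = 200, n_blocks = 8,
                         p_in = 0.9, p_out = 0.02,
                         authors_per_record = 2:6,
                         trl_distribution = c(
                           TRL1 = 26, TRL2 = 834, TRL3 = 83,
                           TRL4_5 = 464, TRL6_9 = 442
                         ) / 1849,
                         vocab_size = 60, background_size = 150,
                         overlap = 0.3,
                         abstract_length_mean = 120,
                         citation_mean = 15, citation_dispersion = 1,
                         n_duplicates = 0, n_name_variants = 0,
                         seed = 1L) {
  years <- seq(year_range[1], year_range[2])
  if (is.null(year_weights)) {
    year_weights <- ifelse(years <= 2010, 1, 1 + 0.2 * (years - 2010))
  }
  stopifnot(length(year_weights) == length(years))
  p <- list(
    n_records = as.integer(n_records), years = years,
    year_weights = year_weights / sum(year_weights),
    country_mixture = country_mixture / sum(country_mixture),
    p_second_country = p_second_country,
    n_authors = as.integer(n_authors), n_blocks = as.integer(n_blocks),
    p_in = p_in, p_out = p_out,
    authors_per_record = as.integer(authors_per_record),
    trl_distribution = trl_distribution / sum(trl_distribution),
    vocab_size = as.integer(vocab_size),
    background_size = as.integer(background_size),
    overlap = overlap,
    abstract_length_mean = abstract_length_mean,
    citation_mean = citation_mean, citation_dispersion = citation_dispersion,
    n_duplicates = as.integer(n_duplicates),
    n_name_variants = as.integer(n_name_variants),
    seed = as.integer(seed)
  )
  if (p$n_blocks > p$n_authors) abort_arg("n_blocks cannot exceed n_authors")
  if (p$p_in < p$p_out) abort_arg("p_in must be >= p_out for planted-block recovery")
  if (p$overlap < 0 || p$overlap > 1) abort_arg("overlap must lie in [0, 1]")
  if (!setequal(names(p$trl_distribution), trl_categories())) {
    abort_arg("trl_distribution must be named by the five TRL categories")
  }
  if (any(p$year_weights < 0) || any(p$trl_distribution < 0) ||
      any(p$country_mixture < 0)) {
    abort_arg("probabilities must be non-negative")
  }
  structure(p, class = "synth_params")
}

# Disjoint per-category vocabularies: the shipped anchor tokens (minus any
# token shared between categories) padded with synthetic filler terms.
synth_vocabularies <- function(params, keywords = default_trl_keywords()) {
  anchors <- category_representation(keywords, mode = "token_set")
  all_tokens <- unlist(anchors, use.names = FALSE)
  shared <- unique(all_tokens[duplicated(all_tokens)])
  cats <- trl_categories()
  vocab <- lapply(cats, function(cc) {
    base <- setdiff(anchors[[cc]], shared)
    # filler tokens must be single alphanumeric words so that they survive
    # preprocessing intact and stay unique to their category
    fill <- sprintf("%sterm%02d", tolower(gsub("_", "", cc)),
                    seq_len(max(0, params$vocab_size - length(base))))
    c(base, fill)
  })
  names(vocab) <- cats
  list(
    category = vocab,
    background = sprintf("commonterm%03d", seq_len(params$background_size))
  )
}

#' Generate a synthetic bibliographic corpus with ground truth
#'
#' Emits `n_records + n_duplicates` rows together with the ground truth
#' needed to test every pipeline stage: true TRL labels, author block
#' assignments, injected duplicate pairs, and the institution name-variant
#' map.  Abstract tokens are drawn from the record's true-category
#' vocabulary with probability `1 - overlap` and from the shared background
#' vocabulary otherwise; co-authors are drawn from the lead author's block
#' with relative weight `p_in` against `p_out` per other block.
#'
#' @param params a [synth_params()] object.
#' @param keywords anchor sets whose tokens seed the category vocabularies.
#' @return list with elements `corpus` (a `biblio_corpus`) and `truth`
#'   (`trl_labels`, `author_blocks`, `duplicate_pairs`, `name_variants`,
#'   `institution_counts`, `vocabularies`).
#' @export
generate_corpus <- function(params = synth_params(),
                            keywords = default_trl_keywords()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  vocabs <- synth_vocabularies(params, keywords)
  cats <- trl_categories()

  blocks <- rep(seq_len(params$n_blocks), length.out = params$n_authors)
  blocks <- sort(blocks)
  authors <- sprintf("Author %02d-%03d", blocks, seq_len(params$n_authors))
  author_blocks <- stats::setNames(blocks, authors)
  institutions <- sprintf("Institute %02d", seq_len(params$n_blocks))
  author_inst <- institutions[blocks]

  gaz <- country_gazetteer()
  mix <- params$country_mixture
  other_pool <- setdiff(gaz, names(mix))
  draw_country <- function(exclude = character(0)) {
    repeat {
      cc <- sample(names(mix), 1, prob = mix)
      if (cc == "OTHER") cc <- sample(other_pool, 1)
      if (!(cc %in% exclude)) return(cc)
    }
  }

  n <- params$n_records
  p_same <- params$p_in /
    (params$p_in + params$p_out * max(1, params$n_blocks - 1))
  rows <- vector("list", n)
  trl_labels <- character(n)
  for (i in seq_len(n)) {
    year <- sample(params$years, 1, prob = params$year_weights)
    trl <- sample(cats, 1, prob = params$trl_distribution)
    trl_labels[i] <- trl

    k_auth <- if (length(params$authors_per_record) == 1) {
      params$authors_per_record
    } else sample(params$authors_per_record, 1)
    lead <- sample(authors, 1)
    b <- author_blocks[[lead]]
    rec_authors <- lead
    while (length(rec_authors) < k_auth) {
      pool <- if (stats::runif(1) < p_same) {
        authors[blocks == b]
      } else {
        authors[blocks != b]
      }
      pool <- setdiff(pool, rec_authors)
      if (length(pool) == 0) break
      rec_authors <- c(rec_authors, sample(pool, 1))
    }
    rec_inst <- unique(author_inst[match(rec_authors, authors)])

    country <- draw_country()
    if (stats::runif(1) < params$p_second_country) {
      country <- c(country, draw_country(exclude = country))
    }

    len <- max(30, stats::rpois(1, params$abstract_length_mean))
    from_bg <- stats::runif(len) < params$overlap
    toks <- character(len)
    toks[from_bg] <- sample(vocabs$background, sum(from_bg), replace = TRUE)
    toks[!from_bg] <- sample(vocabs$category[[trl]], sum(!from_bg), replace = TRUE)

    rows[[i]] <- tibble::tibble(
      record_id = sprintf("SYN%05d", i),
      doi = sprintf("10.5555/synth.%05d", i),
      title = sprintf("Synthetic record %05d on %s", i,
                      sample(vocabs$category[[trl]], 1)),
      abstract = paste(toks, collapse = " "),
      year = year,
      doc_type = sample(c("article", "review", "other"), 1,
                        prob = c(0.885, 0.072, 0.043)),
      language = sample(c("English", "Portuguese", "Spanish"), 1,
                        prob = c(0.903, 0.068, 0.029)),
      authors = list(rec_authors),
      institutions = list(rec_inst),
      countries = list(country),
      author_keywords = list(unique(c(sample(vocabs$category[[trl]], 3),
                                      sample(vocabs$background, 1)))),
      index_keywords = list(sample(vocabs$background, 3)),
      citation_count = stats::rnbinom(1, size = params$citation_dispersion,
                                      mu = params$citation_mean)
    )
  }
  records <- dplyr::bind_rows(rows)
  names(trl_labels) <- records$record_id

  # injected duplicates: exact-DOI copies and DOI-less title-case variants,
  # half each, exercising both deduplication keys
  dup_pairs <- tibble::tibble(original = character(0), duplicate = character(0))
  if (params$n_duplicates > 0) {
    src <- sample(records$record_id, params$n_duplicates)
    dup_rows <- vector("list", params$n_duplicates)
    for (j in seq_len(params$n_duplicates)) {
      orig <- records[records$record_id == src[j], , drop = FALSE]
      dup <- orig
      dup$record_id <- sprintf("SYNDUP%03d", j)
      if (j %% 2 == 1) {
        # exact copy sharing the DOI; equal citation count keeps the original
      } else {
        # title-case variant exercising the DOI-less fallback key: the
        # original loses its DOI too, so both fall back to title + year
        records$doi[records$record_id == src[j]] <- NA_character_
        dup$doi <- NA_character_
        dup$title <- toupper(dup$title)
        dup$citation_count <- pmax(0L, dup$citation_count - 1L)
      }
      dup_rows[[j]] <- dup
    }
    dup_pairs <- tibble::tibble(original = src,
                                duplicate = sprintf("SYNDUP%03d",
                                                    seq_len(params$n_duplicates)))
    records <- dplyr::bind_rows(records, dplyr::bind_rows(dup_rows))
  }

  # ground-truth institution tallies before any name perturbation
  inst_counts <- table(unlist(records$institutions[seq_len(n)]))

  name_variants <- character(0)
  if (params$n_name_variants > 0) {
    n_var <- min(params$n_name_variants, length(institutions))
    varied <- sample(institutions, n_var)
    variants <- sub("Institute", "Inst.", varied, fixed = TRUE)
    name_variants <- stats::setNames(varied, variants)
    for (i in seq_len(nrow(records))) {
      inst <- records$institutions[[i]]
      hit <- inst %in% varied & stats::runif(length(inst)) < 0.5
      inst[hit] <- variants[match(inst[hit], varied)]
      records$institutions[[i]] <- inst
    }
  }

  corpus <- biblio_corpus(records, provenance = list(
    source = sprintf("synthetic(seed=%d)", params$seed)
  ))
  list(
    corpus = corpus,
    truth = list(
      trl_labels = trl_labels,
      author_blocks = author_blocks,
      duplicate_pairs = dup_pairs,
      name_variants = name_variants,
      institution_counts = inst_counts,
      vocabularies = vocabs,
      params = params
    )
  )
}

#' Draw a labeled benchmark from synthetic ground truth
#'
#' Uniform sample without replacement from the generated (non-duplicate)
#' records, mirroring manual expert labeling of a random subset.
#'
#' @param truth the `truth` element of [generate_corpus()].
#' @param n_labeled benchmark size (e.g. 107).
#' @param seed RNG seed.
#' @return tibble `record_id`, `category`.
#' @export
make_benchmark <- function(truth, n_labeled, seed = 1L) {
  ids <- names(truth$trl_labels)
  if (n_labeled > length(ids)) {
    abort_arg("cannot label ", n_labeled, " records from a corpus of ",
              length(ids))
  }
  set.seed(seed)
  picked <- sample(ids, n_labeled)
  tibble::tibble(record_id = picked,
                 category = unname(truth$trl_labels[picked]))
}

#' Planted-partition benchmark graph
#'
#' Stochastic block model with equal-size blocks: within-block edge
#' probability `p_in`, cross-block `p_out`.  Used to measure community
#' recovery against known ground truth.
#'
#' @param n_blocks,block_size partition shape.
#' @param p_in,p_out edge probabilities.
#' @param seed RNG seed.
#' @return list: `graph` (igraph, unit edge weights, vertex attribute
#'   `pubs = 1`) and `blocks` (named ground-truth membership).
#' @export
planted_partition_graph <- function(n_blocks = 4, block_size = 10,
                                    p_in = 0.9, p_out = 0.02, seed = 1L) {
  set.seed(seed)
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  g <- igraph::sample_sbm(n, pref.matrix = pref,
                          block.sizes = rep(block_size, n_blocks))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::V(g)$pubs <- 1L
  igraph::E(g)$weight <- 1
  blocks <- stats::setNames(rep(seq_len(n_blocks), each = block_size),
                            igraph::V(g)$name)
  list(graph = g, blocks = blocks)
}
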