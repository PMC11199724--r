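#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported shares and citation
#' ratios so that printed tables match hand-computed values.  Base R's
#' `round()` rounds half to even, which turns 101.75 into 101.8 or 101.7
#' depending on binary representation; reporting conventions in bibliometric
#' tables expect 0.5 to round up.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be 0).
#' @return numeric vector rounded half-up (half-down for negatives, i.e. half
#'   away from zero).
#' @export
#' @examples
#' round_half_up(88.54, 1)
#' round_half_up(101.75, 0)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_arg <- function(...) stop(paste0(...), call. = FALSE)

# English stoplist (standard snowball-style function words).  Embedded as a
# constant because token filtering must be deterministic and dependency-free.
trl_stopwords <- function() {
  c(
    "a", "about", "above", "after", "again", "against", "all", "am", "an",
    "and", "any", "are", "as", "at", "be", "because", "been", "before",
    "being", "below", "between", "both", "but", "by", "can", "cannot",
    "could", "did", "do", "does", "doing", "down", "during", "each", "few",
    "for", "from", "further", "had", "has", "have", "having", "he", "her",
    "here", "hers", "herself", "him", "himself", "his", "how", "i", "if",
    "in", "into", "is", "it", "its", "itself", "just", "me", "more", "most",
    "my", "myself", "no", "nor", "not", "now", "of", "off", "on", "once",
    "only", "or", "other", "our", "ours", "ourselves", "out", "over", "own",
    "same", "she", "should", "so", "some", "such", "than", "that", "the",
    "their", "theirs", "them", "themselves", "then", "there", "these",
    "they", "this", "those", "through", "to", "too", "under", "until", "up",
    "very", "was", "we", "were", "what", "when", "where", "which", "while",
    "who", "whom", "why", "will", "with", "would", "you", "your", "yours",
    "yourself", "yourselves"
  )
}

# Minimal country gazetteer used when countries must be extracted from
# affiliation strings (Scopus convention: country is the last comma-separated
# token of each affiliation).
country_gazetteer <- function() {
  c(
    "Argentina", "Australia", "Austria", "Belgium", "Bolivia", "Brazil",
    "Canada", "Chile", "China", "Colombia", "Costa Rica", "Cuba",
    "Czech Republic", "Denmark", "Ecuador", "Egypt", "Finland", "France",
    "French Guiana", "Germany", "Greece", "Guyana", "Hungary", "India",
    "Indonesia", "Iran", "Ireland", "Israel", "Italy", "Japan", "Malaysia",
    "Mexico", "Morocco", "Netherlands", "New Zealand", "Nigeria", "Norway",
    "Pakistan", "Panama", "Paraguay", "Peru", "Poland", "Portugal",
    "Romania", "Russian Federation", "Saudi Arabia", "Singapore",
    "South Africa", "South Korea", "Spain", "Suriname", "Sweden",
    "Switzerland", "Taiwan", "Thailand", "Turkey", "Ukraine",
    "United Arab Emirates", "United Kingdom", "United States", "Uruguay",
    "Venezuela", "Vietnam"
  )
}
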