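check_distribution_pair <- function(a, b, measure) {
  if (!is.numeric(a) || !is.numeric(b)) {
    abort_arg(measure, " distance requires numeric probability vectors; ",
              "use measure = 'jaccard' for term sets")
  }
  if (length(a) != length(b)) abort_arg("distributions must have equal length")
  if (any(a < 0) || any(b < 0)) abort_arg("distributions must be non-negative")
  if (abs(sum(a) - 1) > 1e-6 || abs(sum(b) - 1) > 1e-6) {
    abort_arg("distributions must sum to 1")
  }
}

kl_core <- function(p, q, eps) {
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (q[nz] + eps)))
}

#' Distance measures for TRL classification
#'
#' The four measures compared for assigning abstracts to TRL categories.
#' Hellinger, Kullback-Leibler, and Jensen-Shannon operate on probability
#' vectors (topic distributions); Jaccard operates on term sets.  Forms:
#' `H(p,q) = sqrt(sum((sqrt(p)-sqrt(q))^2)) / sqrt(2)`;
#' `KL(p,q) = sum(p * log(p / (q + eps)))` with smoothing `eps` (KL is
#' directed: document-to-category);
#' `JS(p,q) = KL(p,m)/2 + KL(q,m)/2`, `m = (p+q)/2`, in nats (max `log(2)`);
#' `Jaccard(A,B) = 1 - |A intersect B| / |A union B|`.
#'
#' @param a,b probability vectors of equal length (distribution measures) or
#'   character vectors interpreted as sets (`jaccard`).
#' @param measure one of `"hellinger"`, `"kullback_leibler"`,
#'   `"jensen_shannon"`, `"jaccard"`.
#' @param eps smoothing constant for Kullback-Leibler (default 1e-10).
#' @return a non-negative scalar; 0 iff the arguments are equal (for KL,
#'   up to the smoothing term).
#' @export
#' @examples
#' trl_distance(c(1, 0), c(0, 1), "jensen_shannon") # log(2)
#' trl_distance(c("a", "b", "c"), c("b", "c", "d"), "jaccard") # 0.5
trl_distance <- function(a, b,
                         measure = c("jaccard", "jensen_shannon",
                                     "hellinger", "kullback_leibler"),
                         eps = 1e-10) {
  measure <- match.arg(measure)
  if (measure == "jaccard") {
    if (is.numeric(a) || is.numeric(b)) {
      abort_arg("jaccard distance requires term sets (character vectors), ",
                "not distributions")
    }
    a <- unique(as.character(a)); b <- unique(as.character(b))
    u <- length(union(a, b))
    if (u == 0) return(0) # two empty sets are identical
    return(1 - length(intersect(a, b)) / u)
  }
  check_distribution_pair(a, b, measure)
  switch(measure,
    hellinger = sqrt(sum((sqrt(a) - sqrt(b))^2)) / sqrt(2),
    kullback_leibler = kl_core(a, b, eps),
    jensen_shannon = {
      m <- (a + b) / 2
      kl_core(a, m, 0) / 2 + kl_core(b, m, 0) / 2
    }
  )
}

trl_measures <- function() {
  c("jaccard", "jensen_shannon", "hellinger", "kullback_leibler")
}
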