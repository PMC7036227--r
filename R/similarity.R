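#' Levenshtein (edit) distance
#'
#' Minimal number of insertions, deletions and substitutions transforming
#' one sequence into the other; computed with `utils::adist`. Unlike the
#' positional identity used for clone building, the edit distance compares
#' sequences of different lengths.
#'
#' @param a,b Character vectors (recycled to a common length).
#' @return Integer distances.
#' @examples
#' levenshtein_distance("kitten", "sitting") # 3
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- integer(n)
  for (i in seq_len(n)) out[i] <- as.integer(utils::adist(a[i], b[i])[1, 1])
  out
}

#' Mean pairwise Levenshtein distance of a sequence set
#'
#' @param seqs Character vector, length >= 2.
#' @return Mean over all unordered pairs.
#' @export
mean_pairwise_distance <- function(seqs) {
  if (length(seqs) < 2) stop("need at least 2 sequences")
  d <- utils::adist(seqs)
  mean(d[lower.tri(d)])
}

#' Bootstrap test of within-set sequence similarity
#'
#' Tests whether a subset of sequences (e.g. the centres of clones
#' classified as vaccine-specific) is more similar internally than random
#' subsets of the same size drawn from a pool. The statistic is the mean
#' pairwise Levenshtein distance; the null distribution is built from
#' `n_boot` draws without replacement from `pool`; the one-sided empirical
#' p-value (smaller mean = more similar) uses the add-one correction
#' `p = (1 + #[null <= observed]) / (n_boot + 1)`, so the minimum
#' attainable p at the default `n_boot = 1000` is about 0.001.
#'
#' @param subset Character vector of sequences, length >= 2.
#' @param pool Character vector to resample from (defaults should include
#'   the comparison population of clone centres).
#' @param n_boot Number of bootstrap draws (default 1000).
#' @param seed Integer seed.
#' @param length_matched If `TRUE`, each null draw matches the subset's
#'   length multiset: for every sequence length, as many pool sequences of
#'   that length are drawn as the subset contains.
#' @return A `similarity_report`: list with `observed_mean`, `null_means`,
#'   `p_value`, `n_boot`, `seed`, `length_matched`.
#' @export
bootstrap_similarity <- function(subset, pool, n_boot = 1000, seed = 1,
                                 length_matched = FALSE) {
  if (length(subset) < 2) stop("subset must contain at least 2 sequences")
  if (length(pool) < length(subset)) stop("pool smaller than subset")
  set.seed(as.integer(seed))
  observed <- mean_pairwise_distance(subset)
  if (length_matched) {
    want <- table(nchar(subset))
    have <- table(nchar(pool))
    lens <- as.integer(names(want))
    short <- lens[is.na(have[names(want)]) | have[names(want)] < want]
    if (length(short) > 0) {
      stop("pool has too few sequences of length ",
           paste(short, collapse = ", "), " for length-matched draws")
    }
    by_len <- split(pool, nchar(pool))
    draw <- function() {
      unlist(lapply(names(want), function(L) {
        sample(by_len[[L]], want[[L]], replace = FALSE)
      }), use.names = FALSE)
    }
  } else {
    draw <- function() sample(pool, length(subset), replace = FALSE)
  }
  null_means <- vapply(seq_len(n_boot),
                       function(i) mean_pairwise_distance(draw()),
                       numeric(1))
  p <- (1 + sum(null_means <= observed)) / (n_boot + 1)
  structure(
    list(observed_mean = observed, null_means = null_means, p_value = p,
         n_boot = n_boot, seed = as.integer(seed),
         length_matched = length_matched),
    class = "similarity_report"
  )
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf(
    "Similarity bootstrap: observed mean distance %.3f, null mean %.3f (sd %.3f), p = %.4g (%d draws%s)\n",
    x$observed_mean, mean(x$null_means), stats::sd(x$null_means),
    x$p_value, x$n_boot, if (x$length_matched) ", length-matched" else ""
  ))
  invisible(x)
}

#' Similarity graph over clone centres (petri-dish plot edges)
#'
#' Connects two clone centres when their Levenshtein distance is strictly
#' below `n / denom`, where `n` is by default the length of the
#' lexicographically first sequence of the pair (configurable for unequal
#' lengths). The edge list, together with the full node set, is the input
#' for petri-dish style similarity plots.
#'
#' @param centres Character vector of unique clone centre sequences.
#' @param denom Length divisor (paper-style choices: 5 for nucleotide,
#'   3 for amino-acid analyses).
#' @param n_rule How to pick `n` for a pair of unequal lengths: length of
#'   the lexicographically `"first"` sequence (default), `"min"`, `"max"`
#'   or `"mean"` of the two lengths.
#' @return A list with `nodes` (all centres) and `edges` (data.frame
#'   `from`, `to`, `distance`).
#' @export
similarity_graph <- function(centres, denom = 5,
                             n_rule = c("first", "min", "max", "mean")) {
  n_rule <- match.arg(n_rule)
  if (denom < 1) stop("denom must be >= 1")
  centres <- unique(centres)
  m <- length(centres)
  if (m < 2) {
    return(list(nodes = centres,
                edges = data.frame(from = character(0), to = character(0),
                                   distance = integer(0))))
  }
  d <- utils::adist(centres)
  from <- character(0); to <- character(0); dist <- integer(0)
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    a <- centres[i]; b <- centres[j]
    n <- switch(n_rule,
      first = nchar(min(a, b)),
      min = min(nchar(a), nchar(b)),
      max = max(nchar(a), nchar(b)),
      mean = mean(c(nchar(a), nchar(b)))
    )
    if (d[i, j] < n / denom) {
      from <- c(from, a); to <- c(to, b); dist <- c(dist, d[i, j])
    }
  }
  list(nodes = centres,
       edges = data.frame(from = from, to = to, distance = dist,
                          stringsAsFactors = FALSE))
}
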