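#' Quantile abundance threshold for one sample
#'
#' The empirical `q`-quantile (R's default, type-7 interpolated convention)
#' of the *nonzero* clone abundances in one (individual, time) sample. A
#' sample-specific quantile lets the effective count threshold track sample
#' variability such as sequencing depth. A clone counts as highly abundant
#' when its count is strictly greater than the threshold. `q = 0` returns
#' 0, i.e. every observed clone is above threshold.
#'
#' @param sample_abundances Nonzero counts of one sample.
#' @param q Quantile in \[0, 1).
#' @return Scalar count threshold.
#' @export
sample_quantile_threshold <- function(sample_abundances, q) {
  if (length(sample_abundances) == 0) stop("empty sample")
  if (q < 0 || q >= 1) stop("q must be in [0, 1)")
  if (q == 0) return(0)
  stats::quantile(sample_abundances, probs = q, names = FALSE, type = 7)
}

#' Classify clones as vaccine-specific by thresholding
#'
#' The baseline comparison method. A clone is called vaccine-specific iff
#' (a) in at least one individual its abundance is at or below the sample
#' threshold pre-vaccination (absence counts as below) *and* strictly above
#' the sample threshold at one or more post-vaccination time points —
#' by default the rise must occur within the same individual
#' (`rise_scope = "individual"`); and (b) it is observed (`x > 0` at any
#' time) in at least `min_shared` individuals.
#'
#' @param tensor An [abundance_tensor()] with a t = 0 level.
#' @param abundance_quantile Quantile in (0, 1) defining "highly abundant"
#'   per sample (e.g. 0.9, 0.99).
#' @param min_shared Minimum number of individuals sharing the clone (>= 1).
#' @param rise_scope `"individual"`: low at t = 0 and high post-vaccination
#'   in the same individual; `"any"`: the two clauses may hold in different
#'   individuals.
#' @return A data.frame with columns `clone_id`, `vaccine_specific`
#'   (logical), `n_shared`.
#' @export
classify_threshold <- function(tensor, abundance_quantile, min_shared = 1,
                               rise_scope = c("individual", "any")) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  rise_scope <- match.arg(rise_scope)
  if (min_shared < 1) stop("min_shared must be >= 1")
  if (!0 %in% tensor$time_ids) stop("tensor has no t = 0 sample")
  x <- tensor$x
  K <- dim(x)[1]; S <- dim(x)[2]; T <- dim(x)[3]
  j0 <- which(tensor$time_ids == 0)
  jpost <- which(tensor$time_ids > 0)

  thr <- matrix(0, S, T)
  for (s in seq_len(S)) for (j in seq_len(T)) {
    nz <- x[, s, j][x[, s, j] > 0]
    thr[s, j] <- if (length(nz) == 0) 0 else
      sample_quantile_threshold(nz, abundance_quantile)
  }

  low_pre <- x[, , j0, drop = FALSE] <= rep(thr[, j0], each = K)
  low_pre <- matrix(low_pre, K, S)                  # absence (0) is below
  high_post <- matrix(FALSE, K, S)
  for (j in jpost) {
    high_post <- high_post | (x[, , j] > rep(thr[, j], each = K))
  }
  rises <- if (rise_scope == "individual") {
    rowSums(low_pre & high_post) > 0
  } else {
    rowSums(low_pre) > 0 & rowSums(high_post) > 0
  }
  n_shared <- rowSums(apply(x > 0, c(1, 2), any))
  data.frame(
    clone_id = tensor$clone_ids,
    vaccine_specific = rises & n_shared >= min_shared,
    n_shared = n_shared,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Sweep threshold rules over a tensor
#'
#' Applies [classify_threshold()] for each (quantile, sharing) rule and
#' tabulates the number of vaccine-specific clones, the number of
#' sequences they contain (total abundance), and — when a truth set of
#' sequences is supplied — the percentage of those clones whose centre
#' would capture a truth sequence (the same membership rule as
#' [clone_in_truth()]).
#'
#' @param tensor An [abundance_tensor()].
#' @param rules A data.frame with columns `abundance_quantile`,
#'   `min_shared`.
#' @param clones Optional `clone_set` (required for truth agreement).
#' @param truth Optional character vector of truth-set sequences.
#' @param rise_scope Passed to [classify_threshold()].
#' @return A data.frame with one row per rule: `abundance_quantile`,
#'   `min_shared`, `n_clones`, `n_sequences`, and `agreement_pct` when
#'   truth is supplied.
#' @export
threshold_sweep <- function(tensor, rules, clones = NULL, truth = NULL,
                            rise_scope = c("individual", "any")) {
  rise_scope <- match.arg(rise_scope)
  totals <- apply(tensor$x, 1, sum)
  out <- rules[c("abundance_quantile", "min_shared")]
  out$n_clones <- NA_integer_
  out$n_sequences <- NA_real_
  if (!is.null(truth)) out$agreement_pct <- NA_real_
  for (r in seq_len(nrow(rules))) {
    cls <- classify_threshold(tensor, rules$abundance_quantile[r],
                              rules$min_shared[r], rise_scope)
    vs <- cls$vaccine_specific
    out$n_clones[r] <- sum(vs)
    out$n_sequences[r] <- sum(totals[vs])
    if (!is.null(truth) && sum(vs) > 0) {
      stopifnot(inherits(clones, "clone_set"))
      hit <- vapply(
        tensor$clone_ids[vs],
        function(id) clone_in_truth(id, clones, truth),
        logical(1)
      )
      out$agreement_pct[r] <- 100 * mean(hit)
    }
  }
  rownames(out) <- NULL
  out
}
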