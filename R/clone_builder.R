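#' Positional sequence identity
#'
#' Fraction of matching positions between two equal-length sequences
#' (Hamming identity). Sequences of different lengths are not comparable and
#' return `NA` — in the clustering rules below such pairs are never
#' neighbours.
#'
#' @param a,b Non-empty sequences.
#' @return A fraction in \[0, 1\], or `NA` if the lengths differ.
#' @examples
#' sequence_identity("ACGT", "ACGA") # 0.75
#' sequence_identity("ACGT", "ACG")  # NA: not comparable
#' @export
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (nchar(a) != nchar(b)) return(NA_real_)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  sum(av == bv) / length(av)
}

# Identity of one sequence against a character vector of same-length
# sequences, vectorized.
.identity_to_many <- function(seq, others) {
  if (length(others) == 0) return(numeric(0))
  L <- nchar(seq)
  sv <- strsplit(seq, "")[[1]]
  m <- matrix(unlist(strsplit(others, "")), nrow = L)
  colSums(m == sv) / L
}

#' Build clones by greedy same-length similarity clustering
#'
#' Groups the unique CDR3 sequences of a repertoire table into clones.
#' Two sequences are *neighbours* when they have the same length and
#' positional identity strictly greater than `threshold`. Clones are formed
#' greedily: among all unassigned sequences, the one with the greatest
#' number of unassigned neighbours becomes the next *clonal centre* and is
#' assigned to a new clone together with all its unassigned neighbours;
#' this repeats until every sequence is assigned. Ties on neighbour count
#' are broken by larger total read count, then lexicographically smaller
#' sequence, making the output deterministic.
#'
#' Clones are identified pooling all individuals and time points; per-sample
#' counts are retained in the returned abundance tensor `x[i, s, t]`, the
#' number of reads of all member sequences of clone `i` in individual `s`
#' at time `t`.
#'
#' @param table A [repertoire_table()].
#' @param threshold Identity threshold in (0, 1). Default 0.85 for
#'   nucleotide tables, 0.90 for amino-acid tables.
#' @return A list with elements `clones` (a `clone_set`) and `tensor`
#'   (an `abundance_tensor`).
#' @export
build_clones <- function(table, threshold = NULL) {
  stopifnot(inherits(table, "repertoire_table"))
  if (nrow(table) == 0) stop("empty repertoire table")
  alphabet <- attr(table, "alphabet")
  if (is.null(threshold)) threshold <- if (alphabet == "nt") 0.85 else 0.90
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")

  totals <- tapply(table$count, table$sequence, sum)
  seqs <- names(totals)             # unique sequences, sorted
  n <- length(seqs)
  abund <- as.numeric(totals)

  # Neighbour lists within same-length buckets (all-pairs per bucket).
  nbr <- vector("list", n)
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    if (length(idx) == 1) { nbr[[idx]] <- integer(0); next }
    m <- matrix(unlist(strsplit(seqs[idx], "")), nrow = L)
    sim <- matrix(0L, length(idx), length(idx))
    for (p in seq_len(L)) sim <- sim + outer(m[p, ], m[p, ], "==")
    adj <- sim / L > threshold
    diag(adj) <- FALSE
    for (j in seq_along(idx)) nbr[[idx[j]]] <- idx[adj[, j]]
  }

  unassigned <- rep(TRUE, n)
  n_unbrs <- lengths(nbr)           # unassigned-neighbour counts
  clone_of <- integer(n)
  centres <- character(0)
  k <- 0L
  while (any(unassigned)) {
    cand <- which(unassigned)
    best <- cand[n_unbrs[cand] == max(n_unbrs[cand])]
    if (length(best) > 1) {
      best <- best[abund[best] == max(abund[best])]
      if (length(best) > 1) best <- best[order(seqs[best])][1]
    }
    members <- c(best, nbr[[best]][unassigned[nbr[[best]]]])
    k <- k + 1L
    clone_of[members] <- k
    centres[k] <- seqs[best]
    unassigned[members] <- FALSE
    # decrement unassigned-neighbour counts of the survivors
    touched <- unique(unlist(nbr[members]))
    for (j in touched) {
      if (unassigned[j]) n_unbrs[j] <- sum(unassigned[nbr[[j]]])
    }
  }

  clone_ids <- sprintf("C%06d", seq_len(k))
  members_df <- data.frame(
    clone_id = clone_ids[clone_of],
    centre = centres[clone_of],
    member = seqs,
    stringsAsFactors = FALSE
  )
  members_df <- members_df[order(members_df$clone_id, members_df$member), ]
  rownames(members_df) <- NULL
  clone_set <- structure(
    list(members = members_df, threshold = threshold, alphabet = alphabet),
    class = "clone_set"
  )
  tensor <- .tensor_from_assignment(table, clone_of, clone_ids, centres)
  list(clones = clone_set, tensor = tensor)
}

# Aggregate per-sample counts of member sequences into the K x S x T tensor.
.tensor_from_assignment <- function(table, clone_of, clone_ids, centres) {
  seqs <- sort(unique(table$sequence))
  cl <- clone_of[match(table$sequence, seqs)]
  individual_ids <- sort(unique(table$individual))
  time_ids <- sort(unique(table$time))
  K <- length(clone_ids); S <- length(individual_ids); T <- length(time_ids)
  x <- array(0L, dim = c(K, S, T),
             dimnames = list(clone_ids, individual_ids, time_ids))
  i <- cl
  s <- match(table$individual, individual_ids)
  t <- match(table$time, time_ids)
  # accumulate (several records can map to the same cell)
  flat <- (t - 1L) * K * S + (s - 1L) * K + i
  acc <- tapply(table$count, flat, sum)
  x[as.integer(names(acc))] <- as.integer(acc)
  abundance_tensor(x, clone_ids, individual_ids, time_ids, centres = centres)
}

#' Construct a clonal abundance tensor
#'
#' @param x Integer array `K x S x T` of clone-by-individual-by-time counts.
#' @param clone_ids,individual_ids,time_ids Dimension identifiers;
#'   `time_ids` must be integers containing 0 (pre-vaccination) when used
#'   for model fitting.
#' @param centres Optional clone centre sequences (length K).
#' @return An object of class `abundance_tensor`.
#' @export
abundance_tensor <- function(x, clone_ids, individual_ids, time_ids,
                             centres = NULL) {
  x <- array(as.integer(x), dim = dim(x))
  stopifnot(length(dim(x)) == 3,
            dim(x)[1] == length(clone_ids),
            dim(x)[2] == length(individual_ids),
            dim(x)[3] == length(time_ids))
  if (any(x < 0)) stop("abundances must be non-negative")
  ord <- order(time_ids)
  x <- x[, , ord, drop = FALSE]
  time_ids <- as.integer(time_ids)[ord]
  dimnames(x) <- list(clone_ids, individual_ids, time_ids)
  structure(
    list(x = x, clone_ids = as.character(clone_ids),
         individual_ids = as.character(individual_ids),
         time_ids = time_ids, centres = centres),
    class = "abundance_tensor"
  )
}

#' @export
print.abundance_tensor <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "Abundance tensor: %d clones x %d individuals x %d time points (total count %s)\n",
    d[1], d[2], d[3], format(sum(as.numeric(x$x)), big.mark = ",")
  ))
  invisible(x)
}

#' @export
print.clone_set <- function(x, ...) {
  cat(sprintf(
    "Clone set: %d clones over %d sequences (%s, identity > %.2f)\n",
    length(unique(x$members$clone_id)), nrow(x$members), x$alphabet,
    x$threshold
  ))
  invisible(x)
}

#' Assign a sequence to an existing clone
#'
#' Returns the clone whose centre has the same length as `seq` and identity
#' strictly above the clone set's threshold. Among several qualifying clones
#' the one with highest identity wins; ties are broken by larger clone size,
#' then lexicographically smaller centre.
#'
#' @param seq A sequence.
#' @param clones A `clone_set` from [build_clones()].
#' @return A clone id, or `NA` if no clone qualifies.
#' @export
assign_to_clone <- function(seq, clones) {
  stopifnot(inherits(clones, "clone_set"))
  cent <- unique(clones$members[c("clone_id", "centre")])
  cand <- cent[nchar(cent$centre) == nchar(seq), , drop = FALSE]
  if (nrow(cand) == 0) return(NA_character_)
  ident <- .identity_to_many(seq, cand$centre)
  keep <- ident > clones$threshold
  if (!any(keep)) return(NA_character_)
  cand <- cand[keep, , drop = FALSE]
  ident <- ident[keep]
  sizes <- table(clones$members$clone_id)[cand$clone_id]
  ord <- order(-ident, -as.integer(sizes), cand$centre)
  cand$clone_id[ord[1]]
}
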