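#' Simulate a clonal abundance dataset from the generative model
#'
#' Draws clone classes, per-individual presence, per-sample sampling
#' indicators, leaf choices and counts exactly as the model defines them,
#' then discards clones that were observed nowhere and redraws until
#' `K_target` observed clones exist — mirroring the restriction of the
#' fitted model to clones observed at least once. The number of discarded
#' (fully unobserved) clones is recorded, and the class-frequency bias this
#' truncation induces is deliberately reproduced, not corrected.
#'
#' @param params A [mixture_params()] (generating truth).
#' @param K_target Number of observed clones to return (>= 1).
#' @param S Number of individuals (>= 1).
#' @param T Number of time points (>= 2); time ids are `0, 1, ..., T-1`
#'   unless overridden via `time_ids`.
#' @param seed Integer seed; the dataset is bit-exact reproducible from
#'   `(params, K_target, S, T, seed)`.
#' @param time_ids Optional integer time labels (must contain 0).
#' @return A `simulated_dataset`: list with `tensor`
#'   ([abundance_tensor()]), `true_class`, `true_presence` (K x S 0/1
#'   matrix), `params_used`, `seed`, `n_discarded`.
#' @export
sample_dataset <- function(params, K_target, S, T, seed,
                           time_ids = seq_len(T) - 1L) {
  stopifnot(inherits(params, "mixture_params"),
            K_target >= 1, S >= 1, T >= 2, length(time_ids) == T,
            0 %in% time_ids)
  set.seed(as.integer(seed))
  time_ids <- as.integer(sort(time_ids))

  draw_batch <- function(n) {
    cls <- sample(CLASS_LABELS, n, replace = TRUE, prob = params$Gamma)
    p_cl <- ifelse(cls == "vs", params$p[["vs"]], params$p[["bgns"]])
    z <- matrix(stats::rbinom(n * S, 1L, rep(p_cl, S)), n, S)
    x <- array(0L, dim = c(n, S, T))
    for (j in seq_len(T)) {
      t <- time_ids[j]
      reg <- ifelse(cls == "bg", "Q", ifelse(cls == "ns", "A",
                    if (t == 0) "Q" else "A"))
      for (r in REGIMES) {
        cells <- which(z == 1L & matrix(reg == r, n, S))
        if (length(cells) == 0) next
        m <- length(cells)
        sampled <- stats::rbinom(m, 1L, params$q[[r]]) == 1L
        cnt <- integer(m)
        if (any(sampled)) {
          ns_ <- sum(sampled)
          high <- stats::rbinom(ns_, 1L, params$omega[[r]]) == 1L
          v <- integer(ns_)
          if (any(!high)) {
            v[!high] <- rztnb(sum(!high), params$nb[[r]][["mu"]],
                              params$nb[[r]][["size"]])
          }
          if (any(high)) {
            g <- params$gpd[[r]]
            v[high] <- rdgpd(sum(high), g[["xi"]], g[["sigma"]], g[["u"]])
          }
          cnt[sampled] <- v
        }
        slice <- x[, , j]
        slice[cells] <- cnt
        x[, , j] <- slice
      }
    }
    list(cls = cls, z = z, x = x)
  }

  cls_all <- character(0)
  z_all <- NULL
  x_all <- NULL
  n_discarded <- 0L
  while (length(cls_all) < K_target) {
    need <- K_target - length(cls_all)
    b <- draw_batch(max(need, 1000L))
    observed <- apply(b$x > 0, 1, any)
    n_discarded <- n_discarded + sum(!observed)
    keep <- which(observed)
    if (length(keep) > need) keep <- keep[seq_len(need)]
    cls_all <- c(cls_all, b$cls[keep])
    z_all <- rbind(z_all, b$z[keep, , drop = FALSE])
    x_all <- if (is.null(x_all)) b$x[keep, , , drop = FALSE] else {
      xa <- array(0L, dim = c(dim(x_all)[1] + length(keep), S, T))
      xa[seq_len(dim(x_all)[1]), , ] <- x_all
      xa[dim(x_all)[1] + seq_along(keep), , ] <- b$x[keep, , , drop = FALSE]
      xa
    }
  }
  K <- K_target
  clone_ids <- sprintf("sim%06d", seq_len(K))
  tensor <- abundance_tensor(x_all, clone_ids,
                             sprintf("ind%02d", seq_len(S)), time_ids)
  structure(
    list(tensor = tensor,
         true_class = stats::setNames(cls_all, clone_ids),
         true_presence = z_all,
         params_used = params, seed = as.integer(seed),
         n_discarded = n_discarded),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset (seed %d): %d observed clones (%d unobserved discarded)\n",
    x$seed, length(x$true_class), x$n_discarded
  ))
  print(table(factor(x$true_class, levels = CLASS_LABELS)))
  print(x$tensor)
  invisible(x)
}

#' Paired empirical quantiles for QQ comparison of two tensors
#'
#' Matches empirical quantiles of the pooled nonzero abundance
#' distributions, and of the per-clone total abundances, between an
#' observed and a simulated tensor. Intended for QQ plotting as a model
#' check; no fit statistic is computed.
#'
#' @param observed,simulated [abundance_tensor()] objects.
#' @param probs Quantile probabilities (default 99 percentiles).
#' @return A data.frame with columns `what` (`"abundance"` or
#'   `"clone_total"`), `prob`, `observed`, `simulated`.
#' @export
qq_points <- function(observed, simulated, probs = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(inherits(observed, "abundance_tensor"),
            inherits(simulated, "abundance_tensor"))
  nz <- function(tensor) as.numeric(tensor$x[tensor$x > 0])
  totals <- function(tensor) as.numeric(apply(tensor$x, 1, sum))
  qpair <- function(what, a, b) {
    data.frame(what = what, prob = probs,
               observed = stats::quantile(a, probs, names = FALSE, type = 7),
               simulated = stats::quantile(b, probs, names = FALSE, type = 7))
  }
  rbind(
    qpair("abundance", nz(observed), nz(simulated)),
    qpair("clone_total", totals(observed), totals(simulated))
  )
}

#' Per-class, per-time abundance and sharing profiles
#'
#' For each class label and time point, reports the mean clonal relative
#' abundance — `x[i,s,t] / sum_j x[j,s,t]`, averaged over all
#' (clone, individual) pairs of the class — and the mean number of
#' individuals in which a clone of the class is observed (`x > 0`).
#'
#' @param tensor An [abundance_tensor()].
#' @param labels Character vector of class labels, one per clone (in
#'   tensor clone order), or a data.frame with columns `clone_id`, `label`.
#' @return A data.frame with columns `label`, `time`,
#'   `mean_rel_abundance`, `mean_sharing`. Classes with no clones yield NA
#'   rows.
#' @export
summarize_profiles <- function(tensor, labels) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (is.data.frame(labels)) {
    labels <- labels$label[match(tensor$clone_ids, labels$clone_id)]
  }
  stopifnot(length(labels) == length(tensor$clone_ids), !anyNA(labels))
  x <- tensor$x
  K <- dim(x)[1]; S <- dim(x)[2]; T <- dim(x)[3]
  sample_tot <- apply(x, c(2, 3), sum)
  rel <- x / rep(pmax(sample_tot, 1), each = K)  # guard empty samples
  out <- expand.grid(label = unique(labels), time = tensor$time_ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_rel_abundance <- NA_real_
  out$mean_sharing <- NA_real_
  for (r in seq_len(nrow(out))) {
    i <- which(labels == out$label[r])
    j <- which(tensor$time_ids == out$time[r])
    if (length(i) == 0) next
    out$mean_rel_abundance[r] <- mean(rel[i, , j])
    out$mean_sharing[r] <- mean(rowSums(x[i, , j, drop = FALSE] > 0))
  }
  out
}
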