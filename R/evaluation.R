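#' Is a clone represented in a truth set?
#'
#' A clone is considered present in an enrichment-derived truth set (e.g.
#' antigen-sorted or plasmablast sequences) when at least one truth
#' sequence would be assigned to it: same length as the clone centre and
#' positional identity strictly above the clustering threshold.
#'
#' @param clone_id A clone id from the clone set.
#' @param clones A `clone_set` from [build_clones()].
#' @param truth Character vector of truth-set sequences.
#' @return Logical flag.
#' @export
clone_in_truth <- function(clone_id, clones, truth) {
  stopifnot(inherits(clones, "clone_set"))
  centre <- clones$members$centre[match(clone_id, clones$members$clone_id)]
  if (is.na(centre)) stop("unknown clone id: ", clone_id)
  truth <- unique(toupper(truth))
  cand <- truth[nchar(truth) == nchar(centre)]
  if (length(cand) == 0) return(FALSE)
  any(.identity_to_many(centre, cand) > clones$threshold)
}

#' Compare a classification against an enrichment-derived truth set
#'
#' Builds the per-class summary: number of clones, mean and standard
#' deviation of total clone abundance, the same restricted to the clones
#' that overlap the truth set, and the overlap fraction. The
#' vaccine-specific overlap fraction is reported as `sensitivity` — an
#' operational, truth-set-limited quantity. Enrichment of the
#' vaccine-specific class relative to background is tested by a chi-squared
#' test on the 2x2 table (class in \{vs, bg\}) x (in truth: yes/no),
#' without continuity correction by default.
#'
#' @param labels Character vector of class labels per clone (tensor order)
#'   or a data.frame with `clone_id`, `label` columns.
#' @param tensor An [abundance_tensor()].
#' @param clones A `clone_set` (supplies centres and the identity
#'   threshold).
#' @param truth Character vector of truth-set sequences.
#' @param yates Apply Yates continuity correction (default `FALSE`).
#' @return A `truth_comparison`: list with `table` (per-class data.frame),
#'   `sensitivity`, `chisq_stat`, `p_value`, `in_truth` (per-clone logical).
#' @export
compare_to_truth <- function(labels, tensor, clones, truth, yates = FALSE) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (is.data.frame(labels)) {
    labels <- labels$label[match(tensor$clone_ids, labels$clone_id)]
  }
  stopifnot(length(labels) == length(tensor$clone_ids), !anyNA(labels))
  totals <- apply(tensor$x, 1, sum)
  in_truth <- vapply(tensor$clone_ids,
                     function(id) clone_in_truth(id, clones, truth),
                     logical(1))
  lv <- intersect(c(CLASS_LABELS, "UNASSIGNED"), unique(labels))
  per_class <- do.call(rbind, lapply(lv, function(cl) {
    i <- labels == cl
    k <- i & in_truth
    data.frame(
      label = cl,
      n_clones = sum(i),
      mean_abundance = if (any(i)) mean(totals[i]) else NA_real_,
      sd_abundance = if (sum(i) > 1) stats::sd(totals[i]) else NA_real_,
      n_in_truth = sum(k),
      mean_abundance_in_truth = if (any(k)) mean(totals[k]) else NA_real_,
      sd_abundance_in_truth = if (sum(k) > 1) stats::sd(totals[k]) else NA_real_,
      fraction_in_truth = if (any(i)) mean(in_truth[i]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_class) <- NULL

  vs_row <- per_class[per_class$label == "vs", ]
  sensitivity <- if (nrow(vs_row) == 1) vs_row$fraction_in_truth else NA_real_

  tab <- table(
    factor(labels[labels %in% c("vs", "bg")], levels = c("vs", "bg")),
    factor(in_truth[labels %in% c("vs", "bg")], levels = c(TRUE, FALSE))
  )
  chisq_stat <- p_value <- NA_real_
  if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = yates))
    chisq_stat <- unname(ct$statistic)
    p_value <- ct$p.value
  } else {
    warning("degenerate 2x2 table; chi-squared test not computed")
  }
  structure(
    list(table = per_class, sensitivity = sensitivity,
         chisq_stat = chisq_stat, p_value = p_value,
         in_truth = stats::setNames(in_truth, tensor$clone_ids)),
    class = "truth_comparison"
  )
}

#' @export
print.truth_comparison <- function(x, ...) {
  cat("Truth-set comparison\n")
  print(x$table, digits = 4)
  cat(sprintf("Sensitivity (vs-class overlap fraction): %.3f\n", x$sensitivity))
  if (!is.na(x$p_value)) {
    cat(sprintf("vs-vs-bg enrichment: chi-squared = %.3f, two-tailed p = %.4g\n",
                x$chisq_stat, x$p_value))
  }
  invisible(x)
}
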