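# Tabular output helpers and the end-to-end pipeline driver.

.write_tsv <- function(df, path, header_lines = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

.provenance <- function(seed = NULL, extra = character(0)) {
  c(sprintf("clonemix %s", as.character(utils::packageVersion("clonemix"))),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
    extra)
}

#' Write clone membership and abundance tensor as TSV
#'
#' `write_clones` emits one row per (member sequence, individual, time)
#' with its count; `write_tensor` emits the tensor in long form
#' (`clone_id`, `individual`, `time`, `abundance`), zero cells omitted.
#' `read_tensor` reads the long form back (zero cells restored).
#'
#' @param clones A `clone_set`.
#' @param table The [repertoire_table()] the clones were built from.
#' @param tensor An [abundance_tensor()].
#' @param path Output path.
#' @param header_lines Optional provenance comment lines (prefixed `# `).
#' @return The path, invisibly (`read_tensor`: an `abundance_tensor`).
#' @export
write_clones <- function(clones, table, path, header_lines = .provenance()) {
  stopifnot(inherits(clones, "clone_set"), inherits(table, "repertoire_table"))
  j <- match(table$sequence, clones$members$member)
  df <- data.frame(
    clone_id = clones$members$clone_id[j],
    centre = clones$members$centre[j],
    member = table$sequence,
    individual = table$individual,
    time = table$time,
    count = table$count,
    stringsAsFactors = FALSE
  )
  df <- df[order(df$clone_id, df$member, df$individual, df$time), ]
  .write_tsv(df, path, header_lines)
}

#' @rdname write_clones
#' @export
write_tensor <- function(tensor, path, header_lines = .provenance()) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  idx <- which(tensor$x > 0, arr.ind = TRUE)
  df <- data.frame(
    clone_id = tensor$clone_ids[idx[, 1]],
    individual = tensor$individual_ids[idx[, 2]],
    time = tensor$time_ids[idx[, 3]],
    abundance = tensor$x[idx],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$clone_id, df$individual, df$time), ]
  .write_tsv(df, path, header_lines)
}

#' @rdname write_clones
#' @export
read_tensor <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  needed <- c("clone_id", "individual", "time", "abundance")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("tensor file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  clone_ids <- sort(unique(df$clone_id))
  individual_ids <- sort(unique(df$individual))
  time_ids <- sort(unique(as.integer(df$time)))
  x <- array(0L, dim = c(length(clone_ids), length(individual_ids),
                         length(time_ids)))
  i <- match(df$clone_id, clone_ids)
  s <- match(df$individual, individual_ids)
  t <- match(as.integer(df$time), time_ids)
  x[cbind(i, s, t)] <- as.integer(df$abundance)
  abundance_tensor(x, clone_ids, individual_ids, time_ids)
}

#' Run the full analysis pipeline
#'
#' Clusters sequences into clones, fits the mixture model, classifies
#' clones, and optionally runs the thresholding baseline, the similarity
#' bootstrap and the truth-set evaluation, writing all artifacts to
#' `out_dir`. Configuration may come from a YAML file (`config`) with the
#' same field names as the arguments; explicit arguments override the file.
#' Given fixed seeds the run is fully deterministic.
#'
#' @param input Path to a repertoire TSV (columns `sequence`,
#'   `individual`, `time`, `count`), or a [repertoire_table()].
#' @param out_dir Output directory (created if needed).
#' @param config Optional YAML file path with default values for the
#'   remaining arguments.
#' @param alphabet `"nt"`, `"aa"` or `NULL` (auto-detect).
#' @param clustering_threshold Identity threshold for [build_clones()].
#' @param init Optional params JSON path or [mixture_params()] for EM
#'   initialization.
#' @param tol,max_iter EM convergence controls.
#' @param seed Seed used for the similarity bootstrap.
#' @param run_threshold Optional data.frame of threshold rules for
#'   [threshold_sweep()].
#' @param truth Optional truth-set sequences (character vector or path to
#'   a one-column text file).
#' @param n_boot Bootstrap draws for the similarity test.
#' @param verbose Log progress to stderr.
#' @return Invisibly, a list with the in-memory results (`clones`,
#'   `tensor`, `fit`, `labels`, and any optional analyses).
#' @export
run_pipeline <- function(input, out_dir, config = NULL, alphabet = NULL,
                         clustering_threshold = NULL, init = NULL,
                         tol = 1e-6, max_iter = 500, seed = 1,
                         run_threshold = NULL, truth = NULL, n_boot = 1000,
                         verbose = TRUE) {
  if (!is.null(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("config files require the yaml package")
    }
    cfg <- yaml::read_yaml(config)
    for (nm in c("alphabet", "clustering_threshold", "tol", "max_iter",
                 "seed", "n_boot", "truth", "init")) {
      if (is.null(get(nm)) && !is.null(cfg[[nm]])) assign(nm, cfg[[nm]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))

  table <- if (inherits(input, "repertoire_table")) input else
    read_repertoire(input, format = "tsv", alphabet = alphabet)
  log_msg("read %d records (%d unique sequences)", nrow(table),
          length(unique(table$sequence)))

  built <- build_clones(table, threshold = clustering_threshold)
  log_msg("built %d clones", length(built$tensor$clone_ids))
  prov <- .provenance(seed, sprintf("clustering threshold: %.2f",
                                    built$clones$threshold))
  write_clones(built$clones, table, file.path(out_dir, "clones.tsv"), prov)
  write_tensor(built$tensor, file.path(out_dir, "tensor.tsv"), prov)

  if (is.character(init)) init <- read_params(init)
  if (is.null(init)) init <- default_init_params()
  fit <- fit_mixture(built$tensor, init = init, tol = tol,
                     max_iter = max_iter, verbose = verbose)
  log_msg("EM: %d iterations, %sconverged", fit$n_iter,
          if (fit$converged) "" else "NOT ")
  write_params(fit$params, file.path(out_dir, "params.json"))

  labels <- classify_clones(fit)
  centres <- built$tensor$centres
  labels$centre <- centres[match(labels$clone_id, built$tensor$clone_ids)]
  labels <- labels[c("clone_id", "centre", "P_bg", "P_ns", "P_vs", "label")]
  .write_tsv(labels, file.path(out_dir, "labels.tsv"), prov)

  results <- list(clones = built$clones, tensor = built$tensor, fit = fit,
                  labels = labels)

  if (is.character(truth) && length(truth) == 1 && file.exists(truth)) {
    truth <- readLines(truth)
    truth <- truth[nzchar(truth) & !startsWith(truth, "#")]
  }
  if (!is.null(run_threshold)) {
    sweep <- threshold_sweep(built$tensor, run_threshold,
                             clones = built$clones, truth = truth)
    .write_tsv(sweep, file.path(out_dir, "threshold_sweep.tsv"), prov)
    results$threshold_sweep <- sweep
  }
  vs_centres <- labels$centre[labels$label == "vs"]
  if (length(vs_centres) >= 2) {
    rep_sim <- bootstrap_similarity(vs_centres, unique(labels$centre),
                                    n_boot = n_boot, seed = seed)
    jsonlite::write_json(
      list(observed_mean = rep_sim$observed_mean, p_value = rep_sim$p_value,
           n_boot = rep_sim$n_boot, seed = rep_sim$seed),
      file.path(out_dir, "similarity.json"), auto_unbox = TRUE, digits = NA
    )
    results$similarity <- rep_sim
  }
  if (!is.null(truth)) {
    cmp <- compare_to_truth(labels, built$tensor, built$clones, truth)
    .write_tsv(cmp$table, file.path(out_dir, "truth_comparison.tsv"), prov)
    results$truth_comparison <- cmp
  }
  invisible(results)
}
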