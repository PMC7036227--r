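#' Construct a repertoire table of CDR3 counts
#'
#' A repertoire table holds the observed CDR3 sequence counts per
#' (individual, time point) sample, in long format. Records with identical
#' (sequence, individual, time) keys are aggregated by summing counts.
#'
#' @param sequence Character vector of CDR3 sequences (one alphabet per
#'   table: nucleotide or amino-acid).
#' @param individual Individual identifiers (coerced to character).
#' @param time Integer time points (days); 0 denotes pre-vaccination.
#' @param count Positive integer counts.
#' @param alphabet `"nt"`, `"aa"`, or `NULL` to auto-detect.
#' @return A `data.frame` of class `repertoire_table` with columns
#'   `sequence`, `individual`, `time`, `count` and attribute `alphabet`.
#' @export
repertoire_table <- function(sequence, individual, time, count,
                             alphabet = NULL) {
  if (length(sequence) == 0) stop("empty repertoire table")
  n <- length(sequence)
  sequence <- toupper(as.character(sequence))
  individual <- rep_len(as.character(individual), n)
  time <- rep_len(as.integer(time), n)
  count <- rep_len(as.integer(count), n)
  if (any(is.na(time)) || any(time < 0)) stop("time must be non-negative integers")
  if (any(is.na(count)) || any(count < 1)) stop("counts must be integers >= 1")
  if (is.null(alphabet)) alphabet <- detect_alphabet(sequence)
  check_alphabet(sequence, alphabet)
  df <- stats::aggregate(
    list(count = count),
    by = list(sequence = sequence, individual = individual, time = time),
    FUN = sum
  )
  df <- df[order(df$sequence, df$individual, df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, alphabet = alphabet,
            class = c("repertoire_table", "data.frame"))
}

#' Read a repertoire table from TSV, AIRR-style TSV or FASTA
#'
#' * `format = "tsv"`: tab-delimited with header and columns `sequence`,
#'   `individual`, `time`, `count`.
#' * `format = "airr"`: AIRR-rearrangement-style TSV; the sequence is taken
#'   from `junction` (nucleotide) or `junction_aa` (amino-acid), counts from
#'   `duplicate_count` (default 1 if absent), and the sample-to-individual /
#'   time mapping is supplied via `samples`, a data.frame with columns
#'   `sample_id`, `individual`, `time` matched against the file's
#'   `sample_id` column.
#' * `format = "fasta"`: headers of the form `id|individual|time|count`
#'   (requires the Biostrings package).
#'
#' @param path File path.
#' @param format One of `"tsv"`, `"airr"`, `"fasta"`.
#' @param alphabet `"nt"`, `"aa"` or `NULL` (auto-detect).
#' @param samples Sample metadata for `format = "airr"` (see above).
#' @return A [repertoire_table()].
#' @export
read_repertoire <- function(path, format = c("tsv", "airr", "fasta"),
                            alphabet = NULL, samples = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("reading FASTA requires the Biostrings package")
    }
    ss <- Biostrings::readBStringSet(path)
    parts <- strsplit(names(ss), "|", fixed = TRUE)
    bad <- which(lengths(parts) != 4)
    if (length(bad) > 0) {
      stop("FASTA headers must be 'id|individual|time|count' (record ",
           bad[1], " is not)")
    }
    meta <- do.call(rbind, parts)
    return(repertoire_table(
      sequence = as.character(ss), individual = meta[, 2],
      time = as.integer(meta[, 3]), count = as.integer(meta[, 4]),
      alphabet = alphabet
    ))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "airr") {
    seq_col <- if (identical(alphabet, "aa")) "junction_aa" else
      if ("junction" %in% names(df)) "junction" else "junction_aa"
    needed <- c(seq_col, "sample_id")
    missing_cols <- setdiff(needed, names(df))
    if (length(missing_cols) > 0) {
      stop("AIRR input is missing required column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    if (is.null(samples)) stop("format = 'airr' requires a samples mapping")
    idx <- match(df$sample_id, samples$sample_id)
    if (anyNA(idx)) {
      stop("sample_id values missing from the samples mapping: ",
           paste(unique(df$sample_id[is.na(idx)]), collapse = ", "))
    }
    cnt <- if ("duplicate_count" %in% names(df)) df$duplicate_count else 1L
    return(repertoire_table(
      sequence = df[[seq_col]], individual = samples$individual[idx],
      time = samples$time[idx], count = cnt, alphabet = alphabet
    ))
  }
  needed <- c("sequence", "individual", "time", "count")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("input is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  repertoire_table(df$sequence, df$individual, df$time, df$count,
                   alphabet = alphabet)
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat(sprintf(
    "Repertoire table: %d records, %d unique sequences (%s), %d individuals, time points %s\n",
    nrow(x), length(unique(x$sequence)), attr(x, "alphabet"),
    length(unique(x$individual)),
    paste(sort(unique(x$time)), collapse = ", ")
  ))
  NextMethod()
}
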