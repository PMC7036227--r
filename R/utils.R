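# Internal numeric helpers. All likelihood work is done in log space.

# log(1 - exp(x)) for x <= 0, stable near both ends (Maechler's switch point).
log1mexp <- function(x) {
  stopifnot(all(x <= 0 | is.nan(x)))
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# log(exp(a) + exp(b)) elementwise, tolerating -Inf in either argument.
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  out <- mx + log(rowSums(exp(m - mx)))
  out[is.infinite(mx) & mx < 0] <- -Inf
  out
}

.clamp01 <- function(p, floor = 1e-12, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else floor
  pmin(pmax(p, lo), 1 - floor)
}

CLASS_LABELS <- c("bg", "ns", "vs")
REGIMES <- c("Q", "A")

# Abundance regime per (class, time): background always quiet; non-specific
# always active; vaccine-specific quiet pre-vaccination, active after.
regime_for <- function(class, t) {
  stopifnot(class %in% CLASS_LABELS)
  switch(class,
    bg = "Q",
    ns = "A",
    vs = if (t == 0) "Q" else "A"
  )
}

ALPHABETS <- list(
  nt = c("A", "C", "G", "T"),
  aa = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
)

check_alphabet <- function(sequences, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (any(!nzchar(sequences))) stop("empty sequence in input")
  letters_seen <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(letters_seen, ALPHABETS[[alphabet]])
  if (length(bad) > 0) {
    stop(sprintf(
      "sequences contain letters outside the '%s' alphabet: %s",
      alphabet, paste(bad, collapse = ", ")
    ))
  }
  invisible(alphabet)
}

# Guess nt vs aa from the letters present; nucleotide wins when ambiguous.
detect_alphabet <- function(sequences) {
  letters_seen <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  if (all(letters_seen %in% ALPHABETS$nt)) "nt"
  else if (all(letters_seen %in% ALPHABETS$aa)) "aa"
  else stop("sequences fit neither the nucleotide nor the amino-acid alphabet")
}
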