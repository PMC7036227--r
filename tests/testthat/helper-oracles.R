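# Independent reference implementations used as test oracles. These are
# deliberately naive (quadratic DP, exhaustive enumeration) and share no
# code with the package internals they check.

# Classic quadratic dynamic-programming edit distance.
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (av[i] != bv[j]))
  }
  d[n + 1, m + 1]
}

# Literal restatement of the greedy clustering rule: all-pairs identity,
# repeatedly pick the unassigned sequence with most unassigned neighbours
# (ties: larger total abundance, then lexicographically smaller), assign it
# and its unassigned neighbours. Returns the partition as a membership map.
oracle_greedy_clones <- function(seqs, abund, threshold) {
  n <- length(seqs)
  idmat <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && nchar(seqs[i]) == nchar(seqs[j])) {
      ai <- strsplit(seqs[i], "")[[1]]; bj <- strsplit(seqs[j], "")[[1]]
      idmat[i, j] <- mean(ai == bj) > threshold
    }
  }
  assigned <- rep(NA_integer_, n)
  k <- 0
  while (anyNA(assigned)) {
    un <- which(is.na(assigned))
    cnt <- vapply(un, function(i) sum(idmat[i, un]), numeric(1))
    best <- un[cnt == max(cnt)]
    if (length(best) > 1) best <- best[abund[best] == max(abund[best])]
    if (length(best) > 1) best <- best[order(seqs[best])][1]
    k <- k + 1
    members <- c(best, un[idmat[best, un]])
    assigned[unique(members)] <- k
  }
  split(seqs, assigned)
}

# Exhaustive enumeration of the latent variables (class gamma; presence z
# over individuals; leaf e over cells) for one clone's S x T count matrix.
# Returns class-conditional log-likelihoods.
oracle_clone_loglik <- function(x_i, params, time_ids) {
  x_i <- rbind(x_i)
  S <- nrow(x_i); T <- ncol(x_i)
  leaf_lp <- function(x, leaf, reg) {
    if (leaf == 1) { if (x == 0) 0 else -Inf }                    # ZERO
    else if (leaf == 2) {                                         # LOW
      if (x < 1) -Inf else
        clonemix::log_pmf_ztnb(x, params$nb[[reg]][["mu"]],
                               params$nb[[reg]][["size"]])
    } else {                                                      # HIGH
      g <- params$gpd[[reg]]
      if (x < g[["u"]]) -Inf else
        clonemix::log_pmf_dgpd(x, g[["xi"]], g[["sigma"]], g[["u"]])
    }
  }
  out <- numeric(3)
  names(out) <- c("bg", "ns", "vs")
  for (cls in names(out)) {
    p <- if (cls == "vs") params$p[["vs"]] else params$p[["bgns"]]
    tot <- 0
    for (zcfg in 0:(2^S - 1)) {
      z <- as.integer(intToBits(zcfg))[1:S]
      pz <- prod(ifelse(z == 1, p, 1 - p))
      like <- 1
      for (s in 1:S) for (j in 1:T) {
        t <- time_ids[j]
        reg <- if (cls == "bg") "Q" else if (cls == "ns") "A" else
          if (t == 0) "Q" else "A"
        q <- params$q[[reg]]; w <- params$omega[[reg]]
        cell <- 0
        for (leaf in 1:3) {
          pe <- if (z[s] == 0) { if (leaf == 1) 1 else 0 } else {
            c(1 - q, q * (1 - w), q * w)[leaf]
          }
          if (pe > 0) cell <- cell + pe * exp(leaf_lp(x_i[s, j], leaf, reg))
        }
        like <- like * cell
      }
      tot <- tot + pz * like
    }
    out[cls] <- log(tot)
  }
  out
}

# Joint log-probability and responsibilities for a whole tensor, by
# exhaustive enumeration per clone.
oracle_fit_quantities <- function(tensor, params) {
  K <- dim(tensor$x)[1]
  ll <- t(vapply(seq_len(K), function(i) {
    oracle_clone_loglik(tensor$x[i, , ], params, tensor$time_ids)
  }, numeric(3)))
  lp <- sweep(ll, 2, log(params$Gamma), "+")
  lp[, params$Gamma == 0] <- -Inf
  lse <- apply(lp, 1, function(r) { m <- max(r); m + log(sum(exp(r - m))) })
  list(joint = sum(lse), resp = exp(lp - lse), ll = ll)
}

# Small random abundance tensor for property tests.
random_tensor <- function(K, S, T, seed, lambda = 1.2, p_zero = 0.55) {
  set.seed(seed)
  x <- array(0L, dim = c(K, S, T))
  nz <- stats::runif(K * S * T) > p_zero
  x[nz] <- 1L + stats::rpois(sum(nz), lambda)
  # heavy cells now and then
  big <- stats::runif(K * S * T) > 0.97
  x[big] <- x[big] + stats::rgeom(sum(big), 0.05)
  if (all(x == 0)) x[1] <- 1L
  clonemix::abundance_tensor(x, sprintf("c%03d", 1:K),
                             sprintf("s%02d", 1:S), 0:(T - 1))
}

# Random mixture params with moderate values, for property tests.
random_params <- function(seed) {
  set.seed(seed)
  g <- stats::runif(3, 0.1, 1); g <- g / sum(g)
  clonemix::mixture_params(
    Gamma = c(bg = g[1], ns = g[2], vs = g[3]),
    p = c(bgns = stats::runif(1, 0.2, 0.8), vs = stats::runif(1, 0.2, 0.9)),
    q = c(Q = stats::runif(1, 0.3, 0.9), A = stats::runif(1, 0.3, 0.9)),
    omega = c(Q = stats::runif(1, 0.02, 0.3), A = stats::runif(1, 0.1, 0.5)),
    nb = list(Q = c(mu = stats::runif(1, 0.5, 3), size = stats::runif(1, 0.5, 2)),
              A = c(mu = stats::runif(1, 3, 10), size = stats::runif(1, 0.5, 2))),
    gpd = list(Q = c(xi = stats::runif(1, 0, 0.5), sigma = stats::runif(1, 2, 15), u = 1),
               A = c(xi = stats::runif(1, 0, 0.8), sigma = stats::runif(1, 10, 50), u = 1))
  )
}

# Small random repertoire table of nucleotide sequences.
random_repertoire <- function(n_unique, seed, lengths = c(6L, 8L),
                              S = 2, times = c(0L, 7L)) {
  set.seed(seed)
  seqs <- unique(vapply(seq_len(n_unique * 2), function(i) {
    L <- sample(lengths, 1)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))[seq_len(n_unique)]
  seqs <- seqs[!is.na(seqs)]
  recs <- do.call(rbind, lapply(seqs, function(sq) {
    k <- sample(1:3, 1)
    data.frame(sequence = sq,
               individual = sample(sprintf("s%d", 1:S), k, replace = TRUE),
               time = sample(times, k, replace = TRUE),
               count = sample(1:5, k, replace = TRUE))
  }))
  clonemix::repertoire_table(recs$sequence, recs$individual, recs$time,
                             recs$count, alphabet = "nt")
}
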