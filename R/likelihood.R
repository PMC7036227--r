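# Model probability computations.
#
# Generative structure per clone i of class gamma_i:
#   per individual s:   z_is ~ Bernoulli(p_class)      (presence)
#   per sample (s,t), given z_is = 1:
#     sampled ~ Bernoulli(q_regime)                    (escaped sampling if 0)
#     if sampled: leaf ~ Bernoulli(omega_regime) between
#       LOW  = zero-truncated negative binomial
#       HIGH = discretized generalized Pareto
#   z_is = 0, or an unsampled clone, yields a point mass at x = 0.
# Regimes: bg -> Q always; ns -> A always; vs -> Q at t = 0, A at t > 0.

#' Leaf log-probability of the abundance mixture
#'
#' @param x Integer count(s) >= 0.
#' @param leaf One of `"ZERO"`, `"LOW"`, `"HIGH"`.
#' @param params A [mixture_params()].
#' @param regime `"Q"` or `"A"`.
#' @return Log-probabilities.
#' @export
leaf_log_pmf <- function(x, leaf = c("ZERO", "LOW", "HIGH"), params, regime) {
  leaf <- match.arg(leaf)
  regime <- match.arg(regime, REGIMES)
  switch(leaf,
    ZERO = ifelse(x == 0, 0, -Inf),
    LOW = {
      out <- rep(-Inf, length(x))
      ok <- x >= 1
      if (any(ok)) out[ok] <- log_pmf_ztnb(x[ok], params$nb[[regime]][["mu"]],
                                           params$nb[[regime]][["size"]])
      out
    },
    HIGH = {
      g <- params$gpd[[regime]]
      out <- rep(-Inf, length(x))
      ok <- x >= g[["u"]]
      if (any(ok)) out[ok] <- log_pmf_dgpd(x[ok], g[["xi"]], g[["sigma"]], g[["u"]])
      out
    }
  )
}

# Log-probability of one count under the present branch of one regime:
#   (1-q) 1{x=0} + q [ (1-omega) ZTNB(x) + omega dGPD(x) ]
.log_obs_present <- function(x, params, regime) {
  q <- params$q[[regime]]
  w <- params$omega[[regime]]
  out <- numeric(length(x))
  z <- x == 0
  out[z] <- if (q < 1) log1p(-q) else -Inf
  if (any(!z)) {
    xl <- x[!z]
    lo <- leaf_log_pmf(xl, "LOW", params, regime)
    hi <- leaf_log_pmf(xl, "HIGH", params, regime)
    lmix <- logaddexp(
      if (w < 1) log1p(-w) + lo else rep(-Inf, length(xl)),
      if (w > 0) log(w) + hi else rep(-Inf, length(xl))
    )
    out[!z] <- (if (q > 0) log(q) else -Inf) + lmix
  }
  out
}

#' Per-sample observation log-likelihood
#'
#' Log-probability of a single count `x` for a clone of a given class at
#' time `t`, conditional on the clone's presence indicator for that
#' individual. An absent clone yields a point mass at 0; a present clone
#' may escape sampling (probability `1 - q`) or be observed from the
#' low/high-abundance leaf mixture.
#'
#' @param x Integer count >= 0 (vectorized).
#' @param class `"bg"`, `"ns"` or `"vs"`.
#' @param t Time point (0 = pre-vaccination).
#' @param present 0 or 1, the presence indicator `z`.
#' @param params A [mixture_params()].
#' @return Log-probabilities.
#' @export
obs_log_lik_per_sample <- function(x, class, t, present, params) {
  class <- match.arg(class, CLASS_LABELS)
  if (present == 0) return(ifelse(x == 0, 0, -Inf))
  .log_obs_present(x, params, regime_for(class, t))
}

#' Clone-level marginal log-likelihood under one class
#'
#' Marginalizes the per-individual presence variable: for each individual,
#' `(1 - p_class)` times the all-zero point mass plus `p_class` times the
#' product over time points of the present-branch observation likelihood;
#' the per-individual log terms are summed.
#'
#' @param x_i Integer matrix `S x T` of counts for one clone (columns in the
#'   order of `time_ids`).
#' @param class `"bg"`, `"ns"` or `"vs"`.
#' @param params A [mixture_params()].
#' @param time_ids Integer time points labelling the columns of `x_i`
#'   (default `0:(T-1)`); only the distinction t = 0 vs t > 0 matters.
#' @return Scalar log-likelihood.
#' @export
clone_log_lik <- function(x_i, class, params, time_ids = NULL) {
  class <- match.arg(class, CLASS_LABELS)
  x_i <- rbind(x_i)
  if (is.null(time_ids)) time_ids <- seq_len(ncol(x_i)) - 1L
  stopifnot(length(time_ids) == ncol(x_i))
  p <- if (class == "vs") params$p[["vs"]] else params$p[["bgns"]]
  ll <- 0
  for (s in seq_len(nrow(x_i))) {
    lp_present <- sum(vapply(
      seq_along(time_ids),
      function(j) obs_log_lik_per_sample(x_i[s, j], class, time_ids[j], 1L, params),
      numeric(1)
    ))
    if (all(x_i[s, ] == 0)) {
      ll <- ll + logaddexp(log1p(-p), log(p) + lp_present)
    } else {
      ll <- ll + log(p) + lp_present
    }
  }
  ll
}

#' Joint (marginal MAP) log-probability of an abundance tensor
#'
#' The EM objective: sum over clones of the log of the class-mixture
#' likelihood, `sum_i log sum_c Gamma_c exp(clone_log_lik(x_i, c))`, plus
#' log-prior terms. With the package's non-informative priors (flat
#' Dirichlet on `Gamma`, flat Beta on all probabilities, flat improper on
#' the count-distribution parameters) the prior contribution is a constant
#' zero, so the objective coincides with the marginal log-likelihood.
#'
#' @param tensor An [abundance_tensor()].
#' @param params A [mixture_params()].
#' @return Scalar log-probability.
#' @export
joint_log_prob <- function(tensor, params) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  ll <- .class_loglik_matrix(tensor, params)$ll   # K x 3
  lg <- ifelse(params$Gamma > 0, log(params$Gamma), -Inf)
  sum(row_logsumexp(sweep(ll, 2, lg, "+")))
}

# ---- fast vectorized internals -------------------------------------------
#
# All EM-critical quantities are computed from a lookup table of
# per-unique-count log-probabilities per regime, gathered into K x (S*T)
# matrices. Column order is individual-major: column (s-1)*T + j holds time
# time_ids[j] of individual s, with time_ids sorted so t = 0 is first.

.tensor_layout <- function(tensor) {
  d <- dim(tensor$x)
  K <- d[1]; S <- d[2]; T <- d[3]
  # aperm to K x T x S then flatten: columns individual-major, time within
  Xflat <- matrix(aperm(tensor$x, c(1, 3, 2)), nrow = K)
  ux <- sort(unique(as.vector(Xflat)))
  idx <- matrix(match(Xflat, ux), nrow = K)
  scol <- rep(seq_len(S), each = T)          # individual of each column
  tcol <- rep(tensor$time_ids, times = S)    # time of each column
  list(K = K, S = S, T = T, Xflat = Xflat, ux = ux, idx = idx,
       scol = scol, tcol = tcol, t0 = tcol == 0)
}

# Per-regime lookup over unique counts: present-branch log-probability and
# posterior probability of the HIGH leaf given an observed (x > 0) count.
.regime_lut <- function(ux, params, regime) {
  logf <- .log_obs_present(ux, params, regime)
  ph <- numeric(length(ux))
  pos <- ux > 0
  if (any(pos)) {
    w <- params$omega[[regime]]
    lo <- leaf_log_pmf(ux[pos], "LOW", params, regime)
    hi <- leaf_log_pmf(ux[pos], "HIGH", params, regime)
    la <- if (w < 1) log1p(-w) + lo else rep(-Inf, sum(pos))
    lb <- if (w > 0) log(w) + hi else rep(-Inf, sum(pos))
    ph[pos] <- 1 / (1 + exp(la - lb))   # -> 0 when w = 0, 1 when w = 1
  }
  list(logf = logf, ph = ph)
}

# Sum columns of K x (S*T) matrix within individuals -> K x S.
.sum_by_individual <- function(M, scol, S) {
  K <- nrow(M)
  out <- matrix(0, K, S)
  for (s in seq_len(S)) {
    cols <- which(scol == s)
    out[, s] <- if (length(cols) == 1) M[, cols] else rowSums(M[, cols, drop = FALSE])
  }
  out
}

# Class-conditional clone log-likelihoods (K x 3) plus the per-(i,s)
# structures the E-step needs.
.class_loglik_matrix <- function(tensor, params, layout = NULL) {
  if (is.null(layout)) layout <- .tensor_layout(tensor)
  K <- layout$K; S <- layout$S
  lutQ <- .regime_lut(layout$ux, params, "Q")
  lutA <- .regime_lut(layout$ux, params, "A")
  LQ <- matrix(lutQ$logf[layout$idx], nrow = K)
  LA <- matrix(lutA$logf[layout$idx], nrow = K)
  SQ <- .sum_by_individual(LQ, layout$scol, S)
  SA <- .sum_by_individual(LA, layout$scol, S)
  t0cols <- which(layout$t0)
  LQ0 <- .sum_by_individual(LQ[, t0cols, drop = FALSE],
                            layout$scol[t0cols], S)
  LA0 <- .sum_by_individual(LA[, t0cols, drop = FALSE],
                            layout$scol[t0cols], S)
  Svs <- SA - LA0 + LQ0          # Q at t=0, A at t>0
  allzero <- .sum_by_individual((layout$Xflat > 0) + 0, layout$scol, S) == 0

  per_class <- function(S_is, p) {
    lp <- log(p)
    m <- lp + S_is
    if (any(allzero)) {
      m[allzero] <- logaddexp(log1p(-p), lp + S_is[allzero])
    }
    ez <- matrix(1, K, S)
    ez[allzero] <- exp(lp + S_is[allzero] - m[allzero])
    list(m = m, ez = ez)
  }
  bg <- per_class(SQ, params$p[["bgns"]])
  ns <- per_class(SA, params$p[["bgns"]])
  vs <- per_class(Svs, params$p[["vs"]])
  ll <- cbind(bg = rowSums(bg$m), ns = rowSums(ns$m), vs = rowSums(vs$m))
  list(ll = ll, ez = list(bg = bg$ez, ns = ns$ez, vs = vs$ez),
       layout = layout, lutQ = lutQ, lutA = lutA, allzero = allzero)
}
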