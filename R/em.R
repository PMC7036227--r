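#' E-step: class responsibilities, presence posteriors and leaf posteriors
#'
#' Computes, under the current parameters, the posterior over the class of
#' each clone (`responsibilities`), the posterior probability that each
#' clone is present in each individual conditional on each class
#' (`presence_post`), and the per-regime weighted posterior of the
#' high-abundance leaf for every observed count value (`leaf_stats`). All
#' computation is in log space with max-subtraction.
#'
#' @param tensor An [abundance_tensor()].
#' @param params A [mixture_params()].
#' @return A list with elements `responsibilities` (K x 3 matrix, rows sum
#'   to 1), `presence_post` (K x S x 3 array), `leaf_stats` (per-regime
#'   data frame of observed count, pooled responsibility weight, and
#'   posterior probability of the high-abundance leaf), and internal fields
#'   used by [m_step()].
#' @export
e_step <- function(tensor, params, .layout = NULL) {
  cl <- .class_loglik_matrix(tensor, params, layout = .layout)
  K <- cl$layout$K
  lg <- ifelse(params$Gamma > 0, log(params$Gamma), -Inf)
  lp <- sweep(cl$ll, 2, lg, "+")
  lse <- row_logsumexp(lp)
  if (any(!is.finite(lse))) {
    bad <- which(!is.finite(lse))[1]
    stop("non-finite likelihood for clone ", tensor$clone_ids[bad])
  }
  resp <- exp(lp - lse)
  presence_post <- array(
    c(cl$ez$bg, cl$ez$ns, cl$ez$vs),
    dim = c(K, cl$layout$S, 3),
    dimnames = list(tensor$clone_ids, tensor$individual_ids, CLASS_LABELS)
  )
  # pooled responsibility weight per regime and observed count value
  lay <- cl$layout
  pos <- which(lay$Xflat > 0)
  rows <- ((pos - 1L) %% K) + 1L
  cols <- ((pos - 1L) %/% K) + 1L
  at_t0 <- lay$t0[cols]
  idxpos <- lay$idx[pos]
  wQ <- resp[rows, "bg"] + ifelse(at_t0, resp[rows, "vs"], 0)
  wA <- resp[rows, "ns"] + ifelse(at_t0, 0, resp[rows, "vs"])
  hist_for <- function(w, lut) {
    agg <- rowsum(w, idxpos)
    ui <- as.integer(rownames(agg))
    data.frame(count = lay$ux[ui], weight = as.numeric(agg),
               p_high = lut$ph[ui])
  }
  leaf_stats <- list(Q = hist_for(wQ, cl$lutQ), A = hist_for(wA, cl$lutA))

  structure(
    list(responsibilities = resp, presence_post = presence_post,
         leaf_stats = leaf_stats, log_joint = sum(lse),
         .internal = list(layout = lay, pos = pos, rows = rows,
                          at_t0 = at_t0, ez = cl$ez)),
    class = "e_step_result"
  )
}

# Weighted ZTNB / dGPD maximization over a count histogram. Started at the
# current parameters; the update is only accepted when it improves the
# weighted log-likelihood, so EM retains its monotonicity (generalized EM).
.fit_ztnb_weighted <- function(counts, weights, start) {
  keep <- weights > 0
  counts <- counts[keep]; weights <- weights[keep]
  if (length(counts) == 0 || sum(weights) < 1e-10) return(start)
  nll <- function(par) {
    mu <- exp(par[1]); size <- exp(par[2])
    if (!is.finite(mu) || !is.finite(size)) return(Inf)
    -sum(weights * log_pmf_ztnb(counts, mu, size))
  }
  p0 <- c(log(start[["mu"]]), log(start[["size"]]))
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 200))
  if (opt$value <= nll(p0)) c(mu = exp(opt$par[1]), size = exp(opt$par[2]))
  else start
}

.fit_dgpd_weighted <- function(counts, weights, start) {
  u <- start[["u"]]
  keep <- weights > 0 & counts >= u
  counts <- counts[keep]; weights <- weights[keep]
  if (length(counts) == 0 || sum(weights) < 1e-10) return(start)
  nll <- function(par) {
    xi <- exp(par[1]); sigma <- exp(par[2])
    if (!is.finite(xi) || !is.finite(sigma)) return(Inf)
    -sum(weights * log_pmf_dgpd(counts, xi, sigma, u))
  }
  p0 <- c(log(max(start[["xi"]], 1e-6)), log(start[["sigma"]]))
  opt <- stats::optim(p0, nll, method = "Nelder-Mead",
                      control = list(maxit = 200))
  if (opt$value <= nll(p0)) {
    c(xi = exp(opt$par[1]), sigma = exp(opt$par[2]), u = u)
  } else start
}

#' M-step: maximize the expected complete-data log-posterior
#'
#' Closed-form weighted MAP updates for the class proportions, presence
#' probabilities, sampling probabilities and high-abundance weights, with
#' parameters pooled across their tied cells (background with non-specific
#' for presence; quiet/active regime for everything abundance-related).
#' The zero-truncated negative binomial and discretized generalized Pareto
#' parameters are updated by bounded numerical maximization of their
#' weighted expected log-likelihoods.
#'
#' @param tensor An [abundance_tensor()].
#' @param estep Output of [e_step()].
#' @param params Current parameters (supplies optimizer starting points and
#'   the fixed generalized Pareto location `u`).
#' @param dirichlet_alpha,beta_a,beta_b Conjugate prior hyperparameters;
#'   the defaults (all 1) are the package's non-informative priors, under
#'   which MAP coincides with maximum likelihood.
#' @return An updated [mixture_params()].
#' @export
m_step <- function(tensor, estep, params,
                   dirichlet_alpha = 1, beta_a = 1, beta_b = 1) {
  resp <- estep$responsibilities
  int <- estep$.internal
  lay <- int$layout
  K <- lay$K; S <- lay$S; T <- lay$T
  n_t0 <- sum(lay$t0) / S            # t = 0 samples per individual (1)
  n_post <- T - n_t0

  eps <- 1e-12
  beta_map <- function(num, den) {
    .clamp01((num + beta_a - 1) / (den + beta_a + beta_b - 2), eps)
  }

  rs <- colSums(resp)
  Gamma <- (rs + dirichlet_alpha - 1) / (K + 3 * (dirichlet_alpha - 1))
  Gamma <- pmax(Gamma, eps); Gamma <- Gamma / sum(Gamma)

  ez_sum <- vapply(CLASS_LABELS,
                   function(c) sum(resp[, c] * rowSums(int$ez[[c]])),
                   numeric(1))
  p_bgns <- beta_map(ez_sum[["bg"]] + ez_sum[["ns"]],
                     S * (rs[["bg"]] + rs[["ns"]]))
  p_vs <- beta_map(ez_sum[["vs"]], S * rs[["vs"]])

  # sampled-cell counts per clone: all cells / t=0 cells / t>0 cells
  posmat <- lay$Xflat > 0
  npos_all <- rowSums(posmat)
  npos_t0 <- rowSums(posmat[, lay$t0, drop = FALSE])
  npos_post <- npos_all - npos_t0
  q_Q <- beta_map(
    sum(resp[, "bg"] * npos_all) + sum(resp[, "vs"] * npos_t0),
    T * ez_sum[["bg"]] + n_t0 * ez_sum[["vs"]]
  )
  q_A <- beta_map(
    sum(resp[, "ns"] * npos_all) + sum(resp[, "vs"] * npos_post),
    T * ez_sum[["ns"]] + n_post * ez_sum[["vs"]]
  )

  upd_regime <- function(stats, nb0, gpd0) {
    wtot <- sum(stats$weight)
    whigh <- sum(stats$weight * stats$p_high)
    omega <- if (wtot > 0) {
      w <- (whigh + beta_a - 1) / (wtot + beta_a + beta_b - 2)
      min(max(w, 0), 1 - eps)     # omega may reach exactly 0
    } else 0
    nb <- .fit_ztnb_weighted(stats$count, stats$weight * (1 - stats$p_high), nb0)
    gpd <- .fit_dgpd_weighted(stats$count, stats$weight * stats$p_high, gpd0)
    list(omega = omega, nb = nb, gpd = gpd)
  }
  rQ <- upd_regime(estep$leaf_stats$Q, params$nb$Q, params$gpd$Q)
  rA <- upd_regime(estep$leaf_stats$A, params$nb$A, params$gpd$A)

  mixture_params(
    Gamma = stats::setNames(Gamma, CLASS_LABELS),
    p = c(bgns = unname(p_bgns), vs = unname(p_vs)),
    q = c(Q = unname(q_Q), A = unname(q_A)),
    omega = c(Q = rQ$omega, A = rA$omega),
    nb = list(Q = rQ$nb, A = rA$nb),
    gpd = list(Q = rQ$gpd, A = rA$gpd)
  )
}

#' Fit the clonal abundance mixture model by Expectation-Maximisation
#'
#' Alternates [e_step()] and [m_step()] from a biologically anchored
#' initialization until the joint log-probability changes by less than
#' `tol` or `max_iter` iterations are reached. The anchored initialization
#' (see [default_init_params()]) is what keeps the three latent classes
#' attached to their biological meanings and prevents label switching; no
#' post-hoc relabelling is applied.
#'
#' @param tensor An [abundance_tensor()] with a t = 0 level and at least
#'   one later time point.
#' @param init Initial [mixture_params()]; default
#'   [default_init_params()].
#' @param tol Convergence tolerance on the absolute change of the joint
#'   log-probability (default `1e-6`).
#' @param max_iter Maximum EM iterations (default 500).
#' @param verbose Print the objective each iteration.
#' @return A `fit_result`: list with `params`, `responsibilities`,
#'   `presence_post`, `map_label`, `objective_trace`, `converged`,
#'   `n_iter`.
#' @export
fit_mixture <- function(tensor, init = default_init_params(),
                        tol = 1e-6, max_iter = 500, verbose = FALSE) {
  stopifnot(inherits(tensor, "abundance_tensor"))
  if (!0 %in% tensor$time_ids || length(tensor$time_ids) < 2) {
    stop("model fitting requires a t = 0 sample and at least one later time point")
  }
  if (all(tensor$x == 0)) stop("degenerate tensor: all abundances are zero")
  if (max_iter < 1) stop("max_iter must be >= 1")
  layout <- .tensor_layout(tensor)
  params <- init
  trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  for (it in seq_len(max_iter)) {
    es <- e_step(tensor, params, .layout = layout)
    trace[it] <- es$log_joint
    if (verbose) message(sprintf("iter %3d: log joint = %.6f", it, trace[it]))
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) {
      converged <- TRUE
      break
    }
    params <- m_step(tensor, es, params)
  }
  resp <- es$responsibilities
  rownames(resp) <- tensor$clone_ids
  map_label <- CLASS_LABELS[max.col(resp, ties.method = "first")]
  structure(
    list(params = params, responsibilities = resp,
         presence_post = es$presence_post,
         map_label = stats::setNames(map_label, tensor$clone_ids),
         objective_trace = trace, converged = converged, n_iter = length(trace)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "Mixture fit: %d clones, %d EM iterations (%sconverged), log joint %.4f\n",
    nrow(x$responsibilities), x$n_iter, if (x$converged) "" else "NOT ",
    x$objective_trace[x$n_iter]
  ))
  cat("Class counts (MAP):\n")
  print(table(factor(x$map_label, levels = CLASS_LABELS)))
  print(x$params)
  invisible(x)
}

#' Per-clone classification table from a fitted model
#'
#' MAP class per clone. Exact posterior ties are broken toward the least
#' specific claim (`bg` over `ns` over `vs`). With `min_posterior` set,
#' clones whose maximum posterior falls below it are labelled
#' `"UNASSIGNED"`.
#'
#' @param fit A `fit_result` from [fit_mixture()].
#' @param min_posterior Optional minimum posterior for a hard label.
#' @return A data.frame with columns `clone_id`, `P_bg`, `P_ns`, `P_vs`,
#'   `label`.
#' @export
classify_clones <- function(fit, min_posterior = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  resp <- fit$responsibilities
  label <- CLASS_LABELS[max.col(resp, ties.method = "first")]
  if (!is.null(min_posterior)) {
    label[apply(resp, 1, max) < min_posterior] <- "UNASSIGNED"
  }
  data.frame(
    clone_id = rownames(resp),
    P_bg = resp[, "bg"], P_ns = resp[, "ns"], P_vs = resp[, "vs"],
    label = label, row.names = NULL, stringsAsFactors = FALSE
  )
}
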