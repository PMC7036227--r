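#' Construct the parameter set of the clonal abundance mixture model
#'
#' The model has three clone classes — background (`bg`), non-specific
#' responder (`ns`) and vaccine-specific (`vs`) — and two abundance
#' *regimes*: quiet (`Q`) and active (`A`). Parameter ties follow the model
#' structure: `bg` is quiet at all times, `ns` active at all times, and `vs`
#' quiet pre-vaccination (t = 0) and active afterwards; `bg` and `ns` share
#' one per-individual presence probability. All count-distribution
#' parameters are tied by regime.
#'
#' @param Gamma Probability 3-vector over classes, named `bg`, `ns`, `vs`;
#'   must sum to 1.
#' @param p Presence probabilities: named vector with `bgns` (shared by
#'   background and non-specific clones) and `vs`.
#' @param q Per-regime probability that a present clone is sampled (appears
#'   with nonzero count) in a given sample; named `Q`, `A`.
#' @param omega Per-regime probability that an observed clone is drawn from
#'   the high-abundance (generalized Pareto) leaf rather than the
#'   low-abundance (zero-truncated negative binomial) leaf; named `Q`, `A`.
#'   May be exactly 0.
#' @param nb Per-regime zero-truncated negative binomial parameters: a list
#'   with elements `Q` and `A`, each `c(mu = , size = )`.
#' @param gpd Per-regime discretized generalized Pareto parameters: a list
#'   with elements `Q` and `A`, each `c(xi = , sigma = , u = )`.
#' @return An object of class `mixture_params`.
#' @seealso [default_init_params()], [write_params()], [read_params()]
#' @export
mixture_params <- function(Gamma, p, q, omega, nb, gpd) {
  Gamma <- Gamma[CLASS_LABELS]
  p <- p[c("bgns", "vs")]
  q <- q[REGIMES]
  omega <- omega[REGIMES]
  if (anyNA(Gamma) || anyNA(p) || anyNA(q) || anyNA(omega)) {
    stop("Gamma, p, q, omega must be fully named (bg/ns/vs, bgns/vs, Q/A)")
  }
  if (abs(sum(Gamma) - 1) > 1e-8) stop("Gamma must sum to 1")
  if (any(Gamma < 0)) stop("Gamma must be non-negative")
  if (any(p < 0 | p > 1) || any(q < 0 | q > 1) || any(omega < 0 | omega > 1)) {
    stop("p, q and omega must lie in [0, 1]")
  }
  for (r in REGIMES) {
    nbr <- nb[[r]]; gr <- gpd[[r]]
    if (is.null(nbr) || anyNA(nbr[c("mu", "size")]) ||
        nbr[["mu"]] <= 0 || nbr[["size"]] <= 0) {
      stop("nb$", r, " must have positive mu and size")
    }
    if (is.null(gr) || anyNA(gr[c("xi", "sigma", "u")]) ||
        gr[["sigma"]] <= 0 || gr[["xi"]] < 0 || gr[["u"]] < 1) {
      stop("gpd$", r, " must have sigma > 0, xi >= 0, u >= 1")
    }
  }
  structure(
    list(Gamma = Gamma, p = p, q = q, omega = omega,
         nb = lapply(nb[REGIMES], function(v) v[c("mu", "size")]),
         gpd = lapply(gpd[REGIMES], function(v) v[c("xi", "sigma", "u")])),
    class = "mixture_params"
  )
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Clonal abundance mixture parameters\n")
  cat("  Gamma (class proportions):",
      paste(sprintf("%s=%.4g", names(x$Gamma), x$Gamma), collapse = ", "), "\n")
  cat("  p (presence):",
      paste(sprintf("%s=%.4g", names(x$p), x$p), collapse = ", "), "\n")
  cat("  q (sampling | present):",
      paste(sprintf("%s=%.4g", names(x$q), x$q), collapse = ", "), "\n")
  cat("  omega (high-abundance | observed):",
      paste(sprintf("%s=%.4g", names(x$omega), x$omega), collapse = ", "), "\n")
  for (r in REGIMES) {
    cat(sprintf("  regime %s: ZTNB(mu=%.4g, size=%.4g), dGPD(xi=%.4g, sigma=%.4g, u=%g)\n",
                r, x$nb[[r]][["mu"]], x$nb[[r]][["size"]],
                x$gpd[[r]][["xi"]], x$gpd[[r]][["sigma"]], x$gpd[[r]][["u"]]))
  }
  invisible(x)
}

#' Default anchored initialization for EM
#'
#' Initial parameters encode the biological meaning of each class and thereby
#' prevent label switching: almost all clones start as background; the
#' vaccine-specific class starts with a higher presence probability (shared
#' across individuals); and the active regime starts with a larger
#' high-abundance weight and larger mean count than the quiet regime.
#'
#' @return A `mixture_params` object.
#' @export
default_init_params <- function() {
  mixture_params(
    Gamma = c(bg = 0.99, ns = 0.005, vs = 0.005),
    p = c(bgns = 0.2, vs = 0.6),
    q = c(Q = 0.5, A = 0.5),
    omega = c(Q = 0.01, A = 0.2),
    nb = list(Q = c(mu = 1.5, size = 1), A = c(mu = 8, size = 1)),
    gpd = list(Q = c(xi = 0.5, sigma = 10, u = 1),
               A = c(xi = 0.5, sigma = 40, u = 1))
  )
}

#' Default generating parameters for the simulator's count distributions
#'
#' The printed study parameters cover the class proportions, presence
#' probabilities and high-abundance weights; the sampling probability and the
#' count-distribution parameters are set here to values that reproduce the
#' scale of per-class mean clone abundances seen in bulk BCR repertoire data
#' (background clones averaging a few reads; active clones tens to hundreds,
#' with a heavy Pareto tail).
#'
#' @param Gamma,p,omega Optional overrides for the class proportions,
#'   presence probabilities and high-abundance weights (same shapes as in
#'   [mixture_params()]).
#' @return A `mixture_params` object.
#' @export
default_sim_params <- function(Gamma = c(bg = 0.992, ns = 0.005, vs = 0.003),
                               p = c(bgns = 0.216, vs = 0.970),
                               omega = c(Q = 0.006, A = 0.277)) {
  mixture_params(
    Gamma = Gamma / sum(Gamma),
    p = p,
    q = c(Q = 0.5, A = 0.5),
    omega = omega,
    nb = list(Q = c(mu = 1.0, size = 0.8), A = c(mu = 8, size = 1.2)),
    gpd = list(Q = c(xi = 0.3, sigma = 10, u = 1),
               A = c(xi = 0.6, sigma = 40, u = 1))
  )
}

#' Write / read mixture parameters as JSON
#'
#' The tie structure is stored flattened (one value per tied group), so the
#' files are small, portable and diffable.
#'
#' @param params A `mixture_params` object.
#' @param path File path.
#' @return `read_params` returns a `mixture_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "mixture_params"))
  doc <- list(
    Gamma = as.list(params$Gamma),
    p = as.list(params$p),
    q = as.list(params$q),
    omega = as.list(params$omega),
    nb = lapply(params$nb, as.list),
    gpd = lapply(params$gpd, as.list)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  mixture_params(
    Gamma = unlist(doc$Gamma), p = unlist(doc$p), q = unlist(doc$q),
    omega = unlist(doc$omega),
    nb = lapply(doc$nb, unlist), gpd = lapply(doc$gpd, unlist)
  )
}
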