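test_that("zero-truncated NB is a proper distribution with the Poisson limit", {
  for (par in list(c(2, 1), c(0.5, 0.3), c(10, 4))) {
    total <- sum(exp(log_pmf_ztnb(1:20000, mu = par[1], size = par[2])))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # size -> Inf limit is a zero-truncated Poisson
  expect_equal(exp(log_pmf_ztnb(1, mu = 1, size = 1e9)),
               exp(-1) / (1 - exp(-1)), tolerance = 1e-6)
  # monotone decreasing tail beyond the mode
  lp <- log_pmf_ztnb(5:200, mu = 2, size = 1)
  expect_true(all(diff(lp) < 0))
  expect_error(log_pmf_ztnb(0, 1, 1), "x >= 1")
  expect_error(log_pmf_ztnb(1, -1, 1), "positive")
})

test_that("discretized generalized Pareto normalizes, matches the xi=0 closed form, and is heavy-tailed", {
  for (par in list(c(0.3, 10), c(0.6, 40), c(0, 2))) {
    total <- sum(exp(log_pmf_dgpd(1:5e6, xi = par[1], sigma = par[2], u = 1)))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # xi = 0: discretized exponential, pmf(x) = e^{-(x-u)/sigma} (1 - e^{-1/sigma})
  x <- 1:50; sigma <- 3
  closed <- exp(-(x - 1) / sigma) * (1 - exp(-1 / sigma))
  expect_equal(exp(log_pmf_dgpd(x, xi = 0, sigma = sigma, u = 1)), closed,
               tolerance = 1e-10)
  # xi > 0: log-survival asymptotically linear in log(x)
  xs <- round(10^seq(3, 5, by = 0.5))
  logS <- vapply(xs, function(xx) {
    log(sum(exp(log_pmf_dgpd(xx:(xx * 20), xi = 0.5, sigma = 10, u = 1))))
  }, numeric(1))
  slopes <- diff(logS) / diff(log(xs))
  expect_lt(max(abs(slopes - slopes[1])), 0.05)
  expect_error(log_pmf_dgpd(0, 0.5, 1, u = 1), "x >= u")
  expect_error(log_pmf_dgpd(1, 0.5, -1), "positive")
  expect_error(log_pmf_dgpd(1, -0.5, 1), "non-negative")
})

test_that("leaf log-pmf dispatches point mass, truncated NB and Pareto leaves", {
  params <- default_sim_params()
  expect_equal(leaf_log_pmf(0, "ZERO", params, "Q"), 0)
  expect_equal(leaf_log_pmf(3, "ZERO", params, "Q"), -Inf)
  expect_equal(leaf_log_pmf(4, "LOW", params, "Q"),
               log_pmf_ztnb(4, params$nb$Q[["mu"]], params$nb$Q[["size"]]))
  expect_equal(leaf_log_pmf(4, "HIGH", params, "A"),
               log_pmf_dgpd(4, params$gpd$A[["xi"]], params$gpd$A[["sigma"]],
                            params$gpd$A[["u"]]))
})

test_that("per-sample observation likelihood mixes escape, low and high branches", {
  params <- mixture_params(
    Gamma = c(bg = 0.9, ns = 0.05, vs = 0.05),
    p = c(bgns = 0.3, vs = 0.7),
    q = c(Q = 0.8, A = 0.8),
    omega = c(Q = 0.1, A = 0.1),
    nb = list(Q = c(mu = 2, size = 1), A = c(mu = 5, size = 1)),
    gpd = list(Q = c(xi = 0.3, sigma = 5, u = 1),
               A = c(xi = 0.3, sigma = 5, u = 1))
  )
  expect_equal(obs_log_lik_per_sample(0, "bg", 0, present = 0, params), 0)
  expect_equal(obs_log_lik_per_sample(0, "bg", 0, present = 1, params),
               log(0.2))
  # brute-force leaf enumeration at x = 5
  direct <- 0.8 * (0.9 * exp(log_pmf_ztnb(5, 2, 1)) +
                   0.1 * exp(log_pmf_dgpd(5, 0.3, 5, 1)))
  expect_equal(obs_log_lik_per_sample(5, "bg", 0, present = 1, params),
               log(direct), tolerance = 1e-12)
  # the vs class switches regime with time
  expect_equal(obs_log_lik_per_sample(5, "vs", 0, 1, params),
               obs_log_lik_per_sample(5, "bg", 0, 1, params))
  expect_equal(obs_log_lik_per_sample(5, "vs", 7, 1, params),
               obs_log_lik_per_sample(5, "ns", 7, 1, params))
})

test_that("per-sample mixture has unit total mass over counts", {
  params <- random_params(7)
  for (cls in c("bg", "ns", "vs")) for (t in c(0, 7)) {
    lp <- obs_log_lik_per_sample(0:20000, cls, t, present = 1, params)
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-8)
  }
})

test_that("clone likelihood marginalizes presence and matches hand algebra", {
  params <- mixture_params(
    Gamma = c(bg = 1, ns = 0, vs = 0),
    p = c(bgns = 0.5, vs = 0.5),
    q = c(Q = 0.8, A = 0.8),
    omega = c(Q = 0.1, A = 0.1),
    nb = list(Q = c(mu = 2, size = 1), A = c(mu = 2, size = 1)),
    gpd = list(Q = c(xi = 0.3, sigma = 5, u = 1),
               A = c(xi = 0.3, sigma = 5, u = 1))
  )
  # S = 1, T = 1, x = 0: (1-p) + p (1-q) = 0.5 + 0.5 * 0.2
  expect_equal(clone_log_lik(matrix(0, 1, 1), "bg", params, time_ids = 0),
               log(0.6), tolerance = 1e-12)
  # p = 1 forces the present branch
  params1 <- params; params1$p[] <- 1 - 1e-12
  expect_equal(clone_log_lik(matrix(0, 1, 1), "bg", params1, time_ids = 0),
               log(0.2), tolerance = 1e-9)
})

test_that("clone likelihood equals exhaustive latent enumeration", {
  for (seed in 1:6) {
    params <- random_params(seed)
    tensor <- random_tensor(K = 4, S = 2, T = 2, seed = seed + 100)
    for (i in 1:4) {
      got <- vapply(c("bg", "ns", "vs"), function(cl) {
        clone_log_lik(tensor$x[i, , ], cl, params, tensor$time_ids)
      }, numeric(1))
      want <- oracle_clone_loglik(tensor$x[i, , ], params, tensor$time_ids)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("clone likelihood is invariant to permuting individuals and post-vaccination times", {
  params <- random_params(11)
  set.seed(12)
  x <- matrix(rpois(3 * 4, 2), 3, 4)
  t_ids <- c(0L, 7L, 14L, 21L)
  base <- clone_log_lik(x, "vs", params, t_ids)
  expect_equal(clone_log_lik(x[c(3, 1, 2), ], "vs", params, t_ids), base)
  expect_equal(clone_log_lik(x[, c(1, 4, 2, 3)], "vs", params, t_ids), base)
})

test_that("joint log-probability reduces correctly and stays finite", {
  params <- random_params(3)
  tensor <- random_tensor(K = 6, S = 2, T = 2, seed = 5)
  expect_true(is.finite(joint_log_prob(tensor, params)))

  pdeg <- params; pdeg$Gamma <- c(bg = 1, ns = 0, vs = 0)
  want <- sum(vapply(1:6, function(i) {
    clone_log_lik(tensor$x[i, , ], "bg", pdeg, tensor$time_ids)
  }, numeric(1)))
  expect_equal(joint_log_prob(tensor, pdeg), want, tolerance = 1e-10)

  # appending an all-zero clone adds a computable constant
  x2 <- array(0L, dim = dim(tensor$x) + c(1, 0, 0))
  x2[1:6, , ] <- tensor$x
  t2 <- abundance_tensor(x2, c(tensor$clone_ids, "z"), tensor$individual_ids,
                         tensor$time_ids)
  delta <- log(sum(params$Gamma * exp(vapply(c("bg", "ns", "vs"), function(cl) {
    clone_log_lik(matrix(0L, 2, 2), cl, params, tensor$time_ids)
  }, numeric(1)))))
  expect_equal(joint_log_prob(t2, params),
               joint_log_prob(tensor, params) + delta, tolerance = 1e-10)
})

test_that("parameters serialize to JSON and back unchanged", {
  params <- random_params(21)
  path <- withr::local_tempfile(fileext = ".json")
  write_params(params, path)
  expect_equal(read_params(path), params, tolerance = 1e-12)
  expect_error(mixture_params(
    Gamma = c(bg = 0.5, ns = 0.2, vs = 0.2), p = c(bgns = 0.5, vs = 0.5),
    q = c(Q = 0.5, A = 0.5), omega = c(Q = 0.1, A = 0.1),
    nb = list(Q = c(mu = 1, size = 1), A = c(mu = 1, size = 1)),
    gpd = list(Q = c(xi = 0.1, sigma = 1, u = 1),
               A = c(xi = 0.1, sigma = 1, u = 1))
  ), "sum to 1")
})
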