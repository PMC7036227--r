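test_that("responsibilities reduce to the prior when classes are indistinguishable", {
  # identical distributions in both regimes and tied presence: the data carry
  # no class information, so posteriors equal Gamma
  params <- mixture_params(
    Gamma = c(bg = 0.5, ns = 0.3, vs = 0.2),
    p = c(bgns = 0.4, vs = 0.4),
    q = c(Q = 0.7, A = 0.7),
    omega = c(Q = 0.1, A = 0.1),
    nb = list(Q = c(mu = 2, size = 1), A = c(mu = 2, size = 1)),
    gpd = list(Q = c(xi = 0.3, sigma = 5, u = 1),
               A = c(xi = 0.3, sigma = 5, u = 1))
  )
  tensor <- random_tensor(K = 8, S = 2, T = 2, seed = 31)
  es <- e_step(tensor, params)
  for (i in 1:8) {
    expect_equal(unname(es$responsibilities[i, ]), c(0.5, 0.3, 0.2),
                 tolerance = 1e-10)
  }
  # degenerate prior puts everything on bg
  params$Gamma <- c(bg = 1, ns = 0, vs = 0)
  es <- e_step(tensor, params)
  expect_equal(unname(es$responsibilities[, "bg"]), rep(1, 8))
})

test_that("E-step posteriors and the EM objective match exhaustive enumeration", {
  for (seed in 1:5) {
    params <- random_params(seed + 40)
    tensor <- random_tensor(K = 6, S = 2, T = 2, seed = seed + 50)
    es <- e_step(tensor, params)
    want <- oracle_fit_quantities(tensor, params)
    expect_equal(unname(es$responsibilities), unname(want$resp),
                 tolerance = 1e-8)
    expect_equal(joint_log_prob(tensor, params), want$joint, tolerance = 1e-8)
    expect_equal(es$log_joint, want$joint, tolerance = 1e-8)
    expect_equal(rowSums(es$responsibilities), rep(1, 6), tolerance = 1e-10)
  }
})

test_that("presence posteriors are 1 where observed and correct for all-zero individuals", {
  params <- random_params(8)
  tensor <- random_tensor(K = 10, S = 2, T = 2, seed = 61)
  es <- e_step(tensor, params)
  observed <- apply(tensor$x > 0, c(1, 2), any)
  for (cl in c("bg", "ns", "vs")) {
    expect_true(all(es$presence_post[, , cl][observed] == 1))
  }
  # hand check one all-zero (clone, individual) cell under bg
  az <- which(!observed, arr.ind = TRUE)
  if (nrow(az) > 0) {
    i <- az[1, 1]; s <- az[1, 2]
    p <- params$p[["bgns"]]; q <- params$q[["Q"]]
    lp_pres <- 2 * log(1 - q)            # T = 2 zero cells, present branch
    want <- exp(log(p) + lp_pres - log((1 - p) + p * exp(lp_pres)))
    expect_equal(es$presence_post[i, s, "bg"], want, tolerance = 1e-10)
  }
})

test_that("the M-step recovers weighted closed forms under hard responsibilities", {
  # one clone per class with clean patterns and no high-abundance counts
  x <- array(0L, dim = c(3, 2, 2))
  x[1, 1, 1] <- 1L                       # bg-ish: one small count
  x[2, , ] <- 3L                         # ns-ish: observed everywhere
  x[3, , 2] <- 4L                        # vs-ish: post-vaccination only
  tensor <- abundance_tensor(x, c("a", "b", "c"), c("s1", "s2"), c(0L, 7L))
  params <- random_params(77)
  es <- e_step(tensor, params)
  # overwrite with hard assignments
  es$responsibilities[] <- 0
  es$responsibilities[1, "bg"] <- 1
  es$responsibilities[2, "ns"] <- 1
  es$responsibilities[3, "vs"] <- 1
  # rebuild leaf stats under the hard responsibilities via a fresh e-step on
  # a params object with extreme Gamma (equivalent and simpler than editing
  # internals): instead check the Gamma and p updates, which only use
  # responsibilities and presence posteriors
  newp <- m_step(tensor, es, params)
  expect_equal(unname(newp$Gamma), c(1, 1, 1) / 3, tolerance = 1e-9)
  # p_vs: clone c observed in 1 of 2 individuals; the all-zero individual
  # contributes its presence posterior
  ez <- es$.internal$ez$vs[3, ]
  expect_equal(unname(newp$p[["vs"]]), sum(ez) / 2, tolerance = 1e-9)
})

test_that("one EM pass from the truth does not decrease the objective", {
  gen <- default_sim_params()
  sim <- sample_dataset(gen, K_target = 3000, S = 4, T = 3, seed = 17)
  obj0 <- joint_log_prob(sim$tensor, gen)
  es <- e_step(sim$tensor, gen)
  obj1 <- joint_log_prob(sim$tensor, m_step(sim$tensor, es, gen))
  expect_gte(obj1, obj0 - 1e-6)
})

test_that("EM objective is non-decreasing on random instances", {
  for (seed in 1:20) {
    tensor <- random_tensor(K = 30, S = 2, T = 2, seed = seed + 300)
    fit <- fit_mixture(tensor, tol = 1e-8, max_iter = 40)
    expect_true(all(diff(fit$objective_trace) > -1e-6))
    expect_equal(unname(rowSums(fit$responsibilities)), rep(1, 30),
                 tolerance = 1e-10)
  }
})

test_that("EM recovers a pure background fit on one-class data", {
  gen <- default_sim_params(Gamma = c(bg = 1, ns = 0, vs = 0),
                            p = c(bgns = 0.4, vs = 0.9),
                            omega = c(Q = 0.05, A = 0.3))
  sim <- sample_dataset(gen, K_target = 4000, S = 4, T = 3, seed = 23)
  fit <- fit_mixture(sim$tensor, tol = 1e-4, max_iter = 200)
  # a few heavy-tailed background clones may keep residual mass on the
  # responder classes; the fit must still be overwhelmingly background
  expect_gt(fit$params$Gamma[["bg"]], 0.95)
  expect_gt(mean(fit$map_label == "bg"), 0.995)
})

test_that("the class anchored as vaccine-specific gains abundance after t = 0", {
  gen <- default_sim_params()
  sim <- sample_dataset(gen, K_target = 8000, S = 5, T = 3, seed = 29)
  fit <- fit_mixture(sim$tensor, tol = 1e-4, max_iter = 200)
  # expected observed count for a vs clone: Q regime at t=0, A regime later
  mean_regime <- function(p, r) {
    nb <- p$nb[[r]]; g <- p$gpd[[r]]
    p0 <- (nb[["size"]] / (nb[["size"]] + nb[["mu"]]))^nb[["size"]]
    low <- nb[["mu"]] / (1 - p0)
    xs <- g[["u"]]:200000
    high <- sum(xs * exp(log_pmf_dgpd(xs, g[["xi"]], g[["sigma"]], g[["u"]])))
    (1 - p$omega[[r]]) * low + p$omega[[r]] * high
  }
  expect_gt(mean_regime(fit$params, "A"), mean_regime(fit$params, "Q"))

  # and the fitted vs class is the one whose mean abundance rises after t=0
  lab <- fit$map_label
  x <- sim$tensor$x
  vs_pre <- mean(x[lab == "vs", , 1])
  vs_post <- mean(x[lab == "vs", , -1])
  expect_gt(vs_post, vs_pre)
})

test_that("MAP labels break ties toward background and approximate Gamma at scale", {
  resp <- rbind(c(0.98, 0.01, 0.01), c(1, 1, 1) / 3, c(0.2, 0.4, 0.4))
  colnames(resp) <- c("bg", "ns", "vs")
  rownames(resp) <- c("a", "b", "c")
  fake <- structure(list(responsibilities = resp), class = "fit_result")
  out <- classify_clones(fake)
  expect_equal(out$label, c("bg", "bg", "ns"))
  out2 <- classify_clones(fake, min_posterior = 0.5)
  expect_equal(out2$label, c("bg", "UNASSIGNED", "UNASSIGNED"))

  # simulated class frequencies follow Gamma within 3 SE (binomial check on
  # the pre-discard draws via a near-lossless configuration)
  gen <- default_sim_params(Gamma = c(bg = 0.8, ns = 0.1, vs = 0.1),
                            p = c(bgns = 0.9, vs = 0.9),
                            omega = c(Q = 0.05, A = 0.3))
  sim <- sample_dataset(gen, K_target = 20000, S = 4, T = 3, seed = 41)
  freq <- mean(sim$true_class == "bg")
  se <- sqrt(0.8 * 0.2 / 20000)
  expect_lt(abs(freq - 0.8), 4 * se + 0.005)  # tiny allowance for truncation
})

test_that("degenerate tensors are rejected", {
  x <- array(0L, dim = c(3, 2, 2))
  tensor <- abundance_tensor(x, c("a", "b", "c"), c("s1", "s2"), c(0L, 7L))
  expect_error(fit_mixture(tensor), "degenerate")
  x[1, 1, 1] <- 1L
  t2 <- abundance_tensor(x[, , 1, drop = FALSE], c("a", "b", "c"), c("s1", "s2"), 0L)
  expect_error(fit_mixture(t2), "t = 0")
})
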