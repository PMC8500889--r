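test_that("split-chain R-hat matches a hand-computed oracle and flags divergence", {
  set.seed(421)
  x <- matrix(rnorm(4000), 2000, 2)
  expect_equal(rhat(x), 1, tolerance = 0.01)
  # disjoint supports
  y <- cbind(rnorm(500), rnorm(500, 10))
  expect_gt(rhat(y), 1.1)
  # brute-force split-chain formula on a 2 x 20 toy array
  toy <- matrix(seq_len(40) / 7 + rep(c(0, 1), each = 20), 20, 2)
  halves <- cbind(toy[1:10, 1], toy[11:20, 1], toy[1:10, 2], toy[11:20, 2])
  n <- 10
  W <- mean(apply(halves, 2, var))
  B <- n * var(colMeans(halves))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(rhat(toy), oracle)
  expect_error(rhat(matrix(1:10, 10, 1)), "two chains")
})

test_that("trial splitting partitions data by exact recall", {
  d1 <- make_dataset(0.3, 1, seed = 422)
  parts <- split_trials(d1, tol = 1e-9)
  expect_equal(nrow(parts$recalled), 12)
  expect_equal(nrow(parts$remainder), 20)
  expect_equal(nrow(parts$recalled) + nrow(parts$remainder), nrow(d1))

  d0 <- make_dataset(0.3, 0, seed = 423)
  expect_equal(nrow(split_trials(d0)$recalled), 0)
  expect_equal(nrow(split_trials(d0, tol = Inf)$recalled), 12)
})

test_that("original-model MCMC matches the exact marginal posterior", {
  # tau integrates out analytically, leaving a 1-D posterior for s that a
  # dense quadrature evaluates exactly; the sampler must agree.
  for (seed in c(424, 425)) {
    dat <- make_dataset(0.8, 1, seed = seed)
    oracle <- exact_original_median(dat)
    fit <- fit_original(dat, fit_config(seed = seed))
    expect_lt(abs(fit$medians[["s"]] - oracle), 0.01)
    expect_true(fit$converged)
  }
})

test_that("no-recall data are recovered by the original model", {
  dat <- make_dataset(0.3, 0, seed = 426)
  fit <- fit_original(dat, fit_config(seed = 1))
  expect_equal(fit$medians[["s"]], 0.3, tolerance = 0.005)
  # split fit reduces to the same data when nothing is recalled
  fs <- fit_split(dat, fit_config(seed = 2))
  expect_equal(nrow(fs$data), nrow(dat))
  expect_equal(fs$medians[["s"]], fit$medians[["s"]], tolerance = 0.005)
})

test_that("the mixture model recovers s and the recall process on full-recall data", {
  dat <- make_dataset(0.8, 1, seed = 427)
  fit <- fit_mixture(dat, fit_config(seed = 3))
  expect_equal(fit$medians[["s"]], 0.8, tolerance = 0.01)
  expect_gt(fit$medians[["phi"]], 0.8)
  expect_true(fit$converged)
  expect_true(all(fit$draws$s >= 0 & fit$draws$s <= 1))
  expect_true(all(fit$draws$phi >= 0 & fit$draws$phi <= 1))
  expect_true(all(fit$draws$tau0 > 0) && all(fit$draws$tau1 > 0))
  post_z <- recall_probabilities(fit)
  expect_length(post_z, 12)
  expect_true(all(post_z > 0.9))

  # split estimator is unbiased on the same data
  fs <- fit_split(dat, fit_config(seed = 4))
  expect_equal(fs$medians[["s"]], 0.8, tolerance = 0.005)
})

test_that("the in-house sampler agrees with an independent JAGS fit", {
  library(rjags)
  dat <- make_dataset(0.8, 1, seed = 428)
  mem <- memory_from_data(dat)
  probes <- as.matrix(dat[grep("^cue_", names(dat))])
  px <- rowSums(probes); ex <- rowSums(mem$cues)
  mism <- outer(px, ex, "+") - 2 * probes %*% t(mem$cues)
  model_str <- "model {
    for (t in 1:N) {
      for (j in 1:E) { sim[t,j] <- pow(s, mism[t,j]) }
      pred[t] <- inprod(sim[t,1:E], crit[1:E]) / sum(sim[t,1:E])
      y[t] ~ dnorm(pred[t], tau)
    }
    s ~ dunif(0, 1)
    tau ~ dgamma(0.001, 0.001)
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(N = 32, E = 12, mism = mism,
                               crit = mem$criteria, y = dat$response),
                   n.chains = 2, n.adapt = 2000, quiet = TRUE)
  update(jm, 2000)
  samp <- coda.samples(jm, "s", n.iter = 10000, thin = 5)
  s_jags <- unlist(lapply(samp, function(x) as.vector(x[, "s"])))
  fit <- fit_original(dat, fit_config(seed = 5))
  expect_lt(abs(fit$medians[["s"]] - median(s_jags)), 0.02)
  expect_lt(abs(fit$sds[["s"]] - sd(s_jags)), 0.5 * sd(s_jags))
})

test_that("Savage-Dickey estimators recover known densities at the boundary", {
  fake_fit <- function(phi) {
    structure(list(draws = list(phi = matrix(phi, ncol = 2))),
              class = c("mixture_fit", "exemplar_fit"))
  }
  set.seed(429)
  # posterior identical to the prior: densities cancel
  bf_unif <- savage_dickey_log_bf(fake_fit(runif(10000)), method = "logspline")
  expect_lt(abs(bf_unif), 0.35)
  # Beta(2, 1): analytic density 0 at the boundary, so strong evidence
  bf_beta <- savage_dickey_log_bf(fake_fit(rbeta(10000, 2, 1)), method = "logspline")
  expect_gt(bf_beta, 1.5)
  # half-normal with known analytic density at 0, via the reflection KDE
  z <- abs(rnorm(40000, 0, 0.2))
  z <- z[z <= 1]
  bf_kde <- savage_dickey_log_bf(fake_fit(z[1:20000]), method = "kde")
  f0 <- 2 * dnorm(0, 0, 0.2) / (2 * pnorm(1, 0, 0.2) - 1)
  expect_equal(as.numeric(bf_kde), -log(f0), tolerance = 0.1)
  expect_error(savage_dickey_log_bf(fake_fit(rep(0.5, 1000))), "degenerate")
})

test_that("the exact conditional density estimator reports the boundary underflow", {
  # on noise-free full-recall data the exact posterior density of phi at 0 is
  # astronomically small, so the conditional estimator's Bayes factor is huge
  # compared to the spline estimate of the same posterior
  dat <- make_dataset(0.1, 1, seed = 430)
  fit <- fit_mixture(dat, fit_config(seed = 6))
  bf_cond <- savage_dickey_log_bf(fit, method = "conditional")
  bf_spline <- savage_dickey_log_bf(fit, method = "logspline")
  expect_gt(bf_cond, bf_spline)
  expect_gt(bf_spline, 5)
})

test_that("posterior-predictive RMSE reflects model misfit", {
  dat <- make_dataset(0.3, 0, seed = 431)
  fit <- fit_original(dat, fit_config(seed = 7))
  expect_lt(posterior_predictive_rmse(fit), 0.1)  # data fit perfectly

  dat1 <- make_dataset(0.8, 1, seed = 432)
  f_orig <- fit_original(dat1, fit_config(seed = 8))
  f_mix <- fit_mixture(dat1, fit_config(seed = 9))
  r_orig <- posterior_predictive_rmse(f_orig)
  r_mix <- posterior_predictive_rmse(f_mix)
  expect_gt(r_orig, 1)
  expect_lt(r_mix, 0.2)
  expect_lt(r_mix, r_orig)
})

test_that("fits export long-format posteriors and JSON-ready summaries", {
  dat <- make_dataset(0.3, 0.5, seed = 433)
  fit <- fit_mixture(dat, fit_config(seed = 10, draws = 200, burn_in = 500,
                                     adapt = 1000, thin = 2))
  path <- tempfile(fileext = ".csv")
  export_posterior(fit, path)
  tab <- read.csv(path)
  expect_named(tab, c("chain", "draw", "parameter", "value"))
  expect_equal(nrow(tab), 200 * 2 * 4)
  expect_setequal(unique(tab$parameter), c("s", "phi", "tau0", "tau1"))
  summ <- fit_summary(fit, log_bf = 1.23)
  expect_equal(summ$model, "mixture")
  expect_equal(summ$log_bf, 1.23)
  expect_true(all(c("medians", "rhat", "converged") %in% names(summ)))
})
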