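#' MCMC fitting configuration
#'
#' Sampler settings shared by all model fits. The defaults mirror the
#' recovery study conditions: two independent chains, 5000 retained samples
#' per chain collected after 5000 adaptation and 5000 burn-in iterations,
#' thinning every 5th sample. Priors: `s, phi ~ Uniform(0, 1)` and diffuse
#' `Gamma(0.001, 0.001)` priors on all precisions.
#'
#' @param chains number of independent chains (>= 2).
#' @param draws retained samples per chain (after burn-in and thinning).
#' @param burn_in discarded iterations after adaptation.
#' @param adapt iterations during which the random-walk proposal scales are
#'   tuned (then frozen, so the retained chain is a valid Markov chain).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed optional integer seed set before sampling; `NULL` uses the
#'   current RNG state.
#' @param tau_shape,tau_rate Gamma prior on the precisions.
#' @param rhat_threshold convergence gate on the split-chain R-hat.
#' @return a `fit_config` list.
#' @export
fit_config <- function(chains = 2, draws = 5000, burn_in = 5000, adapt = 5000,
                       thin = 5, seed = NULL, tau_shape = 0.001,
                       tau_rate = 0.001, rhat_threshold = 1.05) {
  stopifnot(chains >= 2, draws >= 1, burn_in >= 1, adapt >= 0, thin >= 1,
            tau_shape > 0, tau_rate > 0, rhat_threshold > 1)
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 burn_in = as.integer(burn_in), adapt = as.integer(adapt),
                 thin = as.integer(thin), seed = seed,
                 tau_shape = tau_shape, tau_rate = tau_rate,
                 rhat_threshold = rhat_threshold),
            class = "fit_config")
}

#' Exemplar memory stored in a judgment dataset
#'
#' The trained trials of a dataset define the exemplars available to the
#' judge: their cue patterns and learned criterion values. Duplicated
#' (pattern, criterion) rows are collapsed.
#'
#' @param data a `judgment_data` data frame.
#' @return an [exemplar_memory()].
#' @export
memory_from_data <- function(data) {
  cue_cols <- grep("^cue_", names(data), value = TRUE)
  tr <- data[data$is_trained, , drop = FALSE]
  if (nrow(tr) == 0L) stop("dataset contains no trained trials; no exemplar memory")
  tab <- unique(tr[, c(cue_cols, "learned_criterion")])
  exemplar_memory(as.matrix(tab[, cue_cols, drop = FALSE]),
                  tab$learned_criterion)
}

probe_matrix <- function(data) {
  cue_cols <- grep("^cue_", names(data), value = TRUE)
  m <- as.matrix(data[, cue_cols, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Split-chain R-hat
#'
#' Potential-scale-reduction factor computed on chains split in half, so
#' within-chain drift also inflates the statistic. Values near 1 indicate
#' convergence.
#'
#' @param x matrix of MCMC samples, iterations x chains (>= 2 chains, >= 10
#'   iterations).
#' @return the R-hat statistic (scalar).
#' @export
rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat needs at least two chains")
  if (nrow(x) < 10L) stop("R-hat needs at least 10 iterations per chain")
  n <- floor(nrow(x) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[1:n, j], x[(n + 1):(2 * n), j])
  }))
  m <- ncol(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

post_stats <- function(draws) {
  pooled <- lapply(draws, as.vector)
  # R-hat for the precisions is computed on the log scale: when a mixture
  # component is nearly empty its precision follows the diffuse gamma prior,
  # whose raw-scale draws span hundreds of orders of magnitude
  rhat_scale <- function(p) {
    x <- draws[[p]]
    if (startsWith(p, "tau")) x <- log(pmax(x, 5e-324))
    rhat(x)
  }
  list(medians = vapply(pooled, stats::median, numeric(1)),
       means = vapply(pooled, mean, numeric(1)),
       sds = vapply(pooled, stats::sd, numeric(1)),
       rhat = vapply(stats::setNames(names(draws), names(draws)),
                     rhat_scale, numeric(1)))
}

new_fit <- function(model, draws, data, memory, config, accept) {
  st <- post_stats(draws)
  structure(list(model = model, draws = draws, data = data, memory = memory,
                 config = config, accept = accept,
                 medians = st$medians, means = st$means, sds = st$sds,
                 rhat = st$rhat,
                 converged = all(st$rhat < config$rhat_threshold)),
            class = c(paste0(model, "_fit"), "exemplar_fit"))
}

#' Fit the original exemplar model
#'
#' Samples from the posterior of `(s, tau)` under the likelihood
#' `y_t ~ Normal(c'(probe_t; s), 1/tau)` for every trial, where `c'` is the
#' similarity-weighted exemplar prediction. This is the conventional fitting
#' procedure that ignores the possibility of direct recall; on data that
#' contain exactly recalled exemplars its `s` estimate is biased towards 0.
#'
#' @param data a `judgment_data` data frame.
#' @param config a [fit_config()].
#' @param memory exemplar memory used for predictions; defaults to the
#'   memory implied by the trained trials of `data`. Passing it explicitly
#'   allows fitting on a subset of trials while keeping the full memory.
#' @return an object of class `original_fit` with posterior draws for `s`
#'   and `tau`, posterior medians/means/SDs, per-parameter split-chain
#'   R-hat, and a `converged` flag.
#' @export
fit_original <- function(data, config = fit_config(),
                         memory = memory_from_data(data)) {
  stopifnot(nrow(data) > 0, all(is.finite(data$response)))
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- mismatch_matrix(probe_matrix(data), memory)
  res <- mcmc_original_cpp(m, memory$criteria, data$response,
                           config$chains, config$draws, config$burn_in,
                           config$adapt, config$thin,
                           config$tau_shape, config$tau_rate)
  new_fit("original", list(s = res$s, tau = res$tau), data, memory, config,
          accept = res$accept_rate)
}

#' Partition trials into recalled exemplars and the rest
#'
#' A trained trial counts as exactly recalled when its response is within
#' `tol` of its learned criterion value. All untrained trials go to the
#' remainder. For noise-free simulated data the default tolerance is
#' essentially exact equality; for noisy or empirical data the tolerance
#' must be chosen by the analyst.
#'
#' @param data a `judgment_data` data frame.
#' @param tol non-negative absolute tolerance (default `1e-9`).
#' @return list with elements `recalled` and `remainder`, which partition
#'   `data`.
#' @export
split_trials <- function(data, tol = 1e-9) {
  stopifnot(tol >= 0)
  rec <- data$is_trained & abs(data$response - data$learned_criterion) <= tol
  rec[is.na(rec)] <- FALSE
  list(recalled = data[rec, , drop = FALSE],
       remainder = data[!rec, , drop = FALSE])
}

#' Fit the original model on the not-recalled subset
#'
#' The split-data estimator: [split_trials()] removes the exactly recalled
#' exemplar trials, and the original exemplar model is fitted to the
#' remainder (not-recalled exemplars plus new stimuli) while keeping the
#' full exemplar memory. This is the heuristic, post-hoc remedy for the
#' recall-induced bias.
#'
#' @inheritParams fit_original
#' @param tol recall tolerance passed to [split_trials()].
#' @return an `original_fit` on the remainder subset.
#' @export
fit_split <- function(data, config = fit_config(), tol = 1e-9) {
  parts <- split_trials(data, tol)
  if (nrow(parts$remainder) == 0L) {
    stop("all trials classified as recalled; nothing left to fit")
  }
  fit_original(parts$remainder, config, memory = memory_from_data(data))
}

#' Fit the latent-mixture extension
#'
#' Samples from the posterior of `(s, phi, tau0, tau1)` under the
#' latent-mixture model: untrained trials follow
#' `Normal(c'(probe; s), 1/tau0)`; each trained trial is, with probability
#' `phi`, a direct recall `Normal(c_t, 1/tau1)` of its learned criterion,
#' and otherwise a similarity-based judgment `Normal(c'(probe; s), 1/tau0)`.
#' The per-trial recall indicators are marginalized out of the likelihood;
#' their posterior probabilities are recoverable with
#' [recall_probabilities()].
#'
#' @inheritParams fit_original
#' @return an object of class `mixture_fit` with draws for `s`, `phi`,
#'   `tau0`, `tau1`.
#' @export
fit_mixture <- function(data, config = fit_config(),
                        memory = memory_from_data(data)) {
  stopifnot(nrow(data) > 0, all(is.finite(data$response)))
  if (!any(data$is_trained)) {
    warning("no trained trials: phi is unidentified and follows its prior")
  }
  if (any(data$is_trained & is.na(data$learned_criterion))) {
    stop("trained trials must carry a learned criterion value")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- mismatch_matrix(probe_matrix(data), memory)
  ct <- ifelse(data$is_trained, data$learned_criterion, 0)
  res <- mcmc_mixture_cpp(m, memory$criteria, data$response,
                          data$is_trained, ct,
                          config$chains, config$draws, config$burn_in,
                          config$adapt, config$thin,
                          config$tau_shape, config$tau_rate)
  new_fit("mixture",
          list(s = res$s, phi = res$phi, tau0 = res$tau0, tau1 = res$tau1),
          data, memory, config, accept = res$accept_rate)
}

#' Posterior recall probabilities per trained trial
#'
#' Posterior probability that each trained trial was generated by the
#' direct-recall component, obtained as the posterior mean of the mixture
#' responsibility across draws.
#'
#' @param fit a `mixture_fit`.
#' @return numeric vector, one probability per trained trial (in dataset
#'   order).
#' @export
recall_probabilities <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  data <- fit$data
  tr <- which(data$is_trained)
  m <- mismatch_matrix(probe_matrix(data[tr, , drop = FALSE]), fit$memory)
  resp <- responsibilities_cpp(as.vector(fit$draws$s), as.vector(fit$draws$phi),
                               as.vector(fit$draws$tau0), as.vector(fit$draws$tau1),
                               m, fit$memory$criteria,
                               data$response[tr], data$learned_criterion[tr])
  colMeans(resp)
}

#' @export
print.exemplar_fit <- function(x, ...) {
  cat(sprintf("%s exemplar-model fit (%d trials, %d chains x %d draws)\n",
              x$model, nrow(x$data), x$config$chains, x$config$draws))
  tab <- data.frame(median = x$medians, mean = x$means, sd = x$sds,
                    rhat = x$rhat)
  print(round(tab, 4))
  if (!x$converged) cat("WARNING: convergence gate failed (R-hat above threshold)\n")
  invisible(x)
}

logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

#' Savage-Dickey log Bayes factor for the mixture model
#'
#' Because the original exemplar model is the mixture model constrained to
#' `phi = 0`, the Bayes factor in its favor is the ratio of prior to
#' posterior density of `phi` at 0. Under the Uniform(0, 1) prior the prior
#' density is 1 everywhere, so the log Bayes factor is minus the log
#' posterior density of `phi` at 0.
#'
#' Estimators for the posterior density at the boundary:
#' \describe{
#'   \item{`logspline`}{maximum-likelihood log-spline density fit to the
#'     pooled `phi` samples (natural cubic spline in the log-density with
#'     knots at sample quantiles, hence linear tails), evaluated at 0. When
#'     the posterior mass sits away from 0 the estimate extrapolates the
#'     fitted left tail to the boundary and stays finite. The default, and
#'     the estimator whose behavior the model-comparison summaries of the
#'     recovery study refer to.}
#'   \item{`conditional`}{Rao-Blackwellized estimate
#'     `p(phi = 0 | D) = E[p(phi = 0 | s, tau0, tau1, D)]` averaged over
#'     posterior draws; the inner conditional density is available in closed
#'     form up to a one-dimensional normalizing integral over `phi`, which
#'     is a polynomial and is integrated exactly by Gauss-Legendre
#'     quadrature. This targets the exact posterior density at 0, which on
#'     noise-free data can underflow to astronomically small values (the
#'     resulting log Bayes factor is then huge); it is also a high-variance
#'     estimator when the posterior of the precisions conflicts with the
#'     `phi = 0` constraint. Provided for analyses on noisy data and for
#'     contrast with the spline estimate.}
#'   \item{`kde`}{boundary-reflection kernel density estimate on the pooled
#'     `phi` samples, evaluated at 0. Only usable when the posterior has
#'     support near 0; returns `Inf` (with a warning) otherwise.}
#'   \item{`beta`}{method-of-moments Beta fit to the pooled samples,
#'     evaluated at 0. Degenerate at the boundary (the Beta density at
#'     exactly 0 is 0 or infinite unless the first shape equals 1); kept as
#'     a diagnostic.}
#' }
#'
#' @param fit a `mixture_fit`.
#' @param method density estimator for the posterior of `phi` at 0.
#' @param prior_density_at_zero prior density of `phi` at 0 (1 for the
#'   Uniform(0, 1) prior).
#' @param gl_nodes number of Gauss-Legendre nodes for the conditional
#'   estimator.
#' @return `log BF_10` (positive values favor the mixture model), with the
#'   estimator recorded in the `"method"` attribute.
#' @export
savage_dickey_log_bf <- function(fit,
                                 method = c("logspline", "conditional",
                                            "kde", "beta"),
                                 prior_density_at_zero = 1, gl_nodes = 96) {
  stopifnot(inherits(fit, "mixture_fit"))
  method <- match.arg(method)
  phi <- as.vector(fit$draws$phi)
  if (stats::sd(phi) == 0) stop("degenerate phi samples (all identical)")
  log_post0 <- switch(method,
    logspline = {
      logspline_density(phi)(0)
    },
    conditional = {
      data <- fit$data
      tr <- which(data$is_trained)
      if (length(tr) == 0L) stop("no trained trials: phi density is the prior")
      m <- mismatch_matrix(probe_matrix(data[tr, , drop = FALSE]), fit$memory)
      gl <- pracma::gaussLegendre(gl_nodes, 0, 1)
      ld <- phi_cond_logdens_cpp(as.vector(fit$draws$s),
                                 as.vector(fit$draws$tau0),
                                 as.vector(fit$draws$tau1),
                                 m, fit$memory$criteria,
                                 data$response[tr], data$learned_criterion[tr],
                                 gl$x, gl$w)
      logmeanexp(ld)
    },
    kde = {
      h <- stats::bw.nrd0(phi)
      f0 <- 2 * mean(stats::dnorm((0 - phi) / h)) / h
      if (f0 == 0) warning("no phi mass near 0: KDE density underflows to 0")
      log(f0)
    },
    beta = {
      sh <- beta_moments_shape(mean(phi), stats::sd(phi))
      log(stats::dbeta(0, sh[1], sh[2]))
    })
  out <- log(prior_density_at_zero) - log_post0
  attr(out, "method") <- method
  out
}

#' Posterior-predictive RMSE
#'
#' Simulates one replicate response per trial and posterior draw, takes the
#' per-trial median of the replicates, and returns the root-mean-squared
#' error between those medians and the observed responses. For the mixture
#' model, replicates of trained trials first draw the recall indicator from
#' its per-draw posterior responsibility, so the predictive distribution
#' conditions on what the fit learned about each trial.
#'
#' @param fit an `original_fit` or `mixture_fit`.
#' @param data dataset to predict; defaults to the data the model was
#'   fitted to.
#' @return the RMSE in criterion units.
#' @export
posterior_predictive_rmse <- function(fit, data = fit$data) {
  m <- mismatch_matrix(probe_matrix(data), fit$memory)
  s_pool <- as.vector(fit$draws$s)
  nd <- length(s_pool)
  n <- nrow(data)
  pred <- predict_draws_cpp(s_pool, m, fit$memory$criteria)
  if (inherits(fit, "original_fit")) {
    tau <- as.vector(fit$draws$tau)
    yrep <- pred + matrix(stats::rnorm(nd * n), nd, n) / sqrt(tau)
  } else {
    tau0 <- as.vector(fit$draws$tau0)
    tau1 <- as.vector(fit$draws$tau1)
    yrep <- pred + matrix(stats::rnorm(nd * n), nd, n) / sqrt(tau0)
    tr <- which(data$is_trained)
    if (length(tr) > 0L) {
      resp <- responsibilities_cpp(s_pool, as.vector(fit$draws$phi),
                                   tau0, tau1,
                                   m[tr, , drop = FALSE], fit$memory$criteria,
                                   data$response[tr], data$learned_criterion[tr])
      z <- matrix(stats::runif(nd * length(tr)) < resp, nd, length(tr))
      recall_rep <- matrix(rep(data$learned_criterion[tr], each = nd),
                           nd, length(tr)) +
        matrix(stats::rnorm(nd * length(tr)), nd, length(tr)) / sqrt(tau1)
      yrep[, tr][z] <- recall_rep[z]
    }
  }
  med <- apply(yrep, 2, stats::median)
  sqrt(mean((data$response - med)^2))
}

#' Export posterior draws as a long CSV
#'
#' One row per retained draw and parameter, with columns
#' `chain, draw, parameter, value`.
#'
#' @param fit an `exemplar_fit`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
export_posterior <- function(fit, path) {
  rows <- lapply(names(fit$draws), function(p) {
    m <- fit$draws[[p]]
    data.frame(chain = rep(seq_len(ncol(m)), each = nrow(m)),
               draw = rep(seq_len(nrow(m)), times = ncol(m)),
               parameter = p, value = as.vector(m))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Summarize a fit as a plain list
#'
#' Medians, means, SDs, and R-hat per parameter, plus the convergence flag;
#' suitable for JSON serialization.
#'
#' @param fit an `exemplar_fit`.
#' @param ... named extras (e.g. `log_bf`, `rmse`) appended to the summary.
#' @return a named list.
#' @export
fit_summary <- function(fit, ...) {
  c(list(model = fit$model,
         n_trials = nrow(fit$data),
         medians = as.list(fit$medians),
         means = as.list(fit$means),
         sds = as.list(fit$sds),
         rhat = as.list(fit$rhat),
         converged = fit$converged,
         chains = fit$config$chains,
         draws_per_chain = fit$config$draws),
    list(...))
}
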