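#' Enumerate the full binary stimulus space
#'
#' All `2^D` distinct cue patterns over `D` binary cues, in lexicographic
#' order (cue 1 is the most significant position; the first row is all zeros
#' and the last row all ones).
#'
#' @param D number of binary cues, between 1 and 16.
#' @return a `2^D x D` binary matrix with columns `cue_1 .. cue_D`.
#' @examples
#' nrow(enumerate_stimuli(5)) # 32
#' @export
enumerate_stimuli <- function(D) {
  if (!is.numeric(D) || length(D) != 1L || D != round(D) || D < 1 || D > 16) {
    stop("D must be a single integer between 1 and 16")
  }
  D <- as.integer(D)
  idx <- 0:(2^D - 1)
  space <- sapply(D:1, function(bit) idx %/% 2^(bit - 1) %% 2)
  space <- matrix(space, ncol = D)
  colnames(space) <- paste0("cue_", seq_len(D))
  space
}

# inverse-CDF draw from Normal(mu, sd) truncated to [lo, hi]
rtruncnorm <- function(n, mu, sd, lo, hi) {
  plo <- stats::pnorm(lo, mu, sd)
  phi <- stats::pnorm(hi, mu, sd)
  stats::qnorm(stats::runif(n, plo, phi), mu, sd)
}

#' Sample cue weights for the linear criterion rule
#'
#' Draws `D + 1` weights (an intercept plus one weight per cue), each from a
#' Normal(20, 10) truncated to \[0, 100\], then rescales the draw to sum to
#' exactly 100. The rescaling reconciles the marginal distribution with the
#' sum constraint, at the cost of the marginals being only approximately
#' truncated normal.
#'
#' @param D number of cues.
#' @param mu,sd location and scale of the truncated normal (criterion units).
#' @return numeric vector `w_0 .. w_D` summing to 100.
#' @export
sample_weights <- function(D, mu = 20, sd = 10) {
  stopifnot(D >= 1)
  repeat {
    w <- rtruncnorm(D + 1, mu, sd, 0, 100)
    if (sum(w) > 0 && all(w * 100 / sum(w) <= 100)) break
  }
  w * 100 / sum(w)
}

#' Criterion values from the linear additive rule
#'
#' `c = w_0 + cue_1 w_1 + ... + cue_D w_D` per stimulus row. With weights
#' that are non-negative and sum to 100 the criteria span \[w_0, 100\].
#'
#' @param space binary stimulus matrix (rows are stimuli).
#' @param weights numeric vector of length `ncol(space) + 1` (intercept
#'   first).
#' @return numeric vector of criterion values, one per row of `space`.
#' @export
compute_criteria <- function(space, weights) {
  space <- as.matrix(space)
  if (length(weights) != ncol(space) + 1L) {
    stop(sprintf("expected %d weights (intercept + one per cue), got %d",
                 ncol(space) + 1L, length(weights)))
  }
  check_binary(space, "space")
  drop(weights[1] + space %*% weights[-1])
}

#' Build a simulated judgment-study design
#'
#' Selects the to-be-learned exemplars and applies the criterion swap that
#' makes the trained material not perfectly rule-consistent. Mirroring
#' typical multiple-cue judgment experiments, the four most extreme stimuli
#' (the two highest- and the two lowest-criterion ones, ranked before the
#' swap) are never selected as exemplars. One randomly chosen pair of
#' exemplars then has its criterion values exchanged.
#'
#' @param space binary stimulus matrix, usually [enumerate_stimuli()].
#' @param criteria criterion values per stimulus (pre-swap), usually
#'   [compute_criteria()].
#' @param n_exemplars number of exemplars to select (default 12).
#' @param weights optional weight vector, stored for provenance.
#' @return an object of class `simulation_design`: `space`, `criteria`
#'   (post-swap), `criteria_rule` (pre-swap), `exemplar_indices`,
#'   `swap_pair`, `weights`.
#' @export
build_design <- function(space, criteria, n_exemplars = 12, weights = NULL) {
  space <- as.matrix(space)
  stopifnot(length(criteria) == nrow(space))
  if (n_exemplars > nrow(space) - 4L) {
    stop(sprintf("cannot select %d exemplars from %d stimuli after excluding the 4 extremes",
                 n_exemplars, nrow(space)))
  }
  ord <- order(criteria)
  extreme <- c(ord[1:2], ord[(length(ord) - 1):length(ord)])
  eligible <- setdiff(seq_len(nrow(space)), extreme)
  exemplar_indices <- sort(sample(eligible, n_exemplars))
  swap_pair <- sample(exemplar_indices, 2)
  post <- criteria
  post[swap_pair] <- post[rev(swap_pair)]
  structure(list(space = space,
                 criteria = post,
                 criteria_rule = criteria,
                 exemplar_indices = exemplar_indices,
                 swap_pair = swap_pair,
                 weights = weights),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0("simulation design: %d stimuli (%d cues), %d exemplars, ",
                     "criteria swapped between stimuli %d and %d\n"),
              nrow(x$space), ncol(x$space), length(x$exemplar_indices),
              x$swap_pair[1], x$swap_pair[2]))
  invisible(x)
}

#' One-call design generator
#'
#' Convenience wrapper running [enumerate_stimuli()], [sample_weights()],
#' [compute_criteria()], and [build_design()] with the default study
#' conditions (five cues, 32 stimuli, 12 exemplars).
#'
#' @param D number of cues (default 5).
#' @param n_exemplars number of exemplars (default 12).
#' @return a `simulation_design`.
#' @export
simulate_design <- function(D = 5, n_exemplars = 12) {
  space <- enumerate_stimuli(D)
  w <- sample_weights(D)
  build_design(space, compute_criteria(space, w), n_exemplars, weights = w)
}

#' Generation regime for judgment data
#'
#' The data-generating condition of one simulated participant: the true
#' similarity parameter, the probability that a trained exemplar's criterion
#' value is recalled exactly, and an optional response-noise SD (0 in the
#' main recovery study; judgments are then generated without any added
#' error).
#'
#' @param s_true true mismatch-similarity parameter in \[0, 1\].
#' @param recall_prob probability `P_r` in \[0, 1\] that a trained exemplar
#'   trial reproduces its learned criterion value exactly.
#' @param noise_sd response noise SD in criterion units (>= 0; default 0).
#' @return a `generation_regime` list.
#' @export
generation_regime <- function(s_true, recall_prob, noise_sd = 0) {
  check_s(s_true)
  stopifnot(length(recall_prob) == 1L, recall_prob >= 0, recall_prob <= 1,
            length(noise_sd) == 1L, noise_sd >= 0)
  structure(list(s_true = s_true, recall_prob = recall_prob,
                 noise_sd = noise_sd),
            class = "generation_regime")
}

#' Generate a judgment dataset from a design
#'
#' Simulates the test phase: one judgment per stimulus in the space. New
#' (untrained) stimuli are judged by the similarity-weighted exemplar rule at
#' `s_true`. Each trained exemplar is, independently with probability
#' `recall_prob`, recalled directly (the response is its learned, post-swap
#' criterion value, exactly); otherwise it is judged like a new stimulus.
#' With `noise_sd > 0` the response is drawn from a normal centred on that
#' value, truncated to the \[0, 100\] response scale.
#'
#' @param design a [build_design()] result.
#' @param regime a [generation_regime()].
#' @return a `judgment_data` data frame with columns `cue_1..cue_D`,
#'   `response`, `is_trained`, `learned_criterion` (NA when untrained), plus
#'   attributes `D` and `regime`.
#' @export
generate_judgments <- function(design, regime) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(regime, "generation_regime"))
  mem <- design_memory(design)
  n <- nrow(design$space)
  pred <- predict_batch(design$space, mem, regime$s_true)
  is_trained <- seq_len(n) %in% design$exemplar_indices
  learned <- ifelse(is_trained, design$criteria, NA_real_)
  recalled <- is_trained & stats::runif(n) < regime$recall_prob
  y <- ifelse(recalled, learned, pred)
  if (regime$noise_sd > 0) {
    y <- rtruncnorm(n, y, regime$noise_sd, 0, 100)
  }
  out <- as.data.frame(design$space)
  out$response <- y
  out$is_trained <- is_trained
  out$learned_criterion <- learned
  structure(out, D = ncol(design$space), regime = regime,
            class = c("judgment_data", "data.frame"))
}

#' Exemplar memory implied by a design
#'
#' @param design a `simulation_design`.
#' @return the [exemplar_memory()] containing the selected exemplars and
#'   their post-swap criterion values.
#' @export
design_memory <- function(design) {
  exemplar_memory(design$space[design$exemplar_indices, , drop = FALSE],
                  design$criteria[design$exemplar_indices])
}

beta_moments_shape <- function(mean, sd) {
  v <- sd^2
  if (v <= 0) stop("beta SD must be positive")
  if (v >= mean * (1 - mean)) {
    stop(sprintf("infeasible beta moments: SD %.3f too large for mean %.3f",
                 sd, mean))
  }
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Draw a generation regime matched to empirical studies
#'
#' Samples `s_true` and `recall_prob` from beta distributions and the
#' response-noise SD from a Normal(17, 6) truncated below at 0, emulating the
#' spread of similarity parameters, recall rates, and response noise found
#' across typical multiple-cue judgment experiments. Beta parameters are set
#' by matching the supplied means and SDs (method of moments).
#'
#' @param s_mean,s_sd mean and SD of the beta distribution for the true
#'   similarity parameter (defaults 0.50 and 0.21).
#' @param pr_mean,pr_sd mean and SD of the beta distribution for the recall
#'   probability (defaults 0.66 and 0.27).
#' @param sigma_mean,sigma_sd parameters of the (untruncated) normal for the
#'   response-noise SD, truncated below at 0 (defaults 17 and 6).
#' @return a [generation_regime()] with `s_true`, `recall_prob` in (0, 1)
#'   and `noise_sd >= 0`.
#' @export
sample_empirical_regime <- function(s_mean = 0.50, s_sd = 0.21,
                                    pr_mean = 0.66, pr_sd = 0.27,
                                    sigma_mean = 17, sigma_sd = 6) {
  sh_s <- beta_moments_shape(s_mean, s_sd)
  sh_p <- beta_moments_shape(pr_mean, pr_sd)
  generation_regime(
    s_true = stats::rbeta(1, sh_s[1], sh_s[2]),
    recall_prob = stats::rbeta(1, sh_p[1], sh_p[2]),
    noise_sd = rtruncnorm(1, sigma_mean, sigma_sd, 0, Inf)
  )
}
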