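test_that("stimulus enumeration is complete, distinct, and ordered", {
  s5 <- enumerate_stimuli(5)
  expect_equal(dim(s5), c(32, 5))
  expect_equal(nrow(unique(s5)), 32)
  s4 <- enumerate_stimuli(4)
  expect_equal(nrow(unique(s4)), 16)
  expect_identical(enumerate_stimuli(1), matrix(c(0, 1), 2, 1,
                                                dimnames = list(NULL, "cue_1")))
  # lexicographic: rows sorted as binary numbers with cue_1 most significant
  key <- s5 %*% 2^(4:0)
  expect_identical(drop(key), as.numeric(0:31))
  expect_error(enumerate_stimuli(0), "between 1 and 16")
  expect_error(enumerate_stimuli(17), "between 1 and 16")
})

test_that("cue weights respect the sum and truncation constraints", {
  set.seed(411)
  draws <- t(replicate(2000, sample_weights(5)))
  expect_equal(ncol(draws), 6)
  expect_true(all(abs(rowSums(draws) - 100) < 1e-9))
  expect_true(all(draws >= 0 & draws <= 100))
  # sum-to-100 symmetry: each marginal mean is 100 / 6
  expect_equal(mean(draws), 100 / 6, tolerance = 0.02)
})

test_that("criteria follow the linear additive rule", {
  space <- enumerate_stimuli(5)
  w <- sample_weights(5)
  crit <- compute_criteria(space, w)
  expect_equal(crit[32], 100)            # all cues on
  expect_equal(crit[1], w[1])            # all cues off -> intercept
  expect_true(all(crit >= w[1] - 1e-12 & crit <= 100 + 1e-12))
  w2 <- c(0, 100, 0, 0, 0, 0)
  expect_equal(compute_criteria(matrix(c(1, 0, 0, 0, 0), 1), w2), 100)
  expect_error(compute_criteria(space, w[-1]), "expected 6 weights")
})

test_that("design selection excludes the extremes and swaps one recorded pair", {
  space <- enumerate_stimuli(5)
  crit <- as.numeric(1:32)
  set.seed(412)
  for (i in 1:25) {
    des <- build_design(space, crit)
    expect_length(des$exemplar_indices, 12)
    # pre-swap ranking: criteria 1, 2, 31, 32 never selected
    expect_false(any(des$criteria_rule[des$exemplar_indices] %in% c(1, 2, 31, 32)))
    expect_equal(sum(des$criteria), sum(crit))
    a <- des$swap_pair[1]; b <- des$swap_pair[2]
    expect_identical(des$criteria[a], des$criteria_rule[b])
    expect_identical(des$criteria[b], des$criteria_rule[a])
    unchanged <- setdiff(1:32, des$swap_pair)
    expect_identical(des$criteria[unchanged], des$criteria_rule[unchanged])
  }
  expect_error(build_design(space, crit, n_exemplars = 29), "excluding the 4 extremes")
})

test_that("perfect recall reproduces learned criteria and no recall reproduces the model", {
  set.seed(413)
  des <- simulate_design()
  d1 <- generate_judgments(des, generation_regime(0.4, 1))
  expect_equal(sum(d1$is_trained), 12)
  expect_equal(sum(!d1$is_trained), 20)
  tr <- d1[d1$is_trained, ]
  expect_identical(tr$response, tr$learned_criterion)
  expect_true(all(is.na(d1$learned_criterion[!d1$is_trained])))

  d0 <- generate_judgments(des, generation_regime(0.4, 0))
  mem <- design_memory(des)
  expect_identical(d0$response,
                   predict_batch(des$space, mem, 0.4))
})

test_that("the fraction of exactly recalled exemplars matches the recall probability", {
  set.seed(414)
  des <- simulate_design()
  n_rec <- replicate(400, {
    d <- generate_judgments(des, generation_regime(0.3, 0.5))
    nrow(split_trials(d)$recalled)
  })
  # binomial(12, .5) oracle over 400 datasets
  p <- mean(n_rec) / 12
  se <- sqrt(0.5 * 0.5 / (400 * 12))
  expect_lt(abs(p - 0.5), 4 * se)
})

test_that("generation is bit-exact under a fixed seed and respects the response scale", {
  make <- function() {
    set.seed(415)
    des <- simulate_design()
    generate_judgments(des, generation_regime(0.3, 0.5, noise_sd = 17))
  }
  a <- make(); b <- make()
  expect_identical(a, b)
  expect_true(all(a$response >= 0 & a$response <= 100))
})

test_that("empirical regime draws respect supports and moment targets", {
  set.seed(416)
  r <- sample_empirical_regime(s_sd = 1e-4)
  expect_equal(r$s_true, 0.5, tolerance = 1e-2)
  draws <- replicate(4000, {
    x <- sample_empirical_regime()
    c(x$s_true, x$recall_prob, x$noise_sd)
  })
  expect_true(all(draws[1, ] > 0 & draws[1, ] < 1))
  expect_true(all(draws[2, ] > 0 & draws[2, ] < 1))
  expect_true(all(draws[3, ] >= 0))
  # closed-form mean of the lower-truncated Normal(17, 6)
  a <- (0 - 17) / 6
  tn_mean <- 17 + 6 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(draws[3, ]), tn_mean, tolerance = 0.06)
  expect_error(sample_empirical_regime(pr_mean = 0.5, pr_sd = 0.6),
               "infeasible beta moments")
})
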