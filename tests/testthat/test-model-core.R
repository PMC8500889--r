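test_that("worked two-exemplar example reproduces the limiting predictions", {
  mem <- exemplar_memory(rbind(c(0, 1), c(1, 1)), c(3, 7))
  expect_identical(predict_criterion(c(0, 1), mem, s = 1), 5)
  expect_identical(predict_criterion(c(0, 1), mem, s = 0), 3)
  # hand-evaluated weighted average with weights (1, 0.5)
  expect_equal(predict_criterion(c(0, 1), mem, s = 0.5), 13 / 3)
})

test_that("similarity follows the mismatch power rule", {
  expect_equal(similarity(c(0, 1, 1, 1), c(1, 1, 1, 1), s = 0.1), 0.1)
  expect_equal(similarity(c(1, 0, 1), c(1, 0, 1), s = 0.37), 1)
  expect_equal(similarity(c(0, 0, 0, 0), c(1, 1, 1, 1), s = 0.5), 0.0625)
})

test_that("power form agrees with the per-cue product form exhaustively", {
  for (D in 1:6) {
    space <- enumerate_stimuli(D)
    s_vals <- c(0, 0.1, 0.5, 0.9, 1)
    for (s in s_vals) {
      for (i in seq_len(nrow(space))) {
        probe <- space[1, ]
        expect_identical(similarity(probe, space[i, ], s),
                         similarity_product_oracle(probe, space[i, ], s))
      }
    }
  }
})

test_that("similarity decreases in the number of mismatches", {
  probe <- rep(1, 6)
  for (s in c(0.05, 0.3, 0.7, 0.95)) {
    sims <- sapply(0:6, function(k) {
      ex <- probe
      if (k > 0) ex[seq_len(k)] <- 0
      similarity(probe, ex, s)
    })
    expect_true(all(diff(sims) < 0))
  }
  sims1 <- sapply(0:4, function(k) {
    ex <- rep(1, 4); if (k > 0) ex[seq_len(k)] <- 0
    similarity(rep(1, 4), ex, 1)
  })
  expect_true(all(diff(sims1) <= 0))
})

test_that("predictions are convex combinations, permutation invariant, and mean at s = 1", {
  set.seed(401)
  for (rep in 1:20) {
    d <- sample(2:8, 1)
    n <- sample(2:10, 1)
    mem <- exemplar_memory(random_binary_matrix(n, d), runif(n, 0, 100))
    probes <- random_binary_matrix(5, d)
    s <- runif(1, 0.01, 1)
    preds <- predict_batch(probes, mem, s)
    expect_true(all(preds >= min(mem$criteria) - 1e-12))
    expect_true(all(preds <= max(mem$criteria) + 1e-12))
    perm <- sample(n)
    mem_p <- exemplar_memory(mem$cues[perm, , drop = FALSE], mem$criteria[perm])
    expect_equal(predict_batch(probes, mem_p, s), preds, tolerance = 1e-12)
    expect_equal(predict_batch(probes, mem, 1),
                 rep(mean(mem$criteria), nrow(probes)))
  }
})

test_that("batch predictions match per-probe calls", {
  set.seed(402)
  mem <- exemplar_memory(random_binary_matrix(6, 5), runif(6, 0, 100))
  probes <- random_binary_matrix(7, 5)
  batch <- predict_batch(probes, mem, 0.4)
  single <- sapply(seq_len(nrow(probes)), function(i) {
    predict_criterion(probes[i, ], mem, 0.4)
  })
  expect_equal(batch, single)
})

test_that("s = 0 returns exact-match means or an explicit error", {
  space <- enumerate_stimuli(3)
  mem <- exemplar_memory(space, seq_len(8) * 10)
  # probes identical to memory rows: criteria verbatim
  expect_equal(predict_batch(space, mem, 0), seq_len(8) * 10)
  # duplicated exemplar pattern: mean of the exact matches
  mem2 <- exemplar_memory(rbind(c(1, 1), c(1, 1), c(0, 0)), c(10, 20, 99))
  expect_equal(predict_criterion(c(1, 1), mem2, 0), 15)
  mem3 <- exemplar_memory(rbind(c(1, 1), c(0, 0)), c(10, 20))
  expect_error(predict_criterion(c(0, 1), mem3, 0), "undefined prediction")
})

test_that("input validation names the offending dimensions and values", {
  expect_error(similarity(c(0, 1), c(0, 1, 1), 0.5), "2 cues.*3")
  expect_error(similarity(c(0, 2), c(0, 1), 0.5), "0/1")
  expect_error(similarity(c(0, 1), c(0, 1), 1.5), "\\[0, 1\\]")
  mem <- exemplar_memory(rbind(c(0, 1)), 5)
  expect_error(predict_criterion(c(0, 1, 1), mem, 0.5), "3 cues.*2")
  expect_error(exemplar_memory(rbind(c(0, 1)), c(1, 2)), "differ")
  expect_error(exemplar_memory(rbind(c(0, 1)), NaN), "finite")
})
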