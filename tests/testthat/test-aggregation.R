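test_that("nominal group sampling is uniform without replacement", {
  pool <- sprintf("w%02d", 1:12)
  g <- withr::with_seed(1, sample_nominal_group(pool, 5))
  expect_length(g, 5)
  expect_false(anyDuplicated(g) > 0)
  expect_identical(sort(withr::with_seed(2, sample_nominal_group(pool, 12))),
                   sort(pool))
  expect_error(sample_nominal_group(pool, 13), "exceeds")
  expect_error(sample_nominal_group(pool, 0), "at least 1")
  # a 19-worker stringent-screened pool cannot host groups of 25
  expect_error(sample_nominal_group(sprintf("s%02d", 1:19), 25), "19")

  # selection frequencies at n = 1 are uniform within 3-sigma binomial error
  B <- 6000
  withr::with_seed(8, {
    picks <- replicate(B, sample_nominal_group(pool, 1))
  })
  freq <- table(factor(picks, levels = pool)) / B
  p0 <- 1 / length(pool)
  expect_true(all(abs(freq - p0) < 3 * sqrt(p0 * (1 - p0) / B)))
})

test_that("plurality vote picks the strict mode and randomizes ties", {
  expect_equal(plurality_vote(c(A = 3, B = 2, C = 2)), "A")
  expect_equal(plurality_vote(c(B = 1)), "B")
  expect_error(plurality_vote(integer(0)), "non-empty")

  B <- 10000
  withr::with_seed(17, {
    wins <- replicate(B, plurality_vote(c(A = 2, B = 2)))
  })
  pa <- mean(wins == "A")
  expect_lt(abs(pa - 0.5), 3 * sqrt(0.25 / B))
})

test_that("accuracy curves are deterministic and correct at the edges", {
  bank <- tiny_bank()
  resp <- make_responses(
    q1 = c(rep("A", 8), rep("B", 7), rep("C", 5)),  # 40% correct
    q2 = rep("valid", 20)                           # unanimous correct
  )
  cfg <- group_config(sizes = c(1, 3, 5), B = 2000, seed = 77)
  cv1 <- accuracy_curves(resp, bank, c("q1", "q2"), cfg)
  cv2 <- accuracy_curves(resp, bank, c("q1", "q2"), cfg)
  expect_identical(cv1, cv2)

  # unanimously-correct item: accuracy 1 at every n
  acc_q2 <- cv1$item_accuracy$accuracy[cv1$item_accuracy$item_id == "q2"]
  expect_true(all(acc_q2 == 1))

  # n = 1: a singleton's answer is its own, so accuracy is the pool rate
  acc_q1_n1 <- cv1$item_accuracy$accuracy[cv1$item_accuracy$item_id == "q1" &
                                            cv1$item_accuracy$n == 1]
  expect_lt(abs(acc_q1_n1 - 0.4), 3 * sqrt(0.4 * 0.6 / cfg$B))

  # item accuracies and overall scores derive from the same replicates
  by_n <- tapply(cv1$item_accuracy$accuracy, cv1$item_accuracy$n, sum)
  expect_equal(as.vector(by_n[as.character(cv1$sizes)]),
               unname(colMeans(cv1$scores)), tolerance = 1e-12)

  expect_error(accuracy_curves(resp, bank, c("q1", "nope"), cfg), "nope")
  expect_error(
    accuracy_curves(resp, bank, "q1", group_config(sizes = 25, B = 5, seed = 1)),
    "exceeds")
})

test_that("curve item order does not change the results", {
  bank <- tiny_bank()
  resp <- make_responses(
    q1 = c(rep("A", 9), rep("B", 8), rep("C", 3)),
    q2 = c(rep("valid", 11), rep("invalid", 9))
  )
  cfg <- group_config(sizes = c(2, 4), B = 500, seed = 5)
  a <- accuracy_curves(resp, bank, c("q1", "q2"), cfg)
  b <- accuracy_curves(resp, bank, c("q2", "q1"), cfg)
  for (id in c("q1", "q2")) {
    expect_identical(
      a$item_accuracy$accuracy[a$item_accuracy$item_id == id],
      b$item_accuracy$accuracy[b$item_accuracy$item_id == id])
  }
})

test_that("Cohen's d follows the pooled-SD formula with sign preserved", {
  expect_equal(cohens_d(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  # hand-computed: means 1 vs 0.5; pooled SD over {1,1,1,1} and {0,1,0,1}
  x <- c(1, 1, 1, 1); y <- c(0, 1, 0, 1)
  sp <- sqrt((3 * var(x) + 3 * var(y)) / 6)
  expect_equal(cohens_d(x, y), 0.5 / sp)
  expect_equal(cohens_d(y, x), -0.5 / sp)
  expect_error(cohens_d(c(1, 1), c(2, 2)), "degenerate")
})

test_that("lure-dominated pools lose accuracy with group size (and the
           reverse for correct-modal pools)", {
  bank <- tiny_bank()
  # q2 pool: 45% correct -> wrong option modal; q1 pool: correct mode by 10pts
  resp <- make_responses(
    q1 = c(rep("A", 40), rep("B", 30), rep("C", 30)),
    q2 = c(rep("valid", 45), rep("invalid", 55))
  )
  cfg <- group_config(sizes = c(1, 25), B = 4000, seed = 13)
  cv <- accuracy_curves(resp, bank, c("q1", "q2"), cfg)
  ia <- cv$item_accuracy
  q1 <- ia$accuracy[ia$item_id == "q1"]
  q2 <- ia$accuracy[ia$item_id == "q2"]
  expect_gt(q1[2], q1[1])  # unique correct mode, margin >= 0.05
  expect_lt(q2[2], q2[1])  # unique wrong mode: bias amplified

  # effect size of the maximal gain, and its sign convention
  es <- max_gain_effect_size(cv, n_low = 1, n_high = 25)
  expect_equal(es$d, cohens_d(cv$scores[, 2], cv$scores[, 1]))
  expect_error(max_gain_effect_size(cv, 1, 10), "not present")
})
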