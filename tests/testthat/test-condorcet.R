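test_that("iid plurality probability: degenerate and single-voter cases", {
  expect_equal(plurality_prob_multinomial(c(1, 0, 0), 1, 7), 1)
  p <- c(0.5, 0.3, 0.2)
  for (ci in 1:3)
    expect_equal(plurality_prob_multinomial(p, ci, 1), p[ci], tolerance = 1e-12)
  # uniform voting: symmetry plus tie credit give exactly 1/k
  for (k in 2:4) for (n in c(1, 2, 5))
    expect_equal(plurality_prob_multinomial(rep(1 / k, k), 1, n), 1 / k,
                 tolerance = 1e-10)
  expect_error(plurality_prob_multinomial(c(0.5, 0.4), 1, 3), "sum to 1")
  expect_error(plurality_prob_multinomial(c(1.2, -0.2), 1, 3), "non-negative")
})

test_that("iid plurality probability matches labelled brute-force enumeration", {
  cases <- list(c(0.5, 0.3, 0.2), c(0.35, 0.33, 0.32), c(0.2, 0.8),
                c(0.6, 0.4), c(0.1, 0.45, 0.45))
  for (p in cases) for (n in 1:5) for (ci in seq_along(p)) {
    expect_equal(plurality_prob_multinomial(p, ci, n),
                 oracle_plurality_multinomial(p, ci, n),
                 tolerance = 1e-10,
                 label = sprintf("p=(%s) n=%d ci=%d",
                                 paste(p, collapse = ","), n, ci))
  }
})

test_that("finite-pool plurality probability matches subset enumeration", {
  expect_equal(plurality_prob_hypergeometric(c(5, 0, 0), 1, 3), 1)
  # n = pool: indicator of the unique pool mode, 1/t under ties
  expect_equal(plurality_prob_hypergeometric(c(3, 2, 2), 1, 7), 1)
  expect_equal(plurality_prob_hypergeometric(c(3, 2, 2), 2, 7), 0)
  expect_equal(plurality_prob_hypergeometric(c(3, 3, 1), 1, 7), 0.5)

  cases <- list(c(3, 2, 2), c(4, 4, 1), c(2, 2, 2), c(5, 3), c(1, 2, 3))
  for (counts in cases) for (n in c(1, 2, 3, sum(counts))) {
    for (ci in seq_along(counts)) {
      expect_equal(plurality_prob_hypergeometric(counts, ci, n),
                   oracle_plurality_hypergeometric(counts, ci, n),
                   tolerance = 1e-10,
                   label = sprintf("counts=(%s) n=%d ci=%d",
                                   paste(counts, collapse = ","), n, ci))
    }
  }
  expect_error(plurality_prob_hypergeometric(c(3, 2), 1, 6), "exceeds")
})

test_that("win probabilities over all options sum to one", {
  withr::with_seed(41, {
    for (r in 1:5) {
      k <- sample(2:5, 1)
      p <- as.vector(rmultinom(1, 50, rep(1, k))) / 50
      p <- p + 1e-6; p <- p / sum(p)
      n <- sample(1:9, 1)
      tot_m <- sum(vapply(seq_len(k), function(ci)
        plurality_prob_multinomial(p, ci, n), numeric(1)))
      expect_equal(tot_m, 1, tolerance = 1e-10)

      counts <- as.vector(rmultinom(1, 20, rep(1, k)))
      nn <- sample(1:10, 1)
      tot_h <- sum(vapply(seq_len(k), function(ci)
        plurality_prob_hypergeometric(counts, ci, nn), numeric(1)))
      expect_equal(tot_h, 1, tolerance = 1e-10)
    }
  })
})

test_that("results are equivariant under option relabelling", {
  p <- c(0.45, 0.25, 0.2, 0.1)
  perm <- c(3, 1, 4, 2)
  for (n in c(2, 5, 8)) {
    for (ci in 1:4) {
      expect_equal(plurality_prob_multinomial(p[perm], match(ci, perm), n),
                   plurality_prob_multinomial(p, ci, n), tolerance = 1e-12)
    }
  }
  counts <- c(6, 3, 2, 1)
  for (ci in 1:4)
    expect_equal(plurality_prob_hypergeometric(counts[perm], match(ci, perm), 4),
                 plurality_prob_hypergeometric(counts, ci, 4), tolerance = 1e-12)
})

test_that("finite-pool probabilities converge to the iid limit", {
  p <- c(0.4, 0.35, 0.25)
  target <- plurality_prob_multinomial(p, 1, 5)
  diffs <- vapply(c(1e2, 1e3, 1e4), function(m)
    abs(plurality_prob_hypergeometric(round(m * p), 1, 5) - target),
    numeric(1))
  expect_true(all(diff(diffs) < 0))
  expect_lt(diffs[3], 1e-3)
})

test_that("jury-theorem curves amplify in the direction of the pool mode", {
  up <- cjt_curve(c(0.5, 0.3, 0.2), 1, sizes = c(1, 25, 101))
  expect_equal(attr(up, "direction"), "toward_correct")
  expect_gt(up$prob[2], up$prob[1])
  expect_gt(up$prob[3], up$prob[2])
  expect_gt(up$prob[3], 0.95)  # approaching the classic limit

  down <- cjt_curve(c(0.3, 0.5, 0.2), 1, sizes = c(1, 25))
  expect_equal(attr(down, "direction"), "toward_wrong")
  expect_lt(down$prob[2], down$prob[1])

  # a barely-modal correct option still improves, but more slowly
  slow <- cjt_curve(c(0.35, 0.33, 0.32), 1, sizes = c(1, 9, 17, 25))
  fast <- cjt_curve(c(0.5, 0.3, 0.2), 1, sizes = c(1, 9, 17, 25))
  expect_true(all(diff(slow$prob) > 0))
  expect_true(all((fast$prob - fast$prob[1])[-1] >
                    (slow$prob - slow$prob[1])[-1]))

  # hypergeometric backend accepts a response-distribution data frame
  d <- data.frame(option = c("A", "B"), count = c(9, 5), p = c(9, 5) / 14)
  hc <- cjt_curve(d, 1, sizes = c(1, 3, 7), backend = "hypergeometric")
  expect_equal(hc$prob[1], 9 / 14, tolerance = 1e-12)
})
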