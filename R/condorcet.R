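# Exact plurality-winner probabilities under the generalized Condorcet jury
# setting: n voters, k options, the group answer is the option with the
# maximal vote count, ties resolved uniformly at random (so an option tied
# among t maxima receives win credit 1/t — the same quantity the simulation
# estimates).
#
# Both backends share a dynamic program: condition on the focal option's
# vote count m, then sweep the remaining options accumulating (votes used,
# number of options tied at m) while constraining every other count to at
# most m. Cost O(k * n^3), exact to floating point at study scale.

# DP over non-focal options. weight_fun(j, c) gives the unnormalized weight
# of option j receiving c votes; returns sum over all completions of
# prod(weights) / (1 + #ties), with every c_j <= m and sum c_j = rest.
.plurality_dp <- function(k, focal, m, rest, cap_fun, weight_fun) {
  # dp[u + 1, t + 1] = accumulated weight with u votes used, t options tied at m
  dp <- matrix(0, nrow = rest + 1, ncol = k)
  dp[1, 1] <- 1
  for (j in seq_len(k)[-focal]) {
    ndp <- matrix(0, nrow = rest + 1, ncol = k)
    cmax <- min(m, rest, cap_fun(j))
    w <- weight_fun(j, 0:cmax)
    for (u in 0:rest) {
      live <- which(dp[u + 1, ] != 0)
      if (!length(live)) next
      for (cc in 0:min(cmax, rest - u)) {
        tie <- as.integer(cc == m && m > 0)
        ndp[u + cc + 1, live + tie] <- ndp[u + cc + 1, live + tie] +
          dp[u + 1, live] * w[cc + 1]
      }
    }
    dp <- ndp
  }
  sum(dp[rest + 1, ] / seq_len(k))
}

#' Exact plurality-win probability with iid voters
#'
#' Probability that the designated correct option is the group answer when
#' `n` voters vote independently with option probabilities `p`, under
#' plurality rule with uniform random tie-breaking (an option tied among `t`
#' maxima counts `1/t`).
#'
#' @param p Probability vector over the `k` options (sums to 1).
#' @param correct Index of the correct option in `p`.
#' @param n Number of voters.
#' @return The exact win probability.
#' @examples
#' plurality_prob_multinomial(c(0.5, 0.3, 0.2), 1, 3)
#' @export
plurality_prob_multinomial <- function(p, correct, n) {
  assert_prob_vector(p, what = "p")
  k <- length(p)
  stopifnot(correct >= 1, correct <= k, n >= 1)
  if (n > 170) stop_cs("n too large for double-precision factorials (max 170)")
  if (k == 1) return(1)
  total <- 0
  for (m in 0:n) {
    if (p[correct] == 0 && m > 0) break
    w_focal <- p[correct]^m / factorial(m)
    if (w_focal == 0) next
    rest <- n - m
    if (rest > (k - 1) * m) next  # others cannot all stay <= m
    s <- .plurality_dp(k, correct, m, rest,
                       cap_fun = function(j) rest,
                       weight_fun = function(j, c) p[j]^c / factorial(c))
    total <- total + w_focal * s
  }
  total * factorial(n)
}

#' Exact plurality-win probability with finite-pool sampling
#'
#' Finite-pool counterpart of [plurality_prob_multinomial()]: `n` votes are
#' drawn without replacement from a pool holding `counts[j]` supporters of
#' option `j` (multivariate hypergeometric), and the group answer is the
#' plurality winner with uniform random tie-breaking.
#'
#' @param counts Integer vector of pool supporters per option.
#' @param correct Index of the correct option.
#' @param n Group size (at most `sum(counts)`).
#' @return The exact win probability.
#' @examples
#' plurality_prob_hypergeometric(c(3, 2, 2), 1, 3)
#' @export
plurality_prob_hypergeometric <- function(counts, correct, n) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop_cs("pool counts must be non-negative integers")
  k <- length(counts)
  stopifnot(correct >= 1, correct <= k, n >= 1)
  total_pool <- sum(counts)
  if (n > total_pool)
    stop_cs("group size n = %d exceeds the pool of %d workers", n, total_pool)
  if (k == 1) return(1)
  total <- 0
  for (m in 0:min(n, counts[correct])) {
    w_focal <- choose(counts[correct], m)
    rest <- n - m
    if (rest > sum(pmin(counts[-correct], m))) next
    s <- .plurality_dp(k, correct, m, rest,
                       cap_fun = function(j) counts[j],
                       weight_fun = function(j, c) choose(counts[j], c))
    total <- total + w_focal * s
  }
  total / choose(total_pool, n)
}

#' Condorcet curve: win probability across group sizes
#'
#' Evaluates the exact probability that the correct option is the plurality
#' answer at each group size, under either iid voting (`"multinomial"`,
#' from a probability vector) or finite-pool sampling without replacement
#' (`"hypergeometric"`, from pool counts). The direction attribute
#' classifies the pool: `"toward_correct"` if the correct option is the
#' strict mode (the jury theorem's amplification toward truth),
#' `"toward_wrong"` if some incorrect option is the strict mode (bias
#' amplification), `"mixed"` under a tied mode.
#'
#' @param dist Probability vector (multinomial) or integer pool counts
#'   (hypergeometric), or a `response_distribution()` data frame (its
#'   `count` column is used for the hypergeometric backend, `p` otherwise).
#' @param correct Index of the correct option.
#' @param sizes Group sizes to evaluate (default 1 to 25).
#' @param backend `"multinomial"` or `"hypergeometric"`.
#' @return Data frame `n`, `prob` with attributes `direction` and `backend`.
#' @export
cjt_curve <- function(dist, correct, sizes = 1:25,
                      backend = c("multinomial", "hypergeometric")) {
  backend <- match.arg(backend)
  if (is.data.frame(dist)) {
    dist <- if (backend == "hypergeometric") dist$count else dist$p
  }
  prob <- vapply(sizes, function(n) {
    if (backend == "multinomial") plurality_prob_multinomial(dist, correct, n)
    else plurality_prob_hypergeometric(dist, correct, n)
  }, numeric(1))
  out <- data.frame(n = sizes, prob = prob)
  share <- dist / sum(dist)
  mx <- max(share)
  modal <- which(share == mx)
  direction <- if (length(modal) > 1) "mixed"
  else if (modal == correct) "toward_correct" else "toward_wrong"
  attr(out, "direction") <- direction
  attr(out, "backend") <- backend
  out
}
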