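#' Draw one nominal group
#'
#' Uniform sampling without replacement from the available worker pool —
#' nominal groups are statistical aggregates, the members never interact.
#'
#' @param pool Character vector of worker ids.
#' @param n Group size (`1 <= n <= length(pool)`).
#' @return `n` distinct worker ids.
#' @export
sample_nominal_group <- function(pool, n) {
  if (n < 1) stop_cs("group size must be at least 1")
  if (n > length(pool))
    stop_cs("group size n = %d exceeds the available pool of %d workers",
            n, length(pool))
  pool[sample.int(length(pool), n)]
}

#' Plurality vote with random tie-breaking
#'
#' Returns the option with the strictly maximal vote count; among tied
#' maxima one option is chosen uniformly at random (so each of `t` tied
#' options wins with probability `1/t`).
#'
#' @param counts Named integer vector of votes per option (total >= 1).
#' @return The winning option label.
#' @examples
#' plurality_vote(c(A = 3, B = 2, C = 2))
#' @export
plurality_vote <- function(counts) {
  if (!length(counts) || sum(counts) < 1)
    stop_cs("plurality_vote needs a non-empty vote count")
  if (is.null(names(counts))) stop_cs("vote counts must be named by option")
  top <- which(counts == max(counts))
  names(counts)[if (length(top) == 1) top else top[sample.int(length(top), 1)]]
}

#' Group-size configuration for the resampling analysis
#'
#' @param sizes Nominal group sizes (default 1 to 25).
#' @param B Replicates per group size (default 1000).
#' @param seed Master RNG seed.
#' @return List of class `group_config`.
#' @export
group_config <- function(sizes = 1:25, B = 1000L, seed = 1L) {
  stopifnot(all(sizes >= 1), B >= 1)
  structure(list(sizes = as.integer(sizes), B = as.integer(B),
                 seed = as.integer(seed)), class = "group_config")
}

#' Accuracy-versus-group-size curves by nominal-group resampling
#'
#' The core procedure: for each group size `n` and each of `B` replicates,
#' draw a fresh nominal group from the pool (without replacement,
#' unweighted), answer every item of the test by plurality vote with random
#' tie-breaking, and score the group answer vector (1 per correct item,
#' summed into the group's overall test score). Item-level accuracies and
#' the replicate score distributions come from the same replicates.
#' Deterministic given the configuration seed: group draws and per-item
#' tie-breaks use sub-streams derived from (seed, size) and
#' (seed, size, item) counters, so results do not depend on item order.
#'
#' @param responses A `response_matrix`.
#' @param bank Item bank (answer key).
#' @param items Character vector of item ids forming the test.
#' @param config A [group_config()].
#' @param pool Worker ids to sample from (default: all rows of `responses`).
#' @param test_label Label stored on the curve (e.g. `"HBT"`).
#' @return List of class `accuracy_curve`: `test`, `sizes`, `B`, `seed`,
#'   `pool_size`, `item_accuracy` (data frame `n`, `item_id`, `accuracy`),
#'   `scores` (B x length(sizes) matrix of replicate test scores) and
#'   `summary` (data frame `n`, `mean_score`, `sd_score`).
#' @export
accuracy_curves <- function(responses, bank, items, config,
                            pool = NULL, test_label = "custom") {
  stopifnot(inherits(config, "group_config"))
  if (!length(items)) stop_cs("item set is empty")
  rows <- match(items, bank$item_id)
  if (anyNA(rows)) stop_cs("unknown item id '%s'", items[which(is.na(rows))[1]])
  pool <- pool %||% responses$worker_id
  widx <- match(pool, responses$worker_id)
  if (anyNA(widx)) stop_cs("pool contains unknown worker ids")
  npool <- length(widx)
  if (any(config$sizes > npool))
    stop_cs("group size n = %d exceeds the available pool of %d workers",
            max(config$sizes), npool)

  # integer-code responses once: workers x items, option index (NA allowed)
  kk <- vapply(bank$options[rows], length, integer(1))
  code <- matrix(NA_integer_, npool, length(items))
  for (j in seq_along(items)) {
    code[, j] <- match(responses[[items[j]]][widx], bank$options[[rows[j]]])
  }
  correct_idx <- vapply(seq_along(items),
                        function(j) match(bank$correct[rows[j]],
                                          bank$options[[rows[j]]]), integer(1))

  B <- config$B
  nsz <- length(config$sizes)
  item_acc <- matrix(NA_real_, nsz, length(items),
                     dimnames = list(NULL, items))
  scores <- matrix(0L, B, nsz)
  for (s in seq_len(nsz)) {
    n <- config$sizes[s]
    G <- withr::with_seed(derive_seed(config$seed, n, 0L), {
      t(matrix(vapply(seq_len(B), function(b) sample.int(npool, n),
                      integer(n)), nrow = n))
    })
    for (j in seq_along(items)) {
      Rj <- matrix(code[as.vector(G), j], B, n)
      counts <- matrix(0L, B, kk[j])
      for (o in seq_len(kk[j])) counts[, o] <- rowSums(Rj == o, na.rm = TRUE)
      hit <- withr::with_seed(derive_seed(config$seed, n, rows[j]), {
        # all-missing groups cannot vote; guard keeps max.col defined
        voted <- rowSums(counts) > 0
        w <- max.col(counts, ties.method = "random")
        w == correct_idx[j] & voted
      })
      item_acc[s, j] <- mean(hit)
      scores[, s] <- scores[, s] + as.integer(hit)
    }
  }

  structure(list(
    test = test_label, sizes = config$sizes, B = B, seed = config$seed,
    pool_size = npool,
    item_accuracy = data.frame(
      n = rep(config$sizes, times = length(items)),
      item_id = rep(items, each = nsz),
      accuracy = as.vector(item_acc)),
    scores = scores,
    summary = data.frame(n = config$sizes,
                         mean_score = colMeans(scores),
                         sd_score = apply(scores, 2, stats::sd))
  ), class = "accuracy_curve")
}

#' Cohen's d between two score samples
#'
#' Pooled-SD standardized mean difference
#' `d = (mean(x) - mean(y)) / s_pooled` with
#' `s_pooled = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y Numeric samples.
#' @return Signed Cohen's d.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  dm <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (dm == 0) return(0)
    stop_cs("degenerate: zero pooled SD with unequal means")
  }
  dm / sqrt(sp2)
}

#' Maximal gain (or loss) from aggregation as an effect size
#'
#' Cohen's d (pooled SD) between the replicate overall test scores at the
#' largest and smallest group size of interest. A positive d is a
#' performance gain from aggregation; a negative d means the pool's bias was
#' amplified.
#'
#' @param curve An `accuracy_curve`.
#' @param n_low,n_high Group sizes to compare (defaults 1 and 25).
#' @return List of class `effect_size_report`: `n_low`, `n_high`, `d`,
#'   `direction` (`"gain"` or `"loss"`).
#' @export
max_gain_effect_size <- function(curve, n_low = 1L, n_high = 25L) {
  stopifnot(inherits(curve, "accuracy_curve"))
  i_lo <- match(n_low, curve$sizes)
  i_hi <- match(n_high, curve$sizes)
  if (is.na(i_lo) || is.na(i_hi))
    stop_cs("requested sizes not present in the curve")
  d <- cohens_d(curve$scores[, i_hi], curve$scores[, i_lo])
  structure(list(n_low = n_low, n_high = n_high, d = d,
                 direction = if (d >= 0) "gain" else "loss"),
            class = "effect_size_report")
}
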