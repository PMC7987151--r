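#' Pool specification for the synthetic worker generator
#'
#' @param n_workers Number of workers (study-scale default 95).
#' @param bank Item bank (default [default_item_bank()]).
#' @param params Trait-model parameters (default calibrated
#'   [default_trait_params()] for `bank`).
#' @param seed Integer RNG seed; generation is bit-reproducible given it.
#' @return A list of class `pool_spec`.
#' @export
pool_spec <- function(n_workers = 95L, bank = default_item_bank(),
                      params = default_trait_params(bank), seed = 1L) {
  stopifnot(n_workers >= 1, is.numeric(seed), length(seed) == 1)
  validate_item_bank(bank)
  if (!identical(params$item_id, bank$item_id))
    stop_cs("trait params do not match the item bank: unknown or misordered item '%s'",
            setdiff(params$item_id, bank$item_id)[1] %||% params$item_id[1])
  validate_trait_params(params, bank)
  structure(list(n_workers = as.integer(n_workers), bank = bank,
                 params = params, seed = as.integer(seed)),
            class = "pool_spec")
}

#' Sample a synthetic worker pool
#'
#' Draws a worker-by-item categorical response matrix from the latent-trait
#' model: each worker has a reasoning trait `theta ~ Normal(0, 1)`; on item
#' `i` the worker answers correctly with probability
#' `plogis(a_i * theta + b_i)`; an incorrect answer falls on the item's lure
#' option with probability `lambda_i` and otherwise uniformly on the
#' remaining distractors.
#'
#' @param spec A [pool_spec()].
#' @return A data frame of class `response_matrix`: column `worker_id` plus
#'   one character column of chosen option labels per item. The latent
#'   traits are attached as attribute `"theta"`.
#' @examples
#' pool <- sample_pool(pool_spec(n_workers = 20, seed = 7))
#' dim(pool)
#' @export
sample_pool <- function(spec) {
  stopifnot(inherits(spec, "pool_spec"))
  bank <- spec$bank
  n <- spec$n_workers
  withr::with_seed(spec$seed, {
    theta <- stats::rnorm(n)
    resp <- matrix(NA_character_, nrow = n, ncol = nrow(bank),
                   dimnames = list(NULL, bank$item_id))
    for (i in seq_len(nrow(bank))) {
      p <- stats::plogis(spec$params$a[i] * theta + spec$params$b[i])
      correct <- stats::runif(n) < p
      ans <- rep(bank$correct[i], n)
      wrong <- which(!correct)
      if (length(wrong)) {
        opts <- bank$options[[i]]
        distractors <- setdiff(opts, c(bank$correct[i], bank$lure[i]))
        if (!is.na(bank$lure[i])) {
          to_lure <- stats::runif(length(wrong)) < spec$params$lambda[i]
          ans[wrong[to_lure]] <- bank$lure[i]
          rest <- wrong[!to_lure]
        } else {
          distractors <- setdiff(opts, bank$correct[i])
          rest <- wrong
        }
        if (length(rest)) {
          if (!length(distractors))
            stop_cs("item '%s' has no non-lure distractor to assign", bank$item_id[i])
          ans[rest] <- sample(distractors, length(rest), replace = TRUE)
        }
      }
      resp[, i] <- ans
    }
  })
  out <- data.frame(worker_id = sprintf("w%03d", seq_len(n)), resp,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "theta") <- theta
  class(out) <- c("response_matrix", "data.frame")
  out
}

#' Sample worker demographics
#'
#' Generates the covariates used by the hierarchical regressions: age
#' (Normal, mean 48.6, SD 15.4, truncated at 18), a female indicator
#' (rate 0.47) and a completed-tertiary-education indicator (rate 0.42) —
#' the study-pool composition. Demographics are drawn independently of the
#' reasoning trait: the study found little demographic signal once ability
#' measures entered the model, and independence is the neutral default.
#'
#' @param n_workers Number of workers.
#' @param seed Integer RNG seed.
#' @return Data frame `worker_id`, `age`, `female`, `tertiary`.
#' @export
sample_demographics <- function(n_workers, seed = 1L) {
  withr::with_seed(seed, {
    age <- pmax(18, stats::rnorm(n_workers, 48.61, 15.41))
    female <- as.integer(stats::runif(n_workers) < 0.47)
    tertiary <- as.integer(stats::runif(n_workers) < 0.42)
  })
  data.frame(worker_id = sprintf("w%03d", seq_len(n_workers)),
             age = age, female = female, tertiary = tertiary,
             stringsAsFactors = FALSE)
}
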