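# Gauss-Hermite quadrature for marginalizing the standard-normal trait.
# 61 nodes: integrand plogis(a*theta + b) is smooth, so this is far below
# the 1e-6 calibration tolerance.
.gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n = 61L) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    # change of variables theta = sqrt(2) x for Normal(0,1) expectation
    .gh_cache[[key]] <- list(theta = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
  }
  .gh_cache[[key]]
}

#' Trait-marginalized probability of a correct answer
#'
#' Computes `E[plogis(a * theta + b)]` for `theta ~ Normal(0, 1)` by
#' Gauss-Hermite quadrature. This is the expected item accuracy in an
#' infinitely large worker pool under the latent-trait response model.
#'
#' @param a Item discrimination (non-negative).
#' @param b Item easiness offset (larger `b`, easier item).
#' @param nodes Number of quadrature nodes.
#' @return The marginal correct-answer probability.
#' @export
marginal_correct_prob <- function(a, b, nodes = 61L) {
  gh <- gh_nodes(nodes)
  vapply(seq_along(a), function(i) {
    sum(gh$w * stats::plogis(a[i] * gh$theta + b[i]))
  }, numeric(1))
}

#' Calibrate item easiness to target marginal accuracies
#'
#' Adjusts each item's easiness offset `b` so that the trait-marginalized
#' probability of a correct answer equals the requested target within 1e-6,
#' by one-dimensional root finding ([stats::uniroot()]) on `b` with the
#' trait integral evaluated by Gauss-Hermite quadrature. Discriminations and
#' lure weights are left untouched.
#'
#' @param params Trait-model parameter table (see [default_trait_params()]):
#'   columns `item_id`, `a`, `b`, `lambda`.
#' @param target_rates Numeric vector of target marginal accuracies, one per
#'   row of `params` (values strictly inside (0, 1)).
#' @return `params` with the `b` column replaced by calibrated values.
#' @examples
#' p <- data.frame(item_id = "x", a = 0, b = 0, lambda = 1)
#' calibrate_difficulties(p, 0.3)$b  # log(0.3 / 0.7)
#' @export
calibrate_difficulties <- function(params, target_rates) {
  stopifnot(is.data.frame(params), nrow(params) == length(target_rates))
  if (any(!is.finite(target_rates) | target_rates <= 0 | target_rates >= 1))
    stop_cs("target rates must lie strictly inside (0, 1)")
  b <- numeric(nrow(params))
  for (i in seq_len(nrow(params))) {
    a_i <- params$a[i]
    tgt <- target_rates[i]
    f <- function(b) marginal_correct_prob(a_i, b) - tgt
    sol <- tryCatch(
      stats::uniroot(f, lower = -40, upper = 40, tol = 1e-12),
      error = function(e) NULL
    )
    if (is.null(sol) || abs(f(sol$root)) > 1e-6)
      stop_cs("calibration failed to converge for item '%s'", params$item_id[i])
    b[i] <- sol$root
  }
  params$b <- b
  params
}

#' Default trait-model parameters for an item bank
#'
#' One latent reasoning trait `theta ~ Normal(0, 1)` drives all items:
#' `P(correct | theta) = plogis(a * theta + b)`; an incorrect answer lands on
#' the item's lure with probability `lambda`, otherwise uniformly on the
#' remaining distractors. Defaults: discrimination `a = 1` for all items
#' except the incongruent SRT items, where `a = 2.6` lets the pool reproduce
#' the strong observed rank correlation between cognitive reflection and the
#' belief-bias measure (targets r = .44 with HBT, r = .563 with the
#' belief-bias SRT items); `lambda = 1` on two-option items (the only
#' incorrect option is the lure), the construct-specific shares on the HBT,
#' 0.8 on the CRT (the intuitive answer dominates errors), and no lure on the
#' RSPM. Easiness `b` is calibrated to the bank's `target_p` column.
#'
#' @param bank Item bank (see [default_item_bank()]).
#' @param a_default,a_crt,a_srt_incongruent Discrimination defaults,
#'   overridable per call.
#' @return Data frame `item_id`, `a`, `b` (calibrated), `lambda`.
#' @export
default_trait_params <- function(bank = default_item_bank(),
                                 a_default = 1.0, a_crt = 1.0,
                                 a_srt_incongruent = 2.6) {
  a <- rep(a_default, nrow(bank))
  a[bank$subtest == "CRT"] <- a_crt
  a[bank$subtest == "SRT" & bank$congruent %in% FALSE] <- a_srt_incongruent

  lambda <- rep(NA_real_, nrow(bank))
  k <- vapply(bank$options, length, integer(1))
  two_opt <- k == 2L & !is.na(bank$lure)
  lambda[two_opt] <- 1
  lambda[bank$subtest == "CRT"] <- 0.8
  lambda[bank$subtest == "HBT"] <- .hbt_default_lambda
  lambda[is.na(bank$lure)] <- 0  # no lure: incorrect mass uniform

  params <- data.frame(item_id = bank$item_id, a = a, b = 0, lambda = lambda,
                       stringsAsFactors = FALSE)
  validate_trait_params(params, bank)
  calibrate_difficulties(params, bank$target_p)
}

validate_trait_params <- function(params, bank) {
  stopifnot(identical(params$item_id, bank$item_id))
  if (any(params$a < 0)) stop_cs("discriminations must be non-negative")
  if (any(params$lambda < 0 | params$lambda > 1))
    stop_cs("lure weights must lie in [0, 1]")
  k <- vapply(bank$options, length, integer(1))
  bad <- k == 2L & !is.na(bank$lure) & params$lambda != 1
  if (any(bad))
    stop_cs("two-option items must have lambda = 1 (item '%s')",
            bank$item_id[which(bad)[1]])
  invisible(params)
}
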