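#' Score a response matrix against the answer key
#'
#' Assigns 1 for a response equal to the item's correct option and 0
#' otherwise; a missing response scores 0 (denominators stay fixed) and is
#' counted in the `n_missing` attribute. Open-numeric responses are expected
#' in canonical label form (raw free text is normalized by
#' [load_responses()] before scoring).
#'
#' @param responses A `response_matrix` (worker_id plus one column per item).
#' @param bank Item bank serving as the answer key.
#' @return A list of class `score_matrix`: `scores` (worker x item 0/1 data
#'   frame), `totals` (per-worker subtest totals: `crt` 0-4, `rspm` 0-9,
#'   `hbt` 0-9, `srt_congruent` 0-4, `srt_incongruent` 0-4, `srt` 0-8).
#' @export
score_responses <- function(responses, bank) {
  validate_item_bank(bank)
  item_cols <- setdiff(names(responses), "worker_id")
  unknown <- setdiff(item_cols, bank$item_id)
  if (length(unknown))
    stop_cs("response matrix has item columns not in the answer key: %s",
            paste(unknown, collapse = ", "))
  missing_items <- setdiff(bank$item_id, item_cols)
  if (length(missing_items))
    stop_cs("response matrix lacks keyed items: %s",
            paste(missing_items, collapse = ", "))

  sc <- matrix(0L, nrow(responses), nrow(bank),
               dimnames = list(NULL, bank$item_id))
  n_missing <- 0L
  for (i in seq_len(nrow(bank))) {
    r <- responses[[bank$item_id[i]]]
    n_missing <- n_missing + sum(is.na(r))
    sc[, i] <- as.integer(!is.na(r) & r == bank$correct[i])
  }
  if (n_missing > 0)
    message(sprintf("score_responses: %d missing responses scored 0", n_missing))

  st <- subtest_items(bank)
  tot <- function(ids) if (length(ids)) rowSums(sc[, ids, drop = FALSE]) else 0L
  totals <- data.frame(
    worker_id = responses$worker_id,
    crt = tot(st$crt), rspm = tot(st$rspm), hbt = tot(st$hbt),
    srt_congruent = tot(st$srt_congruent),
    srt_incongruent = tot(st$srt_incongruent),
    stringsAsFactors = FALSE
  )
  totals$srt <- totals$srt_congruent + totals$srt_incongruent

  out <- list(scores = data.frame(worker_id = responses$worker_id, sc,
                                  stringsAsFactors = FALSE, check.names = FALSE),
              totals = totals)
  attr(out, "n_missing") <- n_missing
  class(out) <- "score_matrix"
  out
}

#' Percent correct
#'
#' The comparable performance metric across subtests:
#' `100 * total / n_items`, unrounded.
#'
#' @param total Achieved score (0 to `n_items`).
#' @param n_items Number of items in the test (positive).
#' @return Percentage as a real number.
#' @examples
#' percent_correct(3.63, 9)
#' @export
percent_correct <- function(total, n_items) {
  if (any(n_items <= 0)) stop_cs("n_items must be positive")
  if (any(total < 0 | total > n_items))
    stop_cs("total must lie in [0, n_items]")
  100 * total / n_items
}

#' Screen workers by Cognitive Reflection Test performance
#'
#' Partitions the pool into workers who passed (CRT total at or above the
#' threshold) and workers who failed. The default threshold of 2 out of 4 is
#' the study's screening criterion; 3 out of 4 is the stringent variant.
#'
#' @param scores A `score_matrix` from [score_responses()].
#' @param threshold Integer pass mark on the 4-item CRT (0-4).
#' @return A list of class `screen_result`: `threshold`, `passed`, `failed`
#'   (worker-id character vectors).
#' @export
screen_by_crt <- function(scores, threshold = 2L) {
  stopifnot(inherits(scores, "score_matrix"))
  if (threshold < 0) stop_cs("threshold must be non-negative")
  tot <- scores$totals
  passed <- tot$worker_id[tot$crt >= threshold]
  structure(list(threshold = as.integer(threshold),
                 passed = passed,
                 failed = setdiff(tot$worker_id, passed)),
            class = "screen_result")
}

#' Empirical response distribution for one item
#'
#' Relative frequency of each response option within a worker subset — the
#' per-item vote-probability vector that feeds both the plurality-vote
#' simulation and the exact Condorcet machinery. The optional
#' `collapse_unique` display variant folds options chosen by exactly one
#' worker into a single `"other"` bucket (for tabulation only; voting and
#' exact oracles always use the full distribution).
#'
#' @param responses A `response_matrix`.
#' @param item One-row slice of the item bank (or an item id plus `bank`).
#' @param subset Worker ids to include (default: all).
#' @param bank Item bank, needed when `item` is given as an id.
#' @param collapse_unique Fold single-vote options into `"other"`?
#' @return Data frame `option`, `count`, `p` (sums to 1), with attributes
#'   `item_id` and `n_workers`.
#' @export
response_distribution <- function(responses, item, subset = NULL,
                                  bank = NULL, collapse_unique = FALSE) {
  if (is.character(item)) {
    if (is.null(bank)) stop_cs("supply 'bank' when 'item' is an id")
    row <- match(item, bank$item_id)
    if (is.na(row)) stop_cs("unknown item '%s'", item)
    item <- bank[row, ]
  }
  subset <- subset %||% responses$worker_id
  if (!length(subset)) stop_cs("worker subset is empty")
  idx <- match(subset, responses$worker_id)
  if (anyNA(idx)) stop_cs("subset contains unknown worker ids")
  r <- responses[[item$item_id]][idx]
  opts <- item$options[[1]]
  counts <- vapply(opts, function(o) sum(r == o, na.rm = TRUE), numeric(1))
  out <- data.frame(option = opts, count = as.numeric(counts),
                    p = counts / sum(counts), stringsAsFactors = FALSE)
  if (collapse_unique && any(out$count == 1)) {
    uni <- out$count == 1
    kept <- out[!uni, , drop = FALSE]
    kept <- rbind(kept, data.frame(option = "other",
                                   count = sum(out$count[uni]),
                                   p = sum(out$p[uni])))
    out <- kept[order(-kept$count), ]
    rownames(out) <- NULL
  }
  attr(out, "item_id") <- item$item_id
  attr(out, "n_workers") <- length(subset)
  out
}
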