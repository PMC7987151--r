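#' Default 30-item reasoning battery
#'
#' Builds the item bank used throughout the package: a stand-in for a
#' four-subtest, 30-question crowdsolving battery. Item texts are keyed by
#' construct name only; option labels are abstract. Subtests:
#'
#' * `CRT` — 4 Cognitive Reflection Test items. Open-numeric response format:
#'   each item carries a canonical correct numeric answer, a canonical
#'   intuitive "lure" answer, and a catch-all `"other"` category. Free-text
#'   normalization (see [load_responses()]) maps raw strings onto these
#'   canonical labels.
#' * `RSPM` — 9 Raven's Standard Progressive Matrices (short form) items,
#'   8-option multiple choice, no designated lure.
#' * `HBT` — 9 heuristics-and-biases items, one per rational-thinking
#'   construct, 3–5 options each, every item with a designated lure (the
#'   intuitively appealing wrong answer).
#' * `SRT` — 8 syllogistic validity judgements (options `valid`/`invalid`),
#'   4 congruent and 4 incongruent (belief-bias) items; the lure is the
#'   belief-consistent wrong judgement.
#'
#' Each item also carries `target_p`, the marginal probability of a correct
#' answer the default trait model is calibrated to. Targets are anchored to
#' the study-scale subtest means (CRT 1.27/4, RSPM 4.76/9, HBT 3.63/9,
#' SRT-incongruent 1.45/4, SRT-congruent 3.66/4) with per-item spread chosen
#' so that the full-pool modal answer is incorrect exactly on the
#' lure-dominated items: HBT `sample_size_accounting`, `covariation_detection`
#' and (weakly) `methodological_reasoning`, plus all four incongruent SRT
#' items.
#'
#' @return A data frame with one row per item and columns `item_id`,
#'   `subtest`, `construct`, `options` (list column of option labels),
#'   `correct`, `lure` (`NA` if none), `congruent` (logical, `NA` outside
#'   SRT), `type` (`"choice"` or `"open"`), and `target_p`.
#' @examples
#' bank <- default_item_bank()
#' table(bank$subtest)
#' @export
default_item_bank <- function() {
  rows <- list()
  add <- function(item_id, subtest, construct, options, correct, lure,
                  congruent, type, target_p) {
    rows[[length(rows) + 1L]] <<- data.frame(
      item_id = item_id, subtest = subtest, construct = construct,
      options = I(list(options)), correct = correct,
      lure = if (is.null(lure)) NA_character_ else lure,
      congruent = if (is.null(congruent)) NA else congruent,
      type = type, target_p = target_p, stringsAsFactors = FALSE
    )
  }

  # CRT: canonical numeric answers (stand-ins, not published item text).
  # Options are canonical strings; raw free text is normalized at load time.
  crt <- list(
    list(id = "crt_1", correct = "5",  lure = "10",  p = 0.20),
    list(id = "crt_2", correct = "47", lure = "24",  p = 0.28),
    list(id = "crt_3", correct = "4",  lure = "8",   p = 0.35),
    list(id = "crt_4", correct = "29", lure = "30",  p = 0.44)
  )
  for (it in crt) {
    add(it$id, "CRT", "cognitive_reflection",
        c(it$correct, it$lure, "other"), it$correct, it$lure,
        NULL, "open", it$p)
  }

  # RSPM: 8-option matrices, difficulty increasing through the set.
  rspm_p <- c(0.82, 0.70, 0.63, 0.58, 0.53, 0.45, 0.40, 0.35, 0.30)
  for (i in seq_len(9)) {
    add(sprintf("rspm_%d", i), "RSPM", "inductive_reasoning",
        paste0("O", 1:8), "O1", NULL, NULL, "choice", rspm_p[i])
  }

  # HBT: one item per construct; (k, target accuracy, lure share of the
  # incorrect mass) chosen so the item-level error rates span ~29.5%-85.3%
  # and exactly the three listed constructs are lure-modal in the full pool.
  hbt <- list(
    list(c = "methodological_reasoning", k = 4, p = 0.300, lam = 0.60),
    list(c = "sample_size_accounting",   k = 4, p = 0.250, lam = 0.80),
    list(c = "probability_matching",     k = 4, p = 0.550, lam = 0.50),
    list(c = "covariation_detection",    k = 4, p = 0.147, lam = 0.85),
    list(c = "regression_to_the_mean",   k = 5, p = 0.350, lam = 0.30),
    list(c = "probabilistic_reasoning",  k = 3, p = 0.500, lam = 0.40),
    list(c = "gamblers_fallacy",         k = 3, p = 0.705, lam = 0.50),
    list(c = "causal_base_rate",         k = 5, p = 0.408, lam = 0.45),
    list(c = "denominator_neglect",      k = 3, p = 0.420, lam = 0.55)
  )
  for (i in seq_along(hbt)) {
    it <- hbt[[i]]
    opts <- LETTERS[seq_len(it$k)]
    # correct = "A", lure = "B" by convention; labels are abstract.
    add(sprintf("hbt_%d", i), "HBT", it$c, opts, "A", "B", NULL, "choice", it$p)
  }

  # SRT: binary validity judgements. Incongruent items: belief-consistent
  # wrong judgement is the lure; only one incorrect option so lambda = 1.
  srt_cong_p <- c(0.90, 0.91, 0.92, 0.93)
  srt_inc_p  <- c(0.33, 0.35, 0.38, 0.39)
  for (i in 1:4) {
    add(sprintf("srt_cong_%d", i), "SRT", "syllogism_congruent",
        c("valid", "invalid"), if (i %% 2) "valid" else "invalid",
        if (i %% 2) "invalid" else "valid", TRUE, "choice", srt_cong_p[i])
  }
  for (i in 1:4) {
    add(sprintf("srt_inc_%d", i), "SRT", "syllogism_incongruent",
        c("valid", "invalid"), if (i %% 2) "invalid" else "valid",
        if (i %% 2) "valid" else "invalid", FALSE, "choice", srt_inc_p[i])
  }

  bank <- do.call(rbind, rows)
  validate_item_bank(bank)
  bank
}

# HBT lure share of incorrect mass, matching default_item_bank() above; used
# by default_trait_params().
.hbt_default_lambda <- c(0.60, 0.80, 0.50, 0.85, 0.30, 0.40, 0.50, 0.45, 0.55)

validate_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank))
  need <- c("item_id", "subtest", "construct", "options", "correct",
            "lure", "congruent", "type", "target_p")
  miss <- setdiff(need, names(bank))
  if (length(miss)) stop_cs("item bank missing columns: %s",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(bank$item_id))
    stop_cs("duplicate item ids in bank")
  for (i in seq_len(nrow(bank))) {
    opts <- bank$options[[i]]
    if (!(bank$correct[i] %in% opts))
      stop_cs("item '%s': correct option not among options", bank$item_id[i])
    if (!is.na(bank$lure[i])) {
      if (!(bank$lure[i] %in% opts))
        stop_cs("item '%s': lure option not among options", bank$item_id[i])
      if (bank$lure[i] == bank$correct[i])
        stop_cs("item '%s': lure must differ from correct", bank$item_id[i])
    }
    if (bank$subtest[i] == "SRT" && is.na(bank$congruent[i]))
      stop_cs("item '%s': SRT items need a congruent flag", bank$item_id[i])
    if (bank$subtest[i] != "SRT" && !is.na(bank$congruent[i]))
      stop_cs("item '%s': congruent flag is SRT-only", bank$item_id[i])
  }
  invisible(bank)
}

#' Subtest membership of an item bank
#'
#' @param bank An item bank as returned by [default_item_bank()].
#' @return Named list of item-id character vectors: `crt`, `rspm`, `hbt`,
#'   `srt_congruent`, `srt_incongruent`.
#' @export
subtest_items <- function(bank) {
  list(
    crt  = bank$item_id[bank$subtest == "CRT"],
    rspm = bank$item_id[bank$subtest == "RSPM"],
    hbt  = bank$item_id[bank$subtest == "HBT"],
    srt_congruent  = bank$item_id[bank$subtest == "SRT" & bank$congruent %in% TRUE],
    srt_incongruent = bank$item_id[bank$subtest == "SRT" & bank$congruent %in% FALSE]
  )
}
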