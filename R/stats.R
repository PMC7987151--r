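#' Descriptive summary of subtest performance
#'
#' Mean, sample SD (n-1 denominator) and median per subtest for a worker
#' subset — the descriptive table layout used for pool characterization
#' (score range, mean (SD), median per subtest).
#'
#' @param scores A `score_matrix` from [score_responses()].
#' @param subset Worker ids to include (default: all).
#' @return Data frame `subtest`, `range_max`, `n`, `mean`, `sd`, `median`,
#'   `percent_correct`.
#' @export
summarize_scores <- function(scores, subset = NULL) {
  stopifnot(inherits(scores, "score_matrix"))
  tot <- scores$totals
  subset <- subset %||% tot$worker_id
  if (!length(subset)) stop_cs("worker subset is empty")
  idx <- match(subset, tot$worker_id)
  if (anyNA(idx)) stop_cs("subset contains unknown worker ids")
  cols <- c(crt = 4, rspm = 9, hbt = 9, srt_incongruent = 4, srt_congruent = 4)
  out <- do.call(rbind, lapply(names(cols), function(cn) {
    x <- tot[[cn]][idx]
    data.frame(subtest = cn, range_max = cols[[cn]], n = length(x),
               mean = mean(x), sd = stats::sd(x), median = stats::median(x),
               percent_correct = percent_correct(mean(x), cols[[cn]]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Nonparametric (Spearman) correlation
#'
#' Spearman rank correlation with average ranks for ties; the p-value uses
#' the large-sample t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on `n - 2` degrees of freedom. A Pearson variant is available via
#' `method`.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return List `rho`, `p`, `n`, `method`.
#' @export
spearman_corr <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_cs("correlation undefined: constant input vector")
  rho <- stats::cor(x, y, method = method)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Welch two-sample t test from summary statistics or raw samples
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom and a
#' 95% confidence interval for the mean difference. Accepts either the two
#' summary triplets (mean, SD, n) or two raw samples via `x` and `y` (the
#' raw path recomputes the summaries and reuses the same formulas).
#'
#' @param m1,s1,n1,m2,s2,n2 Group summaries (sample SDs, n-1 denominator).
#' @param x,y Optional raw samples overriding the summaries.
#' @param conf_level Confidence level for the interval.
#' @return List of class `welch_result`: `t`, `df`, `p`, `estimate`
#'   (mean difference), `ci` (length-2 vector), `conf_level`.
#' @examples
#' welch_t(2.63, 0.65, 35, 0.48, 0.50, 60)
#' @export
welch_t <- function(m1, s1, n1, m2, s2, n2, x = NULL, y = NULL,
                    conf_level = 0.95) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    m1 <- mean(x); s1 <- stats::sd(x); n1 <- length(x)
    m2 <- mean(y); s2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  if (s1 == 0 && s2 == 0)
    stop_cs("degenerate: both group SDs are zero")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  se <- sqrt(v1 + v2)
  tt <- (m1 - m2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  crit <- stats::qt(1 - (1 - conf_level) / 2, df = df)
  structure(list(t = tt, df = df, p = p, estimate = m1 - m2,
                 ci = c((m1 - m2) - crit * se, (m1 - m2) + crit * se),
                 conf_level = conf_level),
            class = "welch_result")
}

#' Chi-square contrast of correct-answer proportions between screened groups
#'
#' Pearson chi-square (df = 1, no continuity correction by default) on the
#' 2x2 table of passed/failed workers by correct/incorrect answer for one
#' item — the per-item check of whether screened workers converge on the
#' correct answer more often.
#'
#' @param responses A `response_matrix`.
#' @param item Item id.
#' @param bank Item bank.
#' @param screen A `screen_result` from [screen_by_crt()].
#' @param correct_continuity Apply Yates correction?
#' @return List `statistic`, `df`, `p`, `table` (2x2), `p_correct`
#'   (named proportions for passed/failed). With a zero marginal the test is
#'   undefined: `statistic` and `p` are `NA` and `degenerate` is `TRUE`.
#' @export
chisq_pass_fail <- function(responses, item, bank, screen,
                            correct_continuity = FALSE) {
  stopifnot(inherits(screen, "screen_result"))
  if (!length(screen$passed) || !length(screen$failed))
    stop_cs("both screened groups must be non-empty")
  row <- match(item, bank$item_id)
  if (is.na(row)) stop_cs("unknown item '%s'", item)
  correct_of <- function(ids) {
    r <- responses[[item]][match(ids, responses$worker_id)]
    c(correct = sum(r == bank$correct[row], na.rm = TRUE),
      incorrect = sum(r != bank$correct[row] | is.na(r)))
  }
  tab <- rbind(passed = correct_of(screen$passed),
               failed = correct_of(screen$failed))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    res <- list(statistic = NA_real_, df = 1L, p = NA_real_)
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(tab, correct = correct_continuity))
    res <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value)
  }
  c(res, list(table = tab,
              p_correct = tab[, "correct"] / rowSums(tab),
              degenerate = degenerate))
}

#' Estimate full-scale IQ from the short-form matrices score
#'
#' Synthetic stand-in mapping (the published short-form-to-IQ conversion is
#' not reproduced here): a linear rescaling of the pool-referenced z score
#' onto the IQ metric, `100 + 15 * (score - mean) / sd`. Standardized
#' regression results are invariant to this affine choice.
#'
#' @param rspm_total Short-form matrices total (0-9), vectorized.
#' @param ref_mean,ref_sd Reference pool mean and SD (SD > 0).
#' @return IQ-scale scores.
#' @export
estimate_iq <- function(rspm_total, ref_mean, ref_sd) {
  if (ref_sd <= 0) stop_cs("reference SD must be positive")
  100 + 15 * (rspm_total - ref_mean) / ref_sd
}

#' Hierarchical (blockwise) ordinary least squares regression
#'
#' Fits a sequence of nested OLS models, each block adding predictors to the
#' previous one, and reports standardized coefficients (all variables
#' z-scored), adjusted R-squared, and the R-squared change with its F test
#' (`dfs = (number of added predictors, n - k_full - 1)`).
#'
#' @param data Data frame holding outcome and predictors.
#' @param outcome Name of the outcome column.
#' @param blocks List of character vectors; block `j` fits the union of
#'   blocks `1..j`.
#' @return List of class `hier_regression`; one element per block with
#'   `predictors`, `coefficients` (data frame `term`, `beta`, `t`, `p`),
#'   `r_squared`, `adj_r_squared`, `delta_r_squared`, `delta_f`,
#'   `delta_df`, `delta_p`.
#' @export
hierarchical_regression <- function(data, outcome, blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  all_pred <- unique(unlist(blocks))
  miss <- setdiff(c(outcome, all_pred), names(data))
  if (length(miss))
    stop_cs("columns not in data: %s", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n <= length(all_pred) + 1)
    stop_cs("need more rows than predictors plus one")

  z <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop_cs("constant column cannot be standardized")
    (v - mean(v)) / s
  }
  zd <- as.data.frame(lapply(data[c(outcome, all_pred)], z))

  out <- vector("list", length(blocks))
  prev_r2 <- 0
  prev_k <- 0
  cum <- character(0)
  for (j in seq_along(blocks)) {
    cum <- unique(c(cum, blocks[[j]]))
    fml <- stats::reformulate(cum, response = outcome)
    fit <- stats::lm(fml, data = zd)
    if (fit$rank < length(cum) + 1) {
      alias <- names(which(is.na(stats::coef(fit))))
      stop_cs("rank-deficient design: collinear columns %s",
              paste(alias, collapse = ", "))
    }
    sm <- summary(fit)
    r2 <- sm$r.squared
    k <- length(cum)
    dk <- k - prev_k
    df2 <- n - k - 1
    dF <- ((r2 - prev_r2) / dk) / ((1 - r2) / df2)
    co <- stats::coef(sm)
    out[[j]] <- list(
      predictors = cum,
      coefficients = data.frame(term = rownames(co), beta = co[, 1],
                                t = co[, 3], p = co[, 4],
                                row.names = NULL, stringsAsFactors = FALSE),
      r_squared = r2, adj_r_squared = sm$adj.r.squared,
      delta_r_squared = r2 - prev_r2, delta_f = dF,
      delta_df = c(dk, df2),
      delta_p = stats::pf(dF, dk, df2, lower.tail = FALSE)
    )
    prev_r2 <- r2
    prev_k <- k
  }
  class(out) <- "hier_regression"
  out
}
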