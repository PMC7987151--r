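#' Run configuration for the full analysis
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_workers Pool size when simulating (ignored when `responses_csv`
#'   is given).
#' @param responses_csv Optional path to a worker-by-item response CSV; when
#'   `NULL` a synthetic pool is generated.
#' @param bank Item bank (answer key).
#' @param params Trait parameters for simulation.
#' @param threshold CRT screening threshold (2 default, 3 stringent).
#' @param sizes Nominal group sizes.
#' @param B Replicates per group size.
#' @param out_dir Optional output directory; when given, CSV/JSON artifacts
#'   and a run log are written there.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_workers = 95L, responses_csv = NULL,
                       bank = default_item_bank(),
                       params = default_trait_params(bank),
                       threshold = 2L, sizes = 1:25, B = 1000L,
                       out_dir = NULL) {
  if (!is.null(responses_csv) && !file.exists(responses_csv))
    stop_cs("responses file '%s' does not exist", responses_csv)
  if (!all(threshold %in% 0:4))
    stop_cs("CRT thresholds must lie in 0..4")
  structure(list(seed = as.integer(seed), n_workers = as.integer(n_workers),
                 responses_csv = responses_csv, bank = bank, params = params,
                 threshold = as.integer(threshold), sizes = as.integer(sizes),
                 B = as.integer(B), out_dir = out_dir),
            class = "run_config")
}

#' Run the complete crowdsolving analysis
#'
#' Executes the whole pipeline: generate (or load) the worker pool, score it,
#' screen by CRT, tabulate per-item response distributions, estimate
#' accuracy-versus-group-size curves for the HBT and the two SRT halves in
#' the full / passed / failed pools, overlay exact finite-pool Condorcet
#' curves, and compute the descriptive and inferential statistics (summary
#' table, rank correlations, Welch t of passed vs failed CRT means, per-item
#' chi-squares, hierarchical regressions, aggregation effect sizes).
#' Group sizes are capped at the relevant pool size (a stringent screen
#' shrinks the passed pool, and with it the largest investigable group).
#' Reruns with the same configuration are bit-identical.
#'
#' @param config A [run_config()].
#' @return A list of class `crowd_report`; see the elements in the examples.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  bank <- config$bank
  st <- subtest_items(bank)

  responses <- if (is.null(config$responses_csv)) {
    sample_pool(pool_spec(config$n_workers, bank, config$params, config$seed))
  } else {
    load_responses(config$responses_csv, bank)
  }
  demo <- sample_demographics(nrow(responses),
                              seed = derive_seed(config$seed, 17L))
  scores <- score_responses(responses, bank)
  screen <- screen_by_crt(scores, config$threshold)

  bias_items <- c(st$hbt, st$srt_incongruent)
  distributions <- lapply(stats::setNames(bias_items, bias_items), function(id)
    response_distribution(responses, id, bank = bank))
  distributions_passed <- lapply(stats::setNames(bias_items, bias_items),
                                 function(id)
    response_distribution(responses, id, subset = screen$passed, bank = bank))

  pools <- list(all = responses$worker_id, passed = screen$passed,
                failed = screen$failed)
  tests <- list(HBT = st$hbt, SRT_incongruent = st$srt_incongruent,
                SRT_congruent = st$srt_congruent)
  curves <- list()
  for (pn in names(pools)) {
    for (tn in names(tests)) {
      sizes <- config$sizes[config$sizes <= length(pools[[pn]])]
      if (!length(sizes)) next
      cfg <- group_config(sizes, config$B,
                          derive_seed(config$seed, match(pn, names(pools)),
                                      match(tn, names(tests))))
      curves[[paste(tn, pn, sep = ".")]] <-
        accuracy_curves(responses, bank, tests[[tn]], cfg,
                        pool = pools[[pn]], test_label = tn)
    }
  }

  # exact finite-pool plurality curves for the bias items, full vs passed pool
  exact <- lapply(stats::setNames(bias_items, bias_items), function(id) {
    row <- match(id, bank$item_id)
    ci <- match(bank$correct[row], bank$options[[row]])
    list(all = cjt_curve(distributions[[id]], ci,
                         sizes = config$sizes[config$sizes <= nrow(responses)],
                         backend = "hypergeometric"),
         passed = cjt_curve(distributions_passed[[id]], ci,
                            sizes = config$sizes[config$sizes <= length(screen$passed)],
                            backend = "hypergeometric"))
  })

  tot <- scores$totals
  pass_ind <- as.integer(tot$worker_id %in% screen$passed)
  welch <- welch_t(x = tot$crt[pass_ind == 1], y = tot$crt[pass_ind == 0])
  correlations <- list(
    crt_hbt = spearman_corr(tot$crt, tot$hbt),
    crt_srt_incongruent = spearman_corr(tot$crt, tot$srt_incongruent),
    rspm_hbt = spearman_corr(tot$rspm, tot$hbt),
    rspm_srt_incongruent = spearman_corr(tot$rspm, tot$srt_incongruent))
  chisq <- lapply(stats::setNames(bias_items, bias_items), function(id)
    chisq_pass_fail(responses, id, bank, screen))

  reg_data <- data.frame(
    hbt = tot$hbt, srt_incongruent = tot$srt_incongruent,
    age = demo$age, female = demo$female, tertiary = demo$tertiary,
    iq = estimate_iq(tot$rspm, mean(tot$rspm), stats::sd(tot$rspm)),
    passed_crt = pass_ind)
  blocks <- list(c("age", "female", "tertiary"), "iq", "passed_crt")
  regressions <- list(
    hbt = hierarchical_regression(reg_data, "hbt", blocks),
    srt_incongruent = hierarchical_regression(reg_data, "srt_incongruent",
                                              blocks))

  effect_sizes <- lapply(curves, function(cv)
    max_gain_effect_size(cv, n_low = min(cv$sizes), n_high = max(cv$sizes)))
  directions <- lapply(exact, function(e) attr(e$all, "direction"))

  report <- structure(list(
    config = config, responses = responses, demographics = demo,
    scores = scores, screen = screen,
    summary_all = summarize_scores(scores),
    summary_passed = summarize_scores(scores, screen$passed),
    distributions = distributions,
    distributions_passed = distributions_passed,
    curves = curves, exact_curves = exact,
    welch_crt = welch, correlations = correlations, chisq = chisq,
    regressions = regressions, effect_sizes = effect_sizes,
    item_directions = directions
  ), class = "crowd_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the tabular artifacts of a full analysis
#'
#' Emits fixed-dialect CSVs (curves, summaries, distributions), a JSON
#' record of the inferential statistics at full precision, and a plain-text
#' run log with the seeds consumed by each stage.
#'
#' @param report A `crowd_report`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }

  curve_rows <- do.call(rbind, lapply(names(report$curves), function(nm) {
    cv <- report$curves[[nm]]
    pool <- sub("^.*\\.", "", nm)
    rbind(
      data.frame(test = cv$test, pool = pool, n = cv$summary$n,
                 item_id = "OVERALL", accuracy = cv$summary$mean_score,
                 sd = cv$summary$sd_score, B = cv$B, seed = cv$seed),
      data.frame(test = cv$test, pool = pool, n = cv$item_accuracy$n,
                 item_id = cv$item_accuracy$item_id,
                 accuracy = cv$item_accuracy$accuracy,
                 sd = NA_real_, B = cv$B, seed = cv$seed))
  }))
  w(curve_rows, "curves.csv")

  exact_rows <- do.call(rbind, lapply(names(report$exact_curves), function(id) {
    e <- report$exact_curves[[id]]
    do.call(rbind, lapply(names(e), function(pool)
      data.frame(backend = attr(e[[pool]], "backend"), pool = pool,
                 item_id = id, n = e[[pool]]$n, probability = e[[pool]]$prob,
                 direction = attr(e[[pool]], "direction"))))
  }))
  w(exact_rows, "condorcet_curves.csv")

  w(cbind(pool = "all", report$summary_all), "summary_all.csv")
  w(cbind(pool = "passed", report$summary_passed), "summary_passed.csv")

  dist_rows <- do.call(rbind, lapply(names(report$distributions), function(id)
    cbind(item_id = id, pool = "all", report$distributions[[id]])))
  w(dist_rows, "response_distributions.csv")

  stats_json <- list(
    welch_crt = unclass(report$welch_crt),
    correlations = report$correlations,
    chisq = lapply(report$chisq, function(x)
      x[c("statistic", "df", "p", "degenerate")]),
    effect_sizes = lapply(report$effect_sizes, unclass),
    delta_r2 = lapply(report$regressions, function(r)
      vapply(r, `[[`, numeric(1), "delta_r_squared")))
  pj <- file.path(out_dir, "statistics.json")
  jsonlite::write_json(stats_json, pj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, pj)

  log_lines <- c(
    sprintf("crowdscreen run log"),
    sprintf("seed: %d", report$config$seed),
    sprintf("n_workers: %d", nrow(report$responses)),
    sprintf("threshold: %d", report$config$threshold),
    sprintf("B: %d", report$config$B),
    sprintf("sizes: %s", paste(report$config$sizes, collapse = ",")),
    sprintf("demographics seed: %d", derive_seed(report$config$seed, 17L)),
    vapply(report$curves, function(cv)
      sprintf("curve %s pool_size=%d seed=%d", cv$test, cv$pool_size, cv$seed),
      character(1)),
    sprintf("package version: %s",
            as.character(utils::packageVersion("crowdscreen"))))
  pl <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, pl)
  invisible(c(paths, pl))
}
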