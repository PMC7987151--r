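#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t: t(%.2f) = %.2f, p = %.3g\n",
              x$df, x$t, x$p))
  cat(sprintf("mean difference %.3f, %g%% CI [%.3f, %.3f]\n",
              x$estimate, 100 * x$conf_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("CRT screen at >= %d/4: %d passed, %d failed\n",
              x$threshold, length(x$passed), length(x$failed)))
  invisible(x)
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("Accuracy curve '%s': pool %d workers, sizes %d..%d, B = %d\n",
              x$test, x$pool_size, min(x$sizes), max(x$sizes), x$B))
  print(utils::head(x$summary, 3), row.names = FALSE)
  if (nrow(x$summary) > 3) cat(sprintf("... (%d sizes)\n", nrow(x$summary)))
  invisible(x)
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("Cohen's d (n = %d vs n = %d): %.3f (%s)\n",
              x$n_high, x$n_low, x$d, x$direction))
  invisible(x)
}

#' @export
print.pool_spec <- function(x, ...) {
  cat(sprintf("Synthetic pool spec: %d workers, %d items, seed %d\n",
              x$n_workers, nrow(x$bank), x$seed))
  invisible(x)
}
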