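#!/usr/bin/env Rscript
# Stage 5: inferential layer — rank correlations between cognitive
# reflection and the bias measures, Welch t between screened groups,
# per-item chi-square contrasts, and hierarchical regressions with
# R-squared-change tests.
suppressPackageStartupMessages(library(crowdscreen))

seed <- 1L
bank <- read_item_bank("results/item_bank.json")
pool <- load_responses("results/responses.csv", bank)
sc <- score_responses(pool, bank)
scr <- screen_by_crt(sc, 2L)
tot <- sc$totals
st <- subtest_items(bank)

co <- list(crt_hbt = spearman_corr(tot$crt, tot$hbt),
           crt_srt_inc = spearman_corr(tot$crt, tot$srt_incongruent),
           rspm_hbt = spearman_corr(tot$rspm, tot$hbt),
           rspm_srt_inc = spearman_corr(tot$rspm, tot$srt_incongruent))
cat("Spearman correlations (rho, p):\n")
for (nm in names(co))
  cat(sprintf("  %-12s rho = %.3f  p = %.2g\n", nm, co[[nm]]$rho, co[[nm]]$p))

w <- welch_t(x = tot$crt[tot$worker_id %in% scr$passed],
             y = tot$crt[tot$worker_id %in% scr$failed])
cat(sprintf("Welch t on CRT means, passed vs failed: t(%.2f) = %.2f, 95%% CI [%.2f, %.2f]\n",
            w$df, w$t, w$ci[1], w$ci[2]))

bias_items <- c(st$hbt, st$srt_incongruent)
chi <- do.call(rbind, lapply(bias_items, function(id) {
  r <- chisq_pass_fail(pool, id, bank, scr)
  data.frame(item_id = id, chisq = r$statistic, df = r$df, p = r$p,
             p_correct_passed = r$p_correct[["passed"]],
             p_correct_failed = r$p_correct[["failed"]])
}))
write.csv(chi, "results/chisq_items.csv", row.names = FALSE)
cat(sprintf("Chi-square screening contrasts: %d of %d bias items p < .05 (%d of 4 belief-bias)\n",
            sum(chi$p < 0.05, na.rm = TRUE), nrow(chi),
            sum(chi$p[grep("^srt", chi$item_id)] < 0.05, na.rm = TRUE)))

demo <- sample_demographics(nrow(pool), seed = derive_seed(seed, 17L))
reg <- data.frame(hbt = tot$hbt, srt_incongruent = tot$srt_incongruent,
                  age = demo$age, female = demo$female,
                  tertiary = demo$tertiary,
                  iq = estimate_iq(tot$rspm, mean(tot$rspm), sd(tot$rspm)),
                  passed_crt = as.integer(tot$worker_id %in% scr$passed))
blocks <- list(c("age", "female", "tertiary"), "iq", "passed_crt")
tab2 <- list()
for (outc in c("hbt", "srt_incongruent")) {
  fit <- hierarchical_regression(reg, outc, blocks)
  for (j in seq_along(fit)) {
    cf <- fit[[j]]$coefficients
    tab2[[paste(outc, j)]] <- data.frame(
      outcome = outc, model = j, term = cf$term, beta = cf$beta,
      t = cf$t, p = cf$p, adj_r2 = fit[[j]]$adj_r_squared,
      delta_r2 = fit[[j]]$delta_r_squared, delta_f = fit[[j]]$delta_f,
      delta_p = fit[[j]]$delta_p)
  }
  cat(sprintf("%s: block-3 (CRT screen) dR2 = %.3f, F(%d,%d) = %.2f, p = %.3g\n",
              outc, fit[[3]]$delta_r_squared, fit[[3]]$delta_df[1],
              fit[[3]]$delta_df[2], fit[[3]]$delta_f, fit[[3]]$delta_p))
}
write.csv(do.call(rbind, tab2), "results/regressions.csv", row.names = FALSE)
cat("Wrote results/chisq_items.csv, results/regressions.csv\n")
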