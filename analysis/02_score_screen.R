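#!/usr/bin/env Rscript
# Stage 2: score the pool, screen by CRT (>= 2 of 4; stringent >= 3),
# summarize subtest performance, and tabulate per-item response
# distributions for the bias tests.
suppressPackageStartupMessages(library(crowdscreen))

bank <- read_item_bank("results/item_bank.json")
pool <- load_responses("results/responses.csv", bank)
sc <- score_responses(pool, bank)
scr <- screen_by_crt(sc, 2L)
scr3 <- screen_by_crt(sc, 3L)

write.csv(sc$totals, "results/subtest_totals.csv", row.names = FALSE)
write.csv(cbind(pool = "all", summarize_scores(sc)),
          "results/summary_all.csv", row.names = FALSE)
write.csv(cbind(pool = "passed", summarize_scores(sc, scr$passed)),
          "results/summary_passed.csv", row.names = FALSE)

st <- subtest_items(bank)
bias_items <- c(st$hbt, st$srt_incongruent)
dist <- do.call(rbind, lapply(bias_items, function(id) rbind(
  cbind(item_id = id, pool = "all",
        response_distribution(pool, id, bank = bank)),
  cbind(item_id = id, pool = "passed",
        response_distribution(pool, id, subset = scr$passed, bank = bank)))))
write.csv(dist, "results/response_distributions.csv", row.names = FALSE)

cat(sprintf("Screened %d/%d workers as passed (threshold 2/4); stringent 3/4: %d\n",
            length(scr$passed), nrow(pool), length(scr3$passed)))
sm <- summarize_scores(sc)
cat(sprintf("%-16s mean %.2f (SD %.2f), median %g, %.1f%% correct\n",
            sm$subtest, sm$mean, sm$sd, sm$median, sm$percent_correct))
lure_modal <- vapply(bias_items, function(id) {
  d <- response_distribution(pool, id, bank = bank)
  d$option[which.max(d$p)] != bank$correct[match(id, bank$item_id)]
}, logical(1))
cat("Items with an incorrect modal answer (full pool):",
    paste(bias_items[lure_modal], collapse = " "), "\n")
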