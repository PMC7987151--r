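#!/usr/bin/env Rscript
# Stage 3: nominal-group accuracy curves (n = 1..25, B = 1000 replicates) by
# plurality vote with random tie-breaking, for the HBT and both SRT halves,
# in the full, passed and failed pools; maximal-gain effect sizes.
suppressPackageStartupMessages(library(crowdscreen))

seed <- 1L
bank <- read_item_bank("results/item_bank.json")
pool <- load_responses("results/responses.csv", bank)
sc <- score_responses(pool, bank)
scr <- screen_by_crt(sc, 2L)
st <- subtest_items(bank)

pools <- list(all = pool$worker_id, passed = scr$passed, failed = scr$failed)
tests <- list(HBT = st$hbt, SRT_incongruent = st$srt_incongruent,
              SRT_congruent = st$srt_congruent)

rows <- list(); es_rows <- list()
for (pn in names(pools)) for (tn in names(tests)) {
  sizes <- (1:25)[1:25 <= length(pools[[pn]])]
  cfg <- group_config(sizes, 1000L,
                      derive_seed(seed, match(pn, names(pools)),
                                  match(tn, names(tests))))
  cv <- accuracy_curves(pool, bank, tests[[tn]], cfg, pool = pools[[pn]],
                        test_label = tn)
  rows[[paste(tn, pn)]] <- rbind(
    data.frame(test = tn, pool = pn, n = cv$summary$n, item_id = "OVERALL",
               accuracy = cv$summary$mean_score, sd = cv$summary$sd_score,
               B = cv$B, seed = cv$seed),
    data.frame(test = tn, pool = pn, n = cv$item_accuracy$n,
               item_id = cv$item_accuracy$item_id,
               accuracy = cv$item_accuracy$accuracy, sd = NA,
               B = cv$B, seed = cv$seed))
  es <- max_gain_effect_size(cv, n_high = max(sizes))
  es_rows[[paste(tn, pn)]] <- data.frame(
    test = tn, pool = pn, n_low = es$n_low, n_high = es$n_high,
    cohens_d = es$d, direction = es$direction)
}
write.csv(do.call(rbind, rows), "results/curves.csv", row.names = FALSE)
es <- do.call(rbind, es_rows); rownames(es) <- NULL
write.csv(es, "results/effect_sizes.csv", row.names = FALSE)

cat("Maximal aggregation gain/loss (Cohen's d, largest vs smallest n):\n")
print(es, digits = 3)
cat("\nReading: belief-bias (SRT incongruent) answers get WORSE with group\n",
    "size in the unscreened pool and better after CRT screening; the HBT\n",
    "improves in both pools.\n")
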