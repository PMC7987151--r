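# Independent brute-force oracles, kept free of the package's DP code paths.

# Labelled enumeration of all k^n voter outcomes under iid voting; win
# credit 1/t for the focal option among t tied maxima.
oracle_plurality_multinomial <- function(p, correct, n) {
  k <- length(p)
  grid <- expand.grid(rep(list(seq_len(k)), n))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    votes <- as.integer(grid[r, ])
    prob <- prod(p[votes])
    counts <- tabulate(votes, nbins = k)
    mx <- max(counts)
    tied <- which(counts == mx)
    if (correct %in% tied) total <- total + prob / length(tied)
  }
  total
}

# Enumeration of all C(total, n) unordered subsets of a labelled pool.
oracle_plurality_hypergeometric <- function(counts, correct, n) {
  k <- length(counts)
  voters <- rep(seq_len(k), counts)
  subs <- utils::combn(length(voters), n)
  total <- 0
  for (s in seq_len(ncol(subs))) {
    tab <- tabulate(voters[subs[, s]], nbins = k)
    mx <- max(tab)
    tied <- which(tab == mx)
    if (correct %in% tied) total <- total + 1 / length(tied)
  }
  total / ncol(subs)
}

# Tiny deterministic item bank: one 3-option item with a lure, one binary.
tiny_bank <- function() {
  data.frame(
    item_id = c("q1", "q2"),
    subtest = c("HBT", "SRT"),
    construct = c("toy_multi", "toy_binary"),
    options = I(list(c("A", "B", "C"), c("valid", "invalid"))),
    correct = c("A", "valid"),
    lure = c("B", "invalid"),
    congruent = c(NA, TRUE),
    type = "choice",
    target_p = c(0.5, 0.5),
    stringsAsFactors = FALSE
  )
}

# Build a response_matrix from explicit per-item answer vectors.
make_responses <- function(...) {
  cols <- list(...)
  n <- length(cols[[1]])
  df <- data.frame(worker_id = sprintf("w%03d", seq_len(n)), cols,
                   stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("response_matrix", "data.frame")
  df
}

default_bank_cached <- local({
  bank <- NULL
  function() {
    if (is.null(bank)) bank <<- default_item_bank()
    bank
  }
})

default_params_cached <- local({
  params <- NULL
  function() {
    if (is.null(params)) params <<- default_trait_params(default_bank_cached())
    params
  }
})
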