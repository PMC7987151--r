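# File formats: comma-separated UTF-8 CSV with header row and "." decimal;
# item banks as JSON records; trait parameters as YAML. Fixed dialect keeps
# the artifacts reproducible across languages.

#' Normalize a raw open-numeric response
#'
#' Trims, lowercases, strips currency and common unit tokens
#' (dollar/pound/euro signs, "cents"/"c", "days", "minutes", thousands
#' commas) and parses the remainder as a number. Unparseable strings are
#' returned verbatim (they are later matched against literal accepted
#' strings).
#'
#' @param x Character vector of raw responses.
#' @return List with `value` (numeric, `NA` where unparseable) and `text`
#'   (the cleaned string).
#' @export
normalize_open_response <- function(x) {
  tx <- tolower(trimws(x))
  cleaned <- gsub("[$£€,]", "", tx)
  cleaned <- gsub("\\b(cents?|c|dollars?|pounds?|euros?|days?|minutes?|mins?|hours?|hrs?)\\b",
                  "", cleaned)
  cleaned <- trimws(cleaned)
  val <- suppressWarnings(as.numeric(cleaned))
  list(value = val, text = cleaned)
}

# Match raw open-numeric responses onto an item's canonical option labels.
# Each canonical label has an accepted-value set: its numeric value (so
# "5", "5 cents", " 0.05" can all be mapped via the accepted set) plus the
# literal label. Anything unmatched falls into "other" when present.
match_open_responses <- function(raw, item, accepted = NULL) {
  opts <- item$options[[1]]
  canon <- setdiff(opts, "other")
  acc <- accepted %||% lapply(stats::setNames(canon, canon), function(o) {
    v <- suppressWarnings(as.numeric(o))
    list(values = v[!is.na(v)], strings = o)
  })
  norm <- normalize_open_response(raw)
  out <- rep(NA_character_, length(raw))
  for (o in names(acc)) {
    hit_num <- !is.na(norm$value) &
      vapply(norm$value, function(v) any(abs(v - acc[[o]]$values) < 1e-9),
             logical(1))
    hit_str <- norm$text %in% tolower(acc[[o]]$strings)
    out[is.na(out) & (hit_num | hit_str)] <- o
  }
  if ("other" %in% opts) out[is.na(out) & !is.na(raw)] <- "other"
  out
}

#' Read a worker-by-item response CSV
#'
#' Expects a header row `worker_id` followed by one column per item id.
#' Open-numeric items are normalized (trim, lowercase, strip currency/unit
#' tokens, parse number) and mapped onto their canonical option labels via
#' the item's accepted-value set; unparseable entries are matched against
#' literal accepted strings and otherwise fall into `"other"`.
#'
#' @param path CSV file path.
#' @param bank Item bank (answer key).
#' @param accepted Optional named list (by item id) of accepted-value sets
#'   for open items: each a named list of `list(values=, strings=)` per
#'   canonical option.
#' @return A validated `response_matrix`.
#' @export
load_responses <- function(path, bank, accepted = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (!nrow(df)) stop_cs("response file '%s' is empty", path)
  if (names(df)[1] != "worker_id")
    stop_cs("first column must be 'worker_id'")
  if (anyDuplicated(df$worker_id))
    stop_cs("duplicate worker id '%s'", df$worker_id[duplicated(df$worker_id)][1])
  unknown <- setdiff(names(df)[-1], bank$item_id)
  if (length(unknown))
    stop_cs("unknown item columns: %s", paste(unknown, collapse = ", "))
  df[df == ""] <- NA
  for (i in which(bank$type == "open")) {
    id <- bank$item_id[i]
    if (!id %in% names(df)) next
    df[[id]] <- match_open_responses(df[[id]], bank[i, ],
                                     accepted = accepted[[id]])
  }
  class(df) <- c("response_matrix", "data.frame")
  df
}

#' Write a response matrix as CSV
#' @param responses A `response_matrix`.
#' @param path Output path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write / read an item bank as JSON
#'
#' Schema: one record per item with fields `item_id`, `subtest`,
#' `construct`, `options` (array), `correct`, optional `lure`, optional
#' `congruent`, `type`, `target_p`.
#'
#' @param bank Item bank data frame.
#' @param path JSON file path.
#' @export
write_item_bank <- function(bank, path) {
  recs <- lapply(seq_len(nrow(bank)), function(i) {
    r <- list(item_id = bank$item_id[i], subtest = bank$subtest[i],
              construct = bank$construct[i], options = bank$options[[i]],
              correct = bank$correct[i], type = bank$type[i],
              target_p = bank$target_p[i])
    if (!is.na(bank$lure[i])) r$lure <- bank$lure[i]
    if (!is.na(bank$congruent[i])) r$congruent <- bank$congruent[i]
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(recs, function(r) {
    data.frame(item_id = r$item_id, subtest = r$subtest,
               construct = r$construct,
               options = I(list(unlist(r$options))), correct = r$correct,
               lure = r$lure %||% NA_character_,
               congruent = r$congruent %||% NA,
               type = r$type, target_p = r$target_p,
               stringsAsFactors = FALSE)
  })
  bank <- do.call(rbind, rows)
  validate_item_bank(bank)
  bank
}

#' Write / read trait-model parameters as YAML
#' @param params Trait parameter data frame (`item_id`, `a`, `b`, `lambda`).
#' @param path YAML file path.
#' @export
write_trait_params <- function(params, path) {
  yaml::write_yaml(lapply(seq_len(nrow(params)), function(i)
    list(item_id = params$item_id[i], a = params$a[i], b = params$b[i],
         lambda = params$lambda[i])), path, precision = 15L)
  invisible(path)
}

#' @rdname write_trait_params
#' @export
read_trait_params <- function(path) {
  recs <- yaml::read_yaml(path)
  do.call(rbind, lapply(recs, function(r)
    data.frame(item_id = r$item_id, a = r$a, b = r$b, lambda = r$lambda,
               stringsAsFactors = FALSE)))
}
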