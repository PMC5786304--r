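# Preprocessing: tokenization, drug anonymization, number masking,
# candidate generation, negative-instance filtering, deduplication.

#' Tokenize sentence text
#'
#' Deterministic whitespace + punctuation tokenization. Numbers (an
#' optionally signed integer or decimal with `.` or `,`) stay one token;
#' alphanumeric runs stay one token; every other non-space character
#' becomes its own token. Original 0-based half-open character offsets
#' are attached as attributes `start` and `end`.
#'
#' @param text a single character string (may be empty).
#' @return character vector of tokens.
#' @export
ddi_tokenize <- function(text) {
  stopifnot(length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(character(0))
  pat <- "[+-]?[0-9]+(?:[.,][0-9]+)?|[[:alnum:]_#]+|[^[:alnum:][:space:]]"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(text, list(m))[[1]]
  attr(toks, "start") <- as.integer(m) - 1L
  attr(toks, "end") <- as.integer(m) - 1L + attr(m, "match.length")
  toks
}

merge_intervals <- function(iv) {
  # iv: matrix with columns start,end (half-open), any order
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) for (r in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv[r, 1] <= out[k, 2]) out[k, 2] <- max(out[k, 2], iv[r, 2])
    else out <- rbind(out, iv[r, , drop = FALSE])
  }
  out
}

#' Anonymize target drugs in a sentence
#'
#' Every drug-like entity mention (`drug`, `brand`, `group`, `drug_n`)
#' is replaced by a placeholder `Ddrug{k}`, with `k` assigned by order
#' of first span start. A discontinuous mention collapses to a single
#' placeholder at its first span; all remaining annotated characters
#' (the union of every entity span) are deleted, which also resolves
#' mentions that share words (e.g. "nonheme and heme iron" where "iron"
#' belongs to two mentions). Replacement happens on the raw text,
#' before tokenization; whitespace runs are then collapsed.
#'
#' @param record a [ddi_sentence].
#' @return list with `text` (anonymized string), `tokens` (tokenized,
#'   numbers not yet masked), `map` (named integer vector: entity id ->
#'   1-based token index of its placeholder), `placeholders` (named
#'   character vector: entity id -> placeholder string).
#' @export
anonymize <- function(record) {
  ents <- Filter(function(e) e$etype %in% DRUG_LIKE_TYPES, record$entities)
  if (length(ents) == 0L) {
    toks <- ddi_tokenize(record$text)
    return(list(text = record$text, tokens = toks,
                map = integer(0), placeholders = character(0)))
  }
  firsts <- vapply(ents, function(e) e$spans[1, 1], 0L)
  ord <- order(firsts)
  ents <- ents[ord]
  firsts <- firsts[ord]
  fends <- vapply(ents, function(e) e$spans[1, 2], 0L)
  if (length(ents) > 1L && any(fends[-length(fends)] > firsts[-1L]))
    stop("sentence '", record$id,
         "': overlapping first spans of drug entities; cannot anonymize")
  placeholders <- paste0("Ddrug", seq_along(ents) - 1L)
  names(placeholders) <- vapply(ents, `[[`, "", "id")

  all_spans <- do.call(rbind, lapply(ents, `[[`, "spans"))
  removed <- merge_intervals(all_spans)

  # walk the removal intervals, emitting kept text and placeholders
  out <- character(0)
  cur <- 0L
  n <- nchar(record$text)
  for (r in seq_len(nrow(removed))) {
    s <- removed[r, 1]; e <- removed[r, 2]
    if (s > cur) out <- c(out, substr(record$text, cur + 1L, s))
    inside <- which(firsts >= s & firsts < e)
    if (length(inside))
      out <- c(out, paste(placeholders[inside], collapse = " "))
    cur <- e
  }
  if (cur < n) out <- c(out, substr(record$text, cur + 1L, n))
  text <- trimws(gsub("[[:space:]]+", " ", paste(out, collapse = "")))

  tokens <- ddi_tokenize(text)
  map <- match(placeholders, tokens)
  names(map) <- names(placeholders)
  if (anyNA(map))
    stop("sentence '", record$id, "': placeholder lost during tokenization")
  list(text = text, tokens = as.character(tokens), map = map,
       placeholders = placeholders)
}

#' Mask independent numbers
#'
#' Any whole token that is an optionally signed integer or decimal
#' literal becomes `"#"`. Tokens merely containing digits (e.g.
#' `CYP3A4`) are unchanged. Idempotent.
#'
#' @param tokens character vector of tokens.
#' @return character vector with numbers replaced by `"#"`.
#' @export
mask_numbers <- function(tokens) {
  ifelse(grepl("^[+-]?[0-9]+([.,][0-9]+)?$", tokens), "#", tokens)
}

#' Generate candidate instances for a sentence
#'
#' One [ddi_instance] per annotated pair when pair annotations exist
#' (pairs whose endpoints are not drug-like mentions are skipped); when
#' no pairs are annotated, every unordered pair of drug placeholders
#' becomes an unlabeled negative candidate. Fewer than two drugs yields
#' an empty list.
#'
#' @param record a [ddi_sentence].
#' @param anon result of [anonymize] on `record` (computed if missing).
#' @return list of [ddi_instance].
#' @export
generate_candidates <- function(record, anon = anonymize(record)) {
  tokens <- mask_numbers(anon$tokens)
  map <- anon$map
  if (length(map) < 2L) return(list())
  etext <- vapply(record$entities, `[[`, "", "text")
  names(etext) <- vapply(record$entities, `[[`, "", "id")
  mk <- function(e1, e2, label, type) {
    ddi_instance(sentence_id = record$id, e1 = e1, e2 = e2,
                 e1_text = etext[[e1]], e2_text = etext[[e2]],
                 tokens = tokens, targets = c(map[[e1]], map[[e2]]),
                 label = label, type = type)
  }
  if (length(record$pairs)) {
    out <- list()
    for (p in record$pairs) {
      if (!p$e1 %in% names(map) || !p$e2 %in% names(map)) next
      ty <- if (is.null(p$type)) NA_character_ else p$type
      out[[length(out) + 1L]] <-
        mk(p$e1, p$e2, if (isTRUE(p$ddi)) "positive" else "negative", ty)
    }
    out
  } else {
    ids <- names(map)
    out <- list()
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids))
      out[[length(out) + 1L]] <- mk(ids[i], ids[j], "negative", NA_character_)
    out
  }
}

#' Find coordination runs of drug placeholders
#'
#' A coordination run is a maximal subsequence of >= 2 drug placeholders
#' in which consecutive placeholders are separated only by one or more
#' of the tokens `","`, `"and"`, `"or"`, `"/"`. Pairs inside a run of
#' length >= 3 are the negative-instance filtering targets.
#'
#' @param tokens token vector.
#' @return list of integer vectors, each the token positions of the
#'   placeholders forming one run.
#' @keywords internal
coordination_runs <- function(tokens) {
  is_ph <- grepl("^Ddrug[0-9]+$", tokens)
  is_sep <- tokens %in% c(",", "and", "or", "/")
  pos <- which(is_ph)
  if (length(pos) == 0L) return(list())
  runs <- list(pos[1])
  if (length(pos) > 1L) for (k in 2:length(pos)) {
    between <- seq(pos[k - 1] + 1L, pos[k] - 1L)
    joined <- length(between) > 0L && all(is_sep[between])
    if (joined) runs[[length(runs)]] <- c(runs[[length(runs)]], pos[k])
    else runs[[length(runs) + 1L]] <- pos[k]
  }
  runs
}

new_filter_report <- function() {
  list(counts = c(same_drug = 0L, coordination = 0L, duplicate = 0L),
       ledger = list(), removed = list())
}

#' Filter negative candidate instances
#'
#' Two rules, applied per instance on its own token sequence:
#' \describe{
#'   \item{same-drug}{the two target surface forms are equal after
#'     trimming and lower-casing (optionally after mapping through a
#'     user-supplied synonym table);}
#'   \item{coordination}{both targets belong to one coordination run of
#'     three or more drug placeholders separated only by commas,
#'     `and`, `or`, or `/`.}
#' }
#' Gold positives are never removed from a training split unless
#' `filter_train_positives = TRUE`; gold positives removed from a test
#' split are recorded in the report's ledger and must later be counted
#' as false negatives (see [evaluate_predictions]).
#'
#' @param instances list of [ddi_instance].
#' @param split `"train"` or `"test"`.
#' @param filter_train_positives also drop training gold positives that
#'   match a rule (default `FALSE`).
#' @param synonym_map optional named character vector mapping surface
#'   forms (lower-cased) to canonical names before rule-1 comparison.
#' @return list with `kept` (instances) and `report` (a filter report
#'   with per-rule counts, a gold-positive ledger and all removals).
#' @export
filter_negatives <- function(instances, split = c("train", "test"),
                             filter_train_positives = FALSE,
                             synonym_map = NULL) {
  split <- match.arg(split)
  report <- new_filter_report()
  norm <- function(x) {
    x <- tolower(trimws(x))
    if (!is.null(synonym_map) && x %in% names(synonym_map))
      x <- tolower(synonym_map[[x]])
    x
  }
  kept <- list()
  for (inst in instances) {
    rule <- NULL
    if (norm(inst$e1_text) == norm(inst$e2_text)) {
      rule <- "same_drug"
    } else {
      runs <- coordination_runs(inst$tokens)
      for (r in runs) {
        if (length(r) >= 3L && all(inst$targets %in% r)) {
          rule <- "coordination"
          break
        }
      }
    }
    protected <- inst$label == "positive" && split == "train" &&
      !filter_train_positives
    if (is.null(rule) || protected) {
      kept[[length(kept) + 1L]] <- inst
    } else {
      inst$filtered <- TRUE
      report$counts[[rule]] <- report$counts[[rule]] + 1L
      report$removed[[length(report$removed) + 1L]] <- inst
      if (inst$label == "positive" && split == "test")
        report$ledger[[length(report$ledger) + 1L]] <- inst
    }
  }
  list(kept = kept, report = report)
}

#' Remove duplicate instances
#'
#' The duplicate key is the post-preprocessing token string together
#' with the two target indices; the first occurrence is kept.
#'
#' @param instances list of [ddi_instance].
#' @return list with `kept` and `report` (duplicate count + removals).
#' @export
deduplicate <- function(instances) {
  report <- new_filter_report()
  if (length(instances) == 0L) return(list(kept = instances, report = report))
  keys <- vapply(instances, function(x)
    paste(c(x$tokens, "|", x$targets), collapse = " "), "")
  dup <- duplicated(keys)
  removed <- instances[dup]
  removed <- lapply(removed, function(x) { x$duplicate <- TRUE; x })
  report$counts[["duplicate"]] <- sum(dup)
  report$removed <- removed
  list(kept = instances[!dup], report = report)
}

#' Preprocess a corpus into candidate instances
#'
#' Runs anonymization, number masking, candidate generation,
#' negative-instance filtering and deduplication over a list of
#' sentence records.
#'
#' @param records list of [ddi_sentence].
#' @inheritParams filter_negatives
#' @param drop_duplicates drop duplicate instances (default `TRUE`).
#' @return list with `instances` (kept [ddi_instance]s) and `report`
#'   (combined filter report; `report$ledger` holds gold positives
#'   filtered from a test split).
#' @export
preprocess_corpus <- function(records, split = c("train", "test"),
                              filter_train_positives = FALSE,
                              synonym_map = NULL, drop_duplicates = TRUE) {
  split <- match.arg(split)
  raw <- list()
  for (rec in records)
    raw <- c(raw, generate_candidates(rec))
  fl <- filter_negatives(raw, split = split,
                         filter_train_positives = filter_train_positives,
                         synonym_map = synonym_map)
  out <- fl$kept
  report <- fl$report
  if (drop_duplicates) {
    dd <- deduplicate(out)
    out <- dd$kept
    report$counts[["duplicate"]] <- dd$report$counts[["duplicate"]]
    report$removed <- c(report$removed, dd$report$removed)
  }
  report$n_raw <- length(raw)
  report$n_kept <- length(out)
  list(instances = out, report = report)
}
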