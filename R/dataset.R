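# Glue: turn (sentence records, bracketed trees) into model-ready
# compiled instances.

#' Prepare a model-ready dataset from a corpus and its parse trees
#'
#' Runs [preprocess_corpus], then for every kept instance binarizes
#' and annotates its sentence tree with the instance's target indices
#' and compiles it into post-order input arrays.
#'
#' @param records list of [ddi_sentence].
#' @param trees character vector of bracketed trees, aligned with
#'   `records` (one per sentence, leaves matching the preprocessed
#'   anonymized+masked tokens).
#' @param table an [embedding_table].
#' @inheritParams preprocess_corpus
#' @param codec distance encoder (default [encode_distance]).
#' @return list with `instances`, `comps` (aligned `compiled_tree`s),
#'   `labels` (detection), `types` (DDI type or `NA`), `labels5`
#'   (type for positives, `"negative"` otherwise) and the
#'   preprocessing `report`.
#' @export
prepare_dataset <- function(records, trees, table,
                            split = c("train", "test"),
                            filter_train_positives = FALSE,
                            synonym_map = NULL, drop_duplicates = TRUE,
                            codec = encode_distance) {
  split <- match.arg(split)
  stopifnot(length(records) == length(trees))
  tree_of <- stats::setNames(trees, vapply(records, `[[`, "", "id"))
  pp <- preprocess_corpus(records, split = split,
                          filter_train_positives = filter_train_positives,
                          synonym_map = synonym_map,
                          drop_duplicates = drop_duplicates)
  comps <- lapply(pp$instances, function(inst) {
    tr <- binarize(read_bracketed(tree_of[[inst$sentence_id]]))
    tr <- annotate_tree(tr, inst$tokens, inst$targets[1], inst$targets[2],
                        sentence_id = inst$sentence_id)
    compile_tree(tr, table, codec)
  })
  labels <- vapply(pp$instances, `[[`, "", "label")
  types <- vapply(pp$instances, `[[`, "", "type")
  labels5 <- ifelse(labels == "positive", types, "negative")
  list(instances = pp$instances, comps = comps, labels = labels,
       types = types, labels5 = labels5, report = pp$report)
}

#' Split a generated corpus into train and test parts
#'
#' Deterministic split by sentence position: the first
#' `round(train_frac * n)` sentences form the training part.
#'
#' @param corpus result of [generate_corpus] / [make_separable].
#' @param train_frac fraction of sentences for training (default 0.8).
#' @return list with `train` and `test`, each holding `records` and
#'   `trees`.
#' @export
split_corpus <- function(corpus, train_frac = 0.8) {
  n <- length(corpus$records)
  k <- round(train_frac * n)
  idx <- seq_len(k)
  list(train = list(records = corpus$records[idx],
                    trees = corpus$trees[idx]),
       test = list(records = corpus$records[-idx],
                   trees = corpus$trees[-idx]))
}
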