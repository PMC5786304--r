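# Synthetic corpus generator: self-contained toy corpora with planted
# lexical signals, emitted in the same XML + bracketed-tree formats the
# real pipeline consumes, so every stage is testable without downloads.

SYN_CLASSES <- c("negative", "advice", "effect", "mechanism", "int")

syn_templates <- list(
  advice = list(
    c("@D1", "should", "not", "be", "combined", "with", "@D2", "."),
    c("caution", "is", "advised", "when", "@D1", "is", "combined",
      "with", "@D2", ".")),
  effect = list(
    c("@D1", "enhanced", "the", "toxicity", "of", "@D2", "."),
    c("the", "toxicity", "of", "@D2", "was", "markedly", "enhanced",
      "by", "@D1", ".")),
  mechanism = list(
    c("@D1", "increased", "the", "plasma", "concentration", "of",
      "@D2", "."),
    c("@D1", "raised", "the", "concentration", "of", "@D2", "by",
      "2.5", "fold", "."),
    c("the", "plasma", "concentration", "of", "@D2", "rose", "after",
      "@D1", "administration", ".")),
  int = list(
    c("@D1", "interacts", "with", "@D2", "."),
    c("it", "is", "known", "that", "@D1", "interacts", "with",
      "@D2", ".")),
  negative = list(
    c("@D1", "was", "administered", "while", "@D2", "levels", "were",
      "monitored", "."),
    c("patients", "received", "@D1", "before", "@D2", "therapy", "."),
    c("the", "study", "measured", "@D1", "exposure", "after", "@D2",
      "dosing", "."),
    c("@D1", "and", "@D2", "were", "detected", "in", "plasma",
      "samples", "."),
    c("serum", "@D1", "levels", "and", "@D2", "levels", "were",
      "within", "the", "normal", "range", "."))
)

# class-indicative trigger tokens; negatives contain none of them
syn_triggers <- c("combined", "toxicity", "concentration", "interacts")

#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the structure of DDI challenge corpora:
#' sentences with annotated drug mentions and exhaustively annotated
#' pairs, a roughly balanced detection task, occasional distractor
#' drugs (a third drug forming negative pairs inside a positive
#' sentence), coordination runs of three drugs (to exercise the
#' coordination filtering rule) and same-name pairs (rule 1). The seed
#' fully determines the output.
#'
#' @param n number of sentences.
#' @param mixture named probabilities over
#'   `negative/advice/effect/mechanism/int`; must sum to 1.
#' @param distractor_rate probability a positive sentence also carries
#'   an unrelated third drug.
#' @param coordination_rate probability a negative sentence is a
#'   three-drug coordination run.
#' @param same_name_rate probability a negative sentence pairs a drug
#'   with a case-variant of itself.
#' @param vocab_size size of the drug-name pool.
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n = 200L,
                             mixture = c(negative = 0.5, advice = 0.125,
                                         effect = 0.125, mechanism = 0.125,
                                         int = 0.125),
                             distractor_rate = 0.2,
                             coordination_rate = 0.15,
                             same_name_rate = 0.05,
                             vocab_size = 60L, seed = 1L) {
  if (!setequal(names(mixture), SYN_CLASSES))
    stop("mixture must be named over: ", paste(SYN_CLASSES, collapse = ", "))
  mixture <- mixture[SYN_CLASSES]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stop("mixture must be non-negative and sum to 1")
  rates <- c(distractor_rate, coordination_rate, same_name_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if ((coordination_rate > 0 || same_name_rate > 0) &&
      mixture[["negative"]] == 0)
    stop("config error: coordination/same-name sentences are negative, ",
         "but the negative mixture weight is 0")
  if (coordination_rate + same_name_rate > 1)
    stop("coordination_rate + same_name_rate must not exceed 1")
  structure(list(n = as.integer(n), mixture = mixture,
                 distractor_rate = distractor_rate,
                 coordination_rate = coordination_rate,
                 same_name_rate = same_name_rate,
                 vocab_size = as.integer(vocab_size),
                 seed = as.integer(seed)),
            class = "generator_config")
}

drug_pool <- function(vocab_size) sprintf("DRUG%03d", seq_len(vocab_size))

# right-branching binary bracketing over a token vector
right_branch_tree <- function(tokens, label = "S") {
  if (length(tokens) == 1L) return(tokens)
  paste0("(", label, " ", tokens[1], " ",
         right_branch_tree(tokens[-1], "X"), ")")
}

#' Generate a synthetic corpus
#'
#' Each sentence is built from a class-specific template; its binary
#' parse tree is emitted directly from the derivation over the
#' preprocessed (anonymized) token sequence, guaranteeing leaf/token
#' alignment. Pairs are exhaustively annotated: the template pair
#' carries the class label, pairs involving distractor drugs are
#' negative.
#'
#' @param config a [generator_config].
#' @param xml_path optional path: write the corpus XML there.
#' @param trees_path optional path: write the bracketed trees there,
#'   one line per sentence, aligned with sentence order.
#' @return list with `records` (list of [ddi_sentence]), `trees`
#'   (character, one bracketed tree per sentence), `classes` (the
#'   template class per sentence) and `config`.
#' @export
generate_corpus <- function(config, xml_path = NULL, trees_path = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pool <- drug_pool(config$vocab_size)
  adverbs <- c("notably", "clinically", "importantly", "reportedly",
               "interestingly", "previously", "additionally", "overall")
  records <- vector("list", config$n)
  trees <- character(config$n)
  classes <- character(config$n)
  for (s in seq_len(config$n)) {
    cls <- sample(SYN_CLASSES, 1L, prob = config$mixture)
    kind <- "plain"
    if (cls == "negative") {
      r <- stats::runif(1)
      if (r < config$coordination_rate) kind <- "coordination"
      else if (r < config$coordination_rate + config$same_name_rate)
        kind <- "same_name"
    }
    if (kind == "coordination") {
      drugs <- sample(pool, 3L)
      toks <- c("@D1", ",", "@D2", ",", "and", "@D3", "were", "studied",
                "concomitantly", ".")
      pos_pair <- NULL
    } else if (kind == "same_name") {
      d <- sample(pool, 1L)
      drugs <- c(d, tolower(d))
      toks <- c("@D1", "and", "@D2", "were", "compared", ".")
      pos_pair <- NULL
    } else {
      tpl <- syn_templates[[cls]]
      toks <- tpl[[sample.int(length(tpl), 1L)]]
      n_drugs <- 2L
      distract <- cls != "negative" &&
        stats::runif(1) < config$distractor_rate
      if (distract) {
        toks <- c("unlike", "@D0", ",", toks)
        n_drugs <- 3L
      }
      if (stats::runif(1) < 0.3)
        toks <- c(sample(adverbs, 1L), ",", toks)
      drugs <- sample(pool, n_drugs)
      # slot order of appearance maps @D0 (distractor) first if present
      pos_pair <- if (cls == "negative") NULL else c("@D1", "@D2")
    }
    # substitute drug names into slots, in order of slot appearance
    slot_idx <- grep("^@D[0-9]$", toks)
    slots <- toks[slot_idx]
    toks[slot_idx] <- drugs[seq_along(slot_idx)]
    text <- paste(toks, collapse = " ")
    sid <- sprintf("syn.s%d", s - 1L)
    starts <- cumsum(c(0L, nchar(toks) + 1L))[seq_along(toks)]
    entities <- lapply(seq_along(slot_idx), function(k) {
      ti <- slot_idx[k]
      ddi_entity(id = sprintf("%s.e%d", sid, k - 1L),
                 text = toks[ti],
                 spans = cbind(starts[ti], starts[ti] + nchar(toks[ti])),
                 etype = "drug")
    })
    eids <- vapply(entities, `[[`, "", "id")
    pos_eids <- if (is.null(pos_pair)) character(0)
      else eids[match(pos_pair, slots)]
    pairs <- list()
    if (length(eids) >= 2L) {
      for (i in seq_len(length(eids) - 1L)) for (j in (i + 1L):length(eids)) {
        hit <- length(pos_eids) == 2L && all(c(eids[i], eids[j]) %in% pos_eids)
        pairs[[length(pairs) + 1L]] <-
          list(e1 = eids[i], e2 = eids[j], ddi = hit,
               type = if (hit) cls else NA_character_)
      }
    }
    records[[s]] <- ddi_sentence(sid, text, entities, pairs)
    # tree over preprocessed tokens: placeholders in first-start order
    ptoks <- toks
    ptoks[slot_idx] <- paste0("Ddrug", seq_along(slot_idx) - 1L)
    trees[s] <- right_branch_tree(mask_numbers(ptoks))
    classes[s] <- cls
  }
  if (!is.null(xml_path)) write_corpus_xml(records, xml_path)
  if (!is.null(trees_path)) writeLines(trees, trees_path)
  list(records = records, trees = trees, classes = classes,
       config = config)
}

#' Write sentence records as DDI-style XML
#'
#' Inverse of [read_ddi_xml] (offsets are converted back to the
#' 0-based end-inclusive dialect). Output is byte-deterministic.
#'
#' @param records list of [ddi_sentence].
#' @param path output path.
#' @param document_id id for the enclosing document element.
#' @return `path`, invisibly.
#' @export
write_corpus_xml <- function(records, path, document_id = "synthetic") {
  doc <- xml2::xml_new_root("document", id = document_id)
  for (rec in records) {
    sn <- xml2::xml_add_child(doc, "sentence", id = rec$id, text = rec$text)
    for (e in rec$entities) {
      off <- paste(sprintf("%d-%d", e$spans[, 1], e$spans[, 2] - 1L),
                   collapse = ";")
      xml2::xml_add_child(sn, "entity", id = e$id, charOffset = off,
                          type = e$etype, text = e$text)
    }
    for (k in seq_along(rec$pairs)) {
      p <- rec$pairs[[k]]
      attrs <- list(id = sprintf("%s.p%d", rec$id, k - 1L),
                    e1 = p$e1, e2 = p$e2,
                    ddi = if (isTRUE(p$ddi)) "true" else "false")
      if (isTRUE(p$ddi) && !is.na(p$type)) attrs$type <- p$type
      do.call(xml2::xml_add_child, c(list(sn, "pair"), attrs))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Generate a separable synthetic corpus
#'
#' Variant whose class-indicative trigger words are unique and
#' deterministic and whose sentences carry no distractors,
#' coordination runs or same-name pairs, so the detection label is a
#' linearly learnable function of the planted trigger tokens. Used by
#' the learnability tests.
#'
#' @param config a [generator_config]; its distractor, coordination
#'   and same-name rates are forced to 0.
#' @inheritParams generate_corpus
#' @return as [generate_corpus]; the trigger tokens are attached as
#'   attribute `"triggers"`.
#' @export
make_separable <- function(config, xml_path = NULL, trees_path = NULL) {
  config$distractor_rate <- 0
  config$coordination_rate <- 0
  config$same_name_rate <- 0
  out <- generate_corpus(config, xml_path = xml_path,
                         trees_path = trees_path)
  attr(out, "triggers") <- syn_triggers
  out
}

#' Training configuration for the separable synthetic corpus
#'
#' The published hyperparameters target corpus-scale training (batch
#' 100, learning rate 8e-4, 100 epochs); at toy scale (a few hundred
#' instances, 15 epochs) they leave too few optimizer steps. This
#' fixed configuration — hidden 32, batch 25, Adam learning rate
#' 0.005, keep probability 0.9, 15 epochs — is the package's stated
#' setting for learnability checks on [make_separable] corpora.
#'
#' @param seed training seed.
#' @param classes class labels (default detection).
#' @param epochs epochs (default 15).
#' @param hidden hidden size (default 32).
#' @return a [train_config].
#' @export
separable_train_config <- function(seed = 1L,
                                   classes = c("negative", "positive"),
                                   epochs = 15L, hidden = 32L) {
  train_config(classes = classes, hidden = hidden, batch_size = 25L,
               lr = 0.005, keep_p = 0.9, epochs = epochs, seed = seed)
}
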