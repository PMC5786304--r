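# One-stage / two-stage orchestration and micro-averaged F1 with
# filtered-positive (ledger) accounting.

DETECTION_CLASSES <- c("negative", "positive")
ONE_STAGE_CLASSES <- c("negative", "advice", "effect", "mechanism", "int")

#' Collapse typed labels to detection labels
#'
#' Any label other than `"negative"` maps to `"positive"`.
#'
#' @param labels character labels (5-class, 4-class or detection).
#' @return character vector of `"positive"` / `"negative"`.
#' @export
collapse_detection <- function(labels) {
  ifelse(labels == "negative", "negative", "positive")
}

#' One-stage classification
#'
#' A single five-class pass (`negative` + the four DDI types).
#'
#' @param model5 a `treelstm_model` trained on the five classes.
#' @param comps list of `compiled_tree`.
#' @return character vector of predicted labels.
#' @export
run_one_stage <- function(model5, comps) {
  if (model5$params$n_classes != 5L)
    stop("one-stage model must have 5 classes, has ",
         model5$params$n_classes)
  predict_treelstm(model5, comps)$labels
}

#' Two-stage classification
#'
#' The binary detector runs first; instances it predicts negative are
#' labeled `"negative"` and never reach the typer, so detection false
#' negatives surface as type-classification errors. Predicted
#' positives are re-scored by the four-class typer.
#'
#' @param detector a 2-class `treelstm_model`
#'   (classes `negative`/`positive`).
#' @param typer a 4-class `treelstm_model` (the DDI types), trained on
#'   gold positives.
#' @param comps list of `compiled_tree`.
#' @return character vector of predicted labels (`negative` or a type).
#' @export
run_two_stage <- function(detector, typer, comps) {
  if (detector$params$n_classes != 2L)
    stop("detector must have 2 classes")
  if (typer$params$n_classes != 4L)
    stop("typer must have 4 classes")
  det <- predict_treelstm(detector, comps)$labels
  out <- rep("negative", length(comps))
  pos <- which(det == "positive")
  if (length(pos))
    out[pos] <- predict_treelstm(typer, comps[pos])$labels
  out
}

#' Micro-averaged precision, recall and F1
#'
#' `P = sum(TP) / (sum(TP) + sum(FP))`,
#' `R = sum(TP) / (sum(TP) + sum(FN))` (ledger false negatives are
#' already folded into `fn`), `F = 2PR / (P + R)`; each `0/0` is 0 by
#' convention. Sums run over the scored (positive) classes only.
#'
#' @param counts data.frame with columns `tp`, `fp`, `fn` (one row per
#'   scored class).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
micro_f1 <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp); fn <- sum(counts$fn)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Evaluate predictions against gold labels
#'
#' Builds per-class TP/FP/FN counts over the scored positive classes
#' (the `negative` class is never scored) and adds one false negative
#' per ledger entry — a gold-positive test instance removed by
#' negative-instance filtering never gets predicted, but still counts
#' against recall.
#'
#' @param pred,gold character label vectors, aligned.
#' @param ledger list of filtered-out gold-positive [ddi_instance]s
#'   (e.g. `report$ledger` from [filter_negatives]), or a named integer
#'   vector of per-class extra false negatives.
#' @param classes scored classes (default: all gold/pred labels except
#'   `"negative"`).
#' @return list with `counts` (per-class data.frame incl. ledger FNs)
#'   and `micro` (from [micro_f1]).
#' @export
evaluate_predictions <- function(pred, gold, ledger = list(),
                                 classes = NULL) {
  if (length(pred) != length(gold))
    stop("prediction/gold length mismatch: ", length(pred), " vs ",
         length(gold))
  ledger_fn <- if (is.numeric(ledger)) {
    ledger
  } else {
    tab <- table(vapply(ledger, function(x)
      if (is.na(x$type)) "positive" else x$type, ""))
    stats::setNames(as.integer(tab), names(tab))
  }
  if (is.null(classes))
    classes <- setdiff(unique(c(gold, pred, names(ledger_fn))), "negative")
  counts <- data.frame(class = classes,
                       tp = 0L, fp = 0L, fn = 0L, ledger_fn = 0L,
                       stringsAsFactors = FALSE)
  for (k in seq_along(classes)) {
    cl <- classes[k]
    counts$tp[k] <- sum(pred == cl & gold == cl)
    counts$fp[k] <- sum(pred == cl & gold != cl)
    counts$fn[k] <- sum(pred != cl & gold == cl)
    if (cl %in% names(ledger_fn))
      counts$ledger_fn[k] <- ledger_fn[[cl]]
  }
  counts$fn <- counts$fn + counts$ledger_fn
  list(counts = counts, micro = micro_f1(counts))
}

#' Detection-level evaluation of (possibly typed) predictions
#'
#' Collapses typed labels to positive/negative and scores the single
#' positive class; ledger entries each add one detection false
#' negative.
#'
#' @inheritParams evaluate_predictions
#' @return as [evaluate_predictions].
#' @export
evaluate_detection <- function(pred, gold, ledger = list()) {
  lfn <- if (is.numeric(ledger)) sum(ledger) else length(ledger)
  evaluate_predictions(collapse_detection(pred), collapse_detection(gold),
                       ledger = c(positive = lfn), classes = "positive")
}
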