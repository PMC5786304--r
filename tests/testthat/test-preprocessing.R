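test_that("tokenizer splits punctuation, keeps numbers, records offsets", {
  expect_identical(as.character(ddi_tokenize("Ddrug0 and Ddrug1.")),
                   c("Ddrug0", "and", "Ddrug1", "."))
  toks <- ddi_tokenize(calcium_anonymized)
  expect_length(toks, 19L)
  expect_identical(as.character(tail(toks, 2)), c("Ddrug2", "."))
  expect_identical(ddi_tokenize(""), character(0))
  # numbers stay single tokens; offsets recover the original text
  toks <- ddi_tokenize("increased 2.5 fold (p<0.05).")
  expect_true("2.5" %in% toks)
  st <- attr(toks, "start"); en <- attr(toks, "end")
  for (k in seq_along(toks))
    expect_identical(substr("increased 2.5 fold (p<0.05).",
                            st[k] + 1, en[k]), as.character(toks[k]))
})

test_that("anonymize reproduces the calcium worked example exactly", {
  an <- anonymize(calcium_record())
  expect_identical(an$text, calcium_anonymized)
  # shared word "iron" appears nowhere in the output
  expect_false("iron" %in% an$tokens)
  expect_false("nonheme" %in% an$tokens)
  # placeholders indexed by order of first span start
  expect_identical(unname(an$placeholders),
                   c("Ddrug0", "Ddrug1", "Ddrug2"))
  expect_equal(unname(an$map), c(1L, 16L, 18L))
})

test_that("anonymize handles single entities and rejects overlapping anchors", {
  rec <- ddi_sentence("s1", "Give warfarin now .",
                      list(ddi_entity("s1.e0", "warfarin", cbind(5L, 13L))))
  an <- anonymize(rec)
  expect_identical(sum(an$tokens == "Ddrug0"), 1L)
  bad <- ddi_sentence("s2", "warfarin sodium here",
                      list(ddi_entity("s2.e0", "warfarin", cbind(0L, 8L)),
                           ddi_entity("s2.e1", "warfarin sodium",
                                      cbind(0L, 15L))))
  expect_error(anonymize(bad), "overlapping first spans")
  # non-drug entities are kept as text, not anonymized
  rec2 <- ddi_sentence("s3", "aspirin affects CYP3A4 .",
                       list(ddi_entity("s3.e0", "aspirin", cbind(0L, 7L)),
                            ddi_entity("s3.e1", "CYP3A4", cbind(16L, 22L),
                                       etype = "protein")))
  an2 <- anonymize(rec2)
  expect_true("CYP3A4" %in% an2$tokens)
  expect_length(an2$map, 1L)
})

test_that("mask_numbers masks whole-number tokens only, idempotently", {
  expect_identical(mask_numbers(c("increased", "2.5", "fold")),
                   c("increased", "#", "fold"))
  expect_identical(mask_numbers("CYP3A4"), "CYP3A4")
  expect_identical(mask_numbers("#"), "#")
  expect_identical(mask_numbers(c("-3", "+4,5", "12")), c("#", "#", "#"))
  expect_identical(mask_numbers(mask_numbers(c("7", "a1"))),
                   c("#", "a1"))
})

test_that("candidate generation covers annotated and unannotated pairs", {
  rec <- toy_record(drugs = c("ax", "bx", "cx"),
                    ddi = c(TRUE, FALSE, FALSE),
                    types = c("effect", NA, NA))
  insts <- generate_candidates(rec)
  expect_length(insts, 3L)
  expect_identical(vapply(insts, `[[`, "", "label"),
                   c("positive", "negative", "negative"))
  expect_identical(insts[[1]]$type, "effect")
  # targets point at the two placeholders
  for (x in insts)
    expect_true(all(grepl("^Ddrug[0-9]+$", x$tokens[x$targets])))
  # unannotated: all unordered pairs
  rec5 <- toy_record(drugs = paste0("d", 1:5))
  rec5$pairs <- list()
  expect_length(generate_candidates(rec5), 10L)
  rec1 <- toy_record(drugs = c("solo", "other"))
  rec1$entities <- rec1$entities[1]
  rec1$pairs <- list()
  expect_length(generate_candidates(rec1), 0L)
})

test_that("rule 1 removes same-surface pairs (case-insensitive)", {
  rec <- toy_record(drugs = c("aspirin", "Aspirin"))
  insts <- generate_candidates(rec)
  fl <- filter_negatives(insts, split = "train")
  expect_length(fl$kept, 0L)
  expect_equal(unname(fl$report$counts[["same_drug"]]), 1L)
  # synonym map extends rule 1
  rec2 <- toy_record(drugs = c("acetylsalicylic", "aspirin"))
  fl2 <- filter_negatives(generate_candidates(rec2), split = "train",
                          synonym_map = c(acetylsalicylic = "aspirin"))
  expect_length(fl2$kept, 0L)
})

test_that("rule 2 needs a run of three; two coordinated drugs survive", {
  # the worked example: "... of both Ddrug1 and Ddrug2 ." run length 2
  insts <- generate_candidates(calcium_record())
  fl <- filter_negatives(insts, split = "train")
  expect_length(fl$kept, 3L)
  expect_equal(sum(fl$report$counts), 0L)
  # three-drug comma/and run: all 3 pairs removed
  rec3 <- ddi_sentence(
    "run.s0", "aaa , bbb , and ccc were studied .",
    list(ddi_entity("run.s0.e0", "aaa", cbind(0L, 3L)),
         ddi_entity("run.s0.e1", "bbb", cbind(6L, 9L)),
         ddi_entity("run.s0.e2", "ccc", cbind(16L, 19L))))
  rec3$pairs <- list()
  cand <- generate_candidates(rec3)
  expect_length(cand, 3L)
  fl3 <- filter_negatives(cand, split = "train")
  expect_length(fl3$kept, 0L)
  expect_equal(unname(fl3$report$counts[["coordination"]]), 3L)
})

test_that("gold positives are ledgered on test, protected on train", {
  rec <- ddi_sentence(
    "led.s0", "ppp , qqq , and rrr interact .",
    list(ddi_entity("led.s0.e0", "ppp", cbind(0L, 3L)),
         ddi_entity("led.s0.e1", "qqq", cbind(6L, 9L)),
         ddi_entity("led.s0.e2", "rrr", cbind(16L, 19L))),
    list(list(e1 = "led.s0.e0", e2 = "led.s0.e1", ddi = TRUE, type = "int"),
         list(e1 = "led.s0.e0", e2 = "led.s0.e2", ddi = FALSE,
              type = NA_character_),
         list(e1 = "led.s0.e1", e2 = "led.s0.e2", ddi = FALSE,
              type = NA_character_)))
  cand <- generate_candidates(rec)
  # test split: positive removed and ledgered
  fl_test <- filter_negatives(cand, split = "test")
  expect_length(fl_test$kept, 0L)
  expect_length(fl_test$report$ledger, 1L)
  expect_identical(fl_test$report$ledger[[1]]$label, "positive")
  # train split: the gold positive is protected by default
  fl_train <- filter_negatives(cand, split = "train")
  expect_length(fl_train$kept, 1L)
  expect_identical(fl_train$kept[[1]]$label, "positive")
  expect_length(fl_train$report$ledger, 0L)
  # opt-in removal from train: not ledgered (ledger is test-only)
  fl_opt <- filter_negatives(cand, split = "train",
                             filter_train_positives = TRUE)
  expect_length(fl_opt$kept, 0L)
  expect_length(fl_opt$report$ledger, 0L)
})

test_that("filtering is deterministic and conserves counts", {
  cor <- generate_corpus(generator_config(n = 60, seed = 9,
                                          coordination_rate = 0.3,
                                          same_name_rate = 0.2))
  raw <- list()
  for (rec in cor$records) raw <- c(raw, generate_candidates(rec))
  a <- filter_negatives(raw, split = "test")
  b <- filter_negatives(raw, split = "test")
  expect_identical(a, b)
  expect_equal(length(a$kept) + length(a$report$removed), length(raw))
  expect_equal(sum(a$report$counts[c("same_drug", "coordination")]),
               length(a$report$removed))
  # no kept training instance has equal-surface targets
  tr <- filter_negatives(raw, split = "train")
  for (x in tr$kept)
    if (x$label == "negative")
      expect_false(tolower(trimws(x$e1_text)) ==
                   tolower(trimws(x$e2_text)))
})

test_that("deduplicate keys on tokens plus target indices", {
  rec <- toy_record(drugs = c("aa", "bb", "cc"))
  insts <- generate_candidates(rec)
  # same sentence, different target pairs: all kept
  dd <- deduplicate(insts)
  expect_length(dd$kept, 3L)
  # byte-identical duplicate: dropped, first kept
  dd2 <- deduplicate(c(insts, insts[1]))
  expect_length(dd2$kept, 3L)
  expect_equal(unname(dd2$report$counts[["duplicate"]]), 1L)
  expect_true(dd2$report$removed[[1]]$duplicate)
  expect_identical(deduplicate(list())$kept, list())
})
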