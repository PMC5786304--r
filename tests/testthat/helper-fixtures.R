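# Shared fixtures, built in code.

# The calcium / nonheme-iron worked example: three drug mentions, one
# discontinuous ("nonheme ... iron") sharing its trailing word with
# "heme iron".
calcium_record <- function() {
  text <- paste("Calcium is the only known component in the diet that",
                "may affect absorption of both nonheme and heme iron.")
  loc <- function(w) as.integer(regexpr(w, text, fixed = TRUE)) - 1L
  nh <- loc("nonheme"); hi <- loc("heme iron"); ir <- loc("iron.")
  ddi_sentence(
    "cal.s0", text,
    entities = list(
      ddi_entity("cal.s0.e0", "Calcium", cbind(0L, 7L), "drug"),
      ddi_entity("cal.s0.e1", "nonheme iron",
                 rbind(c(nh, nh + 7L), c(ir, ir + 4L)), "drug"),
      ddi_entity("cal.s0.e2", "heme iron", cbind(hi, hi + 9L), "drug")),
    pairs = list(
      list(e1 = "cal.s0.e0", e2 = "cal.s0.e1", ddi = TRUE,
           type = "mechanism"),
      list(e1 = "cal.s0.e0", e2 = "cal.s0.e2", ddi = TRUE,
           type = "mechanism"),
      list(e1 = "cal.s0.e1", e2 = "cal.s0.e2", ddi = FALSE,
           type = NA_character_)))
}

calcium_anonymized <- paste(
  "Ddrug0 is the only known component in the diet that may affect",
  "absorption of both Ddrug1 and Ddrug2.")

# Serialize the calcium record to an XML fixture file.
calcium_xml <- function(path = tempfile(fileext = ".xml")) {
  write_corpus_xml(list(calcium_record()), path, document_id = "cal")
  path
}

# A tiny sentence record with exhaustively annotated pairs.
toy_record <- function(drugs = c("alpha", "beta", "gamma"),
                       id = "toy.s0", ddi = logical(choose(length(drugs), 2)),
                       types = NULL) {
  text <- paste(paste(drugs, collapse = " and "), "were given .")
  ents <- list()
  pos <- 0L
  for (k in seq_along(drugs)) {
    st <- as.integer(regexpr(drugs[k], text, fixed = TRUE)) - 1L
    ents[[k]] <- ddi_entity(sprintf("%s.e%d", id, k - 1L), drugs[k],
                            cbind(st, st + nchar(drugs[k])), "drug")
  }
  pairs <- list()
  m <- 0L
  for (i in seq_len(length(drugs) - 1L)) for (j in (i + 1L):length(drugs)) {
    m <- m + 1L
    pairs[[m]] <- list(e1 = ents[[i]]$id, e2 = ents[[j]]$id,
                       ddi = ddi[m],
                       type = if (!is.null(types)) types[m]
                              else NA_character_)
  }
  ddi_sentence(id, text, ents, pairs)
}

# Shared small embedding table (dim 10 keeps model tests fast).
small_table <- function(dim = 10L, seed = 42L) embedding_table(dim, seed)

# Compile a bracketed tree string for an instance-like input.
compile_from_string <- function(sexpr, tokens, t1, t2, table = small_table(),
                                codec = encode_distance) {
  tr <- annotate_tree(binarize(read_bracketed(sexpr)), tokens, t1, t2)
  compile_tree(tr, table, codec)
}
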