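DRUG_LIKE_TYPES <- c("drug", "brand", "group", "drug_n")
DDI_TYPES <- c("advice", "effect", "mechanism", "int")

#' Create an entity mention
#'
#' An entity mention is one annotated span (or several, for discontinuous
#' mentions such as "nonheme ... iron") of a named substance in a sentence.
#' Offsets follow the DDI-challenge dialect: 0-based, end-inclusive in the
#' XML; internally they are stored half-open (`[start, end)`).
#'
#' @param id entity identifier, unique within the sentence.
#' @param text surface form as annotated.
#' @param spans integer matrix with columns `start`, `end` (0-based,
#'   half-open), one row per contiguous span; rows sorted by start.
#' @param etype entity class label (`drug`, `brand`, `group`, `drug_n`
#'   form candidate pairs; anything else is carried but never paired).
#' @return an object of class `ddi_entity`.
#' @export
ddi_entity <- function(id, text, spans, etype = "drug") {
  spans <- matrix(as.integer(spans), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(spans) == 0L) stop("entity '", id, "': spans must be non-empty")
  if (any(spans[, 2] <= spans[, 1]))
    stop("entity '", id, "': empty or inverted span")
  if (is.unsorted(spans[, 1], strictly = TRUE) && nrow(spans) > 1L)
    stop("entity '", id, "': spans must be sorted by start")
  if (nrow(spans) > 1L && any(spans[-nrow(spans), 2] > spans[-1L, 1]))
    stop("entity '", id, "': spans overlap each other")
  structure(list(id = id, text = text, spans = spans, etype = etype),
            class = "ddi_entity")
}

#' Create a sentence record
#'
#' @param id sentence identifier.
#' @param text raw sentence text.
#' @param entities list of [ddi_entity] objects.
#' @param pairs list of pair annotations, each a list with elements
#'   `e1`, `e2` (entity ids), `ddi` (logical) and `type` (one of
#'   advice/effect/mechanism/int, or `NA` when `ddi` is false).
#' @return an object of class `ddi_sentence`.
#' @export
ddi_sentence <- function(id, text, entities = list(), pairs = list()) {
  ids <- vapply(entities, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("sentence '", id, "': duplicate entity ids")
  for (ent in entities) {
    if (any(ent$spans[, 2] > nchar(text)))
      stop("sentence '", id, "': entity '", ent$id,
           "' span exceeds sentence text")
  }
  for (p in pairs) {
    missing <- setdiff(c(p$e1, p$e2), ids)
    if (length(missing))
      stop("sentence '", id, "': pair references missing entity id(s) ",
           paste(missing, collapse = ", "))
    ty <- p$type
    if (!is.null(ty) && !is.na(ty)) {
      if (!isTRUE(p$ddi))
        stop("sentence '", id, "': type given on a non-DDI pair")
      if (!ty %in% DDI_TYPES)
        stop("sentence '", id, "': unknown DDI type '", ty, "'")
    }
  }
  structure(list(id = id, text = text, entities = entities, pairs = pairs),
            class = "ddi_sentence")
}

parse_char_offset <- function(offset, id) {
  parts <- strsplit(offset, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad) || length(parts) == 0L)
    stop("entity '", id, "': malformed charOffset '", offset, "'")
  a <- vapply(m, function(x) as.integer(x[2]), 0L)
  b <- vapply(m, function(x) as.integer(x[3]), 0L)
  # XML dialect is 0-based end-inclusive; store half-open
  cbind(start = a, end = b + 1L)
}

#' Read a DDI-challenge style XML corpus
#'
#' Parses `document > sentence > entity/pair` elements into a list of
#' [ddi_sentence] records. Discontinuous entity offsets
#' (`"12-18;25-29"`) become multi-span mentions. Unknown attributes are
#' ignored; a pair referencing an undeclared entity id, or an unknown
#' `type` string, is a validation error naming the sentence.
#'
#' @param path path to an XML file.
#' @return list of `ddi_sentence` objects.
#' @export
read_ddi_xml <- function(path) {
  doc <- xml2::read_xml(path)
  sents <- xml2::xml_find_all(doc, ".//sentence")
  lapply(sents, function(s) {
    sid <- xml2::xml_attr(s, "id")
    text <- xml2::xml_attr(s, "text")
    ents <- lapply(xml2::xml_find_all(s, "./entity"), function(e) {
      eid <- xml2::xml_attr(e, "id")
      ddi_entity(id = eid,
                 text = xml2::xml_attr(e, "text"),
                 spans = parse_char_offset(xml2::xml_attr(e, "charOffset"), eid),
                 etype = xml2::xml_attr(e, "type"))
    })
    pairs <- lapply(xml2::xml_find_all(s, "./pair"), function(p) {
      ty <- xml2::xml_attr(p, "type")
      list(e1 = xml2::xml_attr(p, "e1"),
           e2 = xml2::xml_attr(p, "e2"),
           ddi = identical(tolower(xml2::xml_attr(p, "ddi")), "true"),
           type = if (is.na(ty)) NA_character_ else ty)
    })
    ddi_sentence(sid, text, ents, pairs)
  })
}

#' Create a candidate instance
#'
#' One (sentence, drug pair) classification unit after preprocessing.
#'
#' @param sentence_id id of the originating sentence.
#' @param e1,e2 entity ids of the two target drugs.
#' @param e1_text,e2_text original surface forms (needed by the
#'   same-drug filtering rule).
#' @param tokens preprocessed token sequence (anonymized, numbers masked).
#' @param targets length-2 integer: 1-based token positions of the two
#'   `Ddrug` placeholders.
#' @param label `"positive"` or `"negative"` detection label.
#' @param type DDI type for positives (`NA` otherwise).
#' @param filtered,duplicate provenance flags.
#' @return object of class `ddi_instance`.
#' @export
ddi_instance <- function(sentence_id, e1, e2, e1_text, e2_text, tokens,
                         targets, label, type = NA_character_,
                         filtered = FALSE, duplicate = FALSE) {
  targets <- as.integer(targets)
  stopifnot(length(targets) == 2L)
  if (any(targets < 1L) || any(targets > length(tokens)))
    stop("instance ", sentence_id, " (", e1, ",", e2,
         "): target indices out of token range")
  if (!label %in% c("positive", "negative"))
    stop("detection label must be 'positive' or 'negative'")
  if (!is.na(type) && !type %in% DDI_TYPES)
    stop("unknown DDI type '", type, "'")
  structure(list(sentence_id = sentence_id, e1 = e1, e2 = e2,
                 e1_text = e1_text, e2_text = e2_text, tokens = tokens,
                 targets = targets, label = label, type = type,
                 filtered = filtered, duplicate = duplicate),
            class = "ddi_instance")
}

#' Write candidate instances to a TSV file
#'
#' One instance per row; tokens are space-joined (tokens never contain
#' whitespace, so [read_instances] round-trips losslessly).
#'
#' @param instances list of [ddi_instance].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_instances <- function(instances, path) {
  header <- paste(c("sentence_id", "e1", "e2", "e1_text", "e2_text",
                    "label", "type", "target1", "target2", "tokens"),
                  collapse = "\t")
  rows <- vapply(instances, function(x) {
    paste(c(x$sentence_id, x$e1, x$e2, x$e1_text, x$e2_text, x$label,
            ifelse(is.na(x$type), "", x$type), x$targets[1], x$targets[2],
            paste(x$tokens, collapse = " ")), collapse = "\t")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read candidate instances from a TSV file written by [write_instances]
#'
#' @param path input path.
#' @return list of [ddi_instance].
#' @export
read_instances <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty instance file: ", path)
  lapply(lines[-1L], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    ddi_instance(sentence_id = f[1], e1 = f[2], e2 = f[3],
                 e1_text = f[4], e2_text = f[5], label = f[6],
                 type = if (identical(f[7], "")) NA_character_ else f[7],
                 targets = c(as.integer(f[8]), as.integer(f[9])),
                 tokens = strsplit(f[10], " ", fixed = TRUE)[[1]])
  })
}
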