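# Input features: signed relative-distance thermometer code, subtree
# containment block, and the static word-embedding table.

#' Relative distance from a word to a target drug
#'
#' `relative_distance(current, target)` is `target - current`: a word
#' located two tokens after the first target has `d1 = -2`, a word two
#' tokens before the second target has `d2 = +2`.
#'
#' @param current,target token indices (same base).
#' @return integer distance (vectorized).
#' @export
relative_distance <- function(current, target) {
  as.integer(target) - as.integer(current)
}

#' Encode a relative distance as a 10-component binary vector
#'
#' Thermometer-style code: distances with absolute value up to 5 each
#' get their own vector; beyond 5 distances share a vector in buckets
#' of 5 (6-10, 11-15, 16-20, 21+). Component 1 flags a strictly
#' positive distance; components 2-10 are absolute-value thresholds
#' (21, 16, 11, 6, 5, 4, 3, 2, 1). `encode_distance(0)` is all-zero.
#' Negative long-range distances mirror the positive buckets.
#'
#' @param d an integer distance (scalar).
#' @return integer vector of length 10 with values in `{0, 1}`.
#' @export
encode_distance <- function(d) {
  stopifnot(length(d) == 1L, is.finite(d))
  a <- abs(d)
  as.integer(c(d >= 1, a >= 21, a >= 16, a >= 11, a >= 6,
               a >= 5, a >= 4, a >= 3, a >= 2, a >= 1))
}

#' Subtree-containment block
#'
#' All-ones when a target drug occurs among the node's leaves, all
#' zeros otherwise.
#'
#' @param flag logical containment flag.
#' @param size block length (default 10).
#' @return integer vector of `size` zeros or ones.
#' @export
containment_vector <- function(flag, size = 10L) {
  stopifnot(is.logical(flag), length(flag) == 1L, !is.na(flag))
  rep(as.integer(flag), size)
}

# Deterministic per-key RNG: a small string hash folded with the table
# seed, so lookups are order-independent and reproducible.
key_seed <- function(key, seed) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483563
  as.integer((h + seed * 7919) %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Create a static word-embedding table
#'
#' Known words map to their pre-trained vectors; out-of-vocabulary
#' words and internal (constituent-label) nodes get a random vector
#' drawn once per key from a seeded generator and cached, so repeated
#' lookups are identical and independent of lookup order. Embeddings
#' are static: the model never updates them.
#'
#' @param dim embedding dimension (default 200).
#' @param seed seed controlling all random vectors.
#' @param vectors optional named list/environment of pre-trained
#'   vectors (each of length `dim`), e.g. from [read_embeddings].
#' @param internal_policy share internal-node vectors per constituent
#'   `"label"` (default) or draw one per `"node"` instance.
#' @return an object of class `embedding_table`.
#' @export
embedding_table <- function(dim = 200L, seed = 1L, vectors = NULL,
                            internal_policy = c("label", "node")) {
  internal_policy <- match.arg(internal_policy)
  pre <- new.env(parent = emptyenv())
  if (!is.null(vectors)) {
    nm <- if (is.environment(vectors)) ls(vectors) else names(vectors)
    for (w in nm) {
      v <- if (is.environment(vectors)) vectors[[w]] else vectors[[w]]
      if (length(v) != dim)
        stop("embedding for '", w, "' has length ", length(v),
             ", expected ", dim)
      assign(w, as.numeric(v), envir = pre)
    }
  }
  structure(list(dim = as.integer(dim), seed = as.integer(seed),
                 pre = pre, cache = new.env(parent = emptyenv()),
                 internal_policy = internal_policy),
            class = "embedding_table")
}

#' Look up a word (or internal-node label) vector
#'
#' @param table an [embedding_table].
#' @param key the word or constituent label.
#' @param kind `"word"` for leaves, `"label"` for internal nodes.
#' @return numeric vector of length `table$dim`.
#' @export
lookup_embedding <- function(table, key, kind = c("word", "label")) {
  kind <- match.arg(kind)
  if (kind == "word" && exists(key, envir = table$pre, inherits = FALSE))
    return(get(key, envir = table$pre))
  ck <- paste0(kind, "\x01", key)
  if (!exists(ck, envir = table$cache, inherits = FALSE)) {
    v <- with_seed(key_seed(ck, table$seed),
                   stats::runif(table$dim, -0.05, 0.05))
    assign(ck, v, envir = table$cache)
  }
  get(ck, envir = table$cache)
}

#' Read a word-embedding text file
#'
#' Whitespace-separated text, one word per line followed by its vector
#' components; the dimension of every row must equal `dim`.
#'
#' @param path path to the text file.
#' @param dim expected dimension (default 200).
#' @return named list of numeric vectors.
#' @export
read_embeddings <- function(path, dim = 200L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  words <- character(length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(trimws(lines[k]), "[[:space:]]+")[[1]]
    if (length(f) != dim + 1L)
      stop("line ", k, ": expected ", dim, " components, found ",
           length(f) - 1L)
    words[k] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) stop("line ", k, ": non-numeric embedding component")
    out[[k]] <- v
  }
  names(out) <- words
  out
}

#' Write a word-embedding text file
#' @param vectors named list of numeric vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(vectors, path) {
  lines <- vapply(names(vectors), function(w)
    paste(c(w, format(vectors[[w]], digits = 8, trim = TRUE,
                      scientific = FALSE)), collapse = " "), "")
  writeLines(lines, path)
  invisible(path)
}

#' Assemble the model input vector for an annotated tree node
#'
#' Concatenates the containment block (10), the position codes of the
#' two relative distances (10 + 10) and the word vector (`table$dim`,
#' default 200), for a total default length of 230. Leaves use the
#' token's embedding; internal nodes use a cached random vector keyed
#' by constituent label (or node uid under the `"node"` policy).
#'
#' @param node an annotated `parse_node` (see [annotate_tree]).
#' @param table an [embedding_table].
#' @param codec distance encoder (default [encode_distance]).
#' @return numeric vector of length `table$dim + 30`.
#' @export
assemble_input <- function(node, table, codec = encode_distance) {
  if (is.na(node$containment) || is.na(node$d1) || is.na(node$d2))
    stop("node is not annotated; run annotate_tree first")
  word <- if (is_leaf(node)) {
    lookup_embedding(table, node$label, "word")
  } else if (table$internal_policy == "label") {
    lookup_embedding(table, node$label, "label")
  } else {
    lookup_embedding(table, paste0("uid", node$uid), "label")
  }
  c(containment_vector(node$containment), codec(node$d1), codec(node$d2),
    word)
}
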