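# Bracketed constituency trees: reading, binarization, feature annotation.

new_parse_node <- function(label, children = list()) {
  structure(list(label = label, children = children,
                 leaf_index = NA_integer_, containment = NA,
                 d1 = NA_integer_, d2 = NA_integer_),
            class = "parse_node")
}

#' Is this node a leaf?
#' @param node a `parse_node`.
#' @return logical.
#' @export
is_leaf <- function(node) length(node$children) == 0L

#' Read a bracketed (Penn-Treebank style) parse tree
#'
#' Parses one S-expression of the form `(LABEL child ...)` where each
#' child is either another parenthesized node or a bare token (a leaf).
#' Unary chains are preserved as read; use [binarize] to normalize.
#'
#' @param sexpr a single string.
#' @return the root `parse_node`.
#' @export
read_bracketed <- function(sexpr) {
  stopifnot(length(sexpr) == 1L)
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, sexpr, perl = TRUE)[[1]]
  if (m[1] == -1L) stop("empty parse tree input")
  toks <- regmatches(sexpr, list(m))[[1]]
  pos <- as.integer(m)
  i <- 0L
  nxt <- function() {
    i <<- i + 1L
    if (i > length(toks))
      stop("unbalanced parse tree: unexpected end of input at position ",
           nchar(sexpr) + 1L)
    toks[i]
  }
  parse_node_at <- function() {
    t <- nxt()
    if (identical(t, ")"))
      stop("parse error at position ", pos[i], ": unexpected ')'")
    if (!identical(t, "(")) return(new_parse_node(t))  # leaf token
    label <- nxt()
    if (label %in% c("(", ")"))
      stop("parse error at position ", pos[i], ": expected node label")
    kids <- list()
    repeat {
      if (i + 1L > length(toks))
        stop("unbalanced parse tree: missing ')' at end of input")
      if (identical(toks[i + 1L], ")")) { i <<- i + 1L; break }
      kids[[length(kids) + 1L]] <- parse_node_at()
    }
    if (length(kids) == 0L)
      stop("parse error at position ", pos[i], ": node '", label,
           "' has no children")
    new_parse_node(label, kids)
  }
  root <- parse_node_at()
  if (i < length(toks))
    stop("parse error at position ", pos[i + 1L], ": trailing input")
  root
}

#' Binarize a constituency tree
#'
#' Produces a strictly binary tree: n-ary nodes are right-branch
#' collapsed into intermediate nodes labeled `parent|merge`, and unary
#' internal chains are collapsed into their child. Leaf order is
#' preserved. Idempotent on already-binary trees. Internal-node labels
#' never affect model features; only the structure does.
#'
#' @param tree a `parse_node`.
#' @return a strictly binary `parse_node` (or a single leaf).
#' @export
binarize <- function(tree) {
  if (is_leaf(tree)) return(tree)
  kids <- lapply(tree$children, binarize)
  if (length(kids) == 1L) return(kids[[1]])
  merge_label <- paste0(tree$label, "|merge")
  while (length(kids) > 2L) {
    k <- length(kids)
    kids <- c(kids[seq_len(k - 2L)],
              list(new_parse_node(merge_label, kids[(k - 1L):k])))
  }
  new_parse_node(tree$label, kids)
}

#' Leaf labels of a tree, in order
#' @param tree a `parse_node`.
#' @return character vector of leaf labels.
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Annotate a binary tree with containment and position information
#'
#' Leaves receive their 1-based index, relative distances to the two
#' targets (`d_i = target_i - index`, see [relative_distance]) and a
#' containment flag (`TRUE` iff the leaf is a target). Internal nodes
#' take, for each distance component, the child value with the smaller
#' absolute value (tie: the left child's value), and the OR of their
#' children's containment flags.
#'
#' @param tree a strictly binary `parse_node` (see [binarize]).
#' @param tokens token vector the leaves must align with.
#' @param target1,target2 1-based token indices of the two target drugs.
#' @param sentence_id optional id used in error messages.
#' @return the annotated `parse_node`.
#' @export
annotate_tree <- function(tree, tokens, target1, target2,
                          sentence_id = NULL) {
  where <- if (is.null(sentence_id)) "" else paste0(" (sentence ",
                                                    sentence_id, ")")
  leaves <- tree_leaves(tree)
  if (length(leaves) != length(tokens))
    stop("tree/token alignment error", where, ": ", length(leaves),
         " leaves vs ", length(tokens), " tokens")
  if (!all(leaves == tokens))
    stop("tree/token alignment error", where,
         ": leaf labels differ from tokens")
  if (target1 < 1L || target1 > length(tokens) ||
      target2 < 1L || target2 > length(tokens))
    stop("target indices out of range", where)
  counter <- new.env(parent = emptyenv())
  counter$leaf <- 0L
  counter$uid <- 0L
  rec <- function(node) {
    counter$uid <- counter$uid + 1L
    node$uid <- counter$uid
    if (is_leaf(node)) {
      counter$leaf <- counter$leaf + 1L
      idx <- counter$leaf
      node$leaf_index <- idx
      node$d1 <- relative_distance(idx, target1)
      node$d2 <- relative_distance(idx, target2)
      node$containment <- idx == target1 || idx == target2
      return(node)
    }
    if (length(node$children) != 2L)
      stop("annotate_tree requires a strictly binary tree", where,
           "; node '", node$label, "' has ", length(node$children),
           " children (run binarize first)")
    node$children <- lapply(node$children, rec)
    l <- node$children[[1]]; r <- node$children[[2]]
    # smaller absolute value wins; tie goes to the left child
    node$d1 <- if (abs(r$d1) < abs(l$d1)) r$d1 else l$d1
    node$d2 <- if (abs(r$d2) < abs(l$d2)) r$d2 else l$d2
    node$containment <- l$containment || r$containment
    node
  }
  rec(tree)
}

#' Deparse a tree back to a bracketed string
#' @param tree a `parse_node`.
#' @return a single string.
#' @export
write_bracketed <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, write_bracketed, ""), collapse = " "),
         ")")
}

#' @export
print.parse_node <- function(x, ...) {
  cat(write_bracketed(x), "\n")
  invisible(x)
}
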