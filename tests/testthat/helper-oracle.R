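# Independent reference implementations used as oracles. These stay
# scalar/loop-based on purpose: they share no code path with the
# vectorized package implementation.

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# Scalar-loop tree-LSTM node: gates computed element by element.
oracle_node <- function(p, x, children = list()) {
  H <- p$hidden
  ht <- numeric(H)
  for (s in children) ht <- ht + s$h
  i <- o <- u <- numeric(H)
  for (r in seq_len(H)) {
    i[r] <- oracle_sigmoid(sum(p$Wx_iou[r, ] * x) +
                           sum(p$Wh_iou[r, ] * ht) + p$b_iou[r])
    o[r] <- oracle_sigmoid(sum(p$Wx_iou[H + r, ] * x) +
                           sum(p$Wh_iou[H + r, ] * ht) + p$b_iou[H + r])
    u[r] <- tanh(sum(p$Wx_iou[2 * H + r, ] * x) +
                 sum(p$Wh_iou[2 * H + r, ] * ht) + p$b_iou[2 * H + r])
  }
  cc <- i * u
  for (s in children) {
    f <- numeric(H)
    for (r in seq_len(H))
      f[r] <- oracle_sigmoid(sum(p$Wx_f[r, ] * x) +
                             sum(p$Wh_f[r, ] * s$h) + p$b_f[r])
    cc <- cc + f * s$c
  }
  list(h = o * tanh(cc), c = cc)
}

# Random binary tree in compiled-array form plus a nested mirror for
# the oracle recursion.
random_compiled_tree <- function(H, D, max_depth = 6) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  build <- function(depth) {
    if (depth >= max_depth || stats::runif(1) < 0.4) {
      env$n <- env$n + 1L
      return(list(l = NULL, r = NULL, j = env$n))
    }
    l <- build(depth + 1L); r <- build(depth + 1L)
    env$n <- env$n + 1L
    list(l = l, r = r, j = env$n)
  }
  root <- build(0L)
  if (is.null(root$l)) {  # force at least one internal node
    l <- root
    r <- build(max_depth - 1L)
    env$n <- env$n + 1L
    root <- list(l = l, r = r, j = env$n)
  }
  n <- env$n
  kids <- matrix(0L, 2L, n)
  fill <- function(node) {
    if (!is.null(node$l)) {
      kids[1, node$j] <<- node$l$j
      kids[2, node$j] <<- node$r$j
      fill(node$l); fill(node$r)
    }
  }
  fill(root)
  X <- matrix(stats::runif(D * n, -1, 1), D, n)
  list(comp = structure(list(X = X, kids = kids, n = n),
                        class = "compiled_tree"),
       root = root)
}

oracle_forward <- function(p, tree, X) {
  rec <- function(node) {
    ch <- if (is.null(node$l)) list()
      else list(rec(node$l), rec(node$r))
    oracle_node(p, X[, node$j], ch)
  }
  rec(tree)
}

# Finite-difference gradient of the batch loss wrt one parameter entry.
fd_gradient <- function(params, comps, gold, weights, nm, ii, eps = 1e-5) {
  p2 <- params
  p2[[nm]][ii] <- p2[[nm]][ii] + eps
  lp <- treelstm_gradients(p2, comps, gold, weights)$loss
  p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
  lm <- treelstm_gradients(p2, comps, gold, weights)$loss
  (lp - lm) / (2 * eps)
}

# Relative agreement between the analytic gradient entry and central
# differences. Evaluated at two step sizes and the better taken: a
# genuine backprop defect disagrees by O(1) at every step size, while
# pure difference-quotient roundoff shrinks at the better-conditioned
# step.
fd_relative_error <- function(params, comps, gold, weights, nm, ii, g) {
  rel <- vapply(c(1e-5, 1e-4), function(eps) {
    fd <- fd_gradient(params, comps, gold, weights, nm, ii, eps)
    abs(fd - g) / max(1e-8, abs(fd) + abs(g))
  }, 0)
  min(rel)
}

# The printed distance-encoding table, frozen: rows are the 10 vector
# components, columns the 15 printed distance buckets.
printed_distance_table <- function() {
  cols <- c("-5", "-4", "-3", "-2", "-1", "0", "1", "2", "3", "4", "5",
            "6-10", "11-15", "16-20", "21-Inf")
  m <- rbind(
    c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
    c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
    c(1, 1, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1),
    c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  storage.mode(m) <- "integer"
  colnames(m) <- cols
  m
}

# representative distances per printed column
printed_column_distances <- function() {
  list("-5" = -5L, "-4" = -4L, "-3" = -3L, "-2" = -2L, "-1" = -1L,
       "0" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "5" = 5L,
       "6-10" = 6:10, "11-15" = 11:15, "16-20" = 16:20,
       "21-Inf" = c(21L, 22L, 30L, 100L, 5000L))
}
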