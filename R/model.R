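# Binary child-pair tree-LSTM with analytic backpropagation, weighted
# softmax cross-entropy, Adam, recurrent dropout, and a logit-sum
# ensemble. Parameters are stored with the three gates i/o/u stacked
# row-wise (W_iou = rbind(W_i, W_o, W_u)) and split by input block
# (Wx_* acts on the node input x, Wh_* on the child hidden state), so
# a whole tree's input projections reduce to one matrix product.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Dropout specification for the recurrent (memory-update) dropout
#'
#' In training mode the candidate memory update `u` is multiplied by a
#' Bernoulli(keep_p) mask; evaluation mode is the identity. The
#' `"inverted"` variant rescales the mask by `1/keep_p` during training
#' so that expected activations match evaluation; `"paper"` applies the
#' raw mask (the literal published rule, which leaves a train/test
#' scale mismatch).
#'
#' @param keep_p keep probability in (0, 1].
#' @param mode `"train"` or `"eval"`.
#' @param mask optional precomputed 0/1 mask vector (length = hidden
#'   size); drawn by the caller so one mask can be shared per tree.
#' @param variant `"inverted"` (default) or `"paper"`.
#' @return object of class `dropout_spec`.
#' @export
dropout_spec <- function(keep_p = 1, mode = c("eval", "train"),
                         mask = NULL, variant = c("inverted", "paper")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  stopifnot(keep_p > 0, keep_p <= 1)
  structure(list(keep_p = keep_p, mode = mode, mask = mask,
                 variant = variant), class = "dropout_spec")
}

# effective multiplicative factor applied to u
dropout_factor <- function(spec, hidden) {
  if (spec$mode != "train" || spec$keep_p >= 1) return(rep(1, hidden))
  mask <- spec$mask
  if (is.null(mask)) mask <- as.numeric(stats::runif(hidden) < spec$keep_p)
  if (spec$variant == "inverted") mask / spec$keep_p else mask
}

#' Initialize tree-LSTM parameters
#'
#' Weights are drawn uniform(-0.05, 0.05), biases start at zero. The
#' forget-gate weights are shared across both children (child-sum
#' formulation); `W_iou` stacks the input, output and update gates.
#'
#' @param hidden hidden size H.
#' @param n_classes output classes (2 detection / 4 type / 5 one-stage).
#' @param input_dim node input length (default 230 = 10 + 20 + 200).
#' @param seed RNG seed for the initialization.
#' @return list of parameter matrices, class `treelstm_params`.
#' @export
init_treelstm_params <- function(hidden, n_classes, input_dim = 230L,
                                 seed = 1L) {
  set.seed(seed)
  H <- as.integer(hidden); D <- as.integer(input_dim)
  C <- as.integer(n_classes)
  rnd <- function(r, c) matrix(stats::runif(r * c, -0.05, 0.05), r, c)
  structure(list(
    Wx_iou = rnd(3L * H, D), Wh_iou = rnd(3L * H, H),
    b_iou = numeric(3L * H),
    Wx_f = rnd(H, D), Wh_f = rnd(H, H), b_f = numeric(H),
    W_fc = rnd(C, H), b_fc = numeric(C),
    hidden = H, input_dim = D, n_classes = C), class = "treelstm_params")
}

param_names <- c("Wx_iou", "Wh_iou", "b_iou", "Wx_f", "Wh_f", "b_f",
                 "W_fc", "b_fc")

zero_like <- function(params) {
  g <- lapply(params[param_names], function(p) p * 0)
  g
}

#' Single tree-LSTM node forward step
#'
#' Computes one node state from the node input and the states of its
#' zero (leaf) or two (internal) children: the child hidden states are
#' summed for the input/output/update gates, while each child gets its
#' own forget gate computed from that child's hidden state with shared
#' weights. Recurrent dropout applies to the candidate update `u` only,
#' and only in training mode.
#'
#' @param params a `treelstm_params`.
#' @param x node input vector (length `params$input_dim`).
#' @param children list of 0 or 2 node states, each `list(h, c)`.
#' @param dropout a [dropout_spec].
#' @return node state `list(h, c)`.
#' @export
node_forward <- function(params, x, children = list(),
                         dropout = dropout_spec()) {
  if (!length(children) %in% c(0L, 2L))
    stop("structural error: a node has 0 or 2 children, got ",
         length(children))
  if (length(x) != params$input_dim)
    stop("input length ", length(x), " != input_dim ", params$input_dim)
  if (any(!is.finite(x)) ||
      any(vapply(children, function(s) any(!is.finite(c(s$h, s$c))), TRUE)))
    stop("numeric error: non-finite values in node inputs")
  H <- params$hidden
  htilde <- numeric(H)
  for (s in children) htilde <- htilde + s$h
  a <- params$Wx_iou %*% x + params$Wh_iou %*% htilde + params$b_iou
  i <- sigmoid(a[1:H]); o <- sigmoid(a[(H + 1):(2 * H)])
  u <- tanh(a[(2 * H + 1):(3 * H)])
  cc <- i * (dropout_factor(dropout, H) * u)
  fx <- params$Wx_f %*% x + params$b_f
  for (s in children) {
    f <- sigmoid(fx + params$Wh_f %*% s$h)
    cc <- cc + f * s$c
  }
  cc <- as.numeric(cc)
  list(h = o * tanh(cc), c = cc)
}

#' Root classification head
#'
#' Affine map of the root hidden state only; internal-node outputs are
#' never used for scoring.
#'
#' @param params a `treelstm_params`.
#' @param state root node state from [node_forward] / [tl_forward].
#' @return numeric logits vector of length `params$n_classes`.
#' @export
classify_root <- function(params, state) {
  as.numeric(params$W_fc %*% state$h + params$b_fc)
}

#' Argmax class prediction
#'
#' Ties break toward the lower class index (`which.max` convention).
#'
#' @param logits numeric vector of finite logits.
#' @return 1-based class index.
#' @export
predict_class <- function(logits) {
  if (any(!is.finite(logits))) stop("non-finite logits")
  which.max(logits)
}

log_softmax <- function(l) {
  m <- max(l)
  l - m - log(sum(exp(l - m)))
}

#' Weighted softmax cross-entropy loss
#'
#' Mean over the batch of `w_k * (-log softmax(logits_k)[gold_k])`.
#' For the detection classifier positive instances carry weight 3 (the
#' class-imbalance correction); type classifiers use uniform weights.
#'
#' @param logits matrix (n_classes x batch) or vector for a batch of 1.
#' @param gold integer vector of 1-based gold class indices.
#' @param weights per-instance weights (default all 1).
#' @return scalar loss.
#' @export
ddi_loss <- function(logits, gold, weights = rep(1, length(gold))) {
  if (is.null(dim(logits))) logits <- matrix(logits, ncol = 1L)
  m <- ncol(logits)
  stopifnot(m >= 1L, length(gold) == m, length(weights) == m)
  if (any(gold < 1L | gold > nrow(logits)))
    stop("gold label outside class range")
  ll <- vapply(seq_len(m),
               function(k) log_softmax(logits[, k])[gold[k]], 0)
  mean(-weights * ll)
}

#' Per-instance detection loss weights
#'
#' @param labels character labels.
#' @param positive_label the label carrying extra weight.
#' @param pos_weight weight for positives (default 3).
#' @return numeric weights.
#' @export
detection_weights <- function(labels, positive_label = "positive",
                              pos_weight = 3) {
  ifelse(labels == positive_label, pos_weight, 1)
}

# ---------------------------------------------------------------------
# Compiled trees: post-order arrays for fast forward/backward passes.

#' Compile an annotated tree into post-order arrays
#'
#' Produces the per-node input matrix `X` (input_dim x n_nodes, leaves
#' and internal nodes interleaved in post-order) and the child-index
#' matrix `kids` (2 x n_nodes, zeros for leaves). Inputs are assembled
#' once; embeddings are static so `X` never changes during training.
#'
#' @param tree an annotated `parse_node` (see [annotate_tree]).
#' @param table an [embedding_table].
#' @param codec distance encoder (default [encode_distance]).
#' @return list with `X`, `kids`, `n`, class `compiled_tree`.
#' @export
compile_tree <- function(tree, table, codec = encode_distance) {
  xs <- list(); k1 <- integer(0); k2 <- integer(0)
  rec <- function(node) {
    ids <- if (is_leaf(node)) c(0L, 0L)
      else c(rec(node$children[[1]]), rec(node$children[[2]]))
    xs[[length(xs) + 1L]] <<- assemble_input(node, table, codec)
    k1[length(xs)] <<- ids[1]; k2[length(xs)] <<- ids[2]
    length(xs)
  }
  rec(tree)
  structure(list(X = do.call(cbind, xs), kids = rbind(k1, k2),
                 n = length(xs)), class = "compiled_tree")
}

#' Full forward pass over a compiled tree
#'
#' @param params a `treelstm_params`.
#' @param comp a `compiled_tree`.
#' @param dfac dropout factor vector (length H), 1s for evaluation;
#'   see [dropout_spec]. One factor is shared by every node of the
#'   tree (recurrent-dropout, tree scope).
#' @param keep_cache keep gate activations for backpropagation.
#' @return list with `logits`, root `h`, and (if `keep_cache`) the
#'   activation caches.
#' @export
tl_forward <- function(params, comp, dfac = NULL, keep_cache = FALSE) {
  H <- params$hidden; n <- comp$n
  if (is.null(dfac)) dfac <- rep(1, H)
  A <- params$Wx_iou %*% comp$X + params$b_iou   # 3H x n, recycled by col
  FX <- params$Wx_f %*% comp$X + params$b_f
  I <- O <- U <- Hs <- Cs <- Tc <- matrix(0, H, n)
  F1 <- F2 <- matrix(0, H, n)
  kids <- comp$kids
  for (j in seq_len(n)) {
    leaf <- kids[1, j] == 0L
    a <- A[, j]
    if (!leaf) {
      htilde <- Hs[, kids[1, j]] + Hs[, kids[2, j]]
      a <- a + params$Wh_iou %*% htilde
    }
    i <- sigmoid(a[1:H]); o <- sigmoid(a[(H + 1):(2 * H)])
    u <- tanh(a[(2 * H + 1):(3 * H)])
    dv <- if (is.matrix(dfac)) dfac[, j] else dfac  # node-scope masks
    cc <- i * (dv * u)
    if (!leaf) {
      f1 <- sigmoid(FX[, j] + params$Wh_f %*% Hs[, kids[1, j]])
      f2 <- sigmoid(FX[, j] + params$Wh_f %*% Hs[, kids[2, j]])
      cc <- cc + f1 * Cs[, kids[1, j]] + f2 * Cs[, kids[2, j]]
      F1[, j] <- f1; F2[, j] <- f2
    }
    tc <- tanh(cc)
    I[, j] <- i; O[, j] <- o; U[, j] <- u
    Cs[, j] <- cc; Tc[, j] <- tc; Hs[, j] <- o * tc
  }
  logits <- as.numeric(params$W_fc %*% Hs[, n] + params$b_fc)
  out <- list(logits = logits, h_root = Hs[, n])
  if (keep_cache)
    out <- c(out, list(I = I, O = O, U = U, F1 = F1, F2 = F2,
                       Hs = Hs, Cs = Cs, Tc = Tc, dfac = dfac))
  out
}

# Backward pass for one tree given d(loss)/d(logits). Returns the
# parameter gradient list. Heavy outer products are deferred to four
# matrix products over the whole tree.
tl_backward <- function(params, comp, fwd, dlogits) {
  H <- params$hidden; n <- comp$n; kids <- comp$kids
  dfac <- fwd$dfac
  dH <- matrix(0, H, n); dC <- matrix(0, H, n)
  DA <- matrix(0, 3 * H, n)          # d loss / d pre-activation (i,o,u)
  DAF1 <- DAF2 <- matrix(0, H, n)    # per-child forget pre-activations
  g <- zero_like(params)
  g$W_fc <- dlogits %o% fwd$Hs[, n]
  g$b_fc <- dlogits
  dH[, n] <- as.numeric(t(params$W_fc) %*% dlogits)
  tWh_iou <- t(params$Wh_iou); tWh_f <- t(params$Wh_f)
  for (j in n:1) {
    dh <- dH[, j]; dc <- dC[, j]
    if (all(dh == 0) && all(dc == 0)) next
    o <- fwd$O[, j]; tc <- fwd$Tc[, j]
    do <- dh * tc
    dc <- dc + dh * o * (1 - tc^2)
    i <- fwd$I[, j]; u <- fwd$U[, j]
    dv <- if (is.matrix(dfac)) dfac[, j] else dfac
    di <- dc * (dv * u)
    du <- dc * i * dv
    da <- c(di * i * (1 - i), do * o * (1 - o), du * (1 - u^2))
    DA[, j] <- da
    leaf <- kids[1, j] == 0L
    if (!leaf) {
      k1 <- kids[1, j]; k2 <- kids[2, j]
      dhtilde <- as.numeric(tWh_iou %*% da)
      dH[, k1] <- dH[, k1] + dhtilde
      dH[, k2] <- dH[, k2] + dhtilde
      f1 <- fwd$F1[, j]; f2 <- fwd$F2[, j]
      df1 <- dc * fwd$Cs[, k1]; df2 <- dc * fwd$Cs[, k2]
      daf1 <- df1 * f1 * (1 - f1); daf2 <- df2 * f2 * (1 - f2)
      DAF1[, j] <- daf1; DAF2[, j] <- daf2
      dH[, k1] <- dH[, k1] + as.numeric(tWh_f %*% daf1)
      dH[, k2] <- dH[, k2] + as.numeric(tWh_f %*% daf2)
      dC[, k1] <- dC[, k1] + dc * f1
      dC[, k2] <- dC[, k2] + dc * f2
    }
  }
  internal <- which(kids[1, ] != 0L)
  g$Wx_iou <- DA %*% t(comp$X)
  g$b_iou <- rowSums(DA)
  DAF <- DAF1 + DAF2
  g$Wx_f <- DAF %*% t(comp$X)
  g$b_f <- rowSums(DAF)
  if (length(internal)) {
    Htilde <- fwd$Hs[, comp$kids[1, internal], drop = FALSE] +
      fwd$Hs[, comp$kids[2, internal], drop = FALSE]
    g$Wh_iou <- DA[, internal, drop = FALSE] %*% t(Htilde)
    g$Wh_f <- DAF1[, internal, drop = FALSE] %*%
      t(fwd$Hs[, comp$kids[1, internal], drop = FALSE]) +
      DAF2[, internal, drop = FALSE] %*%
      t(fwd$Hs[, comp$kids[2, internal], drop = FALSE])
  }
  g
}

#' Loss and parameter gradients for a batch of compiled trees
#'
#' Used by the training loop and directly by finite-difference checks.
#'
#' @param params a `treelstm_params`.
#' @param comps list of `compiled_tree`.
#' @param gold integer gold class indices (1-based).
#' @param weights per-instance loss weights.
#' @param dfacs optional list of per-tree dropout factors (NULL = eval).
#' @return list with `loss` and `grads` (gradient of the mean weighted
#'   loss over the batch).
#' @export
treelstm_gradients <- function(params, comps, gold,
                               weights = rep(1, length(comps)),
                               dfacs = NULL) {
  m <- length(comps)
  stopifnot(m >= 1L, length(gold) == m)
  grads <- zero_like(params)
  total <- 0
  for (k in seq_len(m)) {
    dfac <- if (is.null(dfacs)) NULL else dfacs[[k]]
    fwd <- tl_forward(params, comps[[k]], dfac = dfac, keep_cache = TRUE)
    ls <- log_softmax(fwd$logits)
    total <- total + weights[k] * (-ls[gold[k]])
    p <- exp(ls)
    dlog <- p; dlog[gold[k]] <- dlog[gold[k]] - 1
    dlog <- dlog * weights[k] / m
    g <- tl_backward(params, comps[[k]], fwd, dlog)
    for (nm in param_names) grads[[nm]] <- grads[[nm]] + g[[nm]]
  }
  list(loss = total / m, grads = grads)
}

#' Training configuration
#'
#' Defaults mirror the published hyperparameter search: hidden size
#' 128, batch size 100, containment block size 10; the learning rate,
#' keep probability and epochs are task-specific (detection defaults
#' shown).
#'
#' @param classes character vector of class labels; the label order
#'   fixes the class index (detection: `c("negative", "positive")`).
#' @param hidden hidden size (default 128).
#' @param batch_size minibatch size (default 100).
#' @param lr Adam learning rate (default 0.0008, the detection value).
#' @param keep_p recurrent-dropout keep probability (default 0.75).
#' @param epochs training epochs (default 100).
#' @param pos_weight loss weight on `positive_label` (default 3 when a
#'   `"positive"` class is present, else 1).
#' @param positive_label label receiving `pos_weight`.
#' @param input_dim node input length (default 230).
#' @param seed seed for initialization, shuffling and dropout masks.
#' @param dropout_variant `"inverted"` or `"paper"` (see [dropout_spec]).
#' @param mask_scope one dropout mask per `"tree"` (default) or per
#'   `"node"`.
#' @return list of class `train_config`.
#' @export
train_config <- function(classes, hidden = 128L, batch_size = 100L,
                         lr = 8e-4, keep_p = 0.75, epochs = 100L,
                         pos_weight = if ("positive" %in% classes) 3 else 1,
                         positive_label = "positive", input_dim = 230L,
                         seed = 1L,
                         dropout_variant = c("inverted", "paper"),
                         mask_scope = c("tree", "node")) {
  structure(list(classes = classes, hidden = as.integer(hidden),
                 batch_size = as.integer(batch_size), lr = lr,
                 keep_p = keep_p, epochs = as.integer(epochs),
                 pos_weight = pos_weight, positive_label = positive_label,
                 input_dim = as.integer(input_dim), seed = as.integer(seed),
                 dropout_variant = match.arg(dropout_variant),
                 mask_scope = match.arg(mask_scope)),
            class = "train_config")
}

#' Train a tree-LSTM classifier
#'
#' Mini-batch Adam over shuffled instances, with recurrent dropout on
#' the candidate memory update (one mask per tree per step by default)
#' and static word embeddings (the compiled inputs are never updated).
#' Fully deterministic given `config$seed`.
#'
#' @param comps list of `compiled_tree` training instances.
#' @param labels character gold labels, matched against
#'   `config$classes`.
#' @param config a [train_config].
#' @param params optional warm-start parameters (default fresh init
#'   seeded by `config$seed`).
#' @return object of class `treelstm_model`: `params`, `config` and the
#'   per-epoch mean-loss log.
#' @export
train_treelstm <- function(comps, labels, config, params = NULL) {
  n <- length(comps)
  if (n == 0L) stop("empty training set")
  stopifnot(length(labels) == n)
  gold <- match(labels, config$classes)
  if (anyNA(gold))
    stop("labels outside config$classes: ",
         paste(unique(labels[is.na(gold)]), collapse = ", "))
  weights <- ifelse(labels == config$positive_label, config$pos_weight, 1)
  if (is.null(params))
    params <- init_treelstm_params(config$hidden, length(config$classes),
                                   config$input_dim, seed = config$seed)
  set.seed(config$seed + 1L)
  H <- config$hidden
  # Adam state
  ms <- zero_like(params); vs <- zero_like(params); t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_log <- numeric(config$epochs)
  train_drop <- config$keep_p < 1
  for (ep in seq_len(config$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0; n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      dfacs <- NULL
      if (train_drop) {
        scale <- if (config$dropout_variant == "inverted")
          1 / config$keep_p else 1
        dfacs <- lapply(idx, function(k) {
          nm <- if (config$mask_scope == "tree") H else H * comps[[k]]$n
          # node scope draws one mask per node; tree scope shares one
          mk <- as.numeric(stats::runif(nm) < config$keep_p) * scale
          if (config$mask_scope == "tree") mk else matrix(mk, H)
        })
      }
      gb <- treelstm_gradients(params, comps[idx], gold[idx],
                               weights[idx], dfacs = dfacs)
      t <- t + 1L
      for (nm in param_names) {
        g <- gb$grads[[nm]]
        ms[[nm]] <- b1 * ms[[nm]] + (1 - b1) * g
        vs[[nm]] <- b2 * vs[[nm]] + (1 - b2) * g * g
        mhat <- ms[[nm]] / (1 - b1^t)
        vhat <- vs[[nm]] / (1 - b2^t)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
      ep_loss <- ep_loss + gb$loss; n_batches <- n_batches + 1L
    }
    loss_log[ep] <- ep_loss / n_batches
  }
  structure(list(params = params, config = config, loss_log = loss_log),
            class = "treelstm_model")
}

#' Predict labels (evaluation mode, dropout-free)
#'
#' @param model a `treelstm_model` (or bare `treelstm_params` plus
#'   `classes`).
#' @param comps list of `compiled_tree`.
#' @param classes class labels (taken from `model$config` if absent).
#' @return list with `labels` (character) and `logits`
#'   (n_classes x n matrix).
#' @export
predict_treelstm <- function(model, comps, classes = NULL) {
  params <- if (inherits(model, "treelstm_model")) model$params else model
  if (is.null(classes)) classes <- model$config$classes
  logits <- vapply(comps, function(cmp) tl_forward(params, cmp)$logits,
                   numeric(params$n_classes))
  logits <- matrix(logits, nrow = params$n_classes)
  list(labels = classes[apply(logits, 2, which.max)], logits = logits)
}

#' Train an ensemble of identically configured models
#'
#' Members differ only by their random initialization (seeds
#' `config$seed + 0:(n_members-1)`).
#'
#' @param comps,labels,config as in [train_treelstm].
#' @param n_members ensemble size (default 10).
#' @return list of `treelstm_model`, class `treelstm_ensemble`.
#' @export
train_ensemble <- function(comps, labels, config, n_members = 10L) {
  members <- lapply(seq_len(n_members) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    train_treelstm(comps, labels, cfg)
  })
  structure(members, class = "treelstm_ensemble")
}

#' Ensemble prediction by logit summation
#'
#' Element-wise sum of the members' root logits, then argmax.
#'
#' @param members list of `treelstm_model` (>= 1), identical
#'   architectures trained from different seeds.
#' @param comps list of `compiled_tree`.
#' @param classes class labels (default from the first member).
#' @return list with `labels` and the summed `logits` matrix.
#' @export
ensemble_predict <- function(members, comps, classes = NULL) {
  stopifnot(length(members) >= 1L)
  ncls <- vapply(members, function(m) m$params$n_classes, 0L)
  if (length(unique(ncls)) != 1L)
    stop("ensemble members disagree on class count")
  if (is.null(classes)) classes <- members[[1]]$config$classes
  total <- NULL
  for (m in members) {
    lg <- predict_treelstm(m, comps, classes)$logits
    total <- if (is.null(total)) lg else total + lg
  }
  list(labels = classes[apply(total, 2, which.max)], logits = total)
}

# ---------------------------------------------------------------------
# Checkpointing: JSON archive of all named tensors + config.

#' Save a trained model to a JSON checkpoint
#'
#' Numbers are written at full precision so [load_checkpoint]
#' round-trips exactly.
#'
#' @param model a `treelstm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  p <- model$params
  # 17 significant digits guarantee exact double round-trip; jsonlite's
  # own numeric formatting does not
  tensors <- lapply(p[param_names], function(x) {
    list(dim = if (is.matrix(x)) dim(x) else length(x),
         data = sprintf("%.17g", as.numeric(x)))
  })
  obj <- list(format = "treeddi-checkpoint-1",
              hidden = p$hidden, input_dim = p$input_dim,
              n_classes = p$n_classes,
              config = unclass(model$config),
              loss_log = model$loss_log,
              tensors = tensors)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#'
#' @param path checkpoint path.
#' @return a `treelstm_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "treeddi-checkpoint-1"))
    stop("not a treeddi checkpoint: ", path)
  params <- list(hidden = as.integer(obj$hidden),
                 input_dim = as.integer(obj$input_dim),
                 n_classes = as.integer(obj$n_classes))
  for (nm in param_names) {
    t <- obj$tensors[[nm]]
    v <- as.numeric(t$data)
    params[[nm]] <- if (length(t$dim) == 2L) matrix(v, t$dim[1], t$dim[2])
      else v
  }
  class(params) <- "treelstm_params"
  cfg <- obj$config
  class(cfg) <- "train_config"
  structure(list(params = params[c(param_names, "hidden", "input_dim",
                                   "n_classes")],
                 config = cfg, loss_log = as.numeric(obj$loss_log)),
            class = "treelstm_model")
}
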