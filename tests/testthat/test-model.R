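zeroed_params <- function(H, C, D) {
  p <- init_treelstm_params(H, C, input_dim = D, seed = 1)
  for (nm in c("Wx_iou", "Wh_iou", "b_iou", "Wx_f", "Wh_f", "b_f",
               "W_fc", "b_fc")) p[[nm]][] <- 0
  p
}

test_that("node_forward zero fixed point and structural errors", {
  p <- zeroed_params(3L, 2L, 5L)
  st <- node_forward(p, rep(0, 5))
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
  expect_error(node_forward(p, rep(0, 5),
                            list(list(h = rep(0, 3), c = rep(0, 3)))),
               "structural error")
  expect_error(node_forward(p, c(NaN, 0, 0, 0, 0)), "numeric error")
  expect_error(node_forward(p, rep(0, 4)), "input length")
})

test_that("H=1 all-ones scalar leaf matches the hand computation", {
  p <- zeroed_params(1L, 2L, 1L)
  for (nm in c("Wx_iou", "Wh_iou", "Wx_f", "Wh_f")) p[[nm]][] <- 1
  st <- node_forward(p, 1)
  s1 <- 1 / (1 + exp(-1))
  expect_equal(st$c, s1 * tanh(1), tolerance = 1e-12)   # ~0.55677
  expect_equal(st$h, s1 * tanh(s1 * tanh(1)), tolerance = 1e-12) # ~0.36961
})

test_that("eval mode is dropout-free; keep_p = 1 train equals eval", {
  set.seed(8)
  p <- init_treelstm_params(4L, 2L, input_dim = 6L, seed = 3)
  x <- runif(6)
  kids <- list(list(h = runif(4), c = runif(4)),
               list(h = runif(4), c = runif(4)))
  ev <- node_forward(p, x, kids, dropout_spec(keep_p = 0.5, mode = "eval"))
  ev2 <- node_forward(p, x, kids, dropout_spec(keep_p = 0.5, mode = "eval"))
  expect_identical(ev, ev2)
  tr1 <- node_forward(p, x, kids, dropout_spec(keep_p = 1, mode = "train"))
  expect_equal(tr1, ev)
  # the literal-rule variant with an all-ones mask is also identity
  trp <- node_forward(p, x, kids,
                      dropout_spec(keep_p = 0.5, mode = "train",
                                   mask = rep(1, 4), variant = "paper"))
  expect_equal(trp, ev)
  # inverted scaling divides the kept mask by keep_p
  tri <- node_forward(p, x, kids,
                      dropout_spec(keep_p = 0.5, mode = "train",
                                   mask = rep(1, 4), variant = "inverted"))
  expect_false(isTRUE(all.equal(tri$c, ev$c)))
})

test_that("vectorized forward equals the scalar-loop oracle on random trees", {
  set.seed(99)
  maxerr <- 0
  for (t in 1:100) {
    H <- sample(2:8, 1)
    D <- sample(3:10, 1)
    p <- init_treelstm_params(H, 2L, input_dim = D, seed = t)
    rt <- random_compiled_tree(H, D)
    f <- tl_forward(p, rt$comp)
    s <- oracle_forward(p, rt$root, rt$comp$X)
    maxerr <- max(maxerr, max(abs(f$h_root - s$h)))
  }
  expect_lt(maxerr, 1e-6)
})

test_that("classify_root and predict_class follow the output-layer contract", {
  p <- zeroed_params(3L, 2L, 5L)
  st <- list(h = runif(3), c = runif(3))
  expect_equal(classify_root(p, st), c(0, 0))
  p$b_fc <- c(0, 1)
  expect_equal(predict_class(classify_root(p, st)), 2L)
  expect_equal(predict_class(c(0.2, 0.9)), 2L)
  expect_equal(predict_class(c(0.5, 0.5)), 1L)  # tie -> lower index
  set.seed(4)
  for (k in 1:20) {
    lg <- runif(5)
    expect_equal(predict_class(lg), which(lg == max(lg))[1])
  }
  # logits equal the oracle matrix product
  p2 <- init_treelstm_params(4L, 5L, input_dim = 6L, seed = 2)
  st2 <- list(h = runif(4), c = runif(4))
  expect_equal(classify_root(p2, st2),
               as.numeric(p2$W_fc %*% st2$h + p2$b_fc))
})

test_that("loss matches closed forms and the 3x positive weighting", {
  # softmax prob -> 1 on gold: loss -> 0
  expect_lt(ddi_loss(c(50, 0), 1L), 1e-10)
  # uniform logits, two classes
  expect_equal(ddi_loss(c(0, 0), 1L), -log(0.5), tolerance = 1e-12)
  expect_equal(ddi_loss(c(0, 0), 2L, weights = 3), 3 * -log(0.5),
               tolerance = 1e-12)
  lg <- matrix(0, 2, 2)
  w <- detection_weights(c("positive", "negative"))
  expect_equal(w, c(3, 1))
  expect_equal(ddi_loss(lg, c(2L, 1L), w), 2 * -log(0.5),
               tolerance = 1e-12)
  # shift invariance
  set.seed(12)
  l0 <- matrix(rnorm(15), 5)
  expect_equal(ddi_loss(l0, c(1L, 4L, 5L)),
               ddi_loss(l0 + 7.3, c(1L, 4L, 5L)), tolerance = 1e-9)
  expect_error(ddi_loss(c(0, 0), 3L), "class range")
})

test_that("analytic gradients agree with finite differences (H=4)", {
  set.seed(5)
  cor <- generate_corpus(generator_config(n = 6, seed = 3))
  tab <- small_table()
  ds <- prepare_dataset(cor$records, cor$trees, tab, split = "train",
                        drop_duplicates = FALSE)
  comps <- ds$comps[1:4]
  gold <- ifelse(ds$labels[1:4] == "positive", 2L, 1L)
  w <- detection_weights(ds$labels[1:4])
  p <- init_treelstm_params(4L, 2L, input_dim = 40L, seed = 9)
  gb <- treelstm_gradients(p, comps, gold, w)
  maxrel <- 0
  for (nm in c("Wx_iou", "Wh_iou", "b_iou", "Wx_f", "Wh_f", "b_f",
               "W_fc", "b_fc")) {
    g <- gb$grads[[nm]]
    for (ii in sample(length(g), min(12, length(g))))
      maxrel <- max(maxrel, fd_relative_error(p, comps, gold, w, nm, ii,
                                              g[ii]))
  }
  expect_lt(maxrel, 1e-4)
})

test_that("training contracts: lr = 0 no-op, determinism, empty set error", {
  cor <- generate_corpus(generator_config(n = 20, seed = 4))
  tab <- small_table()
  ds <- prepare_dataset(cor$records, cor$trees, tab, split = "train",
                        drop_duplicates = FALSE)
  cfg0 <- train_config(classes = c("negative", "positive"), hidden = 4L,
                       batch_size = 8L, lr = 0, keep_p = 1, epochs = 1L,
                       input_dim = 40L, seed = 2)
  init <- init_treelstm_params(4L, 2L, input_dim = 40L, seed = 2)
  m0 <- train_treelstm(ds$comps, ds$labels, cfg0)
  for (nm in c("Wx_iou", "Wh_iou", "b_iou", "Wx_f", "Wh_f", "b_f",
               "W_fc", "b_fc"))
    expect_equal(m0$params[[nm]], init[[nm]])
  cfg <- train_config(classes = c("negative", "positive"), hidden = 4L,
                      batch_size = 8L, lr = 0.01, keep_p = 0.8,
                      epochs = 3L, input_dim = 40L, seed = 2)
  m1 <- train_treelstm(ds$comps, ds$labels, cfg)
  m2 <- train_treelstm(ds$comps, ds$labels, cfg)
  expect_identical(m1$loss_log, m2$loss_log)   # bitwise determinism
  expect_identical(m1$params, m2$params)
  expect_error(train_treelstm(list(), character(0), cfg),
               "empty training set")
  expect_error(train_treelstm(ds$comps, rep("odd", length(ds$comps)), cfg),
               "outside config\\$classes")
})

test_that("training learns a planted signal and dropout regularizes", {
  cor <- make_separable(generator_config(n = 400, seed = 1))
  tab <- small_table(dim = 30L)
  ds <- prepare_dataset(cor$records, cor$trees, tab, split = "train",
                        drop_duplicates = FALSE)
  cfg <- separable_train_config(seed = 1)
  cfg$hidden <- 16L
  cfg$input_dim <- 60L
  m <- train_treelstm(ds$comps, ds$labels, cfg)
  pr <- predict_treelstm(m, ds$comps)
  f1 <- evaluate_detection(pr$labels, ds$labels)$micro[["f1"]]
  expect_gte(f1, 0.95)
  expect_lt(tail(m$loss_log, 1), head(m$loss_log, 1))
})

test_that("ensemble prediction sums logits; single member equals predict", {
  cor <- generate_corpus(generator_config(n = 15, seed = 6))
  tab <- small_table()
  ds <- prepare_dataset(cor$records, cor$trees, tab, split = "train",
                        drop_duplicates = FALSE)
  cfg <- train_config(classes = c("negative", "positive"), hidden = 4L,
                      batch_size = 8L, lr = 0.01, keep_p = 1, epochs = 2L,
                      input_dim = 40L, seed = 3)
  m <- train_treelstm(ds$comps, ds$labels, cfg)
  single <- predict_treelstm(m, ds$comps)
  ens1 <- ensemble_predict(list(m), ds$comps)
  expect_identical(ens1$labels, single$labels)
  expect_equal(ens1$logits, single$logits)
  # two fabricated members: (1,0) + (0,2) -> class 2
  mk <- function(b) {
    mm <- m
    mm$params$W_fc[] <- 0
    mm$params$b_fc <- b
    mm
  }
  ens2 <- ensemble_predict(list(mk(c(1, 0)), mk(c(0, 2))), ds$comps[1])
  expect_equal(as.numeric(ens2$logits), c(1, 2))
  expect_identical(ens2$labels, "positive")
  # mismatched class counts error
  bad <- m
  bad$params$n_classes <- 5L
  bad$params$W_fc <- matrix(0, 5, 4)
  bad$params$b_fc <- numeric(5)
  bad$config$classes <- c("negative", "advice", "effect", "mechanism", "int")
  expect_error(ensemble_predict(list(m, bad), ds$comps), "disagree")
})

test_that("checkpoints round-trip exactly", {
  cor <- generate_corpus(generator_config(n = 10, seed = 2))
  tab <- small_table()
  ds <- prepare_dataset(cor$records, cor$trees, tab, split = "train",
                        drop_duplicates = FALSE)
  cfg <- train_config(classes = c("negative", "positive"), hidden = 3L,
                      batch_size = 4L, lr = 0.01, keep_p = 0.9,
                      epochs = 2L, input_dim = 40L, seed = 5)
  m <- train_treelstm(ds$comps, ds$labels, cfg)
  path <- tempfile(fileext = ".json")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  for (nm in c("Wx_iou", "Wh_iou", "b_iou", "Wx_f", "Wh_f", "b_f",
               "W_fc", "b_fc"))
    expect_identical(m2$params[[nm]], m$params[[nm]])
  expect_equal(m2$config$classes, m$config$classes)
  expect_equal(m2$loss_log, m$loss_log)
  # loaded model predicts identically
  expect_identical(predict_treelstm(m2, ds$comps, m2$config$classes)$labels,
                   predict_treelstm(m, ds$comps)$labels)
  expect_error(load_checkpoint(write_instances(list(), tempfile())))
})
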