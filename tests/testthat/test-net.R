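test_that("model structure follows the configuration", {
  m <- inception_time(random_dataset(), config = tiny_net())
  expect_length(m$params$blocks, 1L)
  expect_equal(dim(m$params$Wout), c(2L, 8L))   # 4 * filters feature maps
  expect_null(m$params$blocks[[1L]]$Wr)

  mr <- inception_time(random_dataset(), config = residual_net())
  expect_false(is.null(mr$params$blocks[[3L]]$Wr))
  expect_null(mr$params$blocks[[1L]]$Wr)

  # kernels longer than the input are rejected
  short <- random_dataset(len = 4L)
  expect_error(inception_time(short, config = tiny_net()), "kernel length")
})

test_that("untrained model outputs are valid probabilities and feature maps
           keep the input length", {
  ds <- random_dataset(n = 6L, len = 40L)
  m <- inception_time(ds, config = tiny_net())
  pr <- predict(m, ds, type = "prob")
  expect_equal(dim(pr), c(6L, 2L))
  expect_equal(rowSums(pr), rep(1, 6L), tolerance = 1e-6)
  A <- feature_maps(m, ds$values[, , 1L])
  expect_equal(dim(A), c(8L, 40L))
})

test_that("compiled gradients match finite differences and the R reference", {
  cfg <- residual_net()
  set.seed(3)
  X <- array(rnorm(2 * 12 * 4), c(12, 2, 4))    # time-major internal layout
  Y <- matrix(0, 2, 4); Y[cbind(c(1, 2, 1, 2), 1:4)] <- 1
  set.seed(4)
  params <- camsched:::init_params(cfg, 2L, 2L, 12L)

  cpp <- camsched:::net_lossgrad_cpp(params, X, Y, cfg$kernel_lengths,
                                     cfg$filters, cfg$residual_every)
  ref <- camsched:::net_loss_grad(params, X, Y, cfg)
  expect_equal(cpp$loss, ref$loss, tolerance = 1e-12)

  flat <- function(g) unlist(g, use.names = FALSE)
  expect_equal(flat(cpp$grads), flat(ref$grads), tolerance = 1e-10)

  # finite differences on a sample of coordinates across all blocks
  loss_at <- function(p) camsched:::net_loss_grad(p, X, Y, cfg)$loss
  eps <- 1e-6
  probes <- list(c("blocks", "1", "Wb"), c("blocks", "2", "Wp"),
                 c("blocks", "3", "Wr"), c("Wout"))
  for (pr in probes) {
    get_leaf <- function(p) { for (k in pr)
      p <- if (grepl("^[0-9]+$", k)) p[[as.integer(k)]] else p[[k]]; p }
    leaf <- get_leaf(params)
    i <- 1L
    bump <- function(delta) {
      p <- params
      path <- lapply(pr, function(k)
        if (grepl("^[0-9]+$", k)) as.integer(k) else k)
      l <- get_leaf(p); l[i] <- l[i] + delta
      if (length(path) == 1L) p[[path[[1L]]]] <- l
      else p[[path[[1L]]]][[path[[2L]]]][[path[[3L]]]] <- l
      p
    }
    g_num <- (loss_at(bump(eps)) - loss_at(bump(-eps))) / (2 * eps)
    g_ana <- get_leaf(ref$grads)[i]
    expect_equal(g_num, g_ana, tolerance = 1e-6)
  }
})

test_that("global average pooling makes the CAM identity exact", {
  ds <- random_dataset(n = 5L, len = 36L, seed = 23L)
  m <- inception_time(ds, config = residual_net())
  logits <- predict(m, ds, type = "logit")
  co <- coef(m)
  for (i in 1:5) {
    A <- feature_maps(m, ds$values[, , i])
    for (cl in seq_along(m$classes)) {
      cam <- cam_from_maps(A, co$weights[cl, ])
      expect_equal(unname(mean(cam) + co$bias[cl]), unname(logits[i, cl]),
                   tolerance = 1e-5)
    }
  }
})

test_that("training separates a trivially separable two-class set", {
  ds <- separable_dataset()
  cfg <- tiny_net(epochs = 50L)
  m <- inception_time(ds, config = cfg)
  expect_equal(evaluate(m, ds)$accuracy, 1)
  expect_true(length(m$history) == 50L)
  expect_lt(utils::tail(m$history, 1L), m$history[1L])
})

test_that("ensembles hold independently initialized fits and select_best
           breaks ties by fit index", {
  ds <- separable_dataset()
  ens <- train_ensemble(ds, tiny_net(epochs = 1L), n_fits = 5L)
  expect_length(ens$fits, 5L)
  W <- lapply(ens$fits, function(f) f$params$Wout)
  for (i in 2:5) expect_false(identical(W[[1L]], W[[i]]))
  expect_length(train_ensemble(ds, tiny_net(epochs = 1L), n_fits = 1L)$fits,
                1L)

  single <- ds[ds$labels == "lo"]
  expect_error(train_ensemble(single, tiny_net(epochs = 1L)), "single class")

  good <- inception_time(ds, config = tiny_net(epochs = 40L))
  bad <- inception_time(ds, config = tiny_net(epochs = 0L, seed = 2L))
  best <- select_best(list(bad, good), ds)
  expect_equal(attr(best, "fit_index"),
               which.max(c(evaluate(bad, ds)$accuracy,
                           evaluate(good, ds)$accuracy)))
  tie <- select_best(list(good, good), ds)
  expect_equal(attr(tie, "fit_index"), 1L)
})

test_that("metrics match a brute-force confusion oracle", {
  truth <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  pred <- factor(c("a", "a", "a", "a"), levels = c("a", "b"))
  m <- classification_metrics(truth, pred)
  cc <- m$counts
  expect_equal(cc$TP[cc$class == "a"], 2L)
  expect_equal(cc$FP[cc$class == "a"], 2L)
  expect_equal(cc$FN[cc$class == "b"], 2L)
  # precision_a = 0.5, recall_a = 1, recall_b = 0
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, mean(c(0.5, 0)))
  expect_equal(m$recall, mean(c(1, 0)))

  set.seed(77)
  lv <- c("CR", "PR", "SNG", "PNG")
  truth <- factor(sample(lv, 1000, TRUE), levels = lv)
  pred <- factor(sample(lv, 1000, TRUE), levels = lv)
  m <- classification_metrics(truth, pred)
  # independent tally
  acc <- sum(as.character(truth) == as.character(pred)) / 1000
  precs <- recs <- c()
  for (cl in lv) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in 1:1000) {
      if (pred[i] == cl && truth[i] == cl) tp <- tp + 1
      if (pred[i] == cl && truth[i] != cl) fp <- fp + 1
      if (pred[i] != cl && truth[i] == cl) fn <- fn + 1
    }
    if (tp + fn > 0) {
      precs <- c(precs, if (tp + fp > 0) tp / (tp + fp) else 0)
      recs <- c(recs, tp / (tp + fn))
    }
  }
  expect_equal(m$accuracy, acc, tolerance = 1e-12)
  expect_equal(m$precision, mean(precs), tolerance = 1e-12)
  expect_equal(m$recall, mean(recs), tolerance = 1e-12)
  # every one-vs-rest row sums to n
  expect_true(all(rowSums(m$counts[c("TP", "TN", "FP", "FN")]) == 1000))

  # invariance to dataset shuffling
  o <- sample(1000)
  m2 <- classification_metrics(truth[o], pred[o])
  expect_equal(m$accuracy, m2$accuracy)
  expect_equal(m$precision, m2$precision)
  expect_equal(m$recall, m2$recall)
})
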