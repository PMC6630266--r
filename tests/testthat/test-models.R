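test_that("softmax is a shift-invariant probability distribution", {
  expect_equal(softmax(c(0, 0, 0, 0)), rep(0.25, 4))
  p <- softmax(c(1, 0, 0, 0))
  expect_equal(p[1], exp(1) / (exp(1) + 3), tolerance = 1e-12)
  expect_equal(sum(p), 1)
  s <- c(2.5, -1, 0.3, 7)
  expect_equal(softmax(s), softmax(s + 42), tolerance = 1e-12)
  m <- softmax(matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(m), rep(1, 3))
  expect_error(softmax(numeric(0)), "non-empty")
})

test_that("network variants build with the specified filter counts and kernels", {
  net <- build_network("idpc", c(8, 8, 4), seed = 1)
  expect_equal(net$kernels, list(c(2L, 4L), c(4L, 2L)))
  filt <- vapply(net$branches[[1]], function(l) dim(l$W)[4], integer(1))
  expect_equal(filt, c(10L, 20L, 20L))
  expect_equal(dim(net$branches[[1]][[1]]$W), c(2L, 4L, 4L, 10L))
  expect_equal(dim(net$branches[[2]][[1]]$W), c(4L, 2L, 4L, 10L))
  expect_equal(dim(net$head[[3]]$W)[2], 4L)   # one unit per gesture class
  # kernel transposition preserves the parameter count
  expect_equal(network_param_count(build_network("dpc1", c(8, 8, 4))),
               network_param_count(build_network("dpc2", c(8, 8, 4))))
  single <- build_network("single", c(8, 8, 4))
  expect_length(single$branches, 1L)
  expect_equal(dim(single$branches[[1]][[1]]$W)[1:2], c(2L, 2L))
  expect_error(build_network("idpc", c(1, 8, 4)), "small")
})

test_that("forward pass yields valid, batch-equivariant, repeatable probabilities", {
  net <- build_network("idpc", c(8, 8, 4), seed = 2)
  p0 <- cnn_predict(net, array(0, c(8, 8, 4, 3)))
  expect_equal(rowSums(p0), rep(1, 3), tolerance = 1e-6)
  set.seed(4)
  x <- array(rnorm(8 * 8 * 4 * 6), c(8, 8, 4, 6))
  p <- cnn_predict(net, x)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(cnn_predict(net, x[, , , perm]), p[perm, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # dropout is inference-inert: identical repeated calls
  expect_identical(cnn_predict(net, x), p)
  expect_error(cnn_predict(net, array(0, c(4, 8, 4, 1))), "shape")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(9)
  x <- array(rnorm(8 * 8 * 4 * 4), c(8, 8, 4, 4))
  for (v in c("idpc", "single")) {
    net <- build_network(v, c(8, 8, 4), seed = 3)
    rel <- semgfall:::cnn_gradient_check(net, x, c(1, 2, 3, 4),
                                         n_checks = 10, seed = 7)
    expect_lt(rel, 1e-4)
  }
})

test_that("training is seed-deterministic and reduces the loss on easy data", {
  tn <- fixture_tensors()
  tb <- stack_blocks(tn$tensors, tn$labels)
  net0 <- build_network("idpc", dim(tb$x)[1:3], seed = 5)
  m1 <- cnn_train(net0, tb$x, tb$y, epochs = 25, seed = 5)
  m2 <- cnn_train(net0, tb$x, tb$y, epochs = 25, seed = 5)
  expect_identical(tail(m1$history$train_loss, 1),
                   tail(m2$history$train_loss, 1))
  h <- m1$history$train_loss
  expect_gt(mean(head(h, 5)), mean(tail(h, 5)))   # loss decreases
  # training-set accuracy on the well-separated setting
  pred <- predict_segments(m1, tn$tensors)
  expect_gte(mean(as.character(pred$class) == tn$labels), 0.95)
  expect_equal(rowSums(pred$probs), rep(1, length(tn$labels)),
               tolerance = 1e-6)
  # single-class training refused
  expect_error(cnn_train(net0, tb$x, rep("falling", length(tb$y))),
               "single class|refus")
})

test_that("early stopping on a validation split restores the best epoch", {
  tn <- fixture_tensors()
  tb <- stack_blocks(tn$tensors, tn$labels)
  net0 <- build_network("single", dim(tb$x)[1:3], seed = 6)
  m <- cnn_train(net0, tb$x, tb$y, epochs = 40, seed = 6, val_frac = 0.2,
                 patience = 3)
  expect_true(all(c("train_loss", "val_loss") %in% names(m$history)))
  expect_true(all(is.finite(m$history$val_loss)))
  expect_lte(nrow(m$history), 40)
})

test_that("baseline classifiers share the fit/predict contract", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  y <- rep(c("falling", "walking"), each = 30)
  svm <- baseline_classifier("svm_rbf", x, y)
  expect_equal(mean(predict(svm, x) == y), 1)
  knn1 <- baseline_classifier("knn", x, y, k = 1)
  expect_equal(mean(predict(knn1, x) == y), 1)   # k = 1 memorises
  lda <- baseline_classifier("lda", x, y)
  expect_true(all(as.character(predict(lda, x)) %in% gesture_classes()))
  expect_error(baseline_classifier("svm_rbf", x, rep("falling", 60)),
               "two classes")
  # all three run on one feature table
  for (kind in c("svm_rbf", "lda", "knn")) {
    clf <- baseline_classifier(kind, x, y)
    expect_length(predict(clf, x), nrow(x))
  }
})
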