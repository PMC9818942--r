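# Network architecture audit, activation, splitting, augmentation,
# classical classifiers and metrics.

test_that("layer extents match the reference architecture exactly", {
  sh <- network_shapes(network_spec())
  want <- function(layer, h, w, c) {
    row <- sh[sh$layer == layer, ]
    expect_equal(unname(unlist(row[, c("height", "width", "channels")])),
                 c(h, w, c), label = layer)
  }
  want("input", 224, 224, 6)
  want("conv1", 112, 112, 64); want("maxpool1", 112, 112, 64)
  want("conv2", 56, 56, 46);   want("maxpool2", 56, 56, 46)
  want("conv3", 28, 28, 32);   want("maxpool3", 28, 28, 32)
  want("conv4", 28, 28, 16);   want("maxpool4", 28, 28, 16)
  want("global_avg_pool", 28, 28, 16)
  want("fc1", 1, 1, 16)
  want("fc2", 1, 1, 2)
  want("class_out", 1, 1, 2)
  # independent re-derivation of the conv extents from the geometry
  out_extent <- function(hin, k, s) floor((hin + 2 * ceiling((k - s) / 2) - k) / s) + 1
  expect_equal(ceiling(224 / 2), 112)
  expect_equal(ceiling(112 / 2), 56)
  expect_equal(ceiling(56 / 2), 28)
})

test_that("parameter count is bounded and near the reference figure", {
  n <- n_parameters(network_spec())
  expect_lte(n, 375500)
  expect_lt(abs(n - 316400) / 316400, 0.01)
  # independent count from the layer geometry
  manual <- (6 * 6 * 6 * 64 + 64) + (5 * 5 * 64 * 46 + 46) +
    (4 * 4 * 46 * 32 + 32) + (3 * 3 * 32 * 16 + 16) +
    (28 * 28 * 16 * 16 + 16) + (16 * 2 + 2)
  expect_equal(n, manual)
  expect_lt(n_parameters(network_spec("global")), n)
})

test_that("initialization is seed-deterministic", {
  n1 <- build_network(network_spec(), seed = 42)
  n2 <- build_network(network_spec(), seed = 42)
  expect_identical(n1$weights, n2$weights)
  n3 <- build_network(network_spec(), seed = 43)
  expect_false(identical(n1$weights, n3$weights))
})

test_that("combined activation reproduces its reference values", {
  expect_equal(combined_activation(c(0, 0)), c(1, 1), tolerance = 1e-12)
  expect_equal(combined_activation(c(1, 0)),
               c(exp(1) / (exp(1) + 1) + 1 / (1 + exp(-1)),
                 1 / (1 + exp(1)) + 0.5), tolerance = 1e-12)
  expect_equal(combined_activation(c(1, 0)), c(1.46212, 0.76894),
               tolerance = 1e-5)
  big <- combined_activation(c(40, -40))
  expect_equal(big, c(2, 0), tolerance = 1e-12)
})

test_that("combined activation is bounded and preserves the argmax", {
  set.seed(1)
  for (i in 1:200) {
    z <- stats::rnorm(2, 0, 5)
    a <- combined_activation(z)
    expect_true(all(a > 0 & a < 2))
    if (z[1] != z[2]) {
      expect_equal(which.max(a), which.max(z))
    }
  }
  m <- combined_activation(rbind(c(0, 0), c(3, -1)))
  expect_equal(dim(m), c(2, 2))
  expect_equal(m[1, ], c(1, 1), tolerance = 1e-12)
})

test_that("grouped splitting never leaks a source id", {
  ids <- rep(sprintf("src%02d", 1:10), each = 5)  # 10 sources x 5 variants
  sp <- grouped_split(ids, test_fraction = 0.1, seed = 1)
  expect_length(sp$test, 5)
  expect_length(sp$test_ids, 1)
  expect_length(intersect(ids[sp$train], ids[sp$test]), 0)
  expect_identical(sp, grouped_split(ids, test_fraction = 0.1, seed = 1))
  for (s in 1:20) {
    n_src <- sample(3:30, 1)
    reps <- sample(1:6, n_src, replace = TRUE)
    ids <- rep(sprintf("s%d", seq_len(n_src)), times = reps)
    sp <- grouped_split(ids, test_fraction = runif(1, 0.05, 0.5), seed = s)
    expect_length(intersect(ids[sp$train], ids[sp$test]), 0)
    expect_equal(sort(c(sp$train, sp$test)), seq_along(ids))
  }
  expect_error(grouped_split(c("a", NA)), "source_id")
})

test_that("translational augmentation shifts within bounds and inverts", {
  img <- rand_image(40, 3)
  vars <- augment_translate(img, 8, max_shift = 11, seed = 2)
  expect_length(vars, 8)
  for (v in vars) {
    s <- attr(v, "shift")
    expect_true(all(abs(s) >= 1 & abs(s) <= 11))
    # shifting back recovers the interior
    back <- cwriig:::.shift_replicate(v, -s[1], -s[2])
    core <- 13:28
    expect_equal(back[core, core], img[core, core])
  }
  expect_identical(augment_translate(img, 3, seed = 9),
                   augment_translate(img, 3, seed = 9))
})

test_that("confusion-matrix metrics satisfy their identities", {
  m <- classification_metrics(
    truth = c(rep("malignant", 100), rep("benign", 100)),
    pred = c(rep("malignant", 99), "benign", rep("benign", 99), "malignant"))
  expect_equal(m$tp, 99); expect_equal(m$tn, 99)
  expect_equal(m$fp, 1);  expect_equal(m$fn, 1)
  for (f in c("accuracy", "sensitivity", "specificity", "ppv", "npv", "f1")) {
    expect_equal(m[[f]], 0.99, tolerance = 1e-12, label = f)
  }
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:50, 4, replace = TRUE)  # tp, tn, fp, fn
    truth <- c(rep("malignant", n[1] + n[4]), rep("benign", n[2] + n[3]))
    pred <- c(rep("malignant", n[1]), rep("benign", n[4]),
              rep("benign", n[2]), rep("malignant", n[3]))
    m <- classification_metrics(truth, pred)
    expect_equal(m$accuracy, (m$tp + m$tn) / length(truth))
    expect_equal(m$sensitivity, m$tp / (m$tp + m$fn))
    expect_equal(m$specificity, m$tn / (m$tn + m$fp))
    expect_equal(m$ppv, m$tp / (m$tp + m$fp))
    expect_equal(m$npv, m$tn / (m$tn + m$fn))
    expect_equal(m$f1, 2 * m$ppv * m$sensitivity / (m$ppv + m$sensitivity))
  }
})

test_that("degenerate confusion cells yield undefined rates, not errors", {
  m <- classification_metrics(rep("benign", 10), rep("benign", 10))
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  expect_output(print(m), "undefined")
})

test_that("classical classifiers separate separable features perfectly", {
  set.seed(3)
  f <- rbind(matrix(rnorm(200, -2, 0.3), 50), matrix(rnorm(200, 2, 0.3), 50))
  y <- rep(c("benign", "malignant"), each = 50)
  for (kind in c("svm", "knn", "random_forest")) {
    clf <- fit_classical(f, y, kind = kind, seed = 1)
    expect_equal(mean(as.character(predict(clf, f)) == y), 1, label = kind)
  }
  expect_error(fit_classical(f, y, kind = "mlp"), "arg")
  expect_error(fit_classical(f, y[1:10]), "aligned")
})

test_that("training validates labels and class balance", {
  stacks <- toy_stacks(2)
  data <- cnn_stack_data(stacks)
  net <- build_network(network_spec(), seed = 1)
  cfg <- training_config(batch_size = 2, iterations = 1)
  expect_error(train_cnn(net, data, cfg, indices = integer(0)), "empty")
  expect_error(train_cnn(net, data, cfg, indices = c(1L, 2L)), "two classes")
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_error(training_config(test_fraction = 1.2), "test_fraction")
})

test_that("the network learns separable stacks and features are stable", {
  stacks <- toy_stacks(20)
  data <- cnn_stack_data(stacks)
  labels <- vapply(stacks, function(s) s$label, character(1))
  net <- build_network(network_spec(), seed = 4)
  cfg <- training_config(batch_size = 10, learning_rate = 0.01,
                         iterations = 100, seed = 8)
  tr <- train_cnn(net, data, cfg)
  expect_length(tr$loss_trace, 100)
  # loss trends downward over the early iterations
  first <- tr$loss_trace[1:50]
  expect_lt(stats::cor(seq_along(first), first, method = "spearman"), 0)
  acc <- mean(as.character(predict(tr, data)) == labels)
  expect_gte(acc, 0.95)
  # pooled features: 16-length, identical inputs give identical rows
  ftr <- extract_features(tr, data)
  expect_equal(ncol(ftr), 16)
  expect_equal(nrow(ftr), data$n)
  f2 <- extract_features(tr, data, indices = c(1L, 1L))
  expect_identical(f2[1, ], f2[2, ])
})

test_that("training is bitwise deterministic given its seeds", {
  stacks <- toy_stacks(3)
  data <- cnn_stack_data(stacks)
  cfg <- training_config(batch_size = 4, learning_rate = 0.01,
                         iterations = 5, seed = 6)
  t1 <- train_cnn(build_network(network_spec(), seed = 2), data, cfg)
  t2 <- train_cnn(build_network(network_spec(), seed = 2), data, cfg)
  expect_identical(t1$weights, t2$weights)
  expect_identical(t1$loss_trace, t2$loss_trace)
})
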