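# small spec shared across predictor tests (tiny widths keep the
# finite-difference checks fast)
tiny_spec <- function(kind) {
  model_spec(kind, recurrent_width = 4L, td_width = 3L,
             dense_widths = c(4L, 3L), fusion_width = 3L,
             diag_dim = 3L, diag_len = 4L, exam_dim = 4L, exam_len = 3L)
}

tiny_data <- function(n, seed, kind) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  mk <- function(len, dim) {
    x <- array(rnorm(n * len * dim), c(n, len, dim))
    for (i in which(y == 1)) x[i, len, 1] <- x[i, len, 1] + 2
    x
  }
  if (kind == "dual_input") {
    out <- list(x_d = mk(4, 3), mask_d = matrix(1, n, 4),
                x_e = mk(3, 4), mask_e = matrix(1, n, 3), y = y)
    class(out) <- "dual_instance_set"
  } else if (kind == "diagnosis_rnn") {
    out <- list(x = mk(4, 3), mask = matrix(1, n, 4), y = y)
    class(out) <- "instance_set"
  } else {
    out <- list(x = mk(3, 4), mask = matrix(1, n, 3), y = y)
    class(out) <- "instance_set"
  }
  out
}

test_that("every model outputs a proper 2-class distribution", {
  for (kind in c("diagnosis_rnn", "exam_dense", "dual_input")) {
    m <- build_model(tiny_spec(kind), seed = 1)
    d <- tiny_data(7, 2, kind)
    sc <- predict_scores(m, d)
    expect_length(sc, 7)
    expect_true(all(sc >= 0 & sc <= 1))
  }
})

test_that("analytic gradients match finite differences for all three models", {
  for (kind in c("diagnosis_rnn", "exam_dense", "dual_input")) {
    m <- build_model(tiny_spec(kind), seed = 3)
    # jitter every parameter away from zero so no relu/gate preactivation
    # sits exactly at a kink, where finite differences are undefined
    set.seed(99)
    m$params <- lapply(m$params, function(p) p + rnorm(length(p), 0, 0.1))
    d <- tiny_data(5, 4, kind)
    nd <- strokehr:::nn_data(d, kind)
    w <- c(1.2, 5.2, 1.2, 5.2, 1.2)
    call_loss <- function(params, grad) {
      strokehr:::nn_call(kind, params, nd, 1:5, nd$y, w, grad = grad)
    }
    g <- call_loss(m$params, TRUE)$grads
    eps <- 1e-6
    for (k in names(m$params)) {
      for (j in seq_len(min(length(m$params[[k]]), 4))) {
        pp <- m$params; pp[[k]][j] <- pp[[k]][j] + eps
        pm <- m$params; pm[[k]][j] <- pm[[k]][j] - eps
        num <- (call_loss(pp, FALSE)$loss - call_loss(pm, FALSE)$loss) / (2 * eps)
        expect_equal(as.numeric(g[[k]])[j], num, tolerance = 1e-5,
                     label = paste(kind, k, j))
      }
    }
  }
})

test_that("leading all-zero padding never changes the recurrent model's output", {
  spec <- tiny_spec("diagnosis_rnn")
  m <- build_model(spec, seed = 5)
  d <- tiny_data(6, 6, "diagnosis_rnn")
  base <- predict_scores(m, d)
  pad <- list(x = array(0, c(6, 7, 3)), mask = cbind(matrix(0, 6, 3), d$mask),
              y = d$y)
  pad$x[, 4:7, ] <- d$x
  class(pad) <- "instance_set"
  expect_equal(predict_scores(m, pad), base, tolerance = 1e-12)

  # an all-padding input still yields a valid distribution
  allpad <- list(x = array(0, c(2, 4, 3)), mask = matrix(0, 2, 4), y = c(0, 1))
  class(allpad) <- "instance_set"
  sc <- predict_scores(m, allpad)
  expect_true(all(is.finite(sc)))
})

test_that("the dual model's parameters are the branch parameters plus fusion head", {
  m1 <- build_model(tiny_spec("diagnosis_rnn"), seed = 1)
  m2 <- build_model(tiny_spec("exam_dense"), seed = 1)
  m3 <- build_model(tiny_spec("dual_input"), seed = 1)
  branch1 <- sum(lengths(m1$params[strokehr:::gru_param_names()]))
  branch2 <- sum(lengths(m2$params[strokehr:::mlp_param_names()]))
  fusion <- sum(lengths(m3$params[c("Wf", "bf", "Wo", "bo")]))
  expect_equal(sum(lengths(m3$params)), branch1 + branch2 + fusion)
})

test_that("weight transfer copies matching layers exactly and reports them", {
  m1 <- build_model(tiny_spec("diagnosis_rnn"), seed = 1)
  m2 <- build_model(tiny_spec("exam_dense"), seed = 2)
  m3 <- transfer_weights(build_model(tiny_spec("dual_input"), seed = 3), m1, m2)
  moved <- attr(m3, "transferred")
  expect_setequal(moved, c(strokehr:::gru_param_names(),
                           strokehr:::mlp_param_names()))
  for (k in strokehr:::gru_param_names())
    expect_identical(m3$params[[k]], m1$params[[k]])
  for (k in strokehr:::mlp_param_names())
    expect_identical(m3$params[[k]], m2$params[[k]])

  # mismatched widths transfer nothing, with a warning
  wide <- build_model(model_spec("diagnosis_rnn", recurrent_width = 6L,
                                 diag_dim = 3L, diag_len = 4L), seed = 1)
  expect_warning(
    m3b <- transfer_weights(build_model(tiny_spec("dual_input"), seed = 3),
                            wide, NULL),
    "nothing transferred")
  expect_length(attr(m3b, "transferred"), 0)
})

test_that("after transfer the dual branches reproduce the source activations", {
  m1 <- build_model(tiny_spec("diagnosis_rnn"), seed = 1)
  m2 <- build_model(tiny_spec("exam_dense"), seed = 2)
  m3 <- transfer_weights(build_model(tiny_spec("dual_input"), seed = 9), m1, m2)
  d <- tiny_data(8, 10, "dual_input")
  acts <- strokehr:::branch_activations(m3, d)
  d1 <- list(x = d$x_d, mask = d$mask_d, y = d$y); class(d1) <- "instance_set"
  d2 <- list(x = d$x_e, mask = d$mask_e, y = d$y); class(d2) <- "instance_set"
  expect_equal(acts$diagnosis, strokehr:::branch_activations(m1, d1),
               tolerance = 1e-12)
  expect_equal(acts$exam, strokehr:::branch_activations(m2, d2),
               tolerance = 1e-12)
})

test_that("training is deterministic under a fixed seed", {
  d <- tiny_data(40, 20, "exam_dense")
  v <- tiny_data(20, 21, "exam_dense")
  cfg <- train_config(epochs = 5, seed = 7)
  a <- train_model(build_model(tiny_spec("exam_dense"), seed = 7), d, v, cfg)
  b <- train_model(build_model(tiny_spec("exam_dense"), seed = 7), d, v, cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("a high-capacity model overfits a 20-instance toy set", {
  d <- tiny_data(20, 30, "exam_dense")
  spec <- model_spec("exam_dense", td_width = 8L, dense_widths = c(16L, 8L),
                     exam_dim = 4L, exam_len = 3L)
  m <- train_model(build_model(spec, seed = 1), d, d,
                   train_config(epochs = 500, seed = 1, loss = "ce"))
  sc <- predict_scores(m, d)
  # per-example cross-entropy near its attainable minimum
  ce <- mean(-log(ifelse(d$y == 1, sc, 1 - sc)))
  expect_lt(ce, 1e-2)
  expect_equal(as.integer(sc > 0.5), d$y)
})

test_that("all-negative training labels under plain CE collapse to negative predictions", {
  d <- tiny_data(40, 31, "exam_dense")
  d$y <- rep(0L, 40)
  m <- train_model(build_model(tiny_spec("exam_dense"), seed = 2), d, d,
                   train_config(epochs = 100, seed = 2, loss = "ce"))
  expect_true(all(predict_scores(m, d) < 0.5))
})

test_that("batch prediction equals per-instance prediction", {
  m <- build_model(tiny_spec("diagnosis_rnn"), seed = 4)
  d <- tiny_data(9, 40, "diagnosis_rnn")
  all_at_once <- predict_scores(m, d)
  one_by_one <- vapply(1:9, function(i) {
    di <- list(x = d$x[i, , , drop = FALSE], mask = d$mask[i, , drop = FALSE],
               y = d$y[i])
    class(di) <- "instance_set"
    predict_scores(m, di)
  }, 0)
  expect_equal(all_at_once, one_by_one, tolerance = 1e-12)
})

test_that("frozen parameters stay at their transferred values during training", {
  m1 <- build_model(tiny_spec("diagnosis_rnn"), seed = 1)
  m3 <- transfer_weights(build_model(tiny_spec("dual_input"), seed = 2), m1, NULL)
  d <- tiny_data(30, 50, "dual_input")
  frz <- strokehr:::gru_param_names()
  tr <- train_model(m3, d, d, train_config(epochs = 4, seed = 3, freeze = frz))
  for (k in frz) expect_identical(tr$params[[k]], m1$params[[k]])
  expect_false(identical(tr$params$Wf, m3$params$Wf))
})
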